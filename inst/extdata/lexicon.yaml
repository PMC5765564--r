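# Default effect-size term lexicon.
#
# Acronyms are matched case-sensitively at word boundaries; full wordings are
# matched case-insensitively and tolerate plural, hyphen, and spacing
# variants.  trap_phrases are full wordings that reuse an ES acronym for a
# non-effect-size quantity; their presence anywhere in a text switches
# detection of that acronym to restrictive mode.
es_terms:
  OR:
    acronyms: ["OR"]
    adjusted_acronyms: ["aOR", "adjOR"]
    wordings: ["odds ratio"]
  RR:
    acronyms: ["RR"]
    adjusted_acronyms: ["aRR", "adjRR"]
    wordings: ["relative risk", "risk ratio", "rate ratio"]
  HR:
    acronyms: ["HR"]
    adjusted_acronyms: ["aHR", "adjHR"]
    wordings: ["hazard ratio"]
trap_phrases:
  HR: ["heart rate"]
  RR: ["respiratory rate", "response rate"]
  OR: ["ovulation rate", "operating room"]
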