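---
title: "Mining ratio effect sizes from biomedical abstracts and testing their temporal trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining ratio effect sizes from biomedical abstracts and testing their temporal trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmine)
```

## The problem

Ratio effect sizes — odds ratios (OR), risk/rate ratios (RR), and hazard
ratios (HR) — are the dominant association measures of epidemiology and
clinical research, and abstracts routinely print them together with a
confidence interval: `aOR = 2.5 (95% CI, 1.5-4.2)`. Meta-research questions
about how these numbers evolve (are published effects shrinking? are they
more often statistically significant?) require extracting millions of such
statements from citation databases, condensing them to per-abstract
outcomes, and testing monotonic trends in the resulting monthly series.

`esmine` implements that pipeline end to end for MEDLINE/PubMed citation
XML (and JATS full text), plus a synthetic-corpus generator that plants
statements with exact ground truth so every stage can be validated without
downloading anything.

## Detection model

Detection is windowed pattern matching, not sentence-level NLP. A
statement is an ES term, followed by a numeric value, followed by an
optional confidence interval:

* **Terms.** Acronyms (`OR`, `RR`, `HR`, and adjusted variants `aOR`,
  `aRR`, `aHR`) are matched case-sensitively at word boundaries; full
  wordings (`odds ratio`, `hazard-ratios`, ...) case-insensitively,
  tolerating plural, hyphen and spacing variants, with an optional
  `adjusted`/`multivariable` modifier marking adjusted estimates. The
  lexicon is a YAML file users can extend.
* **Statement window.** The value must be the first plausible number
  within 80 characters after the term, with no second ES term in between
  (so in `odds ratio (OR) was 2.5` only the defining acronym pairs with
  the value and exactly one mention is emitted). Percentages and 4-digit
  year-like integers are never candidate values, and a number inside an
  already-started CI (`OR (95% CI 1.5-4.2)`) is not a value. The CI is
  then parsed from up to 120 characters after the value, truncated at the
  next ES term. No window sizes are claimed to be canonical; they were
  chosen to cover the common styles while limiting false pairing, and both
  are arguments of `detect_es_mentions()`.
* **CI dialects.** Introducers `95% CI`, `95%CI`, `CI 95%`,
  `95 % confidence interval`, bare `CI`/`confidence interval`, optional
  `:`/`,`/`=`; brackets `()`, `[]`, or none; range separators `-` (all
  Unicode dashes are normalized first), `to`, `;`, and `,` (the comma form
  only inside brackets); the level may precede or follow the limits.
  Decimal commas (`1,23`) are converted only when both bounds match the
  pattern. An unbracketed range with no introducer is never a CI, and a
  bracketed bare range must sit directly after the value. A CI with no
  stated level is assigned 95 — by far the dominant convention — and
  flagged `ci_level_default`. Bounds parsing reversed (lower > upper)
  discards the CI and flags `bounds_swapped_discarded`.
* **Polysemy traps.** Many clinical abbreviations collide with the ES
  acronyms: heart rate (HR), respiratory or response rate (RR), ovulation
  rate or operating room (OR). If a trap wording occurs *anywhere* in a
  text, detection of that acronym — and only that acronym — enters
  restrictive mode: bare-acronym mentions are suppressed; the full wording,
  or an adjusted acronym carrying a CI, is still emitted and flagged
  `restrictive_mode`. This deliberately trades a little sensitivity for
  specificity, since a single false-positive statement contaminates an
  abstract, and it is the main source of false negatives in validation.
* **Plausibility filter.** Purely numeric, applied after detection: values
  above a ceiling (default 10 000) are dropped, and when a CI is present
  the value must satisfy `lower <= value <= upper` within a relative
  tolerance (default 5% of the value, absorbing rounded limits). Values
  are never modified, removals are returned with reasons. Effect sizes
  expressed per unit of a continuous variable are *not* filtered out.

Both crude and adjusted estimates are kept, and repeated identical values
are not deduplicated: the unit of extraction is the printed statement.

## Transformations and per-abstract outcomes

Ratio effect sizes live on a log scale: protective values in (0, 1), risk
values in (1, ∞). Four value transformations are provided by
`transform_es()`: `T4` identity, `T2` = ln v (normalized), `T1` = v for
v ≥ 1 and 1/v otherwise (standardized, original scale), and
`T3` = exp(|ln v|) (standardized via the log scale). T1 and T3 coincide
pointwise and differ only in how aggregates are formed — T3 outcomes are
aggregated on the log scale. This four-way mapping is a reconstruction
from the reported figure scales ("original log scale", "linear scale",
"mean after logarithmic transformation"), not a transcription of a printed
formula table, and should be read as such.

Classification (`classify_es()`): direction is risk (> 1), protective
(< 1) or neutral (= 1); magnitude is *large* when v ≤ 0.2 or v ≥ 5 and
*tiny* when 0.95 ≤ v ≤ 1.05 (inclusive bounds), with exactly 1 kept
neutral rather than tiny; an estimate is statistically significant iff its
CI excludes 1, a limit exactly equal to 1 counting as encompassing (the
conservative reading). CI magnitude is the ratio U/L — the log-scale width
mapped back to the linear scale — which is invariant under the
protective/risk inversion (L, U) → (1/U, 1/L).

`condense_abstracts()` reduces each abstract to: `es_min`/`es_max` (the
value nearest to and farthest from 1, measured in |ln| distance so the
extremes are well defined when protective and risk values coexist),
`es_mean` = exp(mean |ln v|), the same three reductions of ln(U/L) for CI
magnitudes, and the significance outcomes (any, and the proportion over
mentions with a CI). The primary profile keeps non-review abstracts and
95% CIs only — reviews would overrepresent values, and magnitude
comparisons need one CI level; review-only or 90/99%-CI subgroups reuse
the same condensation with a different filter, never a different formula.
Months are indexed from 1990-01 (index 0) through 2015-12 (index 311); a
citation whose month cannot be determined (`MedlineDate` without a month
token) is excluded from monthly series rather than imputed, since imputing
dates would fabricate trend signal.

## Trend statistics

`mann_kendall()` implements the Mann-Kendall test: S = Σ~i<j~
sign(v~j~ − v~i~), tie-corrected variance
varS = [n(n−1)(2n+5) − Σ~t~ t(t−1)(2t+5)]/18, z with ±1 continuity
correction, and two-sided p from the normal approximation (enforced
minimum n = 8, configurable). τ defaults to tau-b (tie-adjusted
denominator) because monthly medians tie frequently; tau-a is exposed for
sensitivity analyses since published τ values do not always state their
variant. The implementation is cross-checked in the test suite against an
exhaustive pair-enumeration oracle (all series of length ≤ 10 over
{1, 2, 3}) and against the Kendall correlation with time.

Group comparisons follow the same nonparametric house style:
`rank_tests()` wraps the Mann-Whitney test (exact for small untied
samples, normal approximation otherwise, via `stats::wilcox.test`) and
Kruskal-Wallis with Dunn's z-based pairwise comparisons. Dunn p-values are
Bonferroni-adjusted by default (the adjustment method is an argument), and
a compact letter display is derived from maximal cliques of the
nonsignificance graph — exact for the small group counts (continents) used
here. The significance threshold for all verdicts is P < 0.001; loess
curves in `plot_monthly_trend()` are presentation only and never feed a
verdict.

## The synthetic corpus

`generate_corpus()` emulates the statistical structure the analyses
target, with exact ground truth:

* |ln ES| is half-normal with sign ±1 equiprobable; the scale
  interpolates linearly across the configured month range. The defaults
  (1.36 → 1.11) make the median standardized ES fall from about 2.50 to
  about 2.11 over 1990–2015, matching the reported period medians.
* CIs are geometric around the value, L = v·e^−w^, U = v·e^+w^, which
  preserves the inversion symmetry the transforms assume. The log
  half-width drifts (defaults 0.70 → 0.54, the widths implied by the
  reported 95% CI limit medians), and when a significance target is set
  (defaults 0.74 → 0.85) the half-width is adapted per mention so the CI
  excludes or spans 1 as drawn.
* Rendered sentences are drawn from 12 templates covering acronym vs full
  wording, adjusted variants, separator and bracket dialects, en-dash and
  "to" ranges, level placement before/after/omitted, and decimal precision
  1–3. The printed (rounded) numbers are the ground truth, so the gold
  table records exactly what the text says; if rounding would undo a drawn
  significance status, the printed bound is nudged by one unit in the last
  digit so the statement realizes the draw. A dedicated `undetectable`
  style separates the value from its term beyond any reasonable pairing
  window; it is planted but excluded from sensitivity scoring.
* Trap sentences are inserted at a configurable rate (default 0.10),
  journals (with synthetic open-access and core-clinical flags), review
  status, MeSH descriptors, and country affiliations (about 5%
  cross-continental) complete the metadata. Abstract counts default to 7
  per month over 312 months — 2184 abstracts, enough to resolve the
  validation thresholds while keeping the battery fast — with half the
  abstracts carrying 1–8 statements (geometric, mean ≈ 2.9).
* Generation is deterministic: each abstract derives a counter-based
  substream from the master seed, so corpora are byte-identical across
  runs and insensitive to evaluation order.

What the generator does **not** emulate: linguistic variety beyond the
template mix, non-English abstracts, OCR noise, real MeSH indexing depth,
or era-accurate journal metadata. Passing validation on this corpus
therefore demonstrates that the grammar covers the encoded style space
and that the statistics behave as designed — it bounds, but does not
measure, performance on real PubMed text.

Calibration of the significance share is checked at the run level: the
mean over months of the detector-derived significant share tracks the
configured schedule to within ±3 percentage points. Individual months
cannot be held to that band — with tens of mentions per month the
binomial noise alone exceeds it.

## Validation battery and problem sizes

The acceptance checks in `tests/testthat/test-acceptance.R` use, as the
package's own choices: a 2184-abstract corpus at the default mixture for
detector validation (mention-level sensitivity ≥ 0.95, abstract-level
specificity ≥ 0.999, mirroring the validation thresholds reported for the
original mining algorithm); exhaustive Mann-Kendall oracle comparison on
all 88 569 series of length ≤ 10 over {1, 2, 3}; 10 000 null series of
length 312 for size control at α = 0.001 (empirical rejection ≤ 0.2%,
conservative by construction of the continuity correction); end-to-end
trend recovery on a 312 × 30 corpus with the default drift, and a
no-drift corpus that must not be rejected; and the condensation
invariants (inversion equivariance, T3 symmetry, min ≤ mean ≤ max) on
10 000 random abstracts. `scripts/acceptance.R` regenerates the
validation corpus from a command-line seed and recomputes the two
detector quantities from scratch.

A further replication check runs the condensation and trend battery over
the publicly deposited effect-size database (a one-time download placed
under `replication/`); it verifies the printed period medians, the
significance proportions, and the reported τ values. Without that local
file the check fails rather than silently passing.

## Known limitations and open choices

* The detection grammar is a re-derivation targeted at the published
  validation thresholds, not a byte-level port of the original (Perl)
  rules; the exact windows and trap list beyond the documented examples
  are this package's choices, shipped as editable configuration.
* Open-access status is defined as membership in a user-supplied journal
  list (a small synthetic example ships with the package): era-accurate
  OA status is a data problem, not an algorithm problem, and any
  authoritative list can be dropped in. The core-clinical-journal default
  carries the well-known Abridged Index Medicus titles; the shipped MeSH
  map is an illustrative subset of the NLM tree.
* Only OR/RR/HR are detected; other metrics (Cohen's d, correlations) and
  conversions between metrics are out of scope, as is autocorrelation- or
  seasonality-corrected trend testing (Hamed-Rao and seasonal
  Mann-Kendall variants are deliberately not implemented).
* `parse_pubmed_citations()` parses one file into memory rather than
  streaming SAX-style; corpora are processed shard by shard, which keeps
  memory bounded by the largest shard (the NLM baseline ships in ~30 MB
  shards). Only the English `AbstractText` channel is read.
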