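# esmine

Mining ratio effect sizes from the biomedical literature and testing
their temporal trends.

Epidemiology and clinical research report associations as odds ratios
(OR), risk/rate ratios (RR), and hazard ratios (HR), usually printed with
a confidence interval: `aOR = 2.5 (95% CI, 1.5-4.2)`. Meta-researchers
who want to know how these numbers evolve across the literature — are
published effects shrinking? are they more often statistically
significant? — need to extract such statements at scale from
MEDLINE/PubMed citations, condense them to per-abstract outcomes, and
test monotonic trends in the monthly series. `esmine` is that pipeline:

* **Detection** — a windowed grammar pairs each ES term with its value
  and CI, tolerant of wording/bracket/separator dialects, guarded against
  acronym polysemy ("heart rate" for HR, "respiratory rate" for RR,
  "ovulation rate" or "operating room" for OR) and implausible numerics.
* **Annotation** — multivariate-analysis evidence, review status,
  open-access and core-clinical-journal membership, continents of author
  affiliation, MeSH research fields (branches C and G).
* **Condensation** — per-abstract outcomes on the log-ratio scale:
  standardized ES min/max/mean (`exp(mean |ln v|)`), CI magnitudes
  (`U/L`), and significance (CI excluding 1).
* **Trend statistics** — the Mann-Kendall test
  (S = Σ<sub>i&lt;j</sub> sign(v<sub>j</sub> − v<sub>i</sub>),
  tie-corrected variance, continuity-corrected z, tau-b), plus
  Mann-Whitney and Kruskal-Wallis/Dunn group comparisons with compact
  letter displays, all at the P &lt; 0.001 house threshold.
* **Synthetic corpus** — a deterministic generator that plants ES
  statements with known ground truth (drifting magnitudes, CI widths and
  significance shares; trap sentences; citation metadata) and writes
  valid PubmedArticleSet XML, so detector sensitivity/specificity and
  Cohen's κ, and end-to-end trend recovery, are measurable without any
  download.

## Worked example

```r
library(esmine)

lex <- compile_lexicon()
detect_es_mentions(
  "The adjusted odds ratio (aOR) was 2.5 (95% CI, 1.5-4.2), while heart rate (HR) was 72 (95% CI, 68-76).",
  lex
)
#> # A tibble: 1 × 10
#>   source_id es_type adjusted value ci_level ci_lower ci_upper span_start
#>   <chr>     <chr>   <lgl>    <dbl>    <int>    <dbl>    <dbl>      <int>
#> 1 <NA>      OR      TRUE       2.5       95      1.5      4.2         26
```

One mention: the `aOR` statement, typed OR, flagged adjusted, with its
95% CI — and nothing for the heart-rate sentence, because "heart rate"
switches HR detection into restrictive mode.

A full round trip on a synthetic corpus (624 abstracts over 1990–2015,
two per month, with planted ground truth):

```r
corp     <- generate_corpus(sim_config(abstracts_per_month = 2, seed = 42))
mentions <- apply_plausibility_filter(detect_es(corp$citations, lex), quiet = TRUE)
evaluate_detection(corp$gold, mentions, unit = "mention")
#> # A tibble: 1 × 8
#>   unit       tp    fp    tn    fn sensitivity specificity kappa
#>   <chr>   <int> <int> <int> <int>       <dbl>       <dbl> <dbl>
#> 1 mention   878     0    74    30       0.967           1 0.815
```

The detector recovers 96.7% of planted statements (the misses are
bare-acronym statements suppressed by trap sentences in the same
abstract — the deliberate specificity trade) with zero false positives.
Condensing to per-abstract outcomes and testing the monthly medians:

```r
ann <- annotate_citations(corp$citations, mentions, load_resources())
sm  <- condense_abstracts(mentions, ann)
mann_kendall(monthly_series(sm, "es_mean", "median"))
#> Mann-Kendall trend test (tau-b)
#>   n = 213, S = -2153, varS = 1081228.33
#>   tau = -0.0954, z = -2.070, p = 0.0385
```

The planted downward drift in |ln ES| shows up as a negative tau; at two
abstracts per month the monthly medians are noisy, so the evidence is
weak — at the 30-abstracts-per-month scale used in the validation suite
the same drift is recovered at p &lt; 0.001.

`run_pipeline()` chains extract → annotate → condense → trends over XML
files and writes the interchange TSV tables (mentions, annotated
citations, abstract summaries, trend report, and — when gold truth is
supplied — the performance report); `inst/cli/esmine.R` is a thin
command-line wrapper around the same functions.

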