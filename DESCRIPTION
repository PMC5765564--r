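Package: esmine
Title: Mining Effect Sizes from the Biomedical Literature and Testing
    Their Temporal Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ratio effect sizes (odds ratios, risk ratios, hazard
    ratios) together with their confidence intervals in MEDLINE/PubMed
    abstracts and PMC full text, guarding against acronym polysemy (for
    example "heart rate" reusing HR) and implausible numerics. Annotates
    citations with multivariate-analysis, review, open-access and
    core-clinical-journal status, continents of affiliation, and MeSH
    research fields; condenses the detected effect sizes to per-abstract
    outcomes on the log-ratio scale; and tests monotonic temporal trends of
    monthly summaries with the Mann-Kendall test, plus Mann-Whitney and
    Kruskal-Wallis/Dunn group comparisons. A deterministic synthetic-corpus
    generator plants effect-size statements with known ground truth so the
    whole pipeline can be validated (sensitivity, specificity, Cohen's
    kappa) without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
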