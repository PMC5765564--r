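test_that("rendering styles instantiate their templates", {
  truth <- list(
    es_type = "OR", adjusted = FALSE, value = 1.9, ci_level = 95L,
    ci_lower = 1.1, ci_upper = 3.3, digits = 1L
  )
  expect_equal(
    render_mention(truth, "acr_eq_paren"), "OR = 1.9 (95% CI 1.1-3.3)."
  )
  hr <- list(
    es_type = "HR", adjusted = FALSE, value = 0.80, ci_level = 95L,
    ci_lower = 0.70, ci_upper = 0.91, digits = 2L
  )
  expect_equal(
    render_mention(hr, "full_prose"),
    "The hazard ratio was 0.80 (95% confidence interval: 0.70 to 0.91)."
  )
  expect_gte(length(setdiff(names(mention_styles()), "undetectable")), 8L)
  expect_error(render_mention(truth, "nope"), "unknown rendering style")
})

test_that("every detectable style round-trips through the detector exactly", {
  lx <- fixture_lexicon()
  styles <- setdiff(names(mention_styles()), "undetectable")
  cases <- expand.grid(
    style = styles,
    es_type = c("OR", "RR", "HR"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    st <- cases$style[i]
    truth <- list(
      es_type = cases$es_type[i],
      adjusted = st %in% c("adj_acr", "adj_full_square"),
      value = 0.73, ci_level = if (st == "no_level") 95L else 99L,
      ci_lower = 0.55, ci_upper = 0.97, digits = 2L
    )
    sent <- render_mention(truth, st)
    m <- detect_es_mentions(paste("Filler first.", sent), lx)
    expect_equal(nrow(m), 1L, info = st)
    expect_equal(m$es_type, truth$es_type, info = st)
    expect_equal(m$value, truth$value, info = st)
    expect_equal(m$ci_level, truth$ci_level, info = st)
    expect_equal(m$ci_lower, truth$ci_lower, info = st)
    expect_equal(m$ci_upper, truth$ci_upper, info = st)
    expect_equal(m$adjusted, truth$adjusted, info = st)
  }

  # the undetectable style never yields a mention
  und <- render_mention(
    list(
      es_type = "OR", adjusted = FALSE, value = 1.9, ci_level = 95L,
      ci_lower = 1.1, ci_upper = 3.3, digits = 1L
    ),
    "undetectable"
  )
  expect_equal(nrow(detect_es_mentions(und, lx)), 0L)
})

test_that("generation is byte-identical under one seed", {
  cfg <- sim_config(months = 0:5, abstracts_per_month = 4, seed = 123)
  d1 <- file.path(tempdir(), "sim1")
  d2 <- file.path(tempdir(), "sim2")
  c1 <- generate_corpus(cfg, dir = d1)
  c2 <- generate_corpus(cfg, dir = d2)
  expect_identical(c1$citations, c2$citations)
  expect_identical(c1$gold, c2$gold)
  expect_identical(readLines(c1$paths$xml), readLines(c2$paths$xml))
  expect_identical(readLines(c1$paths$gold), readLines(c2$paths$gold))

  c3 <- generate_corpus(sim_config(
    months = 0:5, abstracts_per_month = 4, seed = 124
  ))
  expect_false(identical(c1$citations$abstract_text, c3$citations$abstract_text))
})

test_that("degenerate configurations are forced by construction", {
  # every abstract a trap, none planted
  trap_cfg <- sim_config(
    months = 0:2, abstracts_per_month = 5, p_has_es = 0,
    trap_rate = 1, seed = 9
  )
  tc <- generate_corpus(trap_cfg)
  expect_true(all(!tc$gold$planted))
  expect_equal(nrow(tc$gold), 15L)

  # fixed ES count of 2: exact planted total
  two_cfg <- sim_config(
    months = 0:11, abstracts_per_month = 10, p_has_es = 1,
    es_count_probs = c(0, 1), trap_rate = 0, seed = 10
  )
  two <- generate_corpus(two_cfg)
  expect_equal(sum(two$gold$planted), 240L)

  expect_error(sim_config(months = 500), "months")
  expect_error(sim_config(style_probs = c(bogus = 1)), "unknown style")
})

test_that("a trap-only corpus yields zero mentions (specificity 1)", {
  cfg <- sim_config(
    months = 0:11, abstracts_per_month = 10, p_has_es = 0,
    trap_rate = 1, seed = 31
  )
  corp <- generate_corpus(cfg)
  m <- detect_es(corp$citations, fixture_lexicon())
  expect_equal(nrow(m), 0L)
  perf <- evaluate_detection(
    corp$gold, m,
    unit = "abstract", source_ids = corp$citations$pmid
  )
  expect_equal(perf$specificity, 1)
})

test_that("detectable-only, trap-free corpora are recovered exactly", {
  probs <- default_style_probs()
  probs["undetectable"] <- 0
  cfg <- sim_config(
    months = seq(0, 300, by = 20), abstracts_per_month = 8,
    trap_rate = 0, style_probs = probs, seed = 77
  )
  corp <- generate_corpus(cfg)
  m <- apply_plausibility_filter(
    detect_es(corp$citations, fixture_lexicon()),
    quiet = TRUE
  )
  perf <- evaluate_detection(corp$gold, m, unit = "mention")
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$fp, 0L)
  expect_equal(perf$kappa, 1)
})

test_that("planted significance share tracks the configured schedule", {
  cfg <- sim_config(
    months = 0:99, abstracts_per_month = 10,
    p_significant_start = 0.60, p_significant_end = 0.90, seed = 55
  )
  corp <- generate_corpus(cfg)
  g <- corp$gold[which(corp$gold$planted), ]
  sig <- classify_es(g$value, g$ci_lower, g$ci_upper)$significant
  # drift is interpolated across the configured month range
  frac <- g$month_index / 99
  target <- 0.60 + (0.90 - 0.60) * frac
  expect_lt(abs(mean(sig) - mean(target)), 0.03)
})
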