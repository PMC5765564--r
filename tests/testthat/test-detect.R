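lex <- NULL
setup_lex <- function() {
  if (is.null(lex)) lex <<- fixture_lexicon()
  lex
}

test_that("an adjusted full wording with defining acronym gives one mention", {
  m <- detect_es_mentions(
    "The adjusted odds ratio (aOR) was 2.5 (95% CI, 1.5-4.2).", setup_lex()
  )
  expect_equal(nrow(m), 1L)
  expect_equal(m$es_type, "OR")
  expect_true(m$adjusted)
  expect_equal(m$value, 2.5)
  expect_equal(m$ci_level, 95L)
  expect_equal(m$ci_lower, 1.5)
  expect_equal(m$ci_upper, 4.2)
})

test_that("trap wordings suppress the bare acronym (polysemy guard)", {
  m <- detect_es_mentions(
    "Heart rate (HR) was 72 (95% CI, 68-76) at rest.", setup_lex()
  )
  expect_equal(nrow(m), 0L)

  # restrictive mode is per-acronym: OR here is unaffected by heart rate
  m2 <- detect_es_mentions(
    paste(
      "Heart rate (HR) was 72 (95% CI, 68-76) at rest.",
      "OR = 1.9 (95% CI 1.1-3.3).",
      "HR = 0.8 (95% CI 0.7-0.9)."
    ),
    setup_lex()
  )
  expect_equal(m2$es_type, "OR")
  expect_equal(m2$value, 1.9)

  # the full wording stays detectable in restrictive mode, flagged
  m3 <- detect_es_mentions(
    paste(
      "Heart rate was monitored.",
      "The hazard ratio was 0.80 (95% CI 0.70-0.91)."
    ),
    setup_lex()
  )
  expect_equal(m3$es_type, "HR")
  expect_match(m3$flags, "restrictive_mode")
})

test_that("several statements in one text are extracted in span order", {
  m <- detect_es_mentions(
    "RR = 0.80 (95% CI 0.70 to 0.91); OR = 1.9 (1.1-3.3)", setup_lex()
  )
  expect_equal(m$es_type, c("RR", "OR"))
  expect_equal(m$value, c(0.80, 1.9))
  expect_equal(m$ci_lower, c(0.70, 1.1))
  expect_equal(m$ci_upper, c(0.91, 3.3))
  expect_equal(m$ci_level, c(95L, 95L))
  # the bare bracketed range gets the default level, flagged
  expect_match(m$flags[2], "ci_level_default")
  expect_true(all(diff(m$span_start) > 0))
})

test_that("CI fragment dialects parse to canonical level and limits", {
  cases <- list(
    list(" (95% CI, 1.23-4.96)", 95L, 1.23, 4.96),
    list(" [99% confidence interval: 0.42 to 0.91]", 99L, 0.42, 0.91),
    list(" (95%CI 1.1-3.3)", 95L, 1.1, 3.3),
    list(" (CI 95%: 1.1-3.3)", 95L, 1.1, 3.3),
    list(" , 90% CI 0.8 to 1.2, adjusted", 90L, 0.8, 1.2),
    list(" (1.1-3.3; 95% CI)", 95L, 1.1, 3.3),
    list(" (95 % CI 1,23-4,96)", 95L, 1.23, 4.96) # decimal commas
  )
  for (cs in cases) {
    got <- parse_ci_fragment(cs[[1]])
    expect_false(is.null(got), info = cs[[1]])
    expect_equal(got$level, cs[[2]], info = cs[[1]])
    expect_equal(got$lower, cs[[3]], info = cs[[1]])
    expect_equal(got$upper, cs[[4]], info = cs[[1]])
  }

  expect_null(parse_ci_fragment(" no interval at all"))
  # unbracketed range without introducer is not a CI
  expect_null(parse_ci_fragment(" over 2010-2015 follow-up"))
  # reversed bounds are discarded, signalled upstream
  expect_identical(parse_ci_fragment(" (CI 1.10; 0.95)"), "swapped")
})

test_that("statement pairing respects windows and intervening terms", {
  # value beyond the statement window is not paired
  far <- paste0(
    "The OR ",
    paste(rep("in a very long qualifying clause", 6), collapse = " "),
    " was 1.9 (95% CI 1.1-3.3)."
  )
  expect_equal(nrow(detect_es_mentions(far, setup_lex())), 0L)

  # a second ES term between term and value blocks pairing of the first
  m <- detect_es_mentions("odds ratio (OR) = 2.5 (95% CI 1.5-4.2)", setup_lex())
  expect_equal(nrow(m), 1L)

  # CI-introducer numbers are never taken as the value
  m2 <- detect_es_mentions("OR (95% CI 1.5-4.2)", setup_lex())
  expect_equal(nrow(m2), 0L)

  # years are not candidate values
  m3 <- detect_es_mentions(
    "The OR in 2005 was 2.1 (95% CI 1.4-3.1).", setup_lex()
  )
  expect_equal(m3$value, 2.1)
})

test_that("detection is deterministic and span-faithful", {
  lx <- setup_lex()
  texts <- c(
    "aHR = 0.71 (95% CI, 0.55-0.93) after adjustment.",
    "The relative risk was 3.20 [90% CI 1.80-5.70].",
    "OR = 12.5 (95% CI 4.2-37.0); RR: 0.9 (0.7-1.1)."
  )
  for (txt in texts) {
    a <- detect_es_mentions(txt, lx)
    b <- detect_es_mentions(txt, lx)
    expect_identical(a, b)
    for (i in seq_len(nrow(a))) {
      sub <- substr(txt, a$span_start[i], a$span_end[i])
      re <- detect_es_mentions(sub, lx)
      expect_equal(re$value, a$value[i], info = sub)
      expect_equal(re$ci_lower, a$ci_lower[i], info = sub)
      expect_equal(re$ci_upper, a$ci_upper[i], info = sub)
    }
  }
})

test_that("unicode dashes and spaces are normalized before parsing", {
  m <- detect_es_mentions(
    "OR = 1.9 (95% CI 1.1–3.3).", setup_lex()
  )
  expect_equal(m$ci_lower, 1.1)
  expect_equal(m$ci_upper, 3.3)
})

test_that("plausibility filter drops by numeric rule only", {
  base <- random_mentions(1)[0, ]
  mk <- function(value, lo, hi, flags = "") {
    tibble::tibble(
      source_id = "A", es_type = "OR", adjusted = FALSE, value = value,
      ci_level = ifelse(is.na(lo), NA_integer_, 95L),
      ci_lower = lo, ci_upper = hi,
      span_start = 1L, span_end = 10L, flags = flags
    )
  }
  m <- dplyr::bind_rows(
    mk(2.5, 1.5, 4.2),            # consistent: kept
    mk(5.0, 1.2, 3.0),            # value outside CI: dropped
    mk(72, 68, 76),               # numeric check only: kept
    mk(20000, NA, NA, "no_ci"),   # above ceiling: dropped
    mk(3.0, NA, NA, "no_ci"),     # no CI: kept, still flagged
    mk(1.04, 0.999, 1.08)         # within 5% rounding tolerance: kept
  )
  kept <- apply_plausibility_filter(m, quiet = TRUE)
  expect_equal(kept$value, c(2.5, 72, 3.0, 1.04))
  removed <- attr(kept, "removals")
  expect_equal(sort(removed$reason), c("value_above_ceiling", "value_outside_ci"))
  # values are never modified
  expect_equal(kept$ci_lower[1], 1.5)
})
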