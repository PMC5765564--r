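test_that("the four transformations follow their definitions", {
  expect_equal(transform_es(0.5, "T3"), 2.0)
  expect_equal(transform_es(1.0, "T3"), 1.0)
  expect_equal(transform_es(1.0, "T2"), 0.0)
  expect_equal(transform_es(2.5, "T1"), 2.5)
  expect_equal(transform_es(0.4, "T1"), 2.5)
  expect_equal(transform_es(c(0.25, 4), "T4"), c(0.25, 4))
  expect_equal(transform_es(exp(-2), "T2"), -2)
  # T1 and T3 coincide pointwise
  v <- c(0.1, 0.5, 1, 1.7, 20)
  expect_equal(transform_es(v, "T1"), transform_es(v, "T3"))
  expect_error(transform_es(-1, "T3"), "positive")
})

test_that("classification partitions direction and magnitude", {
  cls <- classify_es(c(2.50, 0.63, 1, 5, 0.2, 1.02, 0.95, 1.05, 3))
  expect_equal(cls$direction, c(
    "risk", "protective", "neutral", "risk", "protective", "risk",
    "protective", "risk", "risk"
  ))
  expect_equal(cls$magnitude, c(
    "other", "other", "other", "large", "large", "tiny", "tiny", "tiny",
    "other"
  ))
  # exactly 1 is neutral, not tiny; tiny and large are disjoint by range
  expect_false(any(cls$magnitude == "tiny" & cls$magnitude == "large"))
  expect_equal(cls$magnitude[3], "other")
})

test_that("significance means the CI excludes 1, limits included", {
  cls <- classify_es(
    value = c(2.5, 1.5, 0.8, 0.8, 1.2),
    ci_lower = c(1.23, 1.0, 0.7, 0.65, NA),
    ci_upper = c(4.96, 2.2, 0.9, 1.0, NA)
  )
  expect_equal(cls$significant, c(TRUE, FALSE, TRUE, FALSE, NA))
  expect_error(classify_es(2, 1.5, NA), "together")
})

test_that("CI magnitude is the limit ratio, inversion-invariant", {
  expect_equal(ci_magnitude(1, 4), 4)
  expect_equal(ci_magnitude(0.5, 2), 4)
  expect_equal(ci_magnitude(1.23, 4.96), 4.96 / 1.23)
  l <- runif(20, 0.2, 1.5)
  u <- l * exp(runif(20, 0.1, 2))
  expect_equal(ci_magnitude(1 / u, 1 / l), ci_magnitude(l, u))
  expect_error(ci_magnitude(-1, 2), "positive")
})

fixture_annotation <- function(ids, review = FALSE) {
  tibble::tibble(
    pmid = ids,
    pub_year = 1995L, pub_month = 6L,
    multivariate = FALSE, review = review,
    open_access = FALSE, core_clinical = FALSE,
    continents = replicate(length(ids), "Europe", simplify = FALSE),
    fields = replicate(length(ids), "C04", simplify = FALSE),
    abstract_text = "x"
  )
}

mention_rows <- function(id, value, lo, hi, level = 95L) {
  tibble::tibble(
    source_id = id, es_type = "OR", adjusted = FALSE, value = value,
    ci_level = level, ci_lower = lo, ci_upper = hi,
    span_start = 1L, span_end = 10L, flags = ""
  )
}

test_that("condensation reduces mentions per the log-scale outcomes", {
  # |ln 2| = |ln 0.5|: min = max = mean = 2 on the standardized scale
  m <- dplyr::bind_rows(
    mention_rows("A", 2.0, 1.5, 2.7),
    mention_rows("A", 0.5, 0.3, 0.8)
  )
  sm <- condense_abstracts(m, fixture_annotation("A"))
  expect_equal(sm$es_min, 2.0)
  expect_equal(sm$es_max, 2.0)
  expect_equal(sm$es_mean, 2.0)
  expect_equal(sm$prop_significant, 1.0)
  expect_equal(sm$month_index, (1995 - 1990) * 12 + 5)

  # singleton: min = max = mean
  s1 <- condense_abstracts(
    mention_rows("B", 1.9, 1.1, 3.3), fixture_annotation("B")
  )
  expect_equal(s1$es_min, 1.9)
  expect_equal(s1$es_max, 1.9)
  expect_equal(s1$es_mean, 1.9)
  expect_true(s1$any_significant)

  # mixed significance
  s2 <- condense_abstracts(
    dplyr::bind_rows(
      mention_rows("C", 1.2, 0.9, 1.6),
      mention_rows("C", 3.0, 2.0, 4.5)
    ),
    fixture_annotation("C")
  )
  expect_equal(s2$prop_significant, 0.5)
  expect_true(s2$any_significant)
  expect_equal(s2$cimag_mean, exp(mean(log(c(1.6 / 0.9, 4.5 / 2)))))
})

test_that("review and CI-level filters route abstracts out of the primary set", {
  m <- dplyr::bind_rows(
    mention_rows("A", 2.0, 1.5, 2.7),
    mention_rows("B", 2.0, 1.5, 2.7, level = 99L)
  )
  ann <- dplyr::bind_rows(
    fixture_annotation("A", review = TRUE),
    fixture_annotation("B")
  )
  primary <- condense_abstracts(m, ann)
  expect_equal(nrow(primary), 0L)
  expect_equal(attr(primary, "n_excluded"), 2L)

  reviews <- condense_abstracts(m, ann, include_reviews = TRUE)
  expect_equal(reviews$source_id, "A")
  sub99 <- condense_abstracts(m, ann, ci_levels = 99)
  expect_equal(sub99$source_id, "B")
})

test_that("condensation is equivariant under protective/risk inversion", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      k <- sample(1:6, 1)
      v <- exp(rnorm(k, 0, 1.2))
      w <- abs(rnorm(k, 0.5, 0.3)) + 0.01
      m <- mention_rows(rep("X", k), v, v * exp(-w), v * exp(w))
      inv <- mention_rows(rep("X", k), 1 / v, 1 / (v * exp(w)), 1 / (v * exp(-w)))
      a <- condense_abstracts(m, fixture_annotation("X"))
      b <- condense_abstracts(inv, fixture_annotation("X"))
      cols <- c(
        "es_min", "es_max", "es_mean", "cimag_min", "cimag_max",
        "cimag_mean", "any_significant", "prop_significant"
      )
      expect_equal(a[cols], b[cols], tolerance = 1e-10)
    }
  })
})

test_that("es_mean always lies between es_min and es_max", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      k <- sample(1:8, 1)
      v <- exp(rnorm(k, 0, 1.5))
      m <- mention_rows(rep("X", k), v, v * 0.8, v * 1.3)
      sm <- condense_abstracts(m, fixture_annotation("X"))
      expect_true(sm$es_min >= 1)
      expect_true(sm$es_min <= sm$es_mean + 1e-12)
      expect_true(sm$es_mean <= sm$es_max + 1e-12)
    }
  })
})
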