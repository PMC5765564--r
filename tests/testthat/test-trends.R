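# exhaustive pair-enumeration oracle, deliberately naive
mk_oracle <- function(v) {
  n <- length(v)
  S <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      S <- S + sign(v[j] - v[i])
    }
  }
  t <- as.integer(table(v))
  varS <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  list(S = as.integer(S), varS = varS)
}

test_that("monthly aggregation applies the statistic per month", {
  sm <- tibble::tibble(
    month_index = c(3L, 3L, 3L, 5L, 5L, NA),
    es_mean = c(2, 3, 10, 4, 6, 99),
    any_significant = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  med <- monthly_series(sm, "es_mean", "median")
  expect_equal(med$month_index, c(3L, 5L))
  expect_equal(med$value, c(3, 5))
  expect_equal(med$n, c(3L, 2L))

  prop <- monthly_series(sm, "any_significant", "proportion")
  expect_equal(prop$value, c(2 / 3, 1 / 2))

  expect_equal(nrow(monthly_series(sm[0, ], "es_mean")), 0L)
  expect_error(monthly_series(sm, "nope"), "unknown outcome")
})

test_that("Mann-Kendall matches forced monotone cases", {
  up <- mann_kendall(1:5, min_n = 5)
  expect_equal(up$S, 10L)
  expect_equal(up$tau, 1)
  down <- mann_kendall(5:1, min_n = 5)
  expect_equal(down$tau, -1)
  expect_equal(down$p, up$p)
  expect_equal(down$S, -10L)

  ex <- mann_kendall(c(1, 3, 2, 4, 4, 6, 5, 7))
  orc <- mk_oracle(c(1, 3, 2, 4, 4, 6, 5, 7))
  expect_equal(ex$S, orc$S)
  expect_equal(ex$varS, orc$varS)

  expect_error(mann_kendall(1:4), "at least")
})

test_that("Mann-Kendall equals the pairwise oracle on random ties-heavy series", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      n <- sample(8:40, 1)
      v <- sample(1:4, n, replace = TRUE)
      got <- mann_kendall(v)
      orc <- mk_oracle(v)
      expect_identical(got$S, orc$S)
      expect_equal(got$varS, orc$varS)
    }
  })
})

test_that("tau-b agrees with the Kendall correlation against time", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      v <- round(rnorm(n), 1) # some ties
      got <- mann_kendall(v)
      ct <- suppressWarnings(
        stats::cor.test(seq_len(n), v, method = "kendall")
      )
      expect_equal(got$tau, unname(ct$estimate), tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney reproduces forced separations and the exact law", {
  d <- tibble::tibble(
    y = c(1, 2, 3, 10, 11, 12),
    g = rep(c("a", "b"), each = 3)
  )
  rt <- rank_tests(d, "y", "g", mode = "mann_whitney")
  expect_equal(rt$statistic, 0)

  same <- tibble::tibble(y = rep(1:6, 2), g = rep(c("a", "b"), each = 6))
  expect_gt(rank_tests(same, "y", "g", mode = "mann_whitney")$p, 0.9)

  # exact brute-force null distribution for small untied samples
  withr::with_seed(4, {
    x <- sample(100, 5)
    y <- sample(200, 4) + 0.5
    d2 <- tibble::tibble(y = c(x, y), g = rep(c("a", "b"), c(5, 4)))
    got <- rank_tests(d2, "y", "g", mode = "mann_whitney")
    pooled <- c(x, y)
    u_obs <- got$statistic
    perms <- utils::combn(9, 5)
    u_all <- apply(perms, 2, function(idx) {
      xs <- pooled[idx]
      sum(rank(pooled)[idx]) - 5 * 6 / 2
    })
    p_exact <- mean(abs(u_all - 10) >= abs(u_obs - 10)) # center U at n1 n2/2
    expect_equal(got$p, p_exact, tolerance = 1e-12)
  })

  expect_error(
    rank_tests(tibble::tibble(y = 1:3, g = c("a", "a", "b")), "y", "g"),
    "at least 2"
  )
})

test_that("Dunn pairwise z matches the hand-derived table", {
  # groups 1..3, 4..6, 7..9: mean ranks 2, 5, 8; SE = sqrt(5)
  d <- tibble::tibble(y = 1:9, g = rep(c("a", "b", "c"), each = 3))
  rt <- rank_tests(d, "y", "g", mode = "kruskal_dunn", alpha = 0.05)
  pw <- rt$pairwise
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "b"], -3 / sqrt(5))
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "c"], -6 / sqrt(5))
  expect_equal(pw$p_adj, pmin(1, pw$p * 3))
  expect_equal(
    unname(rt$statistic),
    unname(kruskal.test(d$y, factor(d$g))$statistic)
  )
})

test_that("compact letters separate groups exactly when pairs differ", {
  withr::with_seed(12, {
    low <- rnorm(40, 0)
    mid <- rnorm(40, 0.4)
    high <- rnorm(40, 8)
    d <- tibble::tibble(
      y = c(low, mid, high),
      g = rep(c("low", "mid", "high"), each = 40)
    )
    rt <- rank_tests(d, "y", "g", mode = "kruskal_dunn", alpha = 0.01)
    # low and mid overlap and share a letter; high stands alone
    expect_equal(rt$letters[["low"]], rt$letters[["mid"]])
    expect_false(rt$letters[["high"]] %in%
      c(rt$letters[["low"]], rt$letters[["mid"]]))
  })
})

test_that("trend report covers outcomes and strata with finite results", {
  withr::with_seed(5, {
    sm <- tibble::tibble(
      source_id = as.character(1:200),
      month_index = rep(0:49, 4),
      es_mean = exp(abs(rnorm(200, 0, 1)) - 0.003 * rep(0:49, 4)),
      es_min = 1, es_max = 10,
      cimag_mean = exp(abs(rnorm(200, 0.5, 0.2))),
      any_significant = runif(200) < 0.8,
      prop_significant = runif(200),
      multivariate = runif(200) < 0.5,
      open_access = FALSE,
      core_clinical = FALSE
    )
    rep_tbl <- trend_report(sm, strata = "multivariate")
    expect_true(all(c("outcome", "tau", "p") %in% names(rep_tbl)))
    expect_equal(
      nrow(rep_tbl[rep_tbl$stratum == "overall", ]), 6L
    )
    overall <- rep_tbl[rep_tbl$outcome == "es_mean" &
      rep_tbl$stratum == "overall", ]
    expect_true(is.finite(overall$tau))
    expect_true(overall$p >= 0 && overall$p <= 1)
  })
})
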