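#' Aggregate per-abstract summaries into a monthly series
#'
#' Groups abstract summaries by calendar month (index 0 = 1990-01) and
#' applies a statistic to one outcome column.  Months with no abstracts are
#' absent from the series, never zero-filled; summaries without a month are
#' dropped.
#'
#' @param summaries A summary tibble from [condense_abstracts()].
#' @param outcome Name of the outcome column (e.g. `"es_mean"`,
#'   `"any_significant"`).
#' @param statistic `"median"`, `"mean"`, or `"proportion"` (share of
#'   summaries with a `TRUE` outcome).
#' @return A tibble of class `esm_series`: `month_index`, `value`, `n`.
#' @export
monthly_series <- function(summaries,
                           outcome = "es_mean",
                           statistic = c("median", "mean", "proportion")) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(summaries))
  if (!outcome %in% names(summaries)) {
    abort(paste0("unknown outcome column: ", outcome))
  }
  dat <- summaries[!is.na(summaries$month_index), ]
  stat_fun <- switch(statistic,
    median = function(x) median(x, na.rm = TRUE),
    mean = function(x) mean(x, na.rm = TRUE),
    proportion = function(x) mean(as.logical(x), na.rm = TRUE)
  )
  out <- dat |>
    dplyr::group_by(month_index = as.integer(.data$month_index)) |>
    dplyr::summarise(
      value = stat_fun(.data[[outcome]]),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$month_index)
  class(out) <- c("esm_series", class(out))
  attr(out, "outcome") <- outcome
  attr(out, "statistic") <- statistic
  out
}

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend in a series: the Kendall score
#' `S = sum_{i<j} sign(v_j - v_i)`, its tie-corrected variance, a normal
#' z with +/-1 continuity correction, Kendall's tau, and the two-sided p.
#'
#' `tau_variant = "b"` (default) uses the tie-adjusted denominator, which is
#' appropriate for monthly medians that tie frequently; `"a"` divides by
#' `n(n-1)/2` regardless of ties (exposed so replications can toggle).
#'
#' @param series An `esm_series` tibble, any data frame with a `value`
#'   column, or a plain numeric vector in time order.
#' @param tau_variant `"b"` (tie-corrected) or `"a"`.
#' @param min_n Minimum series length for the normal approximation
#'   (default 8).
#' @return An object of class `esm_mk`: list with `S`, `varS`, `z`, `tau`,
#'   `p`, `n`, `tau_variant`.  Use [tidy()] / [glance()] for a tibble.
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 4, 6, 5, 7))
#' @export
mann_kendall <- function(series, tau_variant = c("b", "a"), min_n = 8) {
  tau_variant <- match.arg(tau_variant)
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < min_n) {
    abort(paste0(
      "series has ", n, " values; the normal approximation needs at least ",
      min_n, " (use an exact test for shorter series)"
    ))
  }
  ks <- kendall_score(v)
  S <- ks$S
  varS <- ks$varS

  z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  if (varS == 0) z <- 0
  p <- 2 * pnorm(-abs(z))

  D <- n * (n - 1) / 2
  tau <- if (tau_variant == "a") {
    S / D
  } else {
    t <- table(v)
    Tt <- sum(t * (t - 1) / 2)
    denom <- sqrt(D - Tt) * sqrt(D) # time has no ties
    if (denom == 0) 0 else S / denom
  }

  structure(
    list(
      S = S, varS = varS, z = z, tau = tau, p = p, n = n,
      tau_variant = tau_variant
    ),
    class = "esm_mk"
  )
}

# S and tie-corrected variance, O(n^2) pairwise (fast enough to n ~ 1000)
kendall_score <- function(v) {
  n <- length(v)
  sgn <- sign(outer(v, v, "-"))
  S <- sum(sgn[lower.tri(sgn)])
  t <- table(v)
  varS <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  list(S = as.integer(S), varS = varS)
}

#' @export
print.esm_mk <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall trend test (tau-%s)\n  n = %d, S = %d, varS = %.2f\n  tau = %.4f, z = %.3f, p = %.3g\n",
    x$tau_variant, x$n, x$S, x$varS, x$tau, x$z, x$p
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname mann_kendall
#' @param x An `esm_mk` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.esm_mk <- function(x, ...) {
  tibble::tibble(
    statistic = x$S, var_statistic = x$varS, z = x$z, tau = x$tau,
    p.value = x$p, n = x$n, tau_variant = x$tau_variant
  )
}

#' @rdname mann_kendall
#' @exportS3Method generics::glance
glance.esm_mk <- function(x, ...) tidy(x)

#' Rank-based group comparisons
#'
#' `mann_whitney` compares exactly two groups with the Mann-Whitney /
#' Wilcoxon rank-sum test (exact when feasible, otherwise normal
#' approximation with tie and continuity correction, as in
#' [stats::wilcox.test()]).  `kruskal_dunn` runs the Kruskal-Wallis omnibus
#' test plus Dunn's z-based pairwise comparisons, adjusts pairwise p-values
#' (Bonferroni by default), and derives a compact letter display at
#' `alpha`: groups sharing a letter are not significantly different.
#'
#' @param data A data frame.
#' @param value Name of the numeric outcome column.
#' @param group Name of the grouping column.
#' @param mode `"mann_whitney"` or `"kruskal_dunn"`.
#' @param p_adjust Adjustment method for Dunn pairwise p-values (a
#'   [stats::p.adjust()] method).
#' @param alpha Significance level for the letter display (default 0.001,
#'   the threshold used for all trend and group tests here).
#' @return An object of class `esm_ranktest`: list with `mode`,
#'   `statistic`, `p`, `groups`, and for `kruskal_dunn` also `pairwise` (a
#'   tibble with `group1`, `group2`, `z`, `p`, `p_adj`) and `letters`
#'   (named character vector).  [tidy()] returns the pairwise table,
#'   [glance()] the omnibus row.
#' @export
rank_tests <- function(data, value, group,
                       mode = c("mann_whitney", "kruskal_dunn"),
                       p_adjust = "bonferroni", alpha = 0.001) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  x <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- g[keep]
  counts <- table(g)
  if (any(counts < 2)) {
    abort("every group needs at least 2 observations")
  }
  labels <- names(counts)

  if (mode == "mann_whitney") {
    if (length(labels) != 2L) {
      abort("mann_whitney requires exactly 2 groups")
    }
    wt <- suppressWarnings(
      wilcox.test(x[g == labels[1]], x[g == labels[2]])
    )
    res <- list(
      mode = mode,
      statistic = unname(wt$statistic),
      p = wt$p.value,
      groups = labels,
      pairwise = NULL,
      letters = NULL,
      alpha = alpha
    )
    return(structure(res, class = "esm_ranktest"))
  }

  if (length(labels) < 3L) {
    abort("kruskal_dunn requires at least 3 groups")
  }
  kw <- kruskal.test(x, factor(g))
  pw <- dunn_pairwise(x, g, p_adjust = p_adjust)
  letters <- compact_letters(labels, pw, alpha = alpha,
    means = tapply(rank(x), g, mean)
  )
  structure(
    list(
      mode = mode,
      statistic = unname(kw$statistic),
      p = kw$p.value,
      groups = labels,
      pairwise = pw,
      letters = letters,
      alpha = alpha
    ),
    class = "esm_ranktest"
  )
}

# Dunn's test: z for each pair from mean ranks over the pooled sample, with
# the usual tie correction of the variance.
dunn_pairwise <- function(x, g, p_adjust = "bonferroni") {
  r <- rank(x)
  N <- length(x)
  t <- table(x)
  tie_term <- sum(t^3 - t) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- table(g)
  labels <- names(mean_ranks)
  pairs <- utils::combn(labels, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt(
      (N * (N + 1) / 12 - tie_term) * (1 / ns[[p[1]]] + 1 / ns[[p[2]]])
    )
    (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = as.numeric(z), p = as.numeric(p),
    p_adj = p.adjust(p, method = p_adjust)
  )
}

# Compact letter display: one letter per maximal set of mutually
# nonsignificant groups (maximal clique of the nonsignificance graph,
# enumerated exhaustively -- group counts here are small), letters ordered
# by the lowest mean rank in the set.
compact_letters <- function(labels, pairwise, alpha, means) {
  ord <- labels[order(unlist(means[labels]))]
  k <- length(ord)
  sig <- matrix(FALSE, k, k, dimnames = list(ord, ord))
  for (r in seq_len(nrow(pairwise))) {
    if (pairwise$p_adj[r] < alpha) {
      sig[pairwise$group1[r], pairwise$group2[r]] <- TRUE
      sig[pairwise$group2[r], pairwise$group1[r]] <- TRUE
    }
  }
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    length(s) == 1L || !any(sig[s, s])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(a) {
    !any(vapply(
      seq_along(cliques),
      function(b) {
        b != a && length(cliques[[b]]) > length(cliques[[a]]) &&
          all(cliques[[a]] %in% cliques[[b]])
      },
      logical(1)
    ))
  }, logical(1))
  cliques <- cliques[maximal]
  cliques <- cliques[order(vapply(cliques, min, integer(1)))]
  lets <- stats::setNames(rep("", k), ord)
  for (ci in seq_along(cliques)) {
    lets[cliques[[ci]]] <- paste0(lets[cliques[[ci]]], letters[ci])
  }
  lets[labels]
}

#' @export
print.esm_ranktest <- function(x, ...) {
  if (x$mode == "mann_whitney") {
    cat(sprintf(
      "Mann-Whitney test: U = %.1f, p = %.3g (groups: %s)\n",
      x$statistic, x$p, paste(x$groups, collapse = ", ")
    ))
  } else {
    cat(sprintf(
      "Kruskal-Wallis: H = %.2f, p = %.3g; Dunn pairwise at alpha = %g\n",
      x$statistic, x$p, x$alpha
    ))
    print(x$letters)
  }
  invisible(x)
}

#' @rdname rank_tests
#' @param x An `esm_ranktest` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.esm_ranktest <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble::tibble(
      group1 = x$groups[1], group2 = x$groups[2],
      z = NA_real_, p = x$p, p_adj = x$p
    ))
  }
  out <- x$pairwise
  out$letters1 <- unname(x$letters[out$group1])
  out$letters2 <- unname(x$letters[out$group2])
  out
}

#' @rdname rank_tests
#' @exportS3Method generics::glance
glance.esm_ranktest <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, statistic = x$statistic, p.value = x$p,
    n_groups = length(x$groups)
  )
}

#' Trend report over outcomes and strata
#'
#' Runs [monthly_series()] + [mann_kendall()] for each requested outcome,
#' optionally within each level of a stratifying flag, and binds the
#' results into the tabular trend report.
#'
#' @param summaries Summary tibble from [condense_abstracts()].
#' @param outcomes Named list mapping outcome column to statistic, e.g.
#'   `list(es_mean = "median", any_significant = "proportion")`.
#' @param strata Optional character vector of logical stratum columns
#'   (e.g. `c("multivariate", "open_access")`); the report then carries one
#'   row per outcome and stratum level.
#' @param min_months Minimum number of months required to test a series.
#' @inheritParams mann_kendall
#' @return A tibble: `outcome`, `statistic`, `stratum`, `level`, `n_months`,
#'   `S`, `varS`, `z`, `tau`, `p`.
#' @export
trend_report <- function(summaries,
                         outcomes = list(
                           es_mean = "median",
                           es_min = "median",
                           es_max = "median",
                           cimag_mean = "median",
                           any_significant = "proportion",
                           prop_significant = "mean"
                         ),
                         strata = NULL,
                         tau_variant = "b",
                         min_months = 8) {
  one <- function(dat, outcome, statistic, stratum, level) {
    ser <- monthly_series(dat, outcome, statistic)
    if (nrow(ser) < min_months) {
      return(tibble::tibble(
        outcome = outcome, statistic = statistic, stratum = stratum,
        level = level, n_months = nrow(ser), S = NA_integer_,
        varS = NA_real_, z = NA_real_, tau = NA_real_, p = NA_real_
      ))
    }
    mk <- mann_kendall(ser, tau_variant = tau_variant, min_n = min_months)
    tibble::tibble(
      outcome = outcome, statistic = statistic, stratum = stratum,
      level = level, n_months = mk$n, S = mk$S, varS = mk$varS,
      z = mk$z, tau = mk$tau, p = mk$p
    )
  }
  blocks <- purrr::imap(outcomes, function(statistic, outcome) {
    base <- one(summaries, outcome, statistic, "overall", "all")
    extra <- purrr::map(strata %||% character(0), function(sv) {
      dplyr::bind_rows(
        one(summaries[isTRUE_vec(summaries[[sv]]), ], outcome, statistic,
          sv, "yes"
        ),
        one(summaries[!isTRUE_vec(summaries[[sv]]), ], outcome, statistic,
          sv, "no"
        )
      )
    })
    dplyr::bind_rows(base, extra)
  })
  dplyr::bind_rows(blocks)
}

isTRUE_vec <- function(x) !is.na(x) & x
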