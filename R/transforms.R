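#' Effect-size transformations
#'
#' The four value transformations used throughout the analyses.  Ratio
#' effect sizes live on a log scale (protective values in (0, 1), risk
#' values in (1, Inf)); normalization means taking logs, standardization
#' means folding protective values onto the risk side so both are
#' comparable.
#'
#' * `T4`: identity (raw value).
#' * `T2`: `ln(value)` (normalized).
#' * `T1`: `value` if `value >= 1`, else `1/value` (standardized on the
#'   original scale; the "inverse transformation").
#' * `T3`: `exp(|ln(value)|)` (normalized, standardized, mapped back to the
#'   linear scale).
#'
#' `T1` and `T3` coincide pointwise; they differ in how per-abstract
#' aggregates are formed (`T3` outcomes are aggregated on the log scale, see
#' [condense_abstracts()]).  This reconstruction of the four modes follows
#' the reported figure scales ("original log scale", "linear scale", "mean
#' after logarithmic transformation").
#'
#' @param value Positive numeric vector.
#' @param mode One of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @return Numeric vector.
#' @examples
#' transform_es(c(0.5, 1, 2.5), "T3")
#' @export
transform_es <- function(value, mode = c("T3", "T1", "T2", "T4")) {
  mode <- match.arg(mode)
  if (any(!is.na(value) & value <= 0)) {
    abort("effect-size values must be positive")
  }
  switch(mode,
    T4 = value,
    T2 = log(value),
    T1 = ifelse(value >= 1, value, 1 / value),
    T3 = exp(abs(log(value)))
  )
}

#' Classify effect sizes
#'
#' Direction: `risk` if value > 1, `protective` if < 1, `neutral` if
#' exactly 1.  Magnitude: `large` when value <= 0.2 or >= 5; `tiny` when
#' 0.95 <= value <= 1.05 but not exactly 1 (a neutral value is its own
#' class); `other` otherwise.  Significance: the CI must exclude 1
#' (`ci_upper < 1` or `ci_lower > 1`; a limit exactly 1 encompasses 1, so
#' not significant); `NA` when no CI is present.
#'
#' @param value Positive numeric vector.
#' @param ci_lower,ci_upper CI limits (NA when absent; if one is present
#'   both must be).
#' @return A tibble with columns `direction`, `magnitude`, `significant`.
#' @examples
#' classify_es(c(2.5, 0.98, 5), c(1.23, 0.90, NA), c(4.96, 1.07, NA))
#' @export
classify_es <- function(value, ci_lower = NA_real_, ci_upper = NA_real_) {
  n <- length(value)
  ci_lower <- rep_len(ci_lower, n)
  ci_upper <- rep_len(ci_upper, n)
  if (any(xor(is.na(ci_lower), is.na(ci_upper)))) {
    abort("ci_lower and ci_upper must be present or absent together")
  }
  tibble::tibble(
    direction = dplyr::case_when(
      value > 1 ~ "risk",
      value < 1 ~ "protective",
      TRUE ~ "neutral"
    ),
    magnitude = dplyr::case_when(
      value <= 0.2 | value >= 5 ~ "large",
      value >= 0.95 & value <= 1.05 & value != 1 ~ "tiny",
      TRUE ~ "other"
    ),
    significant = ifelse(
      is.na(ci_lower), NA, ci_upper < 1 | ci_lower > 1
    )
  )
}

#' Confidence-interval magnitude
#'
#' The width of a CI on the log-ratio scale mapped back to the linear
#' scale: `ci_upper / ci_lower`.  Invariant under the protective/risk
#' inversion `(L, U) -> (1/U, 1/L)`.
#'
#' @param ci_lower,ci_upper Positive numeric vectors with
#'   `ci_lower <= ci_upper`.
#' @return Numeric vector of ratios (all >= 1).
#' @examples
#' ci_magnitude(c(1, 0.5), c(4, 2)) # both 4
#' @export
ci_magnitude <- function(ci_lower, ci_upper) {
  if (any(!is.na(ci_lower) & ci_lower <= 0) ||
    any(!is.na(ci_upper) & ci_upper <= 0)) {
    abort("CI limits must be positive")
  }
  ci_upper / ci_lower
}

#' Condense mentions to per-abstract outcomes
#'
#' Reduces each abstract's effect sizes to the per-abstract outcomes used in
#' the monthly analyses.  "Nearest to 1" and "farthest from 1" are measured
#' in `|ln|` distance, so minima and maxima are well defined when
#' protective and risk values coexist:
#'
#' * `es_min`, `es_max`: min/max over mentions of `T3(value)`;
#' * `es_mean`: `exp(mean(|ln value|))` (mean after log transformation);
#' * `cimag_min`, `cimag_max`, `cimag_mean`: same reductions of
#'   `ci_upper/ci_lower` (the mean on the log scale);
#' * `any_significant`, `prop_significant`: from [classify_es()], the
#'   proportion over mentions with a CI.
#'
#' The primary analysis condenses non-review abstracts restricted to 95%
#' CIs; subgroup profiles (reviews, 90/99% CIs) reuse the same condensation
#' with a different filter, never a different formula.
#'
#' @param mentions Mention tibble (after plausibility filtering).
#' @param annotated Annotated citation tibble from [annotate_citations()].
#' @param include_reviews Keep review citations (default `FALSE`).
#' @param ci_levels CI levels retained (default `95`); `NULL` keeps all
#'   mentions including those without a CI.
#' @return One row per abstract that still has mentions after the filter:
#'   `source_id`, `month_index` (months since 1990-01, `NA` when the month
#'   is unknown), `n_es`, the outcome columns above, and the stratification
#'   columns copied from the annotation.  Abstracts whose mentions are all
#'   filtered out are absent (exclusion counts via `attr(, "n_excluded")`).
#' @export
condense_abstracts <- function(mentions, annotated,
                               include_reviews = FALSE, ci_levels = 95) {
  stopifnot(is.data.frame(mentions), is.data.frame(annotated))
  n_source <- length(unique(mentions$source_id))

  keep <- rep(TRUE, nrow(mentions))
  if (!is.null(ci_levels)) {
    keep <- keep & !is.na(mentions$ci_level) & mentions$ci_level %in% ci_levels
  }
  if (!include_reviews) {
    review_ids <- annotated$pmid[annotated$review]
    keep <- keep & !(mentions$source_id %in% review_ids)
  }
  m <- mentions[keep, ]
  if (nrow(m) == 0L) {
    out <- empty_summaries()
    attr(out, "n_excluded") <- n_source
    return(out)
  }

  cls <- classify_es(m$value, m$ci_lower, m$ci_upper)
  m$significant <- cls$significant
  m$abs_log <- abs(log(m$value))
  m$log_cimag <- ifelse(
    is.na(m$ci_lower), NA_real_, log(m$ci_upper / m$ci_lower)
  )

  sm <- m |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(
      n_es = dplyr::n(),
      es_min = exp(min(.data$abs_log)),
      es_max = exp(max(.data$abs_log)),
      es_mean = exp(mean(.data$abs_log)),
      cimag_min = exp(suppressWarnings(min(.data$log_cimag, na.rm = TRUE))),
      cimag_max = exp(suppressWarnings(max(.data$log_cimag, na.rm = TRUE))),
      cimag_mean = exp(mean(.data$log_cimag, na.rm = TRUE)),
      any_significant = any(.data$significant, na.rm = TRUE),
      prop_significant = {
        s <- .data$significant[!is.na(.data$significant)]
        if (length(s) == 0L) NA_real_ else mean(s)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cimag_min = ifelse(is.finite(.data$cimag_min), .data$cimag_min, NA_real_),
      cimag_max = ifelse(is.finite(.data$cimag_max), .data$cimag_max, NA_real_),
      cimag_mean = ifelse(is.nan(.data$cimag_mean), NA_real_, .data$cimag_mean)
    )

  ann <- annotated |>
    dplyr::transmute(
      source_id = .data$pmid,
      month_index = month_index_from_date(.data$pub_year, .data$pub_month),
      multivariate = .data$multivariate,
      review = .data$review,
      open_access = .data$open_access,
      core_clinical = .data$core_clinical,
      continents = .data$continents,
      fields = .data$fields
    )
  out <- dplyr::inner_join(sm, ann, by = "source_id") |>
    dplyr::relocate("month_index", .after = "source_id") |>
    dplyr::arrange(.data$month_index, .data$source_id)
  attr(out, "n_excluded") <- n_source - nrow(out)
  out
}

empty_summaries <- function() {
  tibble::tibble(
    source_id = character(0), month_index = integer(0), n_es = integer(0),
    es_min = double(0), es_max = double(0), es_mean = double(0),
    cimag_min = double(0), cimag_max = double(0), cimag_mean = double(0),
    any_significant = logical(0), prop_significant = double(0),
    multivariate = logical(0), review = logical(0),
    open_access = logical(0), core_clinical = logical(0),
    continents = list(), fields = list()
  )
}
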