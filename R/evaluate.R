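#' Score detection against gold ground truth
#'
#' Compares detector output with the gold table of a synthetic corpus (or
#' any manually annotated corpus in the same layout) and returns the
#' diagnostic-performance report: TP/FP/TN/FN counts, sensitivity,
#' specificity, and Cohen's kappa between the gold and predicted binary
#' labels.
#'
#' Two units of evaluation:
#'
#' * `"mention"`: a predicted mention is a true positive when a planted gold
#'   record in the same source matches its ES type, value, CI level, and CI
#'   limits exactly after canonicalization.  Unmatched predictions are false
#'   positives; unmatched detectable planted records are false negatives;
#'   trap records with no leftover same-type prediction in their source are
#'   the true negatives.
#' * `"abstract"`: any-ES yes/no per abstract.  Positives are abstracts with
#'   at least one detectable planted record; negatives are all remaining
#'   abstracts in `source_ids` (including trap-only ones).  Abstracts whose
#'   only planted records are undetectable by design are excluded from
#'   scoring.
#'
#' Gold records with `detectable = FALSE` (the style that separates the
#' value from its term beyond any reasonable pairing window) are excluded
#' from sensitivity scoring at both units.
#'
#' @param gold Gold tibble from [generate_corpus()].
#' @param predicted Mention tibble from [detect_es()].
#' @param unit `"mention"` or `"abstract"`.
#' @param source_ids For `unit = "abstract"`, the identifiers of all
#'   abstracts in the corpus (needed to count true negatives); defaults to
#'   the sources present in `gold`.
#' @return A one-row tibble of class `esm_perf`: `unit`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `kappa`.
#' @export
evaluate_detection <- function(gold, predicted,
                               unit = c("mention", "abstract"),
                               source_ids = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(gold), is.data.frame(predicted))
  if (nrow(predicted) > 0L &&
    !any(predicted$source_id %in% c(gold$source_id, source_ids))) {
    abort("predicted mentions refer to sources absent from the gold corpus")
  }

  if (unit == "mention") {
    counts <- match_mentions(gold, predicted)
  } else {
    ids <- source_ids %||% unique(gold$source_id)
    planted <- gold[gold$planted, ]
    pos <- unique(planted$source_id[planted$detectable])
    undetectable_only <- setdiff(planted$source_id, pos)
    neg <- setdiff(ids, union(pos, undetectable_only))
    pred_pos <- unique(predicted$source_id)
    counts <- list(
      tp = sum(pos %in% pred_pos),
      fn = sum(!pos %in% pred_pos),
      fp = sum(neg %in% pred_pos),
      tn = sum(!neg %in% pred_pos)
    )
  }

  res <- tibble::tibble(
    unit = unit,
    tp = as.integer(counts$tp), fp = as.integer(counts$fp),
    tn = as.integer(counts$tn), fn = as.integer(counts$fn),
    sensitivity = counts$tp / (counts$tp + counts$fn),
    specificity = counts$tn / (counts$tn + counts$fp),
    kappa = cohens_kappa(counts$tp, counts$fp, counts$tn, counts$fn)
  )
  class(res) <- c("esm_perf", class(res))
  res
}

# Mention-level matching: greedy pairing of predictions to planted gold
# records on (source, type, value, level, limits); each gold record matches
# at most one prediction.
match_mentions <- function(gold, predicted) {
  key <- function(source_id, es_type, value, ci_level, ci_lower, ci_upper) {
    paste(
      source_id, es_type,
      format(value, digits = 12),
      ifelse(is.na(ci_level), "-", ci_level),
      ifelse(is.na(ci_lower), "-", format(ci_lower, digits = 12)),
      ifelse(is.na(ci_upper), "-", format(ci_upper, digits = 12)),
      sep = "\r"
    )
  }
  planted <- gold[gold$planted, ]
  gk <- key(
    planted$source_id, planted$es_type, planted$value,
    planted$ci_level, planted$ci_lower, planted$ci_upper
  )
  pk <- if (nrow(predicted) == 0L) {
    character(0)
  } else {
    key(
      predicted$source_id, predicted$es_type, predicted$value,
      predicted$ci_level, predicted$ci_lower, predicted$ci_upper
    )
  }

  gold_matched <- logical(length(gk))
  pred_matched <- logical(length(pk))
  gidx <- split(seq_along(gk), gk)
  for (j in seq_along(pk)) {
    cand <- gidx[[pk[j]]]
    cand <- cand[!gold_matched[cand]]
    if (length(cand) > 0L) {
      gold_matched[cand[1]] <- TRUE
      pred_matched[j] <- TRUE
    }
  }

  tp <- sum(gold_matched[planted$detectable])
  # matches on undetectable-style records are neither rewarded nor punished
  fn <- sum(!gold_matched[planted$detectable])
  fp <- sum(!pred_matched)

  # a trap record is a true negative unless a leftover same-type prediction
  # remains in its source (the trap fooled the detector)
  traps <- gold[!gold$planted, ]
  tn <- 0L
  if (nrow(traps) > 0L) {
    leftover <- predicted[!pred_matched, c("source_id", "es_type")]
    fooled <- paste(traps$source_id, traps$es_type) %in%
      paste(leftover$source_id, leftover$es_type)
    tn <- sum(!fooled)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Cohen's kappa from a 2x2 agreement table
#'
#' @param tp,fp,tn,fn Nonnegative counts.
#' @return Kappa in `[-1, 1]`; 1 exactly when `fp = fn = 0` with
#'   `tp + tn > 0`.
#' @examples
#' cohens_kappa(5, 1, 3, 1) # 0.5833...
#' @export
cohens_kappa <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  if (n == 0) return(NA_real_)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe == 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}
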