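#' Detect effect-size statements in one text
#'
#' The core extraction step: finds OR/RR/HR statements with their values and
#' confidence intervals in a single text channel (an abstract, a Results
#' paragraph, or a table cell).
#'
#' Each lexicon term occurrence is paired with the nearest following numeric
#' value inside the statement window (no second ES term may intervene); a
#' confidence interval is then parsed from the context following the value.
#' If a trap full wording (e.g. "heart rate" for HR) occurs anywhere in the
#' text, detection for that acronym enters restrictive mode: bare acronym
#' mentions are suppressed and only the full wording, or an adjusted acronym
#' carrying a CI, is emitted (flagged `restrictive_mode`).
#'
#' Unicode minus and en/em dashes are normalized to ASCII hyphens before
#' matching (a character-for-character substitution, so spans are valid in
#' the original text).  Mentions are non-overlapping and ordered by span.
#'
#' @param text A single character string.
#' @param lexicon An [compile_lexicon()] result.
#' @param source_id Identifier copied into the `source_id` column.
#' @param statement_window Maximum characters between the ES term and its
#'   value (default 80).
#' @param ci_window Maximum characters after the value searched for a CI
#'   (default 120).
#' @return A tibble with one row per mention: `source_id`, `es_type`,
#'   `adjusted`, `value`, `ci_level`, `ci_lower`, `ci_upper`, `span_start`,
#'   `span_end`, `flags` (comma-joined subset of `no_ci`,
#'   `ci_level_default`, `value_outside_ci`, `restrictive_mode`,
#'   `bounds_swapped_discarded`).
#' @examples
#' lex <- compile_lexicon()
#' detect_es_mentions(
#'   "The adjusted odds ratio (aOR) was 2.5 (95% CI, 1.5-4.2).", lex
#' )
#' @export
detect_es_mentions <- function(text, lexicon, source_id = NA_character_,
                               statement_window = 80, ci_window = 120) {
  stopifnot(inherits(lexicon, "esm_lexicon"), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty_mentions())
  txt <- normalize_dashes(normalize_spaces(text))

  terms <- locate_terms(txt, lexicon)
  if (nrow(terms) == 0L) return(empty_mentions())

  restrictive <- trap_acronyms(txt, lexicon)
  nums <- locate_numbers(txt)

  out <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    trm <- terms[i, ]
    next_start <- if (i < nrow(terms)) terms$start[i + 1L] else nchar(txt) + 1L

    # restrictive mode: a bare acronym in trap context never yields a mention
    in_restrictive <- trm$es_type %in% restrictive
    if (in_restrictive && trm$kind == "acronym") next

    val <- find_candidate_value(
      nums, txt,
      from = trm$end + 1L,
      to = min(trm$end + statement_window, next_start - 1L)
    )
    if (is.null(val)) next

    frag_end <- min(val$end + ci_window, next_start - 1L, nchar(txt))
    frag <- if (frag_end > val$end) substr(txt, val$end + 1L, frag_end) else ""
    ci <- parse_ci_fragment(frag)

    flags <- character(0)
    if (in_restrictive) flags <- c(flags, "restrictive_mode")
    if (identical(ci, "swapped")) {
      flags <- c(flags, "bounds_swapped_discarded", "no_ci")
      ci <- NULL
    } else if (is.null(ci)) {
      flags <- c(flags, "no_ci")
    } else if (is.na(ci$level)) {
      ci$level <- 95L
      flags <- c(flags, "ci_level_default")
    }

    # in restrictive mode an adjusted acronym is unambiguous only with a CI
    if (in_restrictive && trm$kind == "adjusted_acronym" && is.null(ci)) next

    out[[i]] <- tibble::tibble(
      source_id = source_id,
      es_type = trm$es_type,
      adjusted = isTRUE(trm$adjusted),
      value = val$value,
      ci_level = if (is.null(ci)) NA_integer_ else as.integer(ci$level),
      ci_lower = if (is.null(ci)) NA_real_ else ci$lower,
      ci_upper = if (is.null(ci)) NA_real_ else ci$upper,
      span_start = trm$start,
      span_end = if (is.null(ci)) val$end else val$end + ci$rel_end,
      flags = paste(flags, collapse = ",")
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_mentions())
  res
}

empty_mentions <- function() {
  tibble::tibble(
    source_id = character(0), es_type = character(0), adjusted = logical(0),
    value = double(0), ci_level = integer(0), ci_lower = double(0),
    ci_upper = double(0), span_start = integer(0), span_end = integer(0),
    flags = character(0)
  )
}

# All lexicon term occurrences in txt, sorted by span, nested/overlapping
# matches resolved leftmost-longest.
locate_terms <- function(txt, lexicon) {
  hits <- purrr::pmap_dfr(
    lexicon$terms[c("es_type", "kind", "adjusted", "pattern")],
    function(es_type, kind, adjusted, pattern) {
      loc <- stringr::str_locate_all(txt, stringr::regex(pattern))[[1]]
      if (nrow(loc) == 0L) return(NULL)
      sub <- stringr::str_sub(txt, loc[, 1], loc[, 2])
      adj <- if (kind == "wording") {
        stringr::str_detect(sub, stringr::regex("^(adjusted|multivaria)",
          ignore_case = TRUE
        ))
      } else {
        rep(adjusted, nrow(loc))
      }
      tibble::tibble(
        start = as.integer(loc[, 1]), end = as.integer(loc[, 2]),
        es_type = es_type, kind = kind, adjusted = adj
      )
    }
  )
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$start, -hits$end), ]
  keep <- logical(nrow(hits))
  max_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > max_end) {
      keep[i] <- TRUE
      max_end <- hits$end[i]
    }
  }
  hits[keep, ]
}

# Acronyms for which a trap full wording occurs anywhere in the text.
trap_acronyms <- function(txt, lexicon) {
  tp <- lexicon$trap_phrases
  if (nrow(tp) == 0L) return(character(0))
  hit <- vapply(
    tp$pattern,
    function(p) stringr::str_detect(txt, stringr::regex(p)),
    logical(1)
  )
  unique(tp$acronym[hit])
}

# Numeric tokens with positions; pct = followed by '%', yearlike = 4-digit
# integer in [1800, 2100] (never a plausible candidate ES value).
locate_numbers <- function(txt) {
  loc <- stringr::str_locate_all(txt, "\\d+(?:\\.\\d+)?")[[1]]
  if (nrow(loc) == 0L) {
    return(tibble::tibble(
      start = integer(0), end = integer(0), value = double(0),
      pct = logical(0), yearlike = logical(0)
    ))
  }
  tok <- stringr::str_sub(txt, loc[, 1], loc[, 2])
  after <- stringr::str_sub(txt, loc[, 2] + 1L, loc[, 2] + 2L)
  val <- as.numeric(tok)
  tibble::tibble(
    start = as.integer(loc[, 1]), end = as.integer(loc[, 2]), value = val,
    pct = stringr::str_detect(after, "^ ?%"),
    yearlike = !stringr::str_detect(tok, "\\.") & val >= 1800 & val <= 2100
  )
}

# First plausible value token in [from, to]: not a percentage, not a year,
# and not already inside CI territory (no CI introducer between the term and
# the number).
find_candidate_value <- function(nums, txt, from, to) {
  if (to < from) return(NULL)
  cand <- nums[nums$start >= from & nums$start <= to &
    !nums$pct & !nums$yearlike, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  pre <- substr(txt, from, cand$start[1] - 1L)
  if (stringr::str_detect(
    pre, stringr::regex("\\bCI\\b|(?i)confidence[ -]interval")
  )) {
    return(NULL)
  }
  list(value = cand$value[1], start = cand$start[1], end = cand$end[1])
}

#' Parse a confidence-interval fragment
#'
#' Parses the text window that follows a candidate effect-size value and
#' returns the CI level and limits, if a confidence interval is present.
#'
#' Recognized dialects: introducers such as `95% CI`, `95%CI`, `CI 95%`,
#' `95 % confidence interval`, bare `CI`/`confidence interval` (optionally
#' followed by `:`/`,`/`=`); brackets `()`, `[]`, or none (an unbracketed CI
#' requires an introducer; a bracketed bare range such as `(1.1-3.3)` must
#' start close to the value); range separators `-` (dashes are normalized
#' upstream), `to`, `;`, and `,` (the comma form only inside brackets).
#' Decimal commas are converted to dots only when both bounds match the
#' `digit,digits` pattern.  A CI without a stated level is reported with
#' `level = NA` (callers assign the 95 default and flag it).
#'
#' @param fragment Character string: the post-value context window.
#' @return `NULL` when no CI is found; the string `"swapped"` when bounds
#'   parse reversed (lower > upper); otherwise a list with `level` (90, 95,
#'   99 or `NA`), `lower`, `upper`, and `rel_end` (last character of the CI
#'   region, relative to the fragment).
#' @examples
#' parse_ci_fragment(" (95% CI, 1.23-4.96)")
#' parse_ci_fragment(" [99% confidence interval: 0.42 to 0.91]")
#' @export
parse_ci_fragment <- function(fragment) {
  if (is.na(fragment) || !nzchar(fragment)) return(NULL)
  frag <- normalize_dashes(normalize_spaces(fragment))

  # bracketed groups first, in order of occurrence
  loc <- stringr::str_locate_all(
    frag, "\\(([^()]{1,120})\\)|\\[([^\\[\\]]{1,120})\\]"
  )[[1]]
  if (nrow(loc) > 0L) {
    for (k in seq_len(nrow(loc))) {
      inner <- substr(frag, loc[k, 1] + 1L, loc[k, 2] - 1L)
      res <- parse_ci_core(inner, bracketed = TRUE)
      if (identical(res, "swapped")) return("swapped")
      if (!is.null(res)) {
        if (is.na(res$level) && loc[k, 1] > 12L) next  # bare range far away
        res$rel_end <- as.integer(loc[k, 2])
        return(res)
      }
    }
  }

  # unbracketed: requires an introducer
  res <- parse_ci_core(frag, bracketed = FALSE)
  if (identical(res, "swapped")) return("swapped")
  if (!is.null(res)) {
    if (is.na(res$intro_present) || !res$intro_present) return(NULL)
    res$rel_end <- res$bounds_end
    return(res)
  }
  NULL
}

# Parse one candidate CI region (bracket contents, or the raw fragment).
parse_ci_core <- function(s, bracketed) {
  intro_present <- stringr::str_detect(
    s, stringr::regex("\\bCI\\b|(?i)confidence[ -]intervals?")
  )
  if (!bracketed && !intro_present) return(NULL)

  # decimal commas -> dots, only when both bounds use them
  dc <- "(\\d+),(\\d{1,2})( ?(?:-|to|;) ?)(\\d+),(\\d{1,2})"
  if (stringr::str_detect(s, dc)) {
    s <- stringr::str_replace(s, dc, "\\1.\\2\\3\\4.\\5")
  }

  sep <- if (bracketed) "(?:-|to|;|,)" else "(?:-|to|;)"
  num <- "(\\d+(?:\\.\\d+)?)"
  bounds_pat <- paste0(num, "(?! ?%) ?", sep, " ?", num, "(?! ?%)")
  m <- stringr::str_locate(s, bounds_pat)
  if (all(is.na(m))) return(NULL)
  g <- stringr::str_match(substr(s, m[1, 1], m[1, 2]), bounds_pat)
  lower <- as.numeric(g[1, 2])
  upper <- as.numeric(g[1, 3])
  if (is.na(lower) || is.na(upper)) return(NULL)
  if (!bracketed && !intro_before(s, m[1, 1])) return(NULL)
  if (lower > upper) return("swapped")

  # CI level: a 90/95/99 percentage anywhere in the region outside the bounds
  lvl <- NA_integer_
  rest <- paste(substr(s, 1L, m[1, 1] - 1L), substr(s, m[1, 2] + 1L, nchar(s)))
  lm <- stringr::str_match(rest, "\\b(90|95|99) ?%")
  if (!is.na(lm[1, 2])) lvl <- as.integer(lm[1, 2])

  list(
    level = lvl, lower = lower, upper = upper,
    intro_present = intro_present, bounds_end = as.integer(m[1, 2])
  )
}

# For an unbracketed CI the introducer must precede the bounds (guards
# against pairing an introducer that only appears later in the window).
intro_before <- function(s, bounds_start) {
  pre <- substr(s, 1L, bounds_start - 1L)
  stringr::str_detect(
    pre, stringr::regex("\\bCI\\b|(?i)confidence[ -]intervals?")
  )
}

#' Detect effect-size mentions across a corpus
#'
#' Data-frame-first wrapper around [detect_es_mentions()]: runs the detector
#' on a text column and binds the per-text mention tables.
#'
#' @param data A data frame of citations (or any records with a text column).
#' @param lexicon An [compile_lexicon()] result.
#' @param text Name of the text column (default `"abstract_text"`).
#' @param id Name of the identifier column (default `"pmid"`).
#' @inheritParams detect_es_mentions
#' @return A tibble of mentions (see [detect_es_mentions()]).
#' @export
detect_es <- function(data, lexicon, text = "abstract_text", id = "pmid",
                      statement_window = 80, ci_window = 120) {
  stopifnot(is.data.frame(data), text %in% names(data), id %in% names(data))
  txts <- data[[text]]
  ids <- as.character(data[[id]])
  # cheap prefilter: most texts contain no ES surface form at all; the
  # combined pattern over-matches (case flags leak across alternatives),
  # which is fine for a superset screen
  combined <- paste0("(?:", lexicon$terms$pattern, ")", collapse = "|")
  quick <- stringr::str_detect(normalize_spaces(txts), stringr::regex(combined))
  quick[is.na(quick)] <- FALSE
  res <- purrr::map(which(quick), function(i) {
    detect_es_mentions(txts[i], lexicon, ids[i], statement_window, ci_window)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) empty_mentions() else out
}

#' Filter implausible effect-size mentions
#'
#' Numeric plausibility filtering of detected mentions: drops values above
#' the ceiling, and mentions whose value falls outside its own CI beyond a
#' relative rounding tolerance.  Mentions without a CI are retained (already
#' flagged `no_ci`).  Values are never modified; polysemy guarding is the
#' detector's job, not this filter's.
#'
#' @param mentions A mention tibble from [detect_es()].
#' @param ceiling Maximum plausible ES value (default 10000).
#' @param tolerance Relative tolerance for `ci_lower <= value <= ci_upper`
#'   (default 0.05, i.e. 5% of the value, absorbing rounded limits).
#' @param quiet Suppress the removal message.
#' @return The retained mentions; removals (with a `reason` column) are
#'   attached as `attr(, "removals")`.
#' @export
apply_plausibility_filter <- function(mentions, ceiling = 10000,
                                      tolerance = 0.05, quiet = FALSE) {
  stopifnot(is.data.frame(mentions))
  if (nrow(mentions) == 0L) {
    out <- mentions
    attr(out, "removals") <- dplyr::mutate(mentions, reason = character(0))
    return(out)
  }
  tol <- tolerance * mentions$value
  reason <- dplyr::case_when(
    mentions$value <= 0 ~ "nonpositive_value",
    mentions$value > ceiling ~ "value_above_ceiling",
    !is.na(mentions$ci_lower) &
      ((mentions$ci_lower - mentions$value) > tol |
        (mentions$value - mentions$ci_upper) > tol) ~ "value_outside_ci",
    TRUE ~ NA_character_
  )
  removed <- mentions[!is.na(reason), ]
  removed$reason <- reason[!is.na(reason)]
  removed$flags <- ifelse(
    removed$reason == "value_outside_ci",
    paste0(removed$flags, ifelse(nzchar(removed$flags), ",", ""),
      "value_outside_ci"
    ),
    removed$flags
  )
  kept <- mentions[is.na(reason), ]
  if (!quiet && nrow(removed) > 0L) {
    inform(paste0(
      "plausibility filter removed ", nrow(removed), " mention(s): ",
      paste(sprintf("%s=%d", names(table(removed$reason)),
        as.integer(table(removed$reason))
      ), collapse = ", ")
    ))
  }
  attr(kept, "removals") <- removed
  kept
}
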