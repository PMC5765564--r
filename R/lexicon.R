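#' Compile an effect-size detection lexicon
#'
#' Turns a term configuration (surface forms of OR/RR/HR plus trap phrases)
#' into compiled detection patterns.  Acronyms ("OR", "aHR", ...) are matched
#' case-sensitively at word boundaries; full wordings ("odds ratio",
#' "hazard-ratios", ...) are matched case-insensitively and tolerate plural,
#' hyphen, and spacing variants.  An optional leading "adjusted" (or
#' "multivariable/multivariate(-adjusted)") modifier marks a wording as an
#' adjusted estimate.
#'
#' Trap phrases are full wordings that reuse an acronym for a quantity that
#' is not an effect size (for example "heart rate" for HR).  When one occurs
#' anywhere in a text, detection of that acronym becomes restrictive: bare
#' acronym mentions are suppressed and only unambiguous forms (full wording,
#' or adjusted acronym carrying a confidence interval) are emitted.
#'
#' @param config Either a path to a YAML file with `es_terms` and
#'   `trap_phrases` entries, or an already-parsed list of the same shape.
#'   Defaults to the lexicon shipped with the package.
#' @return An object of class `esm_lexicon`: a list with `terms` (a tibble of
#'   compiled patterns), `trap_phrases` (a tibble of acronym/phrase/pattern),
#'   and `config` (the raw configuration).
#' @examples
#' lex <- compile_lexicon()
#' lex$terms
#' @export
compile_lexicon <- function(config = default_lexicon_path()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("lexicon config not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$es_terms)) {
    abort("lexicon config must have an 'es_terms' entry")
  }

  rows <- list()
  seen <- new.env(parent = emptyenv())
  note_surface <- function(surface, type) {
    key <- paste0("s_", surface)
    prev <- if (exists(key, envir = seen)) get(key, envir = seen) else NULL
    if (!is.null(prev) && prev != type) {
      abort(paste0(
        "surface form '", surface, "' mapped to two ES types: ",
        prev, " and ", type
      ))
    }
    assign(key, type, envir = seen)
  }

  for (type in names(config$es_terms)) {
    if (!type %in% c("OR", "RR", "HR")) {
      abort(paste0("unknown canonical ES type in lexicon: ", type))
    }
    entry <- config$es_terms[[type]]
    for (a in entry$acronyms %||% character(0)) {
      note_surface(a, type)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        es_type = type, surface = a, kind = "acronym", adjusted = FALSE,
        pattern = paste0("\\b", stringr::str_escape(a), "\\b")
      )
    }
    for (a in entry$adjusted_acronyms %||% character(0)) {
      note_surface(a, type)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        es_type = type, surface = a, kind = "adjusted_acronym",
        adjusted = TRUE,
        pattern = paste0("\\b", stringr::str_escape(a), "\\b")
      )
    }
    for (w in entry$wordings %||% character(0)) {
      note_surface(tolower(w), type)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        es_type = type, surface = w, kind = "wording", adjusted = NA,
        pattern = wording_pattern(w)
      )
    }
  }
  terms <- dplyr::bind_rows(rows)

  traps <- config$trap_phrases %||% list()
  trap_tbl <- purrr::imap_dfr(traps, function(phrases, acronym) {
    tibble::tibble(
      acronym = acronym,
      phrase = unlist(phrases),
      pattern = vapply(unlist(phrases), wording_pattern, character(1))
    )
  })
  if (nrow(trap_tbl) == 0L) {
    trap_tbl <- tibble::tibble(
      acronym = character(0), phrase = character(0), pattern = character(0)
    )
  }

  # compile check: every pattern must be a valid regex
  for (p in c(terms$pattern, trap_tbl$pattern)) {
    ok <- tryCatch(
      {
        stringr::str_detect("x", stringr::regex(p))
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) abort(paste0("lexicon pattern failed to compile: ", p))
  }

  structure(
    list(terms = terms, trap_phrases = trap_tbl, config = config),
    class = "esm_lexicon"
  )
}

#' @rdname compile_lexicon
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "lexicon.yaml", package = "esmine", mustWork = TRUE)
}

# Build a case-insensitive regex for a multi-word full wording, tolerating
# plural on the last word, hyphen or space(s) between words, and an optional
# "adjusted"/"multivariate(-adjusted)" modifier (captured as group 1).
wording_pattern <- function(wording) {
  words <- strsplit(tolower(wording), "[ -]+")[[1]]
  words <- vapply(words, stringr::str_escape, character(1))
  n <- length(words)
  words[n] <- paste0(words[n], "s?")
  core <- paste(words, collapse = "[ -]+")
  paste0(
    "(?i)\\b((?:adjusted|multivaria(?:te|ble)(?:[ -]adjusted)?)[ -]+)?",
    core, "\\b"
  )
}

#' @export
print.esm_lexicon <- function(x, ...) {
  cat(
    "<esm_lexicon> ", nrow(x$terms), " term patterns, ",
    nrow(x$trap_phrases), " trap phrases\n",
    sep = ""
  )
  invisible(x)
}
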