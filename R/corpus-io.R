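#' Read MEDLINE/PubMed citation XML
#'
#' Parses a `PubmedArticleSet` file (plain or gzip-compressed, detected by
#' magic bytes) into one citation record per `PubmedArticle`.
#'
#' Structured abstracts are concatenated in document order with section
#' labels dropped and whitespace collapsed; paragraphs tagged as copyright
#' information are excluded.  Citations without an abstract are emitted with
#' an empty `abstract_text` so callers can count exclusions.  Dates prefer
#' the structured `PubDate` Year/Month; for `MedlineDate` strings the first
#' 4-digit year and first recognizable month token are taken; a missing
#' month is `NA` (such citations are excluded from monthly series
#' downstream).  All author affiliations are collected.  Non-breaking/thin
#' spaces are mapped to plain spaces; dashes are preserved verbatim (the
#' detector normalizes those).
#'
#' @param path Path to a PubmedArticleSet XML file (optionally `.gz`).
#' @return A tibble with columns `pmid`, `pmcid`, `abstract_text`,
#'   `pub_year`, `pub_month`, `journal_title`, `journal_issn`, and
#'   list-columns `pub_types`, `mesh_descriptors`, `affiliations`.
#'   Citations lacking a PMID are skipped with a warning.
#' @export
parse_pubmed_citations <- function(path) {
  doc <- read_xml_maybe_gz(path)
  if (xml2::xml_name(doc) != "PubmedArticleSet") {
    abort(paste0(
      "expected a PubmedArticleSet root element, found <",
      xml2::xml_name(doc), ">"
    ))
  }
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0L) return(empty_citations())

  recs <- purrr::map(arts, parse_one_citation)
  skipped <- sum(vapply(recs, is.null, logical(1)))
  if (skipped > 0L) {
    warn(paste0(skipped, " citation(s) without a PMID were skipped"))
  }
  out <- dplyr::bind_rows(purrr::compact(recs))
  if (nrow(out) == 0L) empty_citations() else out
}

empty_citations <- function() {
  tibble::tibble(
    pmid = character(0), pmcid = character(0), abstract_text = character(0),
    pub_year = integer(0), pub_month = integer(0),
    journal_title = character(0), journal_issn = character(0),
    pub_types = list(), mesh_descriptors = list(), affiliations = list()
  )
}

parse_one_citation <- function(art) {
  pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
  if (is.na(pmid) || !nzchar(pmid)) return(NULL)

  abs_nodes <- xml2::xml_find_all(
    art, ".//Article/Abstract/AbstractText"
  )
  abs_txt <- ""
  if (length(abs_nodes) > 0L) {
    parts <- xml2::xml_text(abs_nodes)
    labels <- xml2::xml_attr(abs_nodes, "Label")
    drop <- !is.na(labels) &
      grepl("copyright|funding", labels, ignore.case = TRUE)
    abs_txt <- squish(normalize_spaces(paste(parts[!drop], collapse = " ")))
  }

  pd <- xml2::xml_find_first(art, ".//Article/Journal/JournalIssue/PubDate")
  date <- parse_pubdate(pd)

  pmcid <- xml2::xml_text(xml2::xml_find_first(
    art, ".//PubmedData/ArticleIdList/ArticleId[@IdType='pmc']"
  ))

  tibble::tibble(
    pmid = pmid,
    pmcid = if (is.na(pmcid)) NA_character_ else pmcid,
    abstract_text = abs_txt,
    pub_year = date$year,
    pub_month = date$month,
    journal_title = xml2::xml_text(
      xml2::xml_find_first(art, ".//Article/Journal/Title")
    ),
    journal_issn = xml2::xml_text(
      xml2::xml_find_first(art, ".//Article/Journal/ISSN")
    ),
    pub_types = list(xml2::xml_text(xml2::xml_find_all(
      art, ".//Article/PublicationTypeList/PublicationType"
    ))),
    mesh_descriptors = list(xml2::xml_text(xml2::xml_find_all(
      art, ".//MeshHeadingList/MeshHeading/DescriptorName"
    ))),
    affiliations = list(xml2::xml_text(xml2::xml_find_all(
      art, ".//AuthorList//AffiliationInfo/Affiliation"
    )))
  )
}

month_token_to_int <- function(tok) {
  if (is.na(tok)) return(NA_integer_)
  if (grepl("^\\d{1,2}$", tok)) {
    m <- as.integer(tok)
    return(if (m >= 1L && m <= 12L) m else NA_integer_)
  }
  m <- match(tolower(substr(tok, 1, 3)), tolower(month.abb))
  if (is.na(m)) NA_integer_ else as.integer(m)
}

parse_pubdate <- function(pd) {
  if (length(pd) == 0L || is.na(xml2::xml_name(pd))) {
    return(list(year = NA_integer_, month = NA_integer_))
  }
  y <- xml2::xml_text(xml2::xml_find_first(pd, "./Year"))
  m <- xml2::xml_text(xml2::xml_find_first(pd, "./Month"))
  if (!is.na(y)) {
    return(list(
      year = as.integer(y),
      month = month_token_to_int(m)
    ))
  }
  # MedlineDate, e.g. "1994 Dec-1995 Jan": first 4-digit year, first month
  md <- xml2::xml_text(xml2::xml_find_first(pd, "./MedlineDate"))
  if (is.na(md)) return(list(year = NA_integer_, month = NA_integer_))
  ym <- stringr::str_match(md, "(\\d{4})")[, 2]
  mm <- stringr::str_match(
    md, stringr::regex(paste0("\\b(", paste(month.abb, collapse = "|"), ")"),
      ignore_case = TRUE
    )
  )[, 2]
  list(
    year = if (is.na(ym)) NA_integer_ else as.integer(ym),
    month = month_token_to_int(mm)
  )
}

read_xml_maybe_gz <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 2L)
  close(con)
  if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    raw <- readBin(con, "raw", n = 64 * 1024^2)
    xml2::read_xml(raw)
  } else {
    xml2::read_xml(path)
  }
}

#' Read a JATS full-text article
#'
#' Extracts the three disjoint text channels mined from PMC full text: the
#' abstract, paragraphs of sections whose title matches a Results pattern,
#' and flattened table cells.
#'
#' @param path Path to a JATS article XML file (optionally `.gz`).
#' @param results_pattern Case-insensitive regex a section title must match
#'   to count as a Results section (default `"result"`).
#' @return A one-row tibble: `pmcid`, `abstract_text`, and list-columns
#'   `results_paragraphs`, `table_cells` (cell text prefixed by nothing;
#'   cells are flattened in row-major order).  An article with no
#'   Results-matching section yields empty `results_paragraphs`.
#' @export
parse_pmc_fulltext <- function(path, results_pattern = "result") {
  doc <- read_xml_maybe_gz(path)
  xml2::xml_ns_strip(doc)

  pmcid <- xml2::xml_text(xml2::xml_find_first(
    doc, ".//front//article-id[@pub-id-type='pmc']"
  ))
  abs_txt <- squish(normalize_spaces(paste(
    xml2::xml_text(xml2::xml_find_all(doc, ".//front//abstract//p")),
    collapse = " "
  )))

  secs <- xml2::xml_find_all(doc, ".//body//sec")
  res_par <- character(0)
  for (sec in secs) {
    title <- xml2::xml_text(xml2::xml_find_first(sec, "./title"))
    if (!is.na(title) &&
      stringr::str_detect(
        title, stringr::regex(results_pattern, ignore_case = TRUE)
      )) {
      ps <- xml2::xml_find_all(sec, "./p")
      res_par <- c(res_par, squish(normalize_spaces(xml2::xml_text(ps))))
    }
  }

  cells <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//table-wrap//td | .//table-wrap//th")
  )
  cells <- squish(normalize_spaces(cells))

  tibble::tibble(
    pmcid = if (is.na(pmcid)) NA_character_ else pmcid,
    abstract_text = abs_txt,
    results_paragraphs = list(res_par),
    table_cells = list(cells)
  )
}

# --- tabular interchange -------------------------------------------------

es_table_columns <- c(
  "source_id", "es_type", "adjusted", "value", "ci_level", "ci_lower",
  "ci_upper", "span_start", "span_end", "flags"
)

#' Write / read the effect-size mention table
#'
#' Tab-separated UTF-8 with a header line; absent values are written as
#' empty strings.  `read_es_table(write_es_table(x))` reproduces `x`
#' field-for-field.
#'
#' @param mentions A mention tibble (see [detect_es()]).
#' @param path Output / input file path.
#' @return `write_es_table` returns the row count, invisibly;
#'   `read_es_table` returns the mention tibble.
#' @export
write_es_table <- function(mentions, path) {
  stopifnot(is.data.frame(mentions))
  missing_cols <- setdiff(es_table_columns, names(mentions))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "mention table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  readr::write_tsv(mentions[es_table_columns], path, na = "")
  invisible(nrow(mentions))
}

#' @rdname write_es_table
#' @export
read_es_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      source_id = readr::col_character(),
      es_type = readr::col_character(),
      adjusted = readr::col_logical(),
      value = readr::col_double(),
      ci_level = readr::col_integer(),
      ci_lower = readr::col_double(),
      ci_upper = readr::col_double(),
      span_start = readr::col_integer(),
      span_end = readr::col_integer(),
      flags = readr::col_character()
    ),
    na = "",
    comment = "#"
  )
  missing_cols <- setdiff(es_table_columns, names(tbl))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "ES table at ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tbl$flags[is.na(tbl$flags)] <- ""
  tbl
}
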