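#' End-to-end extraction and trend pipeline
#'
#' Orchestrates extract -> annotate -> condense -> trends over a set of
#' citation XML files and writes the four interchange tables (mentions,
#' annotated citations, abstract summaries, trend report) plus, when a gold
#' table is supplied, the detection performance report.  Every output file
#' starts with comment lines embedding the package version, the
#' configuration hash, and the active filters, so runs are auditable;
#' identical configuration and inputs give identical outputs.
#'
#' @param xml_paths Character vector of PubmedArticleSet XML files.
#' @param out_dir Output directory (created if needed).
#' @param resources An `esm_resources` list; defaults to the shipped
#'   configuration tables.
#' @param lexicon A compiled lexicon; defaults to the shipped one.
#' @param gold Optional gold tibble (or path to one written by
#'   [generate_corpus()]); adds `performance.tsv`.
#' @param include_reviews,ci_levels Condensation filters (see
#'   [condense_abstracts()]).
#' @param strata Stratum columns passed to [trend_report()].
#' @param tau_variant Mann-Kendall tau variant (see [mann_kendall()]).
#' @param quiet Suppress per-stage progress messages.
#' @return A manifest tibble (one row per written table: `name`, `path`,
#'   `rows`), invisibly.  The loaded tables are attached as
#'   `attr(, "tables")`.
#' @export
run_pipeline <- function(xml_paths, out_dir,
                         resources = load_resources(),
                         lexicon = compile_lexicon(),
                         gold = NULL,
                         include_reviews = FALSE,
                         ci_levels = 95,
                         strata = c(
                           "multivariate", "open_access", "core_clinical"
                         ),
                         tau_variant = "b",
                         quiet = FALSE) {
  missing <- xml_paths[!file.exists(xml_paths)]
  if (length(missing) > 0L) {
    abort(paste0(
      "input file(s) not found: ", paste(missing, collapse = ", ")
    ))
  }
  if (is.character(gold)) gold <- read_gold_table(gold)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(paste0(...))

  say("extract: parsing ", length(xml_paths), " XML file(s)")
  citations <- dplyr::bind_rows(purrr::map(xml_paths, parse_pubmed_citations))
  n_abs <- sum(nzchar(citations$abstract_text))
  say("extract: ", nrow(citations), " citations, ", n_abs, " with abstract")

  mentions <- detect_es(citations, lexicon)
  mentions <- apply_plausibility_filter(mentions, quiet = quiet)
  say(
    "detect: ", nrow(mentions), " mentions kept, ",
    nrow(attr(mentions, "removals")), " removed by plausibility filter"
  )

  annotated <- annotate_citations(citations, mentions, resources)
  summaries <- condense_abstracts(
    mentions, annotated,
    include_reviews = include_reviews, ci_levels = ci_levels
  )
  say(
    "condense: ", nrow(summaries), " abstract summaries (",
    attr(summaries, "n_excluded"), " abstracts excluded by filters)"
  )
  if (nrow(summaries) == 0L) {
    warn("condense stage produced no summaries under the active filters")
  }

  trends <- trend_report(summaries, strata = strata,
    tau_variant = tau_variant
  )

  header <- run_metadata_header(
    xml_paths, include_reviews, ci_levels, tau_variant
  )
  tables <- list(
    mentions = mentions,
    annotated = serialize_annotated(annotated),
    summaries = serialize_summaries(summaries),
    trends = trends
  )
  if (!is.null(gold)) {
    perf <- dplyr::bind_rows(
      evaluate_detection(gold, mentions, unit = "mention"),
      evaluate_detection(gold, mentions,
        unit = "abstract",
        source_ids = citations$pmid
      )
    )
    tables$performance <- perf
  }

  manifest <- purrr::imap_dfr(tables, function(tbl, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    writeLines(header, path)
    suppressMessages(
      readr::write_tsv(tbl, path, na = "", append = TRUE, col_names = TRUE)
    )
    tibble::tibble(name = name, path = path, rows = nrow(tbl))
  })
  say("done: ", nrow(manifest), " tables written to ", out_dir)
  attr(manifest, "tables") <- c(
    list(citations = citations, summaries = summaries), tables
  )
  invisible(manifest)
}

run_metadata_header <- function(xml_paths, include_reviews, ci_levels,
                                tau_variant) {
  cfg <- list(
    inputs = basename(xml_paths),
    include_reviews = include_reviews,
    ci_levels = ci_levels %||% "all",
    tau_variant = tau_variant
  )
  tmp <- tempfile()
  yaml::write_yaml(cfg, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  c(
    paste0("# esmine ", as.character(utils::packageVersion("esmine"))),
    paste0("# config_hash: ", hash),
    paste0(
      "# filters: include_reviews=", include_reviews,
      " ci_levels=", paste(ci_levels %||% "all", collapse = ","),
      " tau_variant=", tau_variant
    )
  )
}

serialize_annotated <- function(annotated) {
  annotated |>
    dplyr::mutate(
      pub_types = join_multi(.data$pub_types),
      mesh_descriptors = join_multi(.data$mesh_descriptors),
      affiliations = join_multi(.data$affiliations),
      continents = join_multi(.data$continents),
      fields = join_multi(.data$fields)
    )
}

serialize_summaries <- function(summaries) {
  summaries |>
    dplyr::mutate(
      continents = join_multi(.data$continents),
      fields = join_multi(.data$fields)
    )
}

#' @rdname generate_corpus
#' @param path Path to a `gold.tsv` written by [generate_corpus()].
#' @export
read_gold_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      source_id = readr::col_character(),
      planted = readr::col_logical(),
      detectable = readr::col_logical(),
      es_type = readr::col_character(),
      adjusted = readr::col_logical(),
      value = readr::col_double(),
      ci_level = readr::col_integer(),
      ci_lower = readr::col_double(),
      ci_upper = readr::col_double(),
      style = readr::col_character(),
      trap_phrase = readr::col_character(),
      month_index = readr::col_integer()
    ),
    na = ""
  )
}
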