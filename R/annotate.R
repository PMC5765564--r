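#' Detect evidence of a multivariate analysis
#'
#' An abstract is flagged multivariate when any of its detected mentions is
#' an adjusted estimate, or when the text matches the adjustment phrase
#' stems ("adjust", "multivariat", "multivariabl").
#'
#' @param text Abstract text (length 1).
#' @param mentions Mentions detected in that text (may have 0 rows).
#' @return Logical scalar.
#' @export
detect_multivariate <- function(text, mentions = empty_mentions()) {
  if (nrow(mentions) > 0L && any(mentions$adjusted)) return(TRUE)
  if (is.na(text) || !nzchar(text)) return(FALSE)
  stringr::str_detect(
    text, stringr::regex("adjust|multivariat|multivariabl", ignore_case = TRUE)
  )
}

#' Map affiliation strings to continents
#'
#' Longest-match country (or alias) search with word boundaries in each
#' affiliation string; the union of mapped continents is returned, so
#' cross-continental author lists count in each continent concerned.
#'
#' @param affiliations Character vector of affiliation strings.
#' @param gazetteer A gazetteer tibble from [load_gazetteer()].
#' @return Character vector of continents (possibly empty); affiliations
#'   with no recognized country are reported via `attr(, "unmapped")`.
#' @export
map_affiliation_continents <- function(affiliations, gazetteer) {
  affiliations <- affiliations[!is.na(affiliations) & nzchar(affiliations)]
  if (length(affiliations) == 0L) {
    out <- character(0)
    attr(out, "unmapped") <- character(0)
    return(out)
  }
  pat <- attr(gazetteer, "combined_pattern") %||% gazetteer_pattern(gazetteer)
  continents <- character(0)
  unmapped <- character(0)
  for (aff in affiliations) {
    hits <- stringr::str_extract_all(normalize_spaces(aff), pat)[[1]]
    if (length(hits) == 0L) {
      unmapped <- c(unmapped, aff)
      next
    }
    continents <- c(
      continents,
      gazetteer$continent[match(hits, gazetteer$name)]
    )
  }
  out <- sort(unique(continents[!is.na(continents)]))
  attr(out, "unmapped") <- unmapped
  out
}

# One alternation over all gazetteer names, longest first, so the leftmost
# match at a position is also the longest ("Papua New Guinea" never yields
# "Guinea").  Word boundaries are added only next to word characters (names
# like "U.S.A." end in punctuation).
gazetteer_pattern <- function(gazetteer) {
  alts <- vapply(gazetteer$name, function(nm) {
    esc <- stringr::str_escape(nm)
    paste0(
      if (grepl("^\\w", nm)) "\\b" else "",
      esc,
      if (grepl("\\w$", nm)) "\\b" else ""
    )
  }, character(1))
  stringr::regex(paste(alts, collapse = "|"))
}

#' Map MeSH descriptors to research fields
#'
#' A citation belongs to field `X` (a second-level MeSH tree branch such as
#' `C04` or `G05`) iff any of its descriptors has a tree number whose prefix
#' is `X`.  Multiple fields per citation are expected.  Only branches `C`
#' (diseases) and `G` (phenomena and processes) are considered.
#'
#' @param descriptors Character vector of MeSH descriptor names.
#' @param mesh_tree A tibble from [load_mesh_tree()].
#' @return Sorted character vector of field codes (possibly empty).
#' @export
map_mesh_fields <- function(descriptors, mesh_tree) {
  descriptors <- descriptors[!is.na(descriptors)]
  if (length(descriptors) == 0L) return(character(0))
  idx <- match(descriptors, mesh_tree$descriptor)
  tns <- unlist(mesh_tree$tree_numbers[idx[!is.na(idx)]])
  if (length(tns) == 0L) return(character(0))
  fields <- stringr::str_match(tns, "^([CG]\\d{2})")[, 2]
  sort(unique(fields[!is.na(fields)]))
}

#' Annotate citations with the stratification characteristics
#'
#' Adds to each citation the derived flags and mappings the trend analyses
#' stratify by: evidence of a multivariate analysis, review status (from
#' publication types), open-access and core-clinical-journal membership
#' (ISSN, falling back to normalized journal title), continents of author
#' affiliation, and MeSH research fields.
#'
#' @param citations A citation tibble from [parse_pubmed_citations()] or
#'   [generate_corpus()].
#' @param mentions The mention tibble detected from these citations.
#' @param resources An `esm_resources` list from [load_resources()].
#' @return The citation tibble with columns `multivariate`, `review`,
#'   `open_access`, `core_clinical` (logical) and list-columns `continents`,
#'   `fields` appended.
#' @export
annotate_citations <- function(citations, mentions, resources) {
  stopifnot(is.data.frame(citations), inherits(resources, "esm_resources"))
  adj_ids <- unique(mentions$source_id[mentions$adjusted])

  issn <- citations$journal_issn
  title_norm <- normalize_journal_title(citations$journal_title)
  in_list <- function(lst) {
    (!is.na(issn) & issn %in% lst$issn) | title_norm %in% lst$title_norm
  }

  citations |>
    dplyr::mutate(
      multivariate = purrr::map2_lgl(
        .data$abstract_text, .data$pmid,
        function(txt, id) {
          id %in% adj_ids || detect_multivariate(txt)
        }
      ),
      review = purrr::map_lgl(.data$pub_types, function(pt) "Review" %in% pt),
      open_access = in_list(resources$oa_journals),
      core_clinical = in_list(resources$ccj_journals),
      continents = purrr::map(.data$affiliations, function(a) {
        out <- map_affiliation_continents(a, resources$gazetteer)
        attributes(out) <- NULL
        out
      }),
      fields = purrr::map(
        .data$mesh_descriptors, map_mesh_fields,
        mesh_tree = resources$mesh_tree
      )
    )
}
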