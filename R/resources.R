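#' Annotation resources
#'
#' Loaders for the configuration tables the annotator needs.  All are plain
#' TSV so they can be audited and replaced: a country/alias gazetteer
#' (`name`, `country`, `continent`), a MeSH descriptor to tree-number map
#' (`descriptor`, `tree_numbers` with `|`-separated numbers), and journal
#' membership lists (`issn`, `title`).
#'
#' The shipped MeSH map is an illustrative subset of the NLM tree, and the
#' shipped open-access list is a small synthetic example; for real corpora
#' supply the full NLM flat files.  The shipped core-clinical-journal list
#' carries the well-known Abridged Index Medicus titles.
#'
#' @param gazetteer,mesh_tree,oa_journals,ccj_journals Paths to the four
#'   TSV resources; defaults are the files shipped with the package.
#' @return `load_resources()` returns a list of class `esm_resources` with
#'   elements `gazetteer`, `mesh_tree`, `oa_journals`, `ccj_journals`.
#' @export
load_resources <- function(
    gazetteer = esm_extdata("gazetteer.tsv"),
    mesh_tree = esm_extdata("mesh-tree-example.tsv"),
    oa_journals = esm_extdata("oa-journals-example.tsv"),
    ccj_journals = esm_extdata("ccj-aim.tsv")) {
  for (p in c(gazetteer, mesh_tree, oa_journals, ccj_journals)) {
    if (!file.exists(p)) abort(paste0("resource file not found: ", p))
  }
  structure(
    list(
      gazetteer = load_gazetteer(gazetteer),
      mesh_tree = load_mesh_tree(mesh_tree),
      oa_journals = load_journal_list(oa_journals),
      ccj_journals = load_journal_list(ccj_journals)
    ),
    class = "esm_resources"
  )
}

#' @rdname load_resources
#' @export
load_gazetteer <- function(gazetteer) {
  tbl <- readr::read_tsv(gazetteer, col_types = "ccc")
  stopifnot(all(c("name", "country", "continent") %in% names(tbl)))
  ok <- tbl$continent %in% c(
    "Africa", "Asia", "Europe", "North America", "Oceania", "South America"
  )
  if (!all(ok)) {
    abort(paste0(
      "gazetteer has unknown continent(s): ",
      paste(unique(tbl$continent[!ok]), collapse = ", ")
    ))
  }
  # longest names first so that e.g. "Papua New Guinea" wins over "Guinea"
  tbl <- tbl[order(-nchar(tbl$name)), ]
  attr(tbl, "combined_pattern") <- gazetteer_pattern(tbl)
  tbl
}

#' @rdname load_resources
#' @export
load_mesh_tree <- function(mesh_tree) {
  tbl <- readr::read_tsv(mesh_tree, col_types = "cc")
  stopifnot(all(c("descriptor", "tree_numbers") %in% names(tbl)))
  tbl$tree_numbers <- split_multi(tbl$tree_numbers)
  tbl
}

#' @rdname load_resources
#' @export
load_journal_list <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cc")
  stopifnot(all(c("issn", "title") %in% names(tbl)))
  tbl$title_norm <- normalize_journal_title(tbl$title)
  tbl
}

esm_extdata <- function(file) {
  system.file("extdata", file, package = "esmine", mustWork = TRUE)
}
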