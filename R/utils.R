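# shared internal helpers

# Collapse a character vector into the "|"-joined form used by the TSV
# interchange tables; NULL/empty becomes "".
join_multi <- function(x) {
  vapply(x, function(v) {
    if (is.null(v) || length(v) == 0L) "" else paste(v, collapse = "|")
  }, character(1))
}

split_multi <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, "|", fixed = TRUE)[[1]]
  })
}

# Map NBSP / thin space to plain space (reader-level normalization); dashes
# are left alone here -- the detector normalizes those in numeric contexts.
normalize_spaces <- function(x) {
  gsub("[\u00a0\u2007\u2009\u202f]", " ", x)
}

# Unicode minus and en/em dashes to ASCII hyphen (detector-level, applied
# before numeric pattern matching).
normalize_dashes <- function(x) {
  gsub("[\u2212\u2013\u2014]", "-", x)
}

squish <- function(x) stringr::str_squish(x)

# months since 1990-01 (index 0); NA when month missing
month_index_from_date <- function(year, month) {
  idx <- (year - 1990L) * 12L + (month - 1L)
  idx[is.na(month)] <- NA_integer_
  as.integer(idx)
}

month_index_to_year <- function(idx) 1990L + idx %/% 12L
month_index_to_month <- function(idx) 1L + idx %% 12L

# strict %in% for possibly-NA numeric equality at a tolerance
num_eq <- function(a, b, tol = 1e-9) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & abs(a - b) <= tol)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

normalize_journal_title <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}
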