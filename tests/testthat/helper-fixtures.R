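# Shared fixtures, built in code at test time.

fixture_lexicon <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- compile_lexicon()
    lex
  }
})

fixture_resources <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- load_resources()
    res
  }
})

# A 3-citation PubmedArticleSet: two with abstracts (one structured, one
# with a MedlineDate), one without an abstract.
pubmed_fixture_xml <- function() {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>1001</PMID><Article>",
    "<Journal><ISSN>9000-0001</ISSN><JournalIssue><PubDate>",
    "<Year>1995</Year><Month>Mar</Month></PubDate></JournalIssue>",
    "<Title>Synthetic Journal of Biomedical Research</Title></Journal>",
    "<ArticleTitle>First</ArticleTitle>",
    "<Abstract>",
    "<AbstractText Label=\"BACKGROUND\">Smoking and risk.</AbstractText>",
    "<AbstractText Label=\"RESULTS\">The odds ratio was 2.5 ",
    "(95% CI, 1.5-4.2).</AbstractText>",
    "<AbstractText Label=\"Copyright\">(c) Synthetic publishing.",
    "</AbstractText>",
    "</Abstract>",
    "<AuthorList><Author><AffiliationInfo>",
    "<Affiliation>Toulouse University Hospital, Toulouse, France.",
    "</Affiliation></AffiliationInfo></Author></AuthorList>",
    "<PublicationTypeList><PublicationType>Journal Article",
    "</PublicationType></PublicationTypeList></Article>",
    "<MeshHeadingList><MeshHeading><DescriptorName>Neoplasms",
    "</DescriptorName></MeshHeading></MeshHeadingList>",
    "</MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>1002</PMID><Article>",
    "<Journal><JournalIssue><PubDate>",
    "<MedlineDate>1994 Dec-1995 Jan</MedlineDate></PubDate>",
    "</JournalIssue><Title>Synthetic Archives of Population Health",
    "</Title></Journal>",
    "<ArticleTitle>Second</ArticleTitle>",
    "<Abstract><AbstractText>No effect sizes here.</AbstractText>",
    "</Abstract>",
    "<PublicationTypeList><PublicationType>Review</PublicationType>",
    "</PublicationTypeList></Article>",
    "</MedlineCitation>",
    "<PubmedData><ArticleIdList>",
    "<ArticleId IdType=\"pmc\">PMC77</ArticleId>",
    "</ArticleIdList></PubmedData></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>1003</PMID><Article>",
    "<Journal><JournalIssue><PubDate><Year>2001</Year></PubDate>",
    "</JournalIssue><Title>Synthetic Clinical Journal</Title></Journal>",
    "<ArticleTitle>Third, no abstract</ArticleTitle>",
    "<PublicationTypeList><PublicationType>Journal Article",
    "</PublicationType></PublicationTypeList></Article>",
    "</MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"
  )
}

jats_fixture_xml <- function() {
  paste0(
    "<?xml version=\"1.0\"?>\n",
    "<article><front>",
    "<article-meta><article-id pub-id-type=\"pmc\">PMC77</article-id>",
    "</article-meta>",
    "<abstract><p>Abstract text with RR = 1.2 (95% CI 1.1-1.4).</p>",
    "</abstract></front>",
    "<body>",
    "<sec><title>Introduction</title><p>Background prose.</p></sec>",
    "<sec><title>Results and Discussion</title>",
    "<p>The hazard ratio was 0.8 (95% CI 0.7-0.9).</p>",
    "<p>Another results paragraph.</p></sec>",
    "<sec><title>Methods</title><p>Methods prose.</p>",
    "<table-wrap><table>",
    "<tr><th>Group</th><th>OR</th><th>CI</th></tr>",
    "<tr><td>A</td><td>1.5</td><td>1.1-2.1</td></tr>",
    "</table></table-wrap></sec>",
    "</body></article>"
  )
}

write_fixture <- function(text, ext = ".xml", gz = FALSE) {
  path <- tempfile(fileext = if (gz) paste0(ext, ".gz") else ext)
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(text, con)
  close(con)
  path
}

# random mention tibble for round-trip / property tests
random_mentions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    value <- exp(rnorm(n, 0, 1))
    w <- abs(rnorm(n, 0.4, 0.2)) + 0.01
    has_ci <- runif(n) < 0.8
    tibble::tibble(
      source_id = sprintf("A%03d", sample.int(n, n, replace = TRUE)),
      es_type = sample(c("OR", "RR", "HR"), n, replace = TRUE),
      adjusted = runif(n) < 0.3,
      value = round(value, 2),
      ci_level = ifelse(has_ci, sample(c(90L, 95L, 99L), n,
        replace = TRUE, prob = c(.1, .8, .1)
      ), NA_integer_),
      ci_lower = ifelse(has_ci, round(value * exp(-w), 2), NA_real_),
      ci_upper = ifelse(has_ci, round(value * exp(w), 2), NA_real_),
      span_start = 1L + seq_len(n),
      span_end = 40L + seq_len(n),
      flags = ifelse(has_ci, "", "no_ci")
    )
  })
}
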