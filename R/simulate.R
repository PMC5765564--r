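#' Configuration for the synthetic literature corpus
#'
#' Builds the configuration of [generate_corpus()].  The defaults emulate
#' the statistical structure reported for PubMed abstracts over 1990-2015:
#' effect sizes whose `|ln ES|` is half-normal with a scale drifting so the
#' median standardized ES falls from about 2.50 to about 2.11 across the
#' window; geometric CIs around the value whose log half-width drifts from
#' 0.70 to 0.54 (the printed 95% CI limit medians); a share of
#' statistically significant ESs drifting from 0.74 to 0.85; 95% CIs
#' dominating, with 90% and 99% minorities; and trap sentences reusing the
#' OR/RR/HR acronyms for non-effect-size quantities in a tenth of
#' abstracts.
#'
#' @param months Integer month indices (0 = 1990-01, 311 = 2015-12).
#' @param abstracts_per_month Abstracts generated per month.
#' @param p_has_es Probability an abstract carries effect sizes.
#' @param es_count_probs Distribution of the ES count per positive
#'   abstract (vector of probabilities for counts `1..length`).
#' @param log_es_scale_start,log_es_scale_end Half-normal scale of
#'   `|ln ES|` at the first and last month (linear interpolation between).
#' @param ci_halfwidth_start,ci_halfwidth_end Log-scale CI half-width drift.
#' @param p_significant_start,p_significant_end Target probability that a
#'   planted CI excludes 1 (set both to `NULL` to leave significance
#'   emergent).
#' @param ci_level_probs Named probabilities over CI levels 90/95/99.
#' @param trap_rate Probability a trap sentence is inserted in an abstract.
#' @param style_probs Named weights over the registered rendering styles
#'   (see [render_mention()]); zero-weight styles are never drawn.
#' @param p_review Probability a citation is a review.
#' @param p_pmc Probability a citation carries a PMCID.
#' @param seed Integer master seed; every abstract derives its own
#'   substream from it, so generation is reproducible and insensitive to
#'   evaluation order.
#' @return A list of class `esm_sim_config`.
#' @export
sim_config <- function(months = 0:311,
                       abstracts_per_month = 7,
                       p_has_es = 0.5,
                       es_count_probs = 0.3 * 0.7^(0:7) / sum(0.3 * 0.7^(0:7)),
                       log_es_scale_start = 1.36,
                       log_es_scale_end = 1.11,
                       ci_halfwidth_start = 0.70,
                       ci_halfwidth_end = 0.54,
                       p_significant_start = 0.74,
                       p_significant_end = 0.85,
                       ci_level_probs = c("90" = 0.05, "95" = 0.90, "99" = 0.05),
                       trap_rate = 0.10,
                       style_probs = default_style_probs(),
                       p_review = 0.10,
                       p_pmc = 0.20,
                       seed = 1L) {
  stopifnot(
    all(months >= 0), all(months <= 311),
    abstracts_per_month >= 1,
    p_has_es >= 0, p_has_es <= 1,
    abs(sum(es_count_probs) - 1) < 1e-8,
    log_es_scale_start > 0, log_es_scale_end > 0,
    ci_halfwidth_start > 0, ci_halfwidth_end > 0,
    trap_rate >= 0, trap_rate <= 1,
    all(names(ci_level_probs) %in% c("90", "95", "99")),
    abs(sum(ci_level_probs) - 1) < 1e-8
  )
  if (xor(is.null(p_significant_start), is.null(p_significant_end))) {
    abort("p_significant_start/_end must be set together or both NULL")
  }
  unknown <- setdiff(names(style_probs), names(mention_styles()))
  if (length(unknown) > 0L) {
    abort(paste0("unknown style(s): ", paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      months = as.integer(months),
      abstracts_per_month = as.integer(abstracts_per_month),
      p_has_es = p_has_es,
      es_count_probs = es_count_probs,
      log_es_scale_start = log_es_scale_start,
      log_es_scale_end = log_es_scale_end,
      ci_halfwidth_start = ci_halfwidth_start,
      ci_halfwidth_end = ci_halfwidth_end,
      p_significant_start = p_significant_start,
      p_significant_end = p_significant_end,
      ci_level_probs = ci_level_probs,
      trap_rate = trap_rate,
      style_probs = style_probs[style_probs > 0],
      p_review = p_review,
      p_pmc = p_pmc,
      seed = as.integer(seed)
    ),
    class = "esm_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_style_probs <- function() {
  detectable <- setdiff(names(mention_styles()), "undetectable")
  c(
    stats::setNames(rep(0.95 / length(detectable), length(detectable)),
      detectable
    ),
    undetectable = 0.05
  )
}

# --- rendering styles ----------------------------------------------------

fmt_num <- function(x, digits) sprintf("%.*f", digits, x)

#' Mention rendering styles
#'
#' `mention_styles()` lists the registered sentence templates;
#' `render_mention()` instantiates one for a planted statement.  Styles
#' cover acronym vs full wording, adjusted variants, `=`/`:`/comma
#' separators, `()`/`[]` bracket dialects, hyphen/en-dash/"to" ranges, CI
#' level placed before or after the limits or omitted (95 only), and the
#' dedicated `undetectable` style whose value sits beyond any reasonable
#' pairing window (excluded from sensitivity scoring).
#'
#' @param truth A one-row list or tibble with `es_type`, `adjusted`,
#'   `value`, `ci_level`, `ci_lower`, `ci_upper` (already rounded to the
#'   rendered precision) and `digits`.
#' @param style A style name from `mention_styles()`.
#' @return `render_mention()`: the sentence text.
#' @export
render_mention <- function(truth, style) {
  styles <- mention_styles()
  if (!style %in% names(styles)) {
    abort(paste0("unknown rendering style: ", style))
  }
  styles[[style]](truth)
}

#' @rdname render_mention
#' @export
mention_styles <- function() {
  full_name <- c(OR = "odds ratio", RR = "relative risk", HR = "hazard ratio")
  v <- function(tr) fmt_num(tr$value, tr$digits)
  lo <- function(tr) fmt_num(tr$ci_lower, tr$digits)
  hi <- function(tr) fmt_num(tr$ci_upper, tr$digits)
  list(
    acr_eq_paren = function(tr) {
      sprintf(
        "%s = %s (%d%% CI %s-%s).", tr$es_type, v(tr), tr$ci_level,
        lo(tr), hi(tr)
      )
    },
    acr_colon_to = function(tr) {
      sprintf(
        "%s: %s (%d%% CI: %s to %s).", tr$es_type, v(tr), tr$ci_level,
        lo(tr), hi(tr)
      )
    },
    acr_square = function(tr) {
      sprintf(
        "%s %s [%d%% CI %s-%s].", tr$es_type, v(tr), tr$ci_level,
        lo(tr), hi(tr)
      )
    },
    full_prose = function(tr) {
      sprintf(
        "The %s was %s (%d%% confidence interval: %s to %s).",
        full_name[[tr$es_type]], v(tr), tr$ci_level, lo(tr), hi(tr)
      )
    },
    full_hyphen = function(tr) {
      sprintf(
        "The pooled %s was %s (%d%% CI, %s-%s).",
        gsub(" ", "-", full_name[[tr$es_type]]), v(tr), tr$ci_level,
        lo(tr), hi(tr)
      )
    },
    adj_acr = function(tr) {
      sprintf(
        "a%s = %s (%d%% CI, %s-%s).", tr$es_type, v(tr), tr$ci_level,
        lo(tr), hi(tr)
      )
    },
    adj_full_square = function(tr) {
      sprintf(
        "The adjusted %s was %s [%d%% CI %s-%s].",
        full_name[[tr$es_type]], v(tr), tr$ci_level, lo(tr), hi(tr)
      )
    },
    level_after = function(tr) {
      sprintf(
        "%s = %s (%s-%s; %d%% CI).", tr$es_type, v(tr), lo(tr), hi(tr),
        tr$ci_level
      )
    },
    endash_range = function(tr) {
      sprintf(
        "%s = %s (%d%% CI %s–%s).", tr$es_type, v(tr), tr$ci_level,
        lo(tr), hi(tr)
      )
    },
    no_level = function(tr) {
      # only drawn when the true level is 95 (the detector's default)
      sprintf("%s = %s (%s to %s).", tr$es_type, v(tr), lo(tr), hi(tr))
    },
    comma_bounds = function(tr) {
      sprintf(
        "%s = %s (%d%% CI, %s, %s).", tr$es_type, v(tr), tr$ci_level,
        lo(tr), hi(tr)
      )
    },
    undetectable = function(tr) {
      sprintf(
        paste0(
          "The %s for the composite endpoint, estimated after exhaustive ",
          "prespecified sensitivity analyses accounting for demographic, ",
          "socioeconomic, clinical, behavioural, and lifestyle covariates ",
          "in the final pooled multilevel model, was %s (%d%% CI %s-%s)."
        ),
        tr$es_type, v(tr), tr$ci_level, lo(tr), hi(tr)
      )
    }
  )
}

trap_templates <- list(
  HR = c(
    "Heart rate (HR) was %d (95%% CI, %d-%d) at rest.",
    "Mean heart rate (HR) decreased to %d (95%% CI, %d-%d) beats per minute."
  ),
  RR = c(
    "The respiratory rate (RR) was %d (95%% CI, %d-%d) breaths per minute.",
    "The overall response rate (RR) reached %d (95%% CI, %d-%d) percent."
  ),
  OR = c(
    "The ovulation rate (OR) was %d (95%% CI, %d-%d) percent.",
    "Median time in the operating room (OR) was %d (95%% CI, %d-%d) minutes."
  )
)

fill_template <- function(tmpl, n) {
  if (grepl("%d", tmpl, fixed = TRUE)) sprintf(tmpl, n) else tmpl
}

filler_templates <- c(
  "We conducted a population-based cohort study including %d participants.",
  "Baseline characteristics were broadly similar between the study groups.",
  "Participants were recruited from %d centres and followed prospectively.",
  "Outcomes were ascertained through record linkage and blinded adjudication.",
  "Sensitivity analyses yielded consistent findings across subgroups."
)

sim_journals <- tibble::tibble(
  issn = c("9000-0001", "9000-0002", "9000-0003", "9000-0004", "9000-0005"),
  title = c(
    "Synthetic Journal of Biomedical Research",
    "Synthetic Open Access Journal of Epidemiology",
    "Synthetic Core Clinical Journal of Medicine",
    "Synthetic Archives of Population Health",
    "Synthetic Open Access Clinical Reports"
  ),
  weight = c(0.35, 0.2, 0.2, 0.15, 0.1)
)

sim_countries <- tibble::tibble(
  country = c(
    "United States", "United Kingdom", "France", "Germany", "Japan",
    "China", "Brazil", "Australia", "Canada", "South Africa", "India",
    "Sweden"
  ),
  weight = c(0.22, 0.12, 0.1, 0.1, 0.08, 0.12, 0.05, 0.05, 0.06, 0.03,
    0.04, 0.03
  )
)

.sim_cache <- new.env(parent = emptyenv())

sim_mesh_pool <- function() {
  if (is.null(.sim_cache$mesh_pool)) {
    tbl <- load_mesh_tree(esm_extdata("mesh-tree-example.tsv"))
    .sim_cache$mesh_pool <- tbl$descriptor
  }
  .sim_cache$mesh_pool
}

# --- generation ----------------------------------------------------------

#' Generate a synthetic PubMed-style corpus with ground truth
#'
#' Generates abstracts with planted OR/RR/HR statements (values, CIs, and
#' rendering styles drawn per [sim_config()]), trap sentences, and citation
#' metadata (dates, journals, publication types, MeSH descriptors,
#' affiliations), together with the exact gold table used for scoring.
#' Fully deterministic given `config$seed`: each abstract draws from its own
#' counter-derived substream.
#'
#' Planted values follow sign(ln ES) = +/-1 equiprobably with half-normal
#' `|ln ES|`; CIs are geometric around the value (`L = v exp(-w)`,
#' `U = v exp(+w)`), preserving the protective/risk inversion symmetry.
#' When a significance target is set, the half-width is adapted so the CI
#' excludes or spans 1 as drawn.  Rendered numbers are rounded to the
#' style's decimal precision and the gold table records the rounded
#' (printed) numbers -- the printed statement is the ground truth.
#'
#' @param config An [sim_config()] list.
#' @param dir Optional output directory; when given, writes
#'   `corpus-001.xml` (PubmedArticleSet), `gold.tsv`, and `config.yaml`.
#' @return A list of class `esm_sim_corpus`: `citations` (tibble in the
#'   layout of [parse_pubmed_citations()]), `gold` (tibble: `source_id`,
#'   `planted`, `detectable`, `es_type`, `adjusted`, `value`, `ci_level`,
#'   `ci_lower`, `ci_upper`, `style`, `trap_phrase`, `month_index`), and
#'   `paths` (when `dir` was given).
#' @export
generate_corpus <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "esm_sim_config"))
  grid <- expand.grid(
    slot = seq_len(config$abstracts_per_month),
    month = config$months
  )
  n <- nrow(grid)
  months_lo <- min(config$months)
  months_hi <- max(config$months)
  span <- max(months_hi - months_lo, 1L)

  cit_list <- vector("list", n)
  gold_list <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- (config$seed %% 100003L) * 10007L + i * 13L
    res <- withr::with_seed(
      sub_seed %% .Machine$integer.max,
      simulate_abstract(
        config,
        id = sprintf("SIM%07d", i),
        month_index = grid$month[i],
        frac = (grid$month[i] - months_lo) / span
      )
    )
    cit_list[[i]] <- res$citation
    gold_list[[i]] <- res$gold
  }
  citations <- dplyr::bind_rows(cit_list)
  gold <- dplyr::bind_rows(gold_list)

  out <- structure(
    list(citations = citations, gold = gold, paths = NULL),
    class = "esm_sim_corpus"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    xml_path <- file.path(dir, "corpus-001.xml")
    writeLines(citations_to_pubmed_xml(citations), xml_path, useBytes = TRUE)
    gold_path <- file.path(dir, "gold.tsv")
    gw <- gold
    readr::write_tsv(gw, gold_path, na = "")
    cfg_path <- file.path(dir, "config.yaml")
    yaml::write_yaml(config_echo(config), cfg_path)
    out$paths <- list(xml = xml_path, gold = gold_path, config = cfg_path)
  }
  out
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$months <- paste0(min(cfg$months), ":", max(cfg$months))
  cfg$es_count_probs <- as.numeric(cfg$es_count_probs)
  cfg$ci_level_probs <- as.list(cfg$ci_level_probs)
  cfg$style_probs <- as.list(cfg$style_probs)
  cfg
}

simulate_abstract <- function(config, id, month_index, frac) {
  lerp <- function(a, b) a + (b - a) * frac
  scale_now <- lerp(config$log_es_scale_start, config$log_es_scale_end)
  hw_now <- lerp(config$ci_halfwidth_start, config$ci_halfwidth_end)
  p_sig_now <- if (is.null(config$p_significant_start)) {
    NULL
  } else {
    lerp(config$p_significant_start, config$p_significant_end)
  }

  has_es <- runif(1) < config$p_has_es
  sentences <- fill_template(sample(filler_templates, 1), sample(200:5000, 1))

  gold <- NULL
  if (has_es) {
    k <- sample(seq_along(config$es_count_probs), 1,
      prob = config$es_count_probs
    )
    drawn <- purrr::map(seq_len(k), function(j) {
      draw_mention(config, scale_now, hw_now, p_sig_now)
    })
    sentences <- c(
      sentences,
      vapply(drawn, function(d) d$sentence, character(1))
    )
    gold <- dplyr::bind_rows(purrr::map(drawn, "gold"))
  }

  trap <- runif(1) < config$trap_rate
  if (trap) {
    acr <- sample(names(trap_templates), 1)
    tmpl <- sample(trap_templates[[acr]], 1)
    centre <- sample(40:110, 1)
    sentence <- sprintf(tmpl, centre, centre - sample(2:8, 1),
      centre + sample(2:8, 1)
    )
    sentences <- c(sentences, sentence)
    gold <- dplyr::bind_rows(gold, tibble::tibble(
      planted = FALSE, detectable = NA, es_type = acr, adjusted = NA,
      value = NA_real_, ci_level = NA_integer_, ci_lower = NA_real_,
      ci_upper = NA_real_, style = "trap",
      trap_phrase = tolower(stringr::str_match(tmpl, "^[^(]*")[, 1])
    ))
  }
  if (runif(1) < 0.5) {
    sentences <- c(
      sentences,
      fill_template(sample(filler_templates, 1), sample(2:40, 1))
    )
  }

  jr <- sim_journals[
    sample(nrow(sim_journals), 1, prob = sim_journals$weight),
  ]
  review <- runif(1) < config$p_review
  n_mesh <- sample(0:3, 1, prob = c(0.15, 0.35, 0.3, 0.2))
  mesh <- if (n_mesh > 0) sample(sim_mesh_pool(), n_mesh) else character(0)
  cross <- runif(1) < 0.052
  n_aff <- if (cross) 2L else 1L
  countries <- sample(sim_countries$country, n_aff,
    prob = sim_countries$weight
  )
  affiliations <- sprintf(
    "Department of Epidemiology, University Hospital, %s.", countries
  )
  pmcid <- if (runif(1) < config$p_pmc) {
    sprintf("PMC%06d", sample(1e5:999999, 1))
  } else {
    NA_character_
  }

  citation <- tibble::tibble(
    pmid = id,
    pmcid = pmcid,
    abstract_text = paste(sentences, collapse = " "),
    pub_year = month_index_to_year(month_index),
    pub_month = month_index_to_month(month_index),
    journal_title = jr$title,
    journal_issn = jr$issn,
    pub_types = list(c(
      "Journal Article",
      if (review) "Review"
    )),
    mesh_descriptors = list(mesh),
    affiliations = list(affiliations)
  )
  if (!is.null(gold) && nrow(gold) > 0L) {
    gold$source_id <- id
    gold$month_index <- month_index
    gold <- gold[, c(
      "source_id", "planted", "detectable", "es_type", "adjusted", "value",
      "ci_level", "ci_lower", "ci_upper", "style", "trap_phrase",
      "month_index"
    )]
  }
  list(citation = citation, gold = gold)
}

# Draw one planted statement: value, CI, style; returns the rendered
# sentence plus its gold record (rounded, i.e. printed, numbers).
draw_mention <- function(config, scale_now, hw_now, p_sig_now) {
  es_type <- sample(c("OR", "RR", "HR"), 1)
  sgn <- sample(c(-1, 1), 1)
  abs_log <- abs(rnorm(1, 0, scale_now))
  # degenerate |ln v| cannot be forced significant; nudge away from 0
  if (abs_log < 0.03) abs_log <- 0.03
  value <- exp(sgn * abs_log)

  w <- hw_now * exp(rnorm(1, 0, 0.2))
  want_sig <- NULL
  if (!is.null(p_sig_now)) {
    want_sig <- runif(1) < p_sig_now
    if (want_sig && w >= 0.85 * abs_log) {
      w <- runif(1, 0.3, 0.85) * abs_log
    } else if (!want_sig && w <= 1.15 * abs_log) {
      w <- abs_log * runif(1, 1.15, 1.6)
    }
  }
  lower <- value * exp(-w)
  upper <- value * exp(w)

  style <- sample(names(config$style_probs), 1, prob = config$style_probs)
  level <- as.integer(sample(
    names(config$ci_level_probs), 1,
    prob = config$ci_level_probs
  ))
  if (style == "no_level") level <- 95L
  digits <- sample(1:3, 1, prob = c(0.25, 0.6, 0.15))
  # near-neutral values need two decimals, or the printed CI could not
  # stay on one side of 1
  if (abs_log < 0.12) digits <- max(digits, 2L)

  # the printed (rounded) numbers are the ground truth
  value_r <- round(value, digits)
  lower_r <- round(lower, digits)
  upper_r <- round(upper, digits)
  if (value_r <= 0) value_r <- 10^-digits
  if (lower_r <= 0) lower_r <- 10^-digits
  if (upper_r < value_r) upper_r <- value_r

  # rounding may undo the drawn significance (a bound landing exactly on
  # 1); nudge the printed bound so the statement realizes the draw
  if (!is.null(want_sig)) {
    eps <- 10^-digits
    sig_now <- upper_r < 1 || lower_r > 1
    if (want_sig && !sig_now) {
      if (value >= 1) {
        lower_r <- min(value_r, 1 + eps)
      } else {
        upper_r <- max(value_r, 1 - eps)
      }
    } else if (!want_sig && sig_now) {
      if (value >= 1) lower_r <- 1 else upper_r <- 1
    }
  }

  adjusted <- style %in% c("adj_acr", "adj_full_square")
  truth <- list(
    es_type = es_type, adjusted = adjusted, value = value_r,
    ci_level = level, ci_lower = lower_r, ci_upper = upper_r,
    digits = digits
  )
  list(
    sentence = render_mention(truth, style),
    gold = tibble::tibble(
      planted = TRUE,
      detectable = style != "undetectable",
      es_type = es_type, adjusted = adjusted, value = value_r,
      ci_level = level, ci_lower = lower_r, ci_upper = upper_r,
      style = style, trap_phrase = NA_character_
    )
  )
}

# --- XML serialization ---------------------------------------------------

citations_to_pubmed_xml <- function(citations) {
  article <- function(i) {
    ct <- citations[i, ]
    mesh <- ct$mesh_descriptors[[1]]
    affs <- ct$affiliations[[1]]
    pts <- ct$pub_types[[1]]
    paste0(
      "<PubmedArticle><MedlineCitation><PMID>", xml_escape(ct$pmid),
      "</PMID><Article><Journal><ISSN>", xml_escape(ct$journal_issn),
      "</ISSN><JournalIssue><PubDate><Year>", ct$pub_year,
      "</Year><Month>", month.abb[ct$pub_month],
      "</Month></PubDate></JournalIssue><Title>",
      xml_escape(ct$journal_title), "</Title></Journal>",
      "<ArticleTitle>Synthetic citation ", xml_escape(ct$pmid),
      "</ArticleTitle>",
      if (nzchar(ct$abstract_text)) {
        paste0(
          "<Abstract><AbstractText>", xml_escape(ct$abstract_text),
          "</AbstractText></Abstract>"
        )
      } else {
        ""
      },
      "<AuthorList>",
      paste0(
        "<Author><LastName>Author</LastName><AffiliationInfo><Affiliation>",
        xml_escape(affs), "</Affiliation></AffiliationInfo></Author>",
        collapse = ""
      ),
      "</AuthorList><PublicationTypeList>",
      paste0(
        "<PublicationType>", xml_escape(pts), "</PublicationType>",
        collapse = ""
      ),
      "</PublicationTypeList></Article>",
      if (length(mesh) > 0L) {
        paste0(
          "<MeshHeadingList>",
          paste0(
            "<MeshHeading><DescriptorName>", xml_escape(mesh),
            "</DescriptorName></MeshHeading>",
            collapse = ""
          ),
          "</MeshHeadingList>"
        )
      } else {
        ""
      },
      "</MedlineCitation>",
      if (!is.na(ct$pmcid)) {
        paste0(
          "<PubmedData><ArticleIdList><ArticleId IdType=\"pmc\">",
          xml_escape(ct$pmcid),
          "</ArticleId></ArticleIdList></PubmedData>"
        )
      } else {
        ""
      },
      "</PubmedArticle>"
    )
  }
  c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<PubmedArticleSet>",
    vapply(seq_len(nrow(citations)), article, character(1)),
    "</PubmedArticleSet>"
  )
}
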