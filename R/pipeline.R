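# End-to-end gene normalization: parse -> soft-tag (n-best CRF, both
# directions) -> confidence scoring + threshold -> abbreviation filter ->
# species designation -> dictionary retrieval / regex filter / resolution
# -> per-article GeneID output.

#' Pipeline configuration
#'
#' Defaults follow the task settings: top 20 solutions per parsing
#' direction (40 combined), confidence threshold 0.2, retrieval cap 50,
#' species rules 1+2+3.
#'
#' @param fwd_model,bwd_model Fitted `gn_crf` taggers (or paths to
#'   [write_crf_model()] files).
#' @param scorer A `gn_scorer` (or path).
#' @param gene_index A `gn_gene_index` (or a gene_info-layout TSV path).
#' @param species_dict A `gn_species_dict` (or TSV path).
#' @param k Solutions per direction (default 20).
#' @param threshold Variant confidence threshold (default 0.2).
#' @param cap Retrieval candidate cap (default 50).
#' @param rules Species rule subset, default `c(1, 2, 3)`.
#' @param use_abbrev_filter Apply the abbreviation veto (default TRUE).
#' @param default_taxid Fallback TaxID when no species rule fires (default
#'   none: such variants are dropped with a warning).
#' @param taxid_redirect Named vector redirecting designated TaxIDs before
#'   retrieval (e.g. `c("4932" = 559292)` for a dictionary whose yeast
#'   records migrated).
#' @param seed Seed recorded in the config (inference is deterministic).
#' @return List of class `gn_config`.
#' @export
pipeline_config <- function(fwd_model, bwd_model, scorer, gene_index,
                            species_dict, k = 20L, threshold = 0.2,
                            cap = 50L, rules = c(1L, 2L, 3L),
                            use_abbrev_filter = TRUE, default_taxid = NULL,
                            taxid_redirect = NULL, seed = 1L) {
  if (is.character(fwd_model)) fwd_model <- read_crf_model(fwd_model)
  if (is.character(bwd_model)) bwd_model <- read_crf_model(bwd_model)
  if (is.character(scorer)) scorer <- read_scorer(scorer)
  if (is.character(gene_index)) gene_index <- build_gene_index(load_gene_info(gene_index))
  if (is.character(species_dict)) species_dict <- load_species_dict(species_dict)
  stopifnot(inherits(fwd_model, "gn_crf"), inherits(bwd_model, "gn_crf"),
            inherits(scorer, "gn_scorer"), inherits(gene_index, "gn_gene_index"),
            inherits(species_dict, "gn_species_dict"),
            k >= 1L, threshold >= 0, threshold <= 1, cap >= 1L,
            all(rules %in% 1:3))
  structure(list(fwd_model = fwd_model, bwd_model = bwd_model,
                 scorer = scorer, gene_index = gene_index,
                 species_dict = species_dict, k = as.integer(k),
                 threshold = threshold, cap = as.integer(cap),
                 rules = as.integer(rules),
                 use_abbrev_filter = isTRUE(use_abbrev_filter),
                 default_taxid = default_taxid,
                 taxid_redirect = taxid_redirect, seed = as.integer(seed)),
            class = "gn_config")
}

# soft-tag one document: article-wide variant table above the threshold
soft_tag_document <- function(doc, config) {
  sents <- doc_sentences(doc)
  rows <- list()
  for (s in sents) {
    if (!nrow(s$tokens)) next
    fwd <- decode_nbest(config$fwd_model, s$tokens$surface, config$k)
    bwd <- decode_nbest(config$bwd_model, s$tokens$surface, config$k)
    v <- extract_variants(combine_solutions(fwd, bwd), s)
    if (!nrow(v)) next
    v <- score_and_filter(v, s, config$scorer, config$threshold)
    if (!nrow(v)) next
    v$sentence <- s$index
    rows[[length(rows) + 1L]] <- v
  }
  if (!length(rows)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      count = integer(), frequency = numeric(),
                      score = numeric(), sentence = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Run the full gene normalization pipeline
#'
#' For each article: parse and section-filter, decode the top-k label
#' solutions of both CRF models per sentence, extract and score overlapping
#' variants, drop those under the threshold, apply the abbreviation veto,
#' designate a TaxID per variant (dropping unassignable ones with a
#' warning), resolve each variant through dictionary retrieval, anchored
#' regex filtering and the GeneID heuristics, keep one GeneID per overlap
#' group (longest resolved variant), and aggregate to one row per
#' (article, GeneID) keeping the maximum confidence score. Per-article
#' failures are warned about and skipped. Deterministic given models,
#' dictionaries and config.
#'
#' @param articles Character vector of file paths (XML or plain text), or a
#'   list of `gn_document`s, or a `gn_corpus`.
#' @param config A `gn_config`.
#' @return Object of class `gn_run`: `results` (data.frame `article_id`,
#'   `gene_id`, `score`, `taxid`, `variant`, `start`, `end`,
#'   `species_rule`, sorted by descending score within article) and
#'   `funnel` (per-article stage counts).
#' @export
run_pipeline <- function(articles, config) {
  stopifnot(inherits(config, "gn_config"))
  docs <- as_documents(articles)
  res_rows <- list(); funnel_rows <- list()
  for (doc in docs) {
    out <- tryCatch(run_one_article(doc, config), error = function(e) {
      warning("article ", doc$article_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(out)) next
    if (nrow(out$results)) res_rows[[length(res_rows) + 1L]] <- out$results
    funnel_rows[[length(funnel_rows) + 1L]] <- out$funnel
  }
  results <- if (length(res_rows)) do.call(rbind, res_rows) else
    data.frame(article_id = character(), gene_id = integer(),
               score = numeric(), taxid = integer(), variant = character(),
               start = integer(), end = integer(), species_rule = integer(),
               stringsAsFactors = FALSE)
  rownames(results) <- NULL
  structure(list(results = results,
                 funnel = if (length(funnel_rows)) do.call(rbind, funnel_rows)
                 else NULL),
            class = "gn_run")
}

as_documents <- function(articles) {
  if (inherits(articles, "gn_corpus")) {
    paths <- write_corpus_xml(articles, tempfile("gn_corpus_"))
    articles <- paths
  }
  if (is.character(articles)) {
    lapply(articles, function(p) {
      txt <- paste(readLines(p, encoding = "UTF-8", warn = FALSE),
                   collapse = "\n")
      id <- sub("\\.[^.]*$", "", basename(p))
      doc <- parse_article(txt)
      if (doc$article_id == "article") doc$article_id <- id
      doc
    })
  } else {
    stopifnot(all(vapply(articles, inherits, logical(1), "gn_document")))
    articles
  }
}

run_one_article <- function(doc, config) {
  doc <- filter_sections(doc)
  sents <- doc_sentences(doc)
  variants <- soft_tag_document(doc, config)
  n_tagged <- nrow(variants)
  if (config$use_abbrev_filter && nrow(variants)) {
    pairs <- detect_abbrev_pairs(doc)
    variants <- filter_by_abbrev(variants, pairs)
  }
  n_after_abbrev <- nrow(variants)
  mentions <- find_species_mentions(doc, config$species_dict)
  n_resolved <- 0L
  rows <- list()
  if (nrow(variants)) {
    des <- lapply(seq_len(nrow(variants)), function(i)
      designate_species(variants[i, ], mentions, config$species_dict,
                        rules = config$rules,
                        default_taxid = config$default_taxid))
    variants$taxid <- vapply(des, function(d) d$taxid, 0L)
    variants$species_rule <- vapply(des, function(d) d$rule, 0L)
    dropped <- is.na(variants$taxid)
    if (any(dropped)) {
      warning(sum(dropped), " variant(s) in ", doc$article_id,
              " had no species designation and were dropped")
      variants <- variants[!dropped, , drop = FALSE]
    }
    if (!is.null(config$taxid_redirect) && nrow(variants)) {
      hit <- match(as.character(variants$taxid), names(config$taxid_redirect))
      variants$taxid[!is.na(hit)] <-
        as.integer(config$taxid_redirect[hit[!is.na(hit)]])
    }
    if (nrow(variants)) {
      variants$geneid <- vapply(seq_len(nrow(variants)), function(i) {
        q <- compile_query(variants$text[i], variants$taxid[i])
        cand <- retrieve_candidates(config$gene_index, q, config$cap)
        resolve_candidates(regex_filter(cand, q))
      }, 0L)
      n_resolved <- sum(!is.na(variants$geneid))
      # one GeneID per overlap group per sentence
      for (sid in unique(variants$sentence)) {
        vs <- variants[variants$sentence == sid, , drop = FALSE]
        comp <- overlap_components(vs)
        for (cid in unique(comp)) {
          pick <- disambiguate_overlapping(vs[comp == cid, , drop = FALSE])
          if (is.null(pick)) next
          w <- pick$variant
          rows[[length(rows) + 1L]] <- data.frame(
            article_id = doc$article_id, gene_id = pick$geneid,
            score = pick$score, taxid = w$taxid, variant = w$text,
            start = w$start, end = w$end, species_rule = w$species_rule,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(article_id = character(), gene_id = integer(),
               score = numeric(), taxid = integer(), variant = character(),
               start = integer(), end = integer(), species_rule = integer(),
               stringsAsFactors = FALSE)
  if (nrow(results)) {
    # max score per (article, gene)
    o <- order(-results$score, results$gene_id, results$start)
    results <- results[o, , drop = FALSE]
    results <- results[!duplicated(results$gene_id), , drop = FALSE]
    results <- results[order(-results$score, results$gene_id), , drop = FALSE]
    rownames(results) <- NULL
  }
  funnel <- data.frame(article_id = doc$article_id, n_sentences = length(sents),
                       variants_tagged = n_tagged,
                       after_abbrev = n_after_abbrev,
                       resolved = n_resolved, output = nrow(results),
                       stringsAsFactors = FALSE)
  list(results = results, funnel = funnel)
}

#' @export
print.gn_run <- function(x, ...) {
  cat("<gn_run> ", length(unique(x$results$article_id)), " article(s), ",
      nrow(x$results), " GeneID record(s)\n", sep = "")
  invisible(x)
}

#' Write pipeline results as TSV
#'
#' Header `article_id, gene_id, score, taxid, variant, start, end,
#' species_rule`; rows sorted by article then descending score — stable, so
#' reruns with identical inputs are byte-identical.
#'
#' @param run A `gn_run` (or its `results` data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(run, path) {
  results <- if (inherits(run, "gn_run")) run$results else run
  o <- order(results$article_id, -results$score, results$gene_id)
  results <- results[o, , drop = FALSE]
  results$score <- sprintf("%.6f", results$score)
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Union of two runs
#'
#' Merges result tables; a (article, GeneID) pair present in both keeps the
#' maximum score.
#'
#' @param run1,run2 `gn_run` objects or result data.frames.
#' @return Merged results data.frame.
#' @export
merge_runs <- function(run1, run2) {
  r1 <- if (inherits(run1, "gn_run")) run1$results else run1
  r2 <- if (inherits(run2, "gn_run")) run2$results else run2
  all <- rbind(r1, r2)
  o <- order(all$article_id, all$gene_id, -all$score)
  all <- all[o, , drop = FALSE]
  all <- all[!duplicated(paste(all$article_id, all$gene_id)), , drop = FALSE]
  all <- all[order(all$article_id, -all$score, all$gene_id), , drop = FALSE]
  rownames(all) <- NULL
  all
}
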