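# Evaluation: article-level precision/recall/F-score and TAP-k over
# score-ranked gene lists, plus the per-article funnel report.

#' Micro-averaged precision, recall and F-score
#'
#' Counts (article, gene) pairs: TP = predicted and gold, FP = predicted
#' only, FN = gold only, pooled over articles.
#'
#' @param predicted data.frame with columns `article_id`, `gene_id`.
#' @param gold data.frame with columns `article_id`, `gene_id`.
#' @param average `"micro"` (default, the BioCreative convention) or
#'   `"macro"` (per-article P/R averaged).
#' @return `list(precision=, recall=, f_score=, tp=, fp=, fn=)`.
#' @export
prf <- function(predicted, gold, average = c("micro", "macro")) {
  average <- match.arg(average)
  pk <- unique(paste(predicted$article_id, predicted$gene_id, sep = "\r"))
  gk <- unique(paste(gold$article_id, gold$gene_id, sep = "\r"))
  tp <- sum(pk %in% gk); fp <- length(pk) - tp; fn <- length(gk) - sum(gk %in% pk)
  if (average == "micro") {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
  } else {
    arts <- unique(c(predicted$article_id, gold$article_id))
    ps <- rs <- numeric(0)
    for (a in arts) {
      pa <- unique(predicted$gene_id[predicted$article_id == a])
      ga <- unique(gold$gene_id[gold$article_id == a])
      if (length(pa)) ps <- c(ps, sum(pa %in% ga) / length(pa))
      if (length(ga)) rs <- c(rs, sum(ga %in% pa) / length(ga))
    }
    p <- if (length(ps)) mean(ps) else 0
    r <- if (length(rs)) mean(rs) else 0
  }
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_score = f, tp = tp, fp = fp, fn = fn)
}

# TAP for one ranked 0/1 relevance vector and the number of gold items:
# average precision truncated at the k-th false positive, with a terminal
# precision term at the cutoff and denominator (gold + 1)
tap_one <- function(rel, n_gold, k) {
  if (!length(rel)) return(0)
  fp_ranks <- which(rel == 0)
  cutoff <- if (length(fp_ranks) >= k) fp_ranks[k] else length(rel)
  rel <- rel[seq_len(cutoff)]
  prec_at <- cumsum(rel) / seq_along(rel)
  s <- sum(prec_at[rel == 1]) + prec_at[cutoff]
  s / (n_gold + 1)
}

#' Threshold average precision at k false positives (TAP-k)
#'
#' For each article the score-ranked prediction list is truncated at its
#' k-th false positive (or the list end if fewer occur); the truncated
#' average precision gains a terminal precision-at-cutoff term and is
#' divided by (number of gold genes + 1). The per-article values are
#' averaged over all gold-bearing articles (articles with no predictions
#' contribute 0).
#'
#' @param predicted data.frame: `article_id`, `gene_id`, `score`.
#' @param gold data.frame: `article_id`, `gene_id`.
#' @param k Number of tolerated false positives (e.g. 5, 10, 20).
#' @return Numeric TAP-k in \[0, 1\].
#' @export
tap_k <- function(predicted, gold, k) {
  stopifnot(k >= 1)
  arts <- unique(gold$article_id)
  vals <- vapply(arts, function(a) {
    ga <- unique(gold$gene_id[gold$article_id == a])
    pa <- predicted[predicted$article_id == a, , drop = FALSE]
    if (!nrow(pa)) return(0)
    pa <- pa[order(-pa$score, pa$gene_id), , drop = FALSE]
    pa <- pa[!duplicated(pa$gene_id), , drop = FALSE]
    tap_one(as.integer(pa$gene_id %in% ga), length(ga), k)
  }, 0)
  mean(vals)
}

#' Per-article funnel statistics of a run
#'
#' Output-list lengths and false-positive counts (min/median/max) and the
#' total false-negative percentage against the gold key.
#'
#' @param predicted data.frame: `article_id`, `gene_id`.
#' @param gold data.frame: `article_id`, `gene_id`.
#' @return `list(records=, false_positives=, fn_total=, fn_percent=,
#'   per_article=)` where `records` and `false_positives` are
#'   `c(min, median, max)` summaries.
#' @export
funnel_report <- function(predicted, gold) {
  arts <- unique(c(predicted$article_id, gold$article_id))
  per <- data.frame(article_id = arts, n_out = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(arts)) {
    pa <- unique(predicted$gene_id[predicted$article_id == arts[i]])
    ga <- unique(gold$gene_id[gold$article_id == arts[i]])
    per$n_out[i] <- length(pa)
    per$fp[i] <- sum(!pa %in% ga)
    per$fn[i] <- sum(!ga %in% pa)
  }
  n_gold <- length(unique(paste(gold$article_id, gold$gene_id)))
  fn_total <- sum(per$fn)
  list(records = c(min = min(per$n_out), median = stats::median(per$n_out),
                   max = max(per$n_out)),
       false_positives = c(min = min(per$fp), median = stats::median(per$fp),
                           max = max(per$fp)),
       fn_total = fn_total,
       fn_percent = if (n_gold > 0) 100 * fn_total / n_gold else 0,
       per_article = per)
}

#' Evaluate a prediction TSV against a gold TSV
#'
#' Convenience wrapper producing the metric table used throughout:
#' precision, recall, F-score and TAP-k for k in 5, 10, 20.
#'
#' @param predicted data.frame (`article_id`, `gene_id`, `score`) or a path
#'   to a [write_results()] TSV.
#' @param gold data.frame (`article_id`, `gene_id`) or a TSV path with those
#'   columns.
#' @return One-row data.frame: `precision`, `recall`, `f_score`, `tap5`,
#'   `tap10`, `tap20`.
#' @export
evaluate_run <- function(predicted, gold) {
  if (is.character(predicted)) predicted <- utils::read.delim(predicted)
  if (is.character(gold)) gold <- utils::read.delim(gold)
  m <- prf(predicted, gold)
  data.frame(precision = m$precision, recall = m$recall, f_score = m$f_score,
             tap5 = tap_k(predicted, gold, 5),
             tap10 = tap_k(predicted, gold, 10),
             tap20 = tap_k(predicted, gold, 20))
}
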