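# Soft tagging: overlapping mention variants with frequencies, feature
# vectors, logistic-regression confidence scores, threshold filtering and
# the recursive non-overlapping max-score selector.

#' Extract overlapping variants from combined n-best solutions
#'
#' Every distinct `(text, span)` pair occurring in any solution becomes one
#' variant; its frequency is its occurrence count across the solution
#' multiset divided by the number of solutions (40 at the defaults: top 20
#' per parsing direction). Label sequences are passed through
#' [ibo2_repair()] before span extraction. Overlapping variants are
#' retained — that is the point.
#'
#' @param solutions Solution list from [combine_solutions()] (or
#'   [decode_nbest()]).
#' @param sentence A sentence object: `list(text=, tokens=)` with tokens from
#'   [tokenize_fine()].
#' @return data.frame with columns `text`, `start`, `end`, `count`,
#'   `frequency`, ordered by `start`, `end`.
#' @export
extract_variants <- function(solutions, sentence) {
  nsol <- length(solutions)
  if (!nsol) stop("no solutions")
  tab <- new.env(parent = emptyenv())
  for (s in solutions) {
    men <- ibo2_to_mentions(ibo2_repair(s$labels), sentence$tokens, sentence$text)
    if (!nrow(men)) next
    keys <- paste(men$start, men$end, sep = ":")
    for (i in seq_len(nrow(men))) {
      cur <- get0(keys[i], envir = tab, inherits = FALSE)
      if (is.null(cur)) {
        assign(keys[i], list(text = men$text[i], start = men$start[i],
                             end = men$end[i], count = 1L), envir = tab)
      } else {
        cur$count <- cur$count + 1L
        assign(keys[i], cur, envir = tab)
      }
    }
  }
  vals <- mget(ls(tab), envir = tab)
  if (!length(vals)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      count = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(text = vapply(vals, `[[`, "", "text"),
                    start = vapply(vals, `[[`, 0L, "start"),
                    end = vapply(vals, `[[`, 0L, "end"),
                    count = vapply(vals, `[[`, 0L, "count"),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / nsol
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# content tokens: lowercase, punctuation removed, then tokenized
content_tokens <- function(text) {
  cleaned <- gsub("[^A-Za-z0-9 ]+", " ", tolower(text))
  toks <- strsplit(trimws(gsub("\\s+", " ", cleaned)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Feature vector of one variant
#'
#' Four families: the continuous solution frequency; nine morphological
#' flags (has / starts-with / ends-with x uppercase / lowercase / digit);
#' binary content-token indicators over the variant's normalized tokens
#' (lowercased, punctuation stripped); and binary context-token indicators
#' over the two sentence tokens on each side of the variant span (fewer at
#' sentence edges).
#'
#' @param variant One row of an [extract_variants()] data.frame (or any list
#'   with `text`, `start`, `end`, `frequency`).
#' @param sentence Sentence object `list(text=, tokens=)`.
#' @return `list(frequency=, binary=)` where `binary` is a character vector
#'   of active feature names.
#' @export
featurize_variant <- function(variant, sentence) {
  text <- variant$text
  f <- character(0)
  if (grepl("[A-Z]", text)) f <- c(f, "m:has_upper")
  if (grepl("[a-z]", text)) f <- c(f, "m:has_lower")
  if (grepl("[0-9]", text)) f <- c(f, "m:has_digit")
  first <- substr(text, 1, 1); last <- substr(text, nchar(text), nchar(text))
  if (grepl("[A-Z]", first)) f <- c(f, "m:start_upper")
  if (grepl("[a-z]", first)) f <- c(f, "m:start_lower")
  if (grepl("[0-9]", first)) f <- c(f, "m:start_digit")
  if (grepl("[A-Z]", last)) f <- c(f, "m:end_upper")
  if (grepl("[a-z]", last)) f <- c(f, "m:end_lower")
  if (grepl("[0-9]", last)) f <- c(f, "m:end_digit")
  f <- c(f, paste0("c:", unique(content_tokens(text))))
  toks <- sentence$tokens
  before <- which(toks$end <= variant$start)
  after <- which(toks$start >= variant$end)
  ctx <- c(utils::tail(before, 2L), utils::head(after, 2L))
  if (length(ctx)) f <- c(f, paste0("x:", unique(tolower(toks$surface[ctx]))))
  list(frequency = as.numeric(variant$frequency), binary = unique(f))
}

featurize_all <- function(variants, sentence) {
  lapply(seq_len(nrow(variants)), function(i)
    featurize_variant(variants[i, ], sentence))
}

#' Build a scorer training set from a tagged corpus
#'
#' Labels every extracted variant positive iff its `(start, end)` span
#' equals a curator-identified gold mention or an acceptable alternative
#' span of its sentence, else negative — exact-span identity, overlap is
#' not enough.
#'
#' @param sentences List of sentence objects each carrying `text`, `tokens`,
#'   `gold` and `acceptable` (data.frames with `start`, `end`).
#' @param variants_by_sentence List (parallel to `sentences`) of
#'   [extract_variants()] data.frames.
#' @return `list(features=, labels=, variants=)`: feature list, 0/1 integer
#'   labels, and the row-bound variant table with a `sentence` column.
#' @export
build_training_set <- function(sentences, variants_by_sentence) {
  stopifnot(length(sentences) == length(variants_by_sentence))
  features <- list(); labels <- integer(); rows <- list()
  for (i in seq_along(sentences)) {
    sen <- sentences[[i]]
    v <- variants_by_sentence[[i]]
    if (!nrow(v)) next
    ok <- rbind(span_df(sen$gold), span_df(sen$acceptable))
    key <- paste(ok$start, ok$end)
    pos <- paste(v$start, v$end) %in% key
    features <- c(features, featurize_all(v, sen))
    labels <- c(labels, as.integer(pos))
    v$sentence <- i
    rows[[length(rows) + 1L]] <- v
  }
  list(features = features, labels = labels,
       variants = if (length(rows)) do.call(rbind, rows) else NULL)
}

span_df <- function(x) {
  if (is.null(x) || !NROW(x)) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = x$start, end = x$end)
}

## ---- logistic-regression scorer ------------------------------------------

build_design <- function(features, vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(lapply(features, `[[`, "binary"))))
  }
  n <- length(features)
  ii <- integer(); jj <- integer()
  for (i in seq_len(n)) {
    j <- match(features[[i]]$binary, vocab)
    j <- j[!is.na(j)]
    ii <- c(ii, rep(i, length(j))); jj <- c(jj, j)
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n, length(vocab)))
  freq <- vapply(features, `[[`, 0, "frequency")
  X <- cbind(Matrix::Matrix(freq, ncol = 1, sparse = TRUE), X)
  colnames(X) <- c("frequency", vocab)
  list(X = X, vocab = vocab)
}

#' Train the logistic-regression variant scorer
#'
#' Ridge-penalized logistic regression ([glmnet::cv.glmnet], `alpha = 0`)
#' with the penalty strength chosen by 5-fold cross-validation on
#' misclassification error; folds are fixed by `seed`. The fitted model's
#' output is a confidence score strictly inside (0, 1). The binary-feature
#' vocabulary is taken from the training data (frequency floor 1); unseen
#' tokens at inference activate no feature.
#'
#' @param features List of [featurize_variant()] vectors.
#' @param labels 0/1 vector, both classes present.
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Fold-assignment seed.
#' @return Object of class `gn_scorer`: `vocab`, `coef` (named, incl.
#'   `(Intercept)` and `frequency`), `lambda`, `cv_accuracy`.
#' @export
train_scorer <- function(features, labels, nfolds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("training labels contain a single class")
  stopifnot(length(features) == length(labels))
  d <- build_design(features)
  foldid <- local({
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
    sample(rep_len(seq_len(nfolds), length(labels)))
  })
  fit <- glmnet::cv.glmnet(d$X, labels, family = "binomial", alpha = 0,
                           type.measure = "class", foldid = foldid,
                           standardize = FALSE)
  cf <- as.matrix(stats::coef(fit, s = "lambda.min"))[, 1]
  structure(list(vocab = d$vocab, coef = cf, lambda = fit$lambda.min,
                 cv_accuracy = 1 - fit$cvm[fit$index["min", 1]]),
            class = "gn_scorer")
}

#' @export
print.gn_scorer <- function(x, ...) {
  cat("<gn_scorer> logistic scorer: ", length(x$vocab), " binary features + frequency; ",
      "CV accuracy ", round(x$cv_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Score variants with a fitted scorer
#'
#' @param features Feature list from [featurize_all()] /
#'   [featurize_variant()].
#' @param model A `gn_scorer`.
#' @return Numeric scores in (0, 1).
#' @export
score_variants <- function(features, model) {
  stopifnot(inherits(model, "gn_scorer"))
  if (!length(features)) return(numeric(0))
  d <- build_design(features, vocab = model$vocab)
  eta <- as.numeric(d$X %*% model$coef[colnames(d$X)]) + model$coef["(Intercept)"]
  stats::plogis(eta)
}

#' Score variants and drop those below the confidence threshold
#'
#' The retained set shrinks monotonically as the threshold rises — the
#' recall/precision trade-off dial of soft tagging. The task default
#' threshold is 0.2.
#'
#' @param variants [extract_variants()] data.frame.
#' @param sentence Sentence object.
#' @param model A `gn_scorer`.
#' @param threshold Minimum confidence score kept (default 0.2).
#' @return `variants` with a `score` column, rows with `score >= threshold`.
#' @export
score_and_filter <- function(variants, sentence, model, threshold = 0.2) {
  if (!nrow(variants)) {
    variants$score <- numeric(0)
    return(variants)
  }
  variants$score <- score_variants(featurize_all(variants, sentence), model)
  out <- variants[variants$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select one maximal-score variant per overlap neighbourhood
#'
#' The recursive selector used for hard gene-mention output: pick the
#' globally maximal-score variant, discard every variant overlapping it,
#' recurse on the remainder. Ties on score prefer the longer variant, then
#' the leftmost. The result is an independent set in the overlap graph and
#' each selected variant has the maximum score among all input variants it
#' overlaps.
#'
#' @param variants data.frame with `start`, `end`, `score` (error if
#'   unscored).
#' @return Subset of `variants`, ordered by `start`.
#' @export
select_nonoverlapping_max <- function(variants) {
  if (is.null(variants$score) || anyNA(variants$score)) {
    stop("variants must be scored before selection")
  }
  keep <- integer(0)
  idx <- seq_len(nrow(variants))
  while (length(idx)) {
    len <- variants$end[idx] - variants$start[idx]
    o <- order(-variants$score[idx], -len, variants$start[idx])
    best <- idx[o[1]]
    keep <- c(keep, best)
    ov <- variants$start[idx] < variants$end[best] &
      variants$start[best] < variants$end[idx]
    idx <- idx[!ov]
  }
  out <- variants[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Write / read the scorer as a versioned flat text file
#'
#' @param model A `gn_scorer`.
#' @param path File path.
#' @export
write_scorer <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#genenorm-scorer\t1",
               sprintf("lambda\t%.17g", model$lambda),
               sprintf("cv_accuracy\t%.17g", model$cv_accuracy)), con)
  for (nm in names(model$coef)) {
    writeLines(sprintf("C\t%s\t%.17g", nm, model$coef[[nm]]), con)
  }
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!startsWith(lines[1], "#genenorm-scorer")) stop("not a genenorm scorer file")
  lam <- as.numeric(sub("^lambda\t", "", lines[startsWith(lines, "lambda\t")][1]))
  acc <- as.numeric(sub("^cv_accuracy\t", "", lines[startsWith(lines, "cv_accuracy\t")][1]))
  parts <- strsplit(lines[startsWith(lines, "C\t")], "\t", fixed = TRUE)
  cf <- vapply(parts, function(p) as.numeric(p[3]), 0)
  names(cf) <- vapply(parts, `[[`, "", 2)
  vocab <- setdiff(names(cf), c("(Intercept)", "frequency"))
  structure(list(vocab = vocab, coef = cf, lambda = lam, cv_accuracy = acc),
            class = "gn_scorer")
}

#' Dump variants as TSV
#'
#' Columns: article, sentence, start, end, text, frequency, score.
#' @param variants data.frame with those columns (missing ones filled NA).
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  cols <- c("article", "sentence", "start", "end", "text", "frequency", "score")
  for (cl in setdiff(cols, names(variants))) variants[[cl]] <- NA
  utils::write.table(variants[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# save/restore .Random.seed so generators and fold assignment don't disturb
# the caller's RNG stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
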