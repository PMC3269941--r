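# Linear-chain CRF over IBO2 labels {B, I, O} with exact top-k Viterbi
# decoding and bidirectional (forward / reversed-sequence) models.
#
# Parameterization: per-label emission weights for sparse indicator features,
# a 3x3 transition matrix and a length-3 start vector, all in the log domain.
# The joint score of a labeling y for tokens x is
#   S(y|x) = start[y1] + sum_t emit(x, t, y_t) + sum_t trans[y_{t-1}, y_t].

CRF_LABELS <- c("B", "I", "O")

#' Construct a CRF model from explicit weights
#'
#' Low-level constructor used for testing and deserialization. `W` holds one
#' emission weight per (feature, label); features fire by string identity via
#' the model's template set.
#'
#' @param features Character vector of feature strings (row names of `W`).
#' @param W Numeric matrix, `length(features)` x 3 (columns B, I, O).
#' @param trans Numeric 3x3 transition matrix (rows = previous label).
#' @param start Numeric length-3 start-label vector.
#' @param direction `"forward"` or `"backward"`.
#' @param templates Character vector naming the active feature templates.
#' @return Object of class `gn_crf`.
#' @export
crf_model <- function(features, W, trans, start, direction = "forward",
                      templates = default_crf_templates()) {
  stopifnot(is.matrix(W), ncol(W) == 3L, nrow(W) == length(features),
            all(is.finite(W)), all(is.finite(trans)), all(is.finite(start)),
            direction %in% c("forward", "backward"))
  dimnames(W) <- list(NULL, CRF_LABELS)
  dimnames(trans) <- list(CRF_LABELS, CRF_LABELS)
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(features)) assign(features[i], i, envir = idx)
  structure(list(features = features, index = idx, W = W, trans = trans,
                 start = as.numeric(start), direction = direction,
                 templates = templates),
            class = "gn_crf")
}

#' @export
print.gn_crf <- function(x, ...) {
  cat("<gn_crf> ", x$direction, " model: ", length(x$features),
      " features x 3 labels\n", sep = "")
  invisible(x)
}

#' Default feature templates for the gene-mention tagger
#'
#' Word identity, lowercased word, character prefixes/suffixes of lengths
#' 2-4, orthographic shape flags, and a window of lowercased words at
#' offsets -2..+2. Part-of-speech templates are deliberately absent.
#'
#' @return Character vector of template names.
#' @export
default_crf_templates <- function() {
  c("word", "lower", "prefix", "suffix", "shape", "window", "bias")
}

# Feature strings for one position of a token sequence.
token_features <- function(words, t, templates) {
  w <- words[t]
  lw <- tolower(w)
  n <- length(words)
  f <- character(0)
  if ("bias" %in% templates) f <- c(f, "b")
  if ("word" %in% templates) f <- c(f, paste0("w=", w))
  if ("lower" %in% templates) f <- c(f, paste0("lw=", lw))
  if ("prefix" %in% templates) {
    for (l in 2:4) if (nchar(w) >= l) f <- c(f, paste0("p", l, "=", substr(w, 1, l)))
  }
  if ("suffix" %in% templates) {
    nc <- nchar(w)
    for (l in 2:4) if (nc >= l) f <- c(f, paste0("s", l, "=", substr(w, nc - l + 1, nc)))
  }
  if ("shape" %in% templates) {
    if (grepl("^[A-Z]", w)) f <- c(f, "sh=ic")
    if (grepl("^[A-Z]+$", w) && nchar(w) > 1) f <- c(f, "sh=ac")
    if (grepl("^[a-z]+$", w)) f <- c(f, "sh=lo")
    if (grepl("[0-9]", w)) f <- c(f, "sh=dg")
    if (grepl("^[0-9]+$", w)) f <- c(f, "sh=ad")
    if (grepl("^[^A-Za-z0-9]$", w)) f <- c(f, paste0("sh=pu:", w))
    if (grepl("[A-Z]", w) && grepl("[0-9]", w)) f <- c(f, "sh=an")
    if (grepl("^[A-Za-z]$", w)) f <- c(f, "sh=sl")
  }
  if ("window" %in% templates) {
    for (d in c(-2L, -1L, 1L, 2L)) {
      tt <- t + d
      val <- if (tt >= 1L && tt <= n) tolower(words[tt]) else "<pad>"
      f <- c(f, paste0("x", d, "=", val))
    }
  }
  f
}

# integer feature ids per position; unknown features dropped
sentence_feature_ids <- function(model, words) {
  lapply(seq_along(words), function(t) {
    fs <- token_features(words, t, model$templates)
    ids <- unlist(lapply(fs, function(x) {
      v <- get0(x, envir = model$index, inherits = FALSE)
      if (is.null(v)) integer(0) else v
    }), use.names = FALSE)
    as.integer(ids)
  })
}

# n x 3 emission matrix (start weights folded into row 1)
emission_matrix <- function(model, fid_list) {
  n <- length(fid_list)
  E <- matrix(0, n, 3L)
  for (t in seq_len(n)) {
    ids <- fid_list[[t]]
    if (length(ids)) E[t, ] <- colSums(model$W[ids, , drop = FALSE])
  }
  E[1L, ] <- E[1L, ] + model$start
  E
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

check_ibo2 <- function(labels, where = "") {
  if (!all(labels %in% CRF_LABELS)) {
    stop("invalid label(s) ", paste(setdiff(unique(labels), CRF_LABELS), collapse = ", "),
         if (nzchar(where)) paste0(" in ", where))
  }
  prev <- c("O", labels[-length(labels)])
  bad <- which(labels == "I" & prev == "O")
  if (length(bad)) {
    stop("invalid IBO2 sequence (I follows O or starts the sentence) at position ",
         bad[1], if (nzchar(where)) paste0(" in ", where))
  }
  invisible(TRUE)
}

#' Repair an IOB label sequence into valid IBO2
#'
#' An `I` at the sentence start or directly after `O` is read as `B`.
#'
#' @param labels Character vector over `{B, I, O}`.
#' @return Valid IBO2 label vector.
#' @export
ibo2_repair <- function(labels) {
  prev <- c("O", labels[-length(labels)])
  labels[labels == "I" & prev == "O"] <- "B"
  labels
}

# Reverse a token sequence's IBO2 labeling: mention spans are mirrored and
# re-encoded so the result is valid IBO2 in the reversed reading order.
reverse_ibo2 <- function(labels) {
  n <- length(labels)
  runs <- label_runs(labels)
  out <- rep("O", n)
  for (r in seq_len(nrow(runs))) {
    a <- n + 1L - runs$to[r]; b <- n + 1L - runs$from[r]
    out[a] <- "B"
    if (b > a) out[(a + 1L):b] <- "I"
  }
  out
}

# data.frame(from, to) of token-index runs B(I)* in a valid IBO2 labeling
label_runs <- function(labels) {
  from <- integer(); to <- integer()
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (labels[i] == "B") {
      j <- i
      while (j < n && labels[j + 1L] == "I") j <- j + 1L
      from <- c(from, i); to <- c(to, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(from = from, to = to)
}

#' Score one labeling under a CRF model
#'
#' Joint (unnormalized, log-domain) model score of an arbitrary label
#' sequence; used by enumeration oracles and model inspection.
#'
#' @param model A `gn_crf` (its `direction` is ignored: tokens/labels are
#'   taken as given, in model order).
#' @param tokens Character vector of token surfaces.
#' @param labels Character vector over `{B, I, O}`, same length.
#' @return Numeric scalar score.
#' @export
score_labeling <- function(model, tokens, labels) {
  stopifnot(length(tokens) == length(labels), all(labels %in% CRF_LABELS))
  fid <- sentence_feature_ids(model, tokens)
  E <- emission_matrix(model, fid)
  y <- match(labels, CRF_LABELS)
  s <- sum(E[cbind(seq_along(y), y)])
  if (length(y) > 1L) s <- s + sum(model$trans[cbind(y[-length(y)], y[-1L])])
  s
}

## ---- training -------------------------------------------------------------

validate_corpus <- function(corpus) {
  if (!length(corpus)) stop("empty training corpus")
  for (i in seq_along(corpus)) {
    s <- corpus[[i]]
    if (length(s$tokens) != length(s$labels)) {
      stop("sentence ", i, ": tokens/labels length mismatch")
    }
    check_ibo2(s$labels, where = paste0("sentence ", i))
  }
}

#' Train a linear-chain CRF gene-mention tagger
#'
#' L2-regularized maximum likelihood fitted with L-BFGS-B; fully
#' deterministic (zero initialization). A `"backward"` model is trained on
#' reversed token sequences with mention spans mirrored and re-encoded as
#' IBO2.
#'
#' @param corpus List of sentences: each `list(tokens=, labels=)` with IBO2
#'   labels over `{B, I, O}`.
#' @param direction `"forward"` (default) or `"backward"`.
#' @param templates Feature templates, see [default_crf_templates()].
#' @param lambda L2 penalty weight (default 1).
#' @param maxit Optimizer iteration cap.
#' @return A fitted `gn_crf`.
#' @export
train_crf <- function(corpus, direction = "forward",
                      templates = default_crf_templates(),
                      lambda = 1, maxit = 200L) {
  validate_corpus(corpus)
  if (direction == "backward") {
    corpus <- lapply(corpus, function(s)
      list(tokens = rev(s$tokens), labels = reverse_ibo2(s$labels)))
  }
  # feature dictionary
  idx <- new.env(parent = emptyenv())
  feats <- character(0)
  fid_list <- vector("list", length(corpus))
  ylab <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    words <- corpus[[i]]$tokens
    ylab[[i]] <- match(corpus[[i]]$labels, CRF_LABELS)
    per_pos <- vector("list", length(words))
    for (t in seq_along(words)) {
      fs <- token_features(words, t, templates)
      ids <- integer(length(fs))
      for (j in seq_along(fs)) {
        v <- get0(fs[j], envir = idx, inherits = FALSE)
        if (is.null(v)) {
          feats <- c(feats, fs[j])
          v <- length(feats)
          assign(fs[j], v, envir = idx)
        }
        ids[j] <- v
      }
      per_pos[[t]] <- ids
    }
    fid_list[[i]] <- per_pos
  }
  nf <- length(feats)
  npar <- nf * 3L + 9L + 3L
  unpack <- function(par) {
    list(W = matrix(par[seq_len(nf * 3L)], nf, 3L),
         trans = matrix(par[nf * 3L + seq_len(9L)], 3L, 3L),
         start = par[nf * 3L + 9L + seq_len(3L)])
  }
  negll <- function(par) {
    p <- unpack(par)
    val <- 0; gW <- matrix(0, nf, 3L); gT <- matrix(0, 3L, 3L); gS <- numeric(3L)
    for (i in seq_along(corpus)) {
      fp <- fid_list[[i]]; y <- ylab[[i]]; n <- length(y)
      E <- matrix(0, n, 3L)
      for (t in seq_len(n)) {
        ids <- fp[[t]]
        if (length(ids)) E[t, ] <- colSums(p$W[ids, , drop = FALSE])
      }
      E[1L, ] <- E[1L, ] + p$start
      # forward / backward
      alpha <- matrix(0, n, 3L); alpha[1L, ] <- E[1L, ]
      if (n > 1L) for (t in 2:n) for (j in 1:3)
        alpha[t, j] <- logsumexp(alpha[t - 1L, ] + p$trans[, j]) + E[t, j]
      beta <- matrix(0, n, 3L)
      if (n > 1L) for (t in (n - 1L):1L) for (j in 1:3)
        beta[t, j] <- logsumexp(p$trans[j, ] + E[t + 1L, ] + beta[t + 1L, ])
      logZ <- logsumexp(alpha[n, ])
      sc <- sum(E[cbind(seq_len(n), y)])
      if (n > 1L) sc <- sc + sum(p$trans[cbind(y[-n], y[-1L])])
      val <- val + (logZ - sc)
      # node marginals -> emission gradient (expected - observed)
      P <- exp(alpha + beta - logZ)
      dE <- P
      dE[cbind(seq_len(n), y)] <- dE[cbind(seq_len(n), y)] - 1
      for (t in seq_len(n)) {
        ids <- fp[[t]]
        if (length(ids)) gW[ids, ] <- gW[ids, ] + rep(dE[t, ], each = length(ids))
      }
      gS <- gS + dE[1L, ]
      if (n > 1L) for (t in 2:n) {
        Q <- exp(matrix(alpha[t - 1L, ], 3L, 3L) + p$trans +
                   matrix(E[t, ] + beta[t, ], 3L, 3L, byrow = TRUE) - logZ)
        Q[cbind(y[t - 1L], y[t])] <- Q[cbind(y[t - 1L], y[t])] - 1
        gT <- gT + Q
      }
    }
    val <- val + lambda * sum(par^2)
    grad <- c(as.numeric(gW), as.numeric(gT), gS) + 2 * lambda * par
    attr(val, "gradient") <- grad
    val
  }
  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    v <- negll(par)
    assign("par", par, envir = cache); assign("grad", attr(v, "gradient"), envir = cache)
    as.numeric(v)
  }
  gr <- function(par) {
    if (exists("par", envir = cache) && identical(par, get("par", envir = cache))) {
      return(get("grad", envir = cache))
    }
    attr(negll(par), "gradient")
  }
  opt <- stats::optim(rep(0, npar), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e8))
  p <- unpack(opt$par)
  crf_model(feats, p$W, p$trans, p$start, direction = direction,
            templates = templates)
}

## ---- k-best decoding ------------------------------------------------------

#' Exact top-k Viterbi decoding
#'
#' Returns the `min(k, 3^n)` highest-scoring label sequences of the model's
#' unnormalized joint score, in non-increasing score order; ties (scores
#' compared at 1e-9 resolution, so that mathematically equal paths summed
#' in different orders still tie) are broken lexicographically on the label
#' string with B < I < O. Backward models
#' decode the reversed token sequence and return labelings re-mapped to the
#' original sentence order. Exact: per-state k-best list Viterbi
#' (max-product lattice generalized to ranked lists).
#'
#' @param model A `gn_crf`.
#' @param tokens Character vector of token surfaces (sentence order).
#' @param k Number of solutions per model (default 20).
#' @return List of solutions `list(labels=, score=)`, class `gn_solutions`.
#' @export
decode_nbest <- function(model, tokens, k = 20L) {
  stopifnot(inherits(model, "gn_crf"), k >= 1L)
  if (!length(tokens)) stop("empty token list")
  words <- if (model$direction == "backward") rev(tokens) else tokens
  fid <- sentence_feature_ids(model, words)
  E <- emission_matrix(model, fid)
  n <- length(words)
  kk <- min(k, 3^n)
  # per-state hypothesis lists: scores + label strings
  hs <- lapply(1:3, function(j) list(score = E[1L, j], seq = CRF_LABELS[j]))
  if (n > 1L) {
    for (t in 2:n) {
      nxt <- vector("list", 3L)
      for (j in 1:3) {
        sc <- unlist(lapply(1:3, function(i) hs[[i]]$score + model$trans[i, j] + E[t, j]))
        sq <- unlist(lapply(1:3, function(i) paste0(hs[[i]]$seq, CRF_LABELS[j])))
        o <- order(-round(sc, 9), sq)[seq_len(min(kk, length(sc)))]
        nxt[[j]] <- list(score = sc[o], seq = sq[o])
      }
      hs <- nxt
    }
  }
  sc <- unlist(lapply(hs, `[[`, "score"))
  sq <- unlist(lapply(hs, `[[`, "seq"))
  o <- order(-round(sc, 9), sq)[seq_len(min(kk, length(sc)))]
  out <- lapply(o, function(i) {
    labs <- strsplit(sq[i], "", fixed = TRUE)[[1]]
    if (model$direction == "backward") labs <- reverse_ibo2(ibo2_repair(labs))
    list(labels = labs, score = sc[i])
  })
  structure(out, class = "gn_solutions")
}

#' Combine forward and backward n-best solutions
#'
#' Plain concatenation: the combined multiset (size `|fwd| + |bwd|`,
#' duplicates retained) is the denominator of variant frequencies.
#'
#' @param fwd,bwd Solution lists from [decode_nbest()] on the same sentence.
#' @return Concatenated solution list.
#' @export
combine_solutions <- function(fwd, bwd) {
  all <- c(unclass(fwd), unclass(bwd))
  len <- unique(vapply(all, function(s) length(s$labels), integer(1)))
  if (length(len) > 1L) stop("solutions decoded on different token counts")
  structure(all, class = "gn_solutions")
}

#' Decode an IBO2 labeling into mention spans
#'
#' Each maximal `B(I)*` run becomes one mention whose text is the sentence
#' substring from the first to the last token of the run.
#'
#' @param labels IBO2 label vector (invalid sequences are an error; see
#'   [ibo2_repair()]).
#' @param tokens Token data.frame from [tokenize_fine()] (columns `surface`,
#'   `start`, `end`).
#' @param sentence_text The sentence string the offsets index into.
#' @return data.frame with columns `text`, `start`, `end` (0-based half-open
#'   character offsets in the sentence).
#' @export
ibo2_to_mentions <- function(labels, tokens, sentence_text) {
  stopifnot(length(labels) == nrow(tokens))
  check_ibo2(labels)
  runs <- label_runs(labels)
  if (!nrow(runs)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- tokens$start[runs$from]
  end <- tokens$end[runs$to]
  data.frame(text = substring(sentence_text, start + 1L, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

## ---- serialization --------------------------------------------------------

#' Write / read a CRF model as a versioned flat text file
#'
#' Tab-separated: header lines (`version`, `direction`, `templates`), then
#' one line per transition, start and emission weight.
#'
#' @param model A `gn_crf`.
#' @param path File path.
#' @return `read_crf_model` returns the reconstructed `gn_crf`.
#' @export
write_crf_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#genenorm-crf\t1",
               paste0("direction\t", model$direction),
               paste0("templates\t", paste(model$templates, collapse = ","))), con)
  for (i in 1:3) for (j in 1:3)
    writeLines(sprintf("T\t%s\t%s\t%.17g", CRF_LABELS[i], CRF_LABELS[j],
                       model$trans[i, j]), con)
  for (j in 1:3)
    writeLines(sprintf("S\t%s\t%.17g", CRF_LABELS[j], model$start[j]), con)
  for (i in seq_along(model$features)) {
    nz <- which(model$W[i, ] != 0)
    for (j in nz)
      writeLines(paste("F", model$features[i], CRF_LABELS[j],
                       sprintf("%.17g", model$W[i, j]), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_crf_model
#' @export
read_crf_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!startsWith(lines[1], "#genenorm-crf")) stop("not a genenorm CRF model file")
  direction <- sub("^direction\t", "", lines[startsWith(lines, "direction\t")][1])
  templates <- strsplit(sub("^templates\t", "",
                            lines[startsWith(lines, "templates\t")][1]), ",")[[1]]
  body <- lines[grepl("^[TSF]\t", lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  trans <- matrix(0, 3, 3); start <- numeric(3)
  featw <- list()
  for (p in parts) {
    if (p[1] == "T") {
      trans[match(p[2], CRF_LABELS), match(p[3], CRF_LABELS)] <- as.numeric(p[4])
    } else if (p[1] == "S") {
      start[match(p[2], CRF_LABELS)] <- as.numeric(p[3])
    } else {
      key <- p[2]
      if (is.null(featw[[key]])) featw[[key]] <- numeric(3)
      featw[[key]][match(p[3], CRF_LABELS)] <- as.numeric(p[4])
    }
  }
  feats <- names(featw)
  W <- if (length(feats)) do.call(rbind, featw) else matrix(0, 0, 3)
  crf_model(feats, W, trans, start, direction = direction, templates = templates)
}
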