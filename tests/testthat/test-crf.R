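test_that("training validates labels and rejects malformed sequences", {
  expect_error(train_crf(list()), "empty")
  bad <- list(list(tokens = c("a", "b"), labels = c("B", "X")))
  expect_error(train_crf(bad), "invalid label")
  iafter <- list(list(tokens = c("a", "b"), labels = c("O", "I")))
  expect_error(train_crf(iafter), "sentence 1")
})

test_that("an all-O corpus yields an all-O decoder", {
  corp <- list(list(tokens = c("the", "cat", "sat"), labels = c("O", "O", "O")),
               list(tokens = c("a", "dog", "ran", "by"), labels = rep("O", 4)))
  m <- train_crf(corp, lambda = 0.1, maxit = 50L)
  d <- decode_nbest(m, c("some", "new", "words"), k = 1L)
  expect_equal(d[[1]]$labels, c("O", "O", "O"))
})

test_that("k=1 decoding is the Viterbi path and scores are non-increasing", {
  set.seed(11)
  for (rep in 1:10) {
    toks <- as.character(sample(letters, sample(2:5, 1), replace = TRUE))
    m <- random_word_crf(toks)
    oracle <- enumerate_labelings(m, toks)
    top <- decode_nbest(m, toks, k = 1L)
    expect_equal(paste0(top[[1]]$labels, collapse = ""), oracle$labels[1])
    expect_equal(top[[1]]$score, oracle$score[1], tolerance = 1e-10)
    ks <- decode_nbest(m, toks, k = 12L)
    sc <- vapply(ks, `[[`, 0, "score")
    expect_true(all(diff(sc) <= 1e-12))
  }
  expect_error(decode_nbest(random_word_crf("a"), character(0)), "empty")
})

test_that("trained tagger recovers planted mentions on held-out sentences", {
  held_spec <- corpus_spec(n_sentences = 40L, seed = 99L)
  held <- corpus_conll(make_tagged_corpus(held_spec))
  ok <- 0L; tot <- 0L
  for (s in held) {
    d <- ibo2_repair(decode_nbest(gn_fix$fwd, s$tokens, k = 1L)[[1]]$labels)
    gold <- label_runs(s$labels); got <- label_runs(d)
    tot <- tot + nrow(gold)
    if (nrow(gold)) {
      ok <- ok + sum(paste(gold$from, gold$to) %in% paste(got$from, got$to))
    }
  }
  expect_gte(ok / tot, 0.9)
})

test_that("recall of the variant union is non-decreasing in k", {
  sents <- gn_fix$sentences[1:40]
  recall_at <- function(k) {
    found <- 0L; tot <- 0L
    for (s in sents) {
      if (!nrow(s$gold)) next
      sol <- combine_solutions(decode_nbest(gn_fix$fwd, s$tokens$surface, k),
                               decode_nbest(gn_fix$bwd, s$tokens$surface, k))
      v <- extract_variants(sol, s)
      tot <- tot + nrow(s$gold)
      found <- found + sum(paste(s$gold$start, s$gold$end) %in%
                             paste(v$start, v$end))
    }
    found / tot
  }
  r <- vapply(c(1L, 5L, 20L), recall_at, 0)
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], 0.9)
})

test_that("combining directions concatenates solution multisets", {
  toks <- c("AB", "1", "gene")
  fwd <- decode_nbest(gn_fix$fwd, toks, k = 20L)
  bwd <- decode_nbest(gn_fix$bwd, toks, k = 20L)
  both <- combine_solutions(fwd, bwd)
  expect_length(both, 40L)
  dup <- combine_solutions(fwd, fwd)
  expect_length(dup, 40L)
  expect_length(unique(lapply(dup, `[[`, "labels")), length(fwd))
  one <- combine_solutions(fwd[1], bwd[1])
  expect_length(one, 2L)
  short <- list(list(labels = c("O", "O"), score = 0))
  expect_error(combine_solutions(fwd, short), "token counts")
})

test_that("IBO2 runs decode to the overlapping variant texts of the worked sentence", {
  sent <- make_sent(paste0("Acetyl-CoA carboxylase from yeast is an ",
                           "essential enzyme and is regulated by factors."))
  toks <- sent$tokens
  lab_for <- function(from_txt, to_txt) {
    labs <- rep("O", nrow(toks))
    i <- which(toks$surface == from_txt)[1]; j <- which(toks$surface == to_txt)[1]
    labs[i] <- "B"; if (j > i) labs[(i + 1):j] <- "I"
    labs
  }
  cases <- list(c("Acetyl", "carboxylase"), c("CoA", "carboxylase"),
                c("essential", "enzyme"), c("carboxylase", "carboxylase"),
                c("CoA", "yeast"))
  texts <- vapply(cases, function(cs) {
    ibo2_to_mentions(lab_for(cs[1], cs[2]), toks, sent$text)$text
  }, "")
  expect_equal(texts, c("Acetyl-CoA carboxylase", "CoA carboxylase",
                        "essential enzyme", "carboxylase",
                        "CoA carboxylase from yeast"))
  expect_equal(nrow(ibo2_to_mentions(rep("O", nrow(toks)), toks, sent$text)), 0L)
  # B on the final token is a single-token span
  tail_sent <- make_sent("regulated by factors")
  last <- c("O", "O", "B")
  expect_equal(ibo2_to_mentions(last, tail_sent$tokens, tail_sent$text)$text,
               "factors")
  expect_error(ibo2_to_mentions(c("O", "I", rep("O", nrow(toks) - 2)), toks, sent$text),
               "IBO2")
})

test_that("backward models return labelings aligned to sentence order", {
  # direction-symmetric corpus: the mention token is flanked identically,
  # so both parsing directions must find the same spans
  words <- c("aa", "bb", "cc", "dd")
  corp <- list()
  set.seed(5)
  for (i in 1:30) {
    flank <- sample(words, 2, replace = TRUE)
    toks <- c(flank[1], flank[2], paste0("GENE", sample(1:3, 1)), flank[2], flank[1])
    corp[[i]] <- list(tokens = toks, labels = c("O", "O", "B", "O", "O"))
  }
  fwd <- train_crf(corp, "forward", lambda = 0.1, maxit = 80L)
  bwd <- train_crf(corp, "backward", lambda = 0.1, maxit = 80L)
  test_toks <- c("bb", "aa", "GENE2", "aa", "bb")
  df <- decode_nbest(fwd, test_toks, k = 1L)[[1]]$labels
  db <- decode_nbest(bwd, test_toks, k = 1L)[[1]]$labels
  expect_equal(df, db)
  expect_equal(df, c("O", "O", "B", "O", "O"))
})

test_that("model files round-trip through the flat serialization", {
  path <- tempfile(fileext = ".crf")
  write_crf_model(gn_fix$bwd, path)
  back <- read_crf_model(path)
  expect_equal(back$direction, "backward")
  toks <- c("Expression", "of", "KR", "4", "rose")
  expect_equal(decode_nbest(back, toks, k = 5L),
               decode_nbest(gn_fix$bwd, toks, k = 5L), tolerance = 1e-12)
  expect_error(suppressWarnings(read_crf_model(tempfile())), ".")
})
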