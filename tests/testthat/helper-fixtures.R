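# Shared fixtures: one synthetic corpus with trained forward/backward CRF
# taggers, a variant scorer fitted on the taggers' own n-best output, and
# dictionaries/index for end-to-end runs. Built once per test session.

make_sent <- function(text) list(text = text, tokens = tokenize_fine(text))

doc_sentence_text <- function(doc, idx) {
  genenorm:::doc_sentences(doc)[[idx]]$text
}

# independent trace of the pick-max recursion used to check the overlap
# selector: pick the global max (ties: longer, then leftmost), drop
# everything overlapping it, recurse
select_oracle <- function(v) {
  if (!nrow(v)) return(v[0, ])
  len <- v$end - v$start
  o <- order(-v$score, -len, v$start)
  best <- v[o[1], , drop = FALSE]
  rest <- v[!(v$start < best$end & best$start < v$end), , drop = FALSE]
  rbind(best, select_oracle(rest))
}

gn_fix <- local({
  spec <- corpus_spec(n_sentences = 120L, seed = 42L)
  corpus <- make_tagged_corpus(spec)
  conll <- corpus_conll(corpus)
  fwd <- train_crf(conll, "forward", lambda = 0.3)
  bwd <- train_crf(conll, "backward", lambda = 0.3)
  sents <- list(); vars <- list()
  for (a in corpus$articles) for (s in a$sentences) {
    sol <- combine_solutions(decode_nbest(fwd, s$tokens$surface, 20L),
                             decode_nbest(bwd, s$tokens$surface, 20L))
    sents[[length(sents) + 1L]] <- s
    vars[[length(vars) + 1L]] <- extract_variants(sol, s)
  }
  training <- build_training_set(sents, vars)
  scorer <- train_scorer(training$features, training$labels)
  gene_dict_path <- tempfile("genes_", fileext = ".tsv")
  species_dict_path <- tempfile("species_", fileext = ".tsv")
  make_gene_dict(spec, gene_dict_path)
  make_species_dict(spec, species_dict_path)
  index <- build_gene_index(load_gene_info(gene_dict_path))
  sdict <- load_species_dict(species_dict_path)
  config <- pipeline_config(fwd, bwd, scorer, index, sdict)
  list(spec = spec, corpus = corpus, conll = conll, fwd = fwd, bwd = bwd,
       variants = vars, sentences = sents, scorer = scorer,
       gene_dict_path = gene_dict_path, species_dict_path = species_dict_path,
       index = index, sdict = sdict, config = config,
       gold = corpus_gold_key(corpus))
})

# random small CRF over word-identity features, for decoding oracles
random_word_crf <- function(tokens, direction = "forward") {
  feats <- unique(paste0("w=", tokens))
  crf_model(feats, matrix(stats::rnorm(length(feats) * 3), ncol = 3),
            matrix(stats::rnorm(9), 3, 3), stats::rnorm(3),
            direction = direction, templates = "word")
}

# enumeration oracle: all 3^n labelings scored position-by-position from
# the model's weight tables (independent of the k-best search)
enumerate_labelings <- function(model, tokens) {
  n <- length(tokens)
  E <- matrix(0, n, 3)
  for (t in seq_len(n)) {
    id <- get0(paste0("w=", tokens[t]), envir = model$index, inherits = FALSE)
    if (!is.null(id)) E[t, ] <- model$W[id, ]
  }
  E[1, ] <- E[1, ] + model$start
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  score <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    y <- grid[r, ]
    s <- sum(E[cbind(seq_len(n), y)])
    if (n > 1) s <- s + sum(model$trans[cbind(y[-n], y[-1])])
    score[r] <- s
  }
  labstr <- apply(grid, 1, function(y) paste0(c("B", "I", "O")[y], collapse = ""))
  # same tie policy as the decoder: scores compared at 1e-9 resolution,
  # then lexicographic on the label string
  o <- order(-round(score, 9), labstr)
  list(labels = labstr[o], score = score[o])
}
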