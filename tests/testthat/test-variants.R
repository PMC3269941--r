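fig2_sentence <- make_sent(paste0("Acetyl-CoA carboxylase from yeast is an ",
                                  "essential enzyme and is regulated."))

# a solution tagging the given (from-token, to-token) mention runs
solution_for <- function(sent, runs, score = 0) {
  labs <- rep("O", nrow(sent$tokens))
  for (r in runs) {
    i <- which(sent$tokens$surface == r[1])[1]
    j <- which(sent$tokens$surface == r[2])[1]
    labs[i] <- "B"; if (j > i) labs[(i + 1):j] <- "I"
  }
  list(labels = labs, score = score)
}

test_that("variant frequencies count occurrences across the solution multiset", {
  s <- fig2_sentence
  acc <- c("Acetyl", "carboxylase"); coa <- c("CoA", "carboxylase")
  ess <- c("essential", "enzyme"); carb <- c("carboxylase", "carboxylase")
  coay <- c("CoA", "yeast")
  sols <- list(
    solution_for(s, list(acc)), solution_for(s, list(acc, ess)),
    solution_for(s, list(acc)), solution_for(s, list(coa, ess)),
    solution_for(s, list(coa)), solution_for(s, list(carb)),
    solution_for(s, list(coay)))
  v <- extract_variants(sols, s)
  counts <- stats::setNames(v$count, v$text)
  expect_equal(counts[["Acetyl-CoA carboxylase"]], 3L)
  expect_equal(counts[["CoA carboxylase"]], 2L)
  expect_equal(counts[["essential enzyme"]], 2L)
  expect_equal(counts[["carboxylase"]], 1L)
  expect_equal(counts[["CoA carboxylase from yeast"]], 1L)
  expect_equal(v$frequency, v$count / 7)
  # conservation: occurrence counts sum to total mentions over solutions
  expect_equal(sum(v$count),
               sum(vapply(sols, function(x) nrow(label_runs(x$labels)), 0L)))
  # degenerate cases
  allo <- list(list(labels = rep("O", nrow(s$tokens)), score = 0))
  expect_equal(nrow(extract_variants(allo, s)), 0L)
  one <- list(solution_for(s, list(acc)))
  expect_equal(extract_variants(one, s)$frequency, 1.0)
})

test_that("feature families fire as designed", {
  s <- make_sent("The IL2R protein binds ligand.")
  v <- list(text = "IL2R", start = 4L, end = 8L, frequency = 0.5)
  f <- featurize_variant(v, s)
  expect_true(all(c("m:start_upper", "m:end_upper", "m:has_digit",
                    "m:has_upper") %in% f$binary))
  expect_false("m:start_lower" %in% f$binary)
  expect_equal(f$frequency, 0.5)
  # content token indicator
  s2 <- make_sent("the beta-galactosidase reporter gene was induced")
  v2 <- list(text = "beta-galactosidase reporter gene", start = 4L, end = 36L,
             frequency = 1)
  f2 <- featurize_variant(v2, s2)
  expect_true(all(c("c:gene", "c:reporter", "c:beta", "c:galactosidase")
                  %in% f2$binary))
  # context: two tokens each side; at sentence start only following ones
  expect_true(all(c("x:the", "x:was", "x:induced") %in% f2$binary))
  s3 <- make_sent("KR4 is expressed here.")
  f3 <- featurize_variant(list(text = "KR4", start = 0L, end = 3L, frequency = 1), s3)
  ctx <- grep("^x:", f3$binary, value = TRUE)
  expect_setequal(ctx, c("x:is", "x:expressed"))
})

test_that("training labels are exact-span matches of gold or acceptable spans", {
  txt <- "high amniotic fluid alpha fetoprotein was found"
  s <- make_sent(txt)
  span <- function(piece) {
    st <- regexpr(piece, txt, fixed = TRUE) - 1L
    c(st, st + nchar(piece))
  }
  spans <- lapply(c("amniotic fluid alpha fetoprotein",
                    "fluid alpha fetoprotein", "alpha fetoprotein", "alpha"),
                  span)
  v <- data.frame(text = c("amniotic fluid alpha fetoprotein",
                           "fluid alpha fetoprotein", "alpha fetoprotein",
                           "alpha"),
                  start = vapply(spans, `[`, 0L, 1),
                  end = vapply(spans, `[`, 0L, 2),
                  count = 1L, frequency = 0.25, stringsAsFactors = FALSE)
  s$gold <- data.frame(start = spans[[1]][1], end = spans[[1]][2])
  s$acceptable <- data.frame(start = spans[[3]][1], end = spans[[3]][2])
  ts <- build_training_set(list(s), list(v))
  expect_equal(ts$labels, c(1L, 0L, 1L, 0L))
  # no acceptables: only the exact gold span is positive
  s$acceptable <- NULL
  ts2 <- build_training_set(list(s), list(v))
  expect_equal(ts2$labels, c(1L, 0L, 0L, 0L))
})

make_synth_scorer_data <- function(n, seed = 1, beta = NULL) {
  set.seed(seed)
  vocab <- paste0("c:tok", 1:8)
  if (is.null(beta)) beta <- c(4, c(3, 2.5, 2, -2, -2.5, -3, 1.5, -1.5))
  feats <- vector("list", n); y <- integer(n)
  for (i in 1:n) {
    active <- vocab[stats::runif(8) < 0.4]
    freq <- stats::runif(1)
    eta <- beta[1] * (freq - 0.5) + sum(beta[-1][match(active, vocab)])
    y[i] <- stats::rbinom(1, 1, stats::plogis(2 * eta))
    feats[[i]] <- list(frequency = freq, binary = active)
  }
  list(features = feats, labels = y, beta = beta, vocab = vocab)
}

test_that("the scorer separates a known generative model and reports CV accuracy", {
  d <- make_synth_scorer_data(2000, seed = 3)
  m <- train_scorer(d$features, d$labels)
  expect_s3_class(m, "gn_scorer")
  expect_gte(m$cv_accuracy, 0.9)
  # sign recovery of planted weights
  est <- m$coef[d$vocab]
  expect_true(all(sign(est) == sign(d$beta[-1])))
  # scores are strictly inside (0, 1)
  sc <- score_variants(d$features[1:50], m)
  expect_true(all(sc > 0 & sc < 1))
})

test_that("weight direction converges on a large known-model sample", {
  d <- make_synth_scorer_data(50000, seed = 8)
  m <- train_scorer(d$features, d$labels)
  est <- unname(c(m$coef["frequency"], m$coef[d$vocab]))
  truth <- d$beta
  cosine <- sum(est * truth) / sqrt(sum(est^2) * sum(truth^2))
  expect_gte(cosine, 0.99)
})

test_that("label-independent features give chance-level CV accuracy", {
  d <- make_synth_scorer_data(1500, seed = 5)
  set.seed(9)
  null_labels <- stats::rbinom(length(d$labels), 1, 0.7)
  m <- train_scorer(d$features, null_labels)
  expect_lt(abs(m$cv_accuracy - max(mean(null_labels), 1 - mean(null_labels))),
            0.05)
})

test_that("degenerate scorer inputs behave as specified", {
  d <- make_synth_scorer_data(10, seed = 2)
  d$labels <- rep(c(0L, 1L), 5)
  expect_s3_class(suppressWarnings(train_scorer(d$features, d$labels)),
                  "gn_scorer")
  expect_error(train_scorer(d$features, rep(1L, 10)), "single class")
})

test_that("threshold filtering is monotone and hits its bounds", {
  s <- gn_fix$sentences[[3]]
  v <- gn_fix$variants[[3]]
  skip_if(nrow(v) == 0)
  all_kept <- score_and_filter(v, s, gn_fix$scorer, threshold = 0)
  expect_equal(nrow(all_kept), nrow(v))
  none <- score_and_filter(v, s, gn_fix$scorer, threshold = 1)
  expect_equal(nrow(none), 0L)
  k02 <- score_and_filter(v, s, gn_fix$scorer, threshold = 0.2)
  k05 <- score_and_filter(v, s, gn_fix$scorer, threshold = 0.5)
  expect_true(all(paste(k05$start, k05$end) %in% paste(k02$start, k02$end)))
  expect_true(all(k02$score >= 0.2))
})

test_that("non-overlapping selection follows the pick-max recursion", {
  # worked example: the longer, higher-scoring boundary wins
  v <- data.frame(text = c("human Na,K-ATPase beta", "human Na,K-ATPase"),
                  start = c(0L, 0L), end = c(22L, 17L),
                  score = c(0.9957, 0.9316), stringsAsFactors = FALSE)
  expect_equal(select_nonoverlapping_max(v)$text, "human Na,K-ATPase beta")
  # disjoint variants pass through
  d <- data.frame(text = c("a", "b"), start = c(0L, 10L), end = c(3L, 13L),
                  score = c(0.5, 0.9))
  expect_equal(nrow(select_nonoverlapping_max(d)), 2L)
  # chain A-B-C with B maximal: only B survives
  ch <- data.frame(text = c("A", "B", "C"), start = c(0L, 2L, 6L),
                   end = c(4L, 8L, 10L), score = c(0.6, 0.9, 0.4))
  expect_equal(select_nonoverlapping_max(ch)$text, "B")
  expect_error(select_nonoverlapping_max(data.frame(start = 1, end = 2)),
               "scored")
})

test_that("selection equals the recursion oracle and is an independent set", {
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(1:7, 1)
    st <- sample(0:12, n, replace = TRUE)
    v <- data.frame(text = letters[1:n], start = st,
                    end = st + sample(1:6, n, replace = TRUE),
                    score = round(stats::runif(n), 2), stringsAsFactors = FALSE)
    got <- select_nonoverlapping_max(v)
    got <- got[order(got$start, got$end), , drop = FALSE]
    want <- select_oracle(v)
    want <- want[order(want$start, want$end), , drop = FALSE]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        expect_false(got$start[i] < got$end[j] && got$start[j] < got$end[i])
      }
    }
    # the first pick dominates everything it overlaps in the full input
    top <- got[which.max(got$score), ]
    ov <- v$start < top$end & top$start < v$end
    expect_equal(top$score, max(v$score[ov]))
  }
})

test_that("scorer files round-trip", {
  p <- tempfile(fileext = ".scorer")
  write_scorer(gn_fix$scorer, p)
  back <- read_scorer(p)
  s <- gn_fix$sentences[[5]]
  v <- gn_fix$variants[[5]]
  skip_if(nrow(v) == 0)
  f <- featurize_all(v, s)
  expect_equal(score_variants(f, back), score_variants(f, gn_fix$scorer),
               tolerance = 1e-12)
})
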