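test_that("gene_info rows expand to one record per name per column", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("9606", "3552", "IL1A", "-", "IL-1A|IL1-ALPHA", "MIM:147760", "2",
          "2q14", "interleukin 1 alpha", "protein-coding", "IL1A",
          "interleukin 1 alpha", "O", "IL-1 alpha|hematopoietin-1", "20100522",
          sep = "\t"),
    paste("9606", "9999", "-", "-", "-", "-", "-", "-", "-", "-", "-", "-",
          "-", "-", "-", sep = "\t")), p)
  recs <- load_gene_info(p)
  # IL1A row: Symbol 1 + Synonyms 2 + dbXrefs 1 + description 1 +
  # authority symbol 1 + authority full name 1 + other designations 2 = 9
  expect_equal(nrow(recs[recs$geneid == 3552, ]), 9L)
  expect_true("147760" %in% recs$name[recs$column == "dbXrefs"])
  # all-dash row contributes nothing
  expect_equal(nrow(recs[recs$geneid == 9999, ]), 0L)
  writeLines("9606\t1\tABC", p)
  expect_error(load_gene_info(p), "line 1")
})

test_that("name normalization follows the indexing rules and is idempotent", {
  expect_equal(normalize_name("IL1-ALPHA"), "il 1 alpha")
  expect_equal(normalize_name("DNAbinding"), "dna binding")
  expect_equal(normalize_name("abc"), "abc")
  expect_equal(normalize_name("tumorNECROSIS"), "tumor NECROSIS" |> tolower())
  cases <- c("IL1-ALPHA", "DNAbinding", "IL-1 alpha", "Na,K-ATPase beta",
             "p53", "IL1F5 (Canonical product IL-1F5a)", "abc2.5def")
  expect_equal(normalize_name(normalize_name(cases)), normalize_name(cases))
  # case-collapsing for letter-only strings
  expect_equal(normalize_name("KinaseReceptor"), normalize_name("kinasereceptor"))
})

test_that("queries attach interchange classes and a TaxID constraint", {
  q <- compile_query("IL-1 alpha", 9606)
  expect_equal(q$tokens, c("il", "1", "alpha"))
  expect_true(all(c("1", "i") %in% q$alts[[2]]))
  expect_true(all(c("alpha", "a") %in% q$alts[[3]]))
  expect_equal(q$taxid, 9606L)
  q2 <- compile_query("p53", 9606)
  expect_equal(q2$tokens, c("p", "53"))
  expect_true(all(c("53", "liii") %in% q2$alts[[2]]))
  q3 <- compile_query("abc", 10090)
  expect_equal(q3$tokens, "abc")
  expect_equal(q3$alts[[1]], "abc")
  expect_equal(q3$taxid, 10090L)
})

worked_index <- build_gene_index(load_candidates(
  system.file("extdata", "il1a_candidates.tsv", package = "genenorm")))

test_that("retrieval ranks exact normalized matches first and respects the cap", {
  q <- compile_query("IL-1 alpha", 9606)
  cand <- retrieve_candidates(worked_index, q)
  expect_true(nrow(cand) >= 10)
  exact <- cand$norm == "il 1 alpha" |
    vapply(strsplit(cand$norm, " "), function(t)
      length(t) == 3 && genenorm:::match_count(t, q$alts) == 3, logical(1))
  expect_true(all(cand$score[exact] == 1))
  expect_true(all(cand$score[!exact] < 1))
  expect_true(all(diff(cand$score) <= 0))
  expect_equal(nrow(retrieve_candidates(worked_index, q, cap = 1L)), 1L)
  expect_equal(retrieve_candidates(worked_index, q, cap = 1L)$score, 1)
  none <- retrieve_candidates(worked_index, compile_query("IL-1 alpha", 10090))
  expect_equal(nrow(none), 0L)
})

test_that("the anchored regex filter removes partial matches", {
  cand <- load_candidates(
    system.file("extdata", "il1a_candidates.tsv", package = "genenorm"))
  kept <- regex_filter(cand, compile_query("IL-1 alpha", 9606))
  expect_setequal(unique(kept$name),
                  c("IL1A", "IL1ALPHA", "IL-1A", "IL-1 alpha", "IL1-ALPHA"))
  expect_false(any(c("IL1", "IL-1", "IL-1R-alpha", "ILIA") %in% kept$name))
  # self-match is always retained
  self <- data.frame(taxid = 1L, geneid = 5L, name = "IL-1 alpha",
                     column = "Symbol", score = 1)
  expect_equal(nrow(regex_filter(self, compile_query("IL-1 alpha", 1))), 1L)
  expect_equal(nrow(regex_filter(cand[0, ], compile_query("x", 1))), 0L)
})

test_that("resolution assigns unique GeneIDs, else trusts authority columns", {
  cand <- load_candidates(
    system.file("extdata", "il1a_candidates.tsv", package = "genenorm"))
  kept <- regex_filter(cand, compile_query("IL-1 alpha", 9606))
  expect_equal(resolve_candidates(kept), 3552L)
  two <- data.frame(taxid = 9606L, geneid = c(10L, 20L), name = c("A1", "A-1"),
                    column = c("Synonyms", "Symbol"), score = 1)
  expect_equal(resolve_candidates(two), 20L)
  noauth <- two; noauth$column <- "Synonyms"
  expect_true(is.na(resolve_candidates(noauth)))
  expect_true(is.na(resolve_candidates(kept[0, ])))
})

test_that("overlap groups emit the longest resolved variant's GeneID", {
  g <- data.frame(text = c("IL-1 alpha", "IL-1"), start = c(0L, 0L),
                  end = c(10L, 4L), score = c(0.8, 0.9),
                  geneid = c(3552L, 3553L), stringsAsFactors = FALSE)
  pick <- disambiguate_overlapping(g)
  expect_equal(pick$geneid, 3552L)
  expect_equal(pick$score, 0.8)
  single <- g[1, ]
  expect_equal(disambiguate_overlapping(single)$geneid, 3552L)
  # equal lengths: higher confidence wins
  eq <- data.frame(text = c("ABC1", "ABD1"), start = c(0L, 2L), end = c(4L, 6L),
                   score = c(0.4, 0.7), geneid = c(1L, 2L))
  expect_equal(disambiguate_overlapping(eq)$geneid, 2L)
  none <- g; none$geneid <- NA_integer_
  expect_null(disambiguate_overlapping(none))
})

test_that("retrieval + filter equals a brute-force normalized scan", {
  recs <- gn_fix$index$records
  set.seed(13)
  sub <- build_gene_index(recs[sample(nrow(recs), min(200, nrow(recs))),
                               c("taxid", "geneid", "name", "column")])
  queries <- unique(data.frame(text = sub$records$name,
                               taxid = sub$records$taxid))
  queries <- queries[sample(nrow(queries), 40), ]
  for (i in seq_len(nrow(queries))) {
    q <- compile_query(queries$text[i], queries$taxid[i])
    got <- regex_filter(retrieve_candidates(sub, q, cap = 500L), q)
    want <- sub$records[sub$records$taxid == q$taxid &
                          grepl(q$pattern, sub$records$norm, perl = TRUE), ]
    expect_setequal(paste(got$geneid, got$name, got$column),
                    paste(want$geneid, want$name, want$column))
    # exact-name guarantee: the query text itself is in the index
    expect_gt(nrow(got), 0)
    # TaxID safety
    expect_true(all(got$taxid == q$taxid))
  }
})
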