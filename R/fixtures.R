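# Synthetic training/testing fixtures: tagged corpora with
# curator-acceptable alternative spans, gene_info-layout gene dictionaries
# and species dictionaries, plus the printed worked-example candidate list.
# Everything is a pure function of the spec (seeded); no downloads.

FIXTURE_TAXA <- data.frame(
  taxid = c(9606L, 10090L, 10116L, 4932L, 7227L),
  name = c("human", "mouse", "rat", "yeast", "Drosophila"),
  latin = c("Homo sapiens", "Mus musculus", "Rattus norvegicus",
            "Saccharomyces cerevisiae", "Drosophila melanogaster"),
  prefix = c("h", "m", "r", "y", "d"),
  stringsAsFactors = FALSE)

GENE_WORD_BANK <- c(
  "activator", "antigen", "binding", "carrier", "channel", "dehydrogenase",
  "element", "enzyme", "factor", "growth", "homolog", "inhibitor", "kinase",
  "ligase", "membrane", "nuclear", "oxidase", "phosphatase", "receptor",
  "subunit", "synthase", "transporter", "uptake", "zinc")

DECOY_ABBREVS <- data.frame(
  long = c("magnetic resonance imaging", "polymerase chain reaction",
           "central nervous system", "analysis of variance",
           "body mass index"),
  short = c("MRI", "PCR", "CNS", "ANOVA", "BMI"),
  stringsAsFactors = FALSE)

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  expr
}

#' Specification of a synthetic corpus
#'
#' The generator's dials: corpus size, gene-name grammar size, rates of
#' species mentions, abbreviation definitions, cross-species name
#' ambiguity, curator-acceptable alternatives, and the seed. Generation is
#' a pure function of this spec.
#'
#' @param n_sentences Total sentences across articles (default 200).
#' @param n_genes Lexicon size (default 30).
#' @param sentences_per_article Sentences per article (default 10).
#' @param species_rate Probability a gene sentence names its species
#'   (default 0.5).
#' @param abbrev_rate Probability a distractor sentence plants a non-gene
#'   abbreviation definition (default 0.3).
#' @param ambiguity_rate Probability a gene name also exists for a second
#'   taxon under a different GeneID (default 0.1).
#' @param acceptable_rate Probability a multi-word gold mention gets a
#'   curator-acceptable shorter alternative span (default 0.6).
#' @param distractor_rate Probability a sentence carries no gene (default
#'   0.25).
#' @param prefix_rate Probability a mention uses the single-letter species
#'   prefix form, e.g. `hKR4` (default 0.08).
#' @param negatives_per_positive Negative:positive candidate-span ratio in
#'   the generated scorer training material (default 3).
#' @param seed RNG seed (default 1).
#' @return List of class `gn_corpus_spec`.
#' @export
corpus_spec <- function(n_sentences = 200L, n_genes = 30L,
                        sentences_per_article = 10L, species_rate = 0.5,
                        abbrev_rate = 0.3, ambiguity_rate = 0.1,
                        acceptable_rate = 0.6, distractor_rate = 0.25,
                        prefix_rate = 0.08, negatives_per_positive = 3L,
                        seed = 1L) {
  structure(as.list(environment()), class = "gn_corpus_spec")
}

#' Generate the synthetic gene lexicon of a spec
#'
#' Each gene has an acronym-style multi-word full name (bank words whose
#' initials spell the symbol), a numbered symbol, hyphenated and
#' Greek-suffixed synonym forms; a configurable fraction of names is shared
#' with a second taxon under a different GeneID (cross-species ambiguity),
#' and sibling genes differing only in a trailing Greek token are planted
#' (the boundary-sensitivity hard case).
#'
#' @param spec A `gn_corpus_spec`.
#' @return data.frame: `geneid`, `taxid`, `symbol`, `full_name`, `greek`,
#'   `synonyms` (pipe-joined).
#' @export
make_gene_lexicon <- function(spec) {
  with_seed(spec$seed, {
    rows <- list()
    next_id <- 1001L
    greeks <- c("alpha", "beta", "gamma", "delta")
    for (g in seq_len(spec$n_genes)) {
      nw <- sample(2:3, 1)
      words <- sample(GENE_WORD_BANK, nw)
      num <- sample(1:9, 1)
      sym <- paste0(paste(toupper(substr(words, 1, 1)), collapse = ""), num)
      full <- paste(c(words, num), collapse = " ")
      greek <- if (stats::runif(1) < 0.35) sample(greeks, 1) else NA_character_
      hyph <- sub("([0-9])", "-\\1", sym)
      syns <- c(hyph, toupper(gsub(" ", "", full)))
      if (!is.na(greek)) {
        sym_g <- paste(sym, greek)
        syns <- c(syns, sym_g, paste0(sym, "-", greek),
                  paste(hyph, substr(greek, 1, 1)))
        full <- paste(full, greek)
      }
      taxid <- sample(FIXTURE_TAXA$taxid, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        geneid = next_id, taxid = taxid, symbol = sym, full_name = full,
        greek = greek, synonyms = paste(unique(syns), collapse = "|"),
        stringsAsFactors = FALSE)
      next_id <- next_id + 1L
      if (stats::runif(1) < spec$ambiguity_rate) {
        other <- sample(setdiff(FIXTURE_TAXA$taxid, taxid), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          geneid = next_id, taxid = other, symbol = sym, full_name = full,
          greek = greek, synonyms = paste(unique(syns), collapse = "|"),
          stringsAsFactors = FALSE)
        next_id <- next_id + 1L
      }
    }
    lex <- do.call(rbind, rows)
    # drop accidental symbol collisions between unrelated genes
    lex[!duplicated(paste(lex$symbol, lex$taxid)), , drop = FALSE]
  })
}

mention_forms <- function(lexrow) {
  forms <- c(lexrow$symbol, strsplit(lexrow$synonyms, "|", fixed = TRUE)[[1]],
             lexrow$full_name)
  unique(forms)
}

#' Generate a tagged synthetic corpus
#'
#' Articles of template sentences with planted gene mentions (gold IBO2
#' labels), curator-acceptable alternative spans, species mentions,
#' single-letter species-prefix forms, abbreviation definitions (gene and
#' decoy), distractor sentences, and candidate variant spans with synthetic
#' frequencies at the configured negative:positive ratio. Deterministic
#' given the spec.
#'
#' @param spec A `gn_corpus_spec`.
#' @return List of class `gn_corpus`: `spec`, `lexicon`, `articles` (each
#'   with `article_id`, `focus_taxid`, `sentences`). Every sentence has
#'   `text`, `tokens`, `labels`, `gold` (spans + `geneid`), `acceptable`,
#'   `candidates`.
#' @export
make_tagged_corpus <- function(spec) {
  lex <- make_gene_lexicon(spec)
  with_seed(spec$seed + 7L, {
    n_art <- max(1L, ceiling(spec$n_sentences / spec$sentences_per_article))
    articles <- vector("list", n_art)
    total <- 0L
    for (ai in seq_len(n_art)) {
      focus <- sample(FIXTURE_TAXA$taxid, 1)
      tax <- FIXTURE_TAXA[FIXTURE_TAXA$taxid == focus, ]
      pool <- lex[lex$taxid == focus, , drop = FALSE]
      if (!nrow(pool)) pool <- lex
      n_sent <- min(spec$sentences_per_article, spec$n_sentences - total)
      if (n_sent <= 0L) { articles <- articles[seq_len(ai - 1L)]; break }
      sentences <- vector("list", n_sent)
      # make the focus species the article majority for Rule 3
      minority <- FIXTURE_TAXA[FIXTURE_TAXA$taxid != focus, ]
      for (qi in seq_len(n_sent)) {
        sentences[[qi]] <- make_sentence(spec, pool, tax, minority, qi)
      }
      total <- total + n_sent
      articles[[ai]] <- list(article_id = sprintf("A%04d", ai),
                             focus_taxid = focus, sentences = sentences)
    }
    structure(list(spec = spec, lexicon = lex, articles = articles),
              class = "gn_corpus")
  })
}

# build one sentence from pieces, tracking offsets exactly
make_sentence <- function(spec, pool, tax, minority, qi) {
  buf <- ""; gold <- list(); species_here <- FALSE
  add <- function(piece) { buf <<- paste0(buf, piece); invisible(NULL) }
  add_mention <- function(lexrow, form) {
    st <- nchar(buf)
    add(form)
    gold[[length(gold) + 1L]] <<- data.frame(
      start = st, end = nchar(buf), text = form, geneid = lexrow$geneid,
      stringsAsFactors = FALSE)
  }
  if (stats::runif(1) < spec$distractor_rate) {
    if (stats::runif(1) < spec$abbrev_rate) {
      d <- DECOY_ABBREVS[sample(nrow(DECOY_ABBREVS), 1), ]
      add(sample(c("Patients underwent ", "Samples were analyzed by ",
                   "Results were assessed with "), 1))
      add(paste0(d$long, " (", d$short, ")"))
      add(sample(c(" at baseline.", " in all groups.", " before treatment."), 1))
    } else {
      add(sample(c("The samples were incubated overnight at room temperature.",
                   "Statistical significance was assessed for all groups.",
                   "Cells were washed twice and collected by centrifugation.",
                   "The cultures were maintained under standard conditions."), 1))
    }
  } else {
    g <- pool[sample(nrow(pool), 1), ]
    forms <- mention_forms(g)
    form <- sample(forms, 1)
    use_prefix <- stats::runif(1) < spec$prefix_rate
    if (use_prefix) form <- paste0(tax$prefix, g$symbol)
    template <- sample(1:5, 1)
    species_name <- if (stats::runif(1) < 0.85) tax$name else tax$latin
    has_species <- stats::runif(1) < spec$species_rate && !use_prefix
    if (template == 1L) {
      add("The "); add_mention(g, form); add(" gene is expressed")
      if (has_species) { add(paste0(" in ", species_name, " cells")); species_here <- TRUE }
      add(".")
    } else if (template == 2L) {
      add("Expression of "); add_mention(g, form); add(" was measured")
      if (has_species) { add(paste0(" in ", species_name, " tissue")); species_here <- TRUE }
      add(".")
    } else if (template == 3L) {
      if (has_species) { add(paste0("In ", species_name, ", ")); species_here <- TRUE }
      add("the "); add_mention(g, form); add(" protein regulates cell growth.")
    } else if (template == 4L) {
      add("We cloned "); add_mention(g, form)
      if (has_species) { add(paste0(" from ", species_name)); species_here <- TRUE }
      add(" and sequenced the product.")
    } else {
      # abbreviation-style definition: full name (symbol)
      add("Levels of "); add_mention(g, g$full_name)
      add(paste0(" (", g$symbol, ")"))
      add(" were elevated")
      if (has_species) { add(paste0(" in ", species_name, " samples")); species_here <- TRUE }
      add(".")
    }
    if (!species_here && stats::runif(1) < 0.1) {
      add(paste0(" Controls used ", minority$name[sample(nrow(minority), 1)],
                 " extracts."))
    }
  }
  finalize_sentence(spec, buf, gold)
}

finalize_sentence <- function(spec, text, gold) {
  tokens <- tokenize_fine(text)
  gold_df <- if (length(gold)) do.call(rbind, gold) else
    data.frame(start = integer(), end = integer(), text = character(),
               geneid = integer(), stringsAsFactors = FALSE)
  labels <- rep("O", nrow(tokens))
  for (i in seq_len(nrow(gold_df))) {
    inside <- which(tokens$start >= gold_df$start[i] & tokens$end <= gold_df$end[i])
    if (length(inside)) {
      labels[inside[1]] <- "B"
      if (length(inside) > 1L) labels[inside[-1]] <- "I"
    }
  }
  acceptable <- data.frame(start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gold_df))) {
    m <- gold_df[i, ]
    if (grepl(" ", m$text) && stats::runif(1) < spec$acceptable_rate) {
      drop_to <- m$start + regexpr(" ", m$text, fixed = TRUE)
      acceptable <- rbind(acceptable, data.frame(start = drop_to, end = m$end))
    }
  }
  candidates <- make_candidate_spans(spec, text, tokens, gold_df, acceptable)
  list(text = text, tokens = tokens, labels = labels, gold = gold_df,
       acceptable = acceptable, candidates = candidates)
}

# candidate variant spans mimicking soft-tagger output: gold + acceptable
# spans (positives, high synthetic frequency) and boundary perturbations /
# random word spans (negatives, low frequency)
make_candidate_spans <- function(spec, text, tokens, gold_df, acceptable) {
  out <- list()
  push <- function(start, end, freq) {
    if (end <= start) return(invisible(NULL))
    out[[length(out) + 1L]] <<- data.frame(
      text = substring(text, start + 1L, end), start = start, end = end,
      frequency = freq, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  pos <- unique(rbind(gold_df[, c("start", "end")], acceptable))
  for (i in seq_len(nrow(pos))) {
    push(pos$start[i], pos$end[i], stats::rbeta(1, 6, 2))
  }
  n_neg <- nrow(pos) * spec$negatives_per_positive
  nt <- nrow(tokens)
  tries <- 0L; made <- 0L
  while (made < n_neg && tries < 50L * n_neg && nt > 0L) {
    tries <- tries + 1L
    if (nrow(gold_df) && stats::runif(1) < 0.5) {
      # boundary perturbation of a gold span
      m <- gold_df[sample(nrow(gold_df), 1), ]
      left <- which(tokens$end <= m$start)
      right <- which(tokens$start >= m$end)
      st <- m$start; en <- m$end
      if (length(left) && stats::runif(1) < 0.5) st <- tokens$start[utils::tail(left, 1)]
      else if (length(right)) en <- tokens$end[right[1]]
      key_ok <- !any(pos$start == st & pos$end == en)
      if (key_ok) { push(st, en, stats::rbeta(1, 2, 6)); made <- made + 1L }
    } else {
      i <- sample(nt, 1); j <- min(nt, i + sample(0:2, 1))
      st <- tokens$start[i]; en <- tokens$end[j]
      if (!any(pos$start == st & pos$end == en)) {
        push(st, en, stats::rbeta(1, 2, 6)); made <- made + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, out))
  rownames(df) <- NULL
  df
}

#' @export
print.gn_corpus <- function(x, ...) {
  ns <- sum(vapply(x$articles, function(a) length(a$sentences), integer(1)))
  cat("<gn_corpus> ", length(x$articles), " article(s), ", ns,
      " sentence(s), ", nrow(x$lexicon), " lexicon gene(s)\n", sep = "")
  invisible(x)
}

#' Flatten a corpus to CRF training sentences
#'
#' @param corpus A `gn_corpus`.
#' @return List of `list(tokens=, labels=)`, CoNLL-style units.
#' @export
corpus_conll <- function(corpus) {
  out <- list()
  for (a in corpus$articles) for (s in a$sentences) {
    out[[length(out) + 1L]] <- list(tokens = s$tokens$surface, labels = s$labels)
  }
  out
}

#' Gold answer key of a corpus
#'
#' @param corpus A `gn_corpus`.
#' @return data.frame: `article_id`, `gene_id` (unique pairs).
#' @export
corpus_gold_key <- function(corpus) {
  rows <- list()
  for (a in corpus$articles) for (s in a$sentences) {
    if (nrow(s$gold)) {
      rows[[length(rows) + 1L]] <- data.frame(
        article_id = a$article_id, gene_id = s$gold$geneid,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(article_id = character(), gene_id = integer()))
  }
  unique(do.call(rbind, rows))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a corpus as PMC-style XML article files
#'
#' One minimal JATS-like file per article: an untyped body `sec` holding
#' the content sentences as `p` elements, plus a `sec-type="methods"`
#' section of boilerplate that section filtering must drop.
#'
#' @param corpus A `gn_corpus`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_corpus_xml <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (a in corpus$articles) {
    ps <- vapply(a$sentences, function(s)
      paste0("      <p>", xml_escape(s$text), "</p>"), "")
    xml <- c("<article>",
             "  <front><article-meta>",
             paste0("    <article-id>", a$article_id, "</article-id>"),
             "  </article-meta></front>",
             "  <body>",
             "    <sec>", ps, "    </sec>",
             "    <sec sec-type=\"methods\">",
             "      <p>Standard protocols were followed as described previously.</p>",
             "    </sec>",
             "  </body>",
             "</article>")
    p <- file.path(dir, paste0(a$article_id, ".xml"))
    writeLines(xml, p, useBytes = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

worked_example_gene_info_rows <- function(corrected = FALSE) {
  syn1 <- if (corrected) "IL1A|IL1ALPHA|IL-1A|IL1-ALPHA|IL1"
  else "ILIA|IL1ALPHA|IL-1A|IL1-ALPHA|IL1"
  rows <- list(
    c("9606", "3552", "IL1A", "-", syn1, "-", "-", "-", "-", "-",
      "IL1A", "-", "O", "IL-1 alpha", "-"),
    c("9606", "3553", "IL1B", "-", "IL1|IL-1", "-", "-", "-", "-", "-",
      "-", "-", "-", "-", "-"),
    c("9606", "3554", "IL1R1", "-", "IL-1R-alpha", "-", "-", "-", "-", "-",
      "-", "-", "-", "-", "-"),
    c("9606", "26525", "IL36RN", "-", "-", "-", "-", "-", "-", "-",
      "-", "-", "-", "IL1F5 (Canonical product IL-1F5a)", "-"),
    c("9606", "27177", "IL36B", "-", "-", "-", "-", "-", "-", "-",
      "-", "-", "-", "IL1F8 (Canonical product IL-1F8a)", "-"),
    c("9606", "84639", "IL1F10", "-", "-", "-", "-", "-", "-", "-",
      "-", "-", "-", "IL-1F10 (canonical form IL-1F10a)", "-"))
  vapply(rows, paste, "", collapse = "\t")
}

#' Write a gene_info-layout dictionary for a spec's lexicon
#'
#' Each lexicon gene contributes a Symbol, pipe-joined Synonyms, a
#' description and a Full name from nomenclature authority. The printed
#' worked-example records (interleukin 1 alpha and its retrieval
#' neighbours) are appended unless disabled, with the `ILIA` synonym as
#' printed or corrected to `IL1A`.
#'
#' @param spec A `gn_corpus_spec` (its lexicon is regenerated
#'   deterministically).
#' @param path Output TSV path.
#' @param include_worked_example Append the worked-example rows (default
#'   TRUE).
#' @param corrected Use the corrected `IL1A` spelling (default FALSE).
#' @return `path`, invisibly.
#' @export
make_gene_dict <- function(spec, path, include_worked_example = TRUE,
                           corrected = FALSE) {
  lex <- make_gene_lexicon(spec)
  lines <- c(paste0("#tax_id\tGeneID\t", paste(GENE_INFO_COLS[-(1:2)], collapse = "\t")))
  for (i in seq_len(nrow(lex))) {
    g <- lex[i, ]
    f <- rep("-", 15L)
    f[1] <- g$taxid; f[2] <- g$geneid; f[3] <- g$symbol
    f[5] <- g$synonyms
    f[9] <- paste(g$full_name, "precursor")
    f[11] <- g$symbol
    f[12] <- g$full_name
    lines <- c(lines, paste(f, collapse = "\t"))
  }
  if (include_worked_example) {
    lines <- c(lines, worked_example_gene_info_rows(corrected))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a species dictionary covering a spec's lexicon
#'
#' Common and Latin names for every taxon used by the gene dictionary plus
#' the five prefix species; errors if the lexicon uses a taxon the
#' dictionary would not cover.
#'
#' @param spec A `gn_corpus_spec`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
make_species_dict <- function(spec, path) {
  lex <- make_gene_lexicon(spec)
  missing <- setdiff(unique(lex$taxid), FIXTURE_TAXA$taxid)
  if (length(missing)) {
    stop("lexicon taxa not covered by the species dictionary: ",
         paste(missing, collapse = ", "))
  }
  lines <- c("# species name\ttaxid",
             paste(FIXTURE_TAXA$name, FIXTURE_TAXA$taxid, sep = "\t"),
             paste(FIXTURE_TAXA$latin, FIXTURE_TAXA$taxid, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a self-contained fixture directory
#'
#' Articles as XML, gene and species dictionaries, and the gold answer key
#' — a pipeline run over the directory needs no other file.
#'
#' @param spec A `gn_corpus_spec`.
#' @param dir Target directory.
#' @return `list(dir=, articles=, gene_dict=, species_dict=, gold=)`.
#' @export
make_fixture_set <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- make_tagged_corpus(spec)
  arts <- write_corpus_xml(corpus, file.path(dir, "articles"))
  gd <- file.path(dir, "gene_info.tsv")
  sd <- file.path(dir, "species.tsv")
  make_gene_dict(spec, gd)
  make_species_dict(spec, sd)
  gold <- corpus_gold_key(corpus)
  gp <- file.path(dir, "gold.tsv")
  utils::write.table(gold, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(dir = dir, articles = arts, gene_dict = gd, species_dict = sd,
       gold = gp)
}
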