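# Gene-name dictionary: rule-based name normalization, interchange classes
# (Arabic/Roman numerals, Greek words/Latin initials), token-overlap
# retrieval with a candidate cap, anchored regex post-filtering, and the
# resolving heuristics that pick a GeneID.

GREEK_WORDS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
                 "theta", "iota", "kappa", "lambda", "mu", "nu", "xi",
                 "omicron", "pi", "rho", "sigma", "tau", "upsilon", "phi",
                 "chi", "psi", "omega")

AUTHORITY_COLUMNS <- c("Symbol", "AuthorizedSymbol",
                       "Symbol from nomenclature authority",
                       "Full name from nomenclature authority")

#' Normalize a gene name for indexing and search
#'
#' Applies, in order: (1) split an uppercase run (>= 2) from a following
#' lowercase run (>= 2), (2) the converse split, (3) replace every
#' character that is not a word character — '.' excepted — with a space,
#' (4) space-delimit runs of digits and dots, (5) collapse whitespace; then
#' lowercase. Idempotent. `"IL1-ALPHA"` becomes `"il 1 alpha"`.
#'
#' @param name Non-empty character vector of names.
#' @return Character vector of normalized (space-joined token) names.
#' @export
normalize_name <- function(name) {
  x <- gsub("([A-Z]{2,})([a-z]{2,})", "\\1 \\2", name)
  x <- gsub("([a-z]{2,})([A-Z]{2,})", "\\1 \\2", x)
  x <- gsub("[^\\w.]", " ", x, perl = TRUE)
  x <- gsub("([0-9.]+)", " \\1 ", x)
  x <- gsub("\\s+", " ", x)
  tolower(trimws(x))
}

roman_of <- function(tok) {
  n <- suppressWarnings(as.integer(tok))
  if (is.na(n) || n < 1L || n > 3999L) return(NA_character_)
  tolower(as.character(utils::as.roman(n)))
}

arabic_of <- function(tok) {
  if (!grepl("^[ivxlcdm]+$", tok)) return(NA_character_)
  n <- suppressWarnings(as.integer(utils::as.roman(toupper(tok))))
  if (is.na(n)) return(NA_character_)
  as.character(n)
}

# alternation set for one normalized token: the token itself plus its
# interchange-class partners
token_alternatives <- function(tok) {
  alts <- tok
  if (grepl("^[0-9]+$", tok)) {
    r <- roman_of(tok)
    if (!is.na(r)) alts <- c(alts, r)
  } else if (tok %in% GREEK_WORDS) {
    alts <- c(alts, substr(tok, 1, 1))
  } else if (nchar(tok) == 1L && grepl("[a-z]", tok)) {
    alts <- c(alts, GREEK_WORDS[startsWith(GREEK_WORDS, tok)])
    a <- arabic_of(tok)
    if (!is.na(a)) alts <- c(alts, a)
  } else {
    a <- arabic_of(tok)
    if (!is.na(a)) alts <- c(alts, a)
  }
  unique(alts)
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Compile a retrieval query from a variant and its TaxID
#'
#' The variant text is normalized with [normalize_name()]; each token
#' carries an alternation set: Arabic numerals interchange with Roman
#' numerals (`53` ~ `liii`), Greek-letter words with their Latin initials
#' (`alpha` ~ `a`) and vice versa. Matching is case-insensitive. The TaxID
#' is attached as a mandatory filter.
#'
#' @param variant_text Non-empty variant string, e.g. `"IL-1 alpha"`.
#' @param taxid Designated taxonomy id.
#' @return Object of class `gn_query`: `tokens`, `alts` (list of character
#'   vectors), `taxid`, `pattern` (anchored whole-name regex).
#' @export
compile_query <- function(variant_text, taxid) {
  stopifnot(nzchar(variant_text))
  norm <- normalize_name(variant_text)
  tokens <- strsplit(norm, " ", fixed = TRUE)[[1]]
  if (!length(tokens)) stop("variant text normalizes to nothing: ", variant_text)
  alts <- lapply(tokens, token_alternatives)
  tok_res <- vapply(alts, function(a)
    paste0("(?:", paste(regex_escape(a), collapse = "|"), ")"), "")
  pattern <- paste0("^(?i)", paste(tok_res, collapse = " "), "$")
  structure(list(tokens = tokens, alts = alts, taxid = as.integer(taxid),
                 pattern = pattern),
            class = "gn_query")
}

#' @export
print.gn_query <- function(x, ...) {
  cat("<gn_query> TaxID:", x$taxid, " ",
      paste(vapply(x$alts, function(a)
        if (length(a) > 1) paste0("{", paste(a, collapse = "|"), "}") else a, ""),
        collapse = " "), "\n", sep = "")
  invisible(x)
}

## ---- gene_info loading ----------------------------------------------------

GENE_INFO_COLS <- c("tax_id", "GeneID", "Symbol", "LocusTag", "Synonyms",
                    "dbXrefs", "chromosome", "map_location", "description",
                    "type_of_gene", "Symbol_from_nomenclature_authority",
                    "Full_name_from_nomenclature_authority",
                    "Nomenclature_status", "Other_designations",
                    "Modification_date")

#' Load gene records from a gene_info-layout table
#'
#' One record per (row, name column, pipe-separated name) from the columns
#' Symbol, Synonyms, dbXrefs, description, Symbol from nomenclature
#' authority, Full name from nomenclature authority and Other designations.
#' `-` marks a missing field; dbXrefs entries are stripped of their
#' `SOURCE:` prefix. Accepts a plain or gzip-compressed TSV with or without
#' the leading `#` header line.
#'
#' @param path gene_info-layout TSV (possibly `.gz`).
#' @return data.frame of gene records: `taxid`, `geneid`, `name`, `column`.
#' @export
load_gene_info <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  lines <- readLines(con, encoding = "UTF-8")
  close(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "#")) lines <- lines[-1]
  recs <- list()
  src <- list(Symbol = 3L, Synonyms = 5L, dbXrefs = 6L, description = 9L,
              `Symbol from nomenclature authority` = 11L,
              `Full name from nomenclature authority` = 12L,
              OtherDesignations = 14L)
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 14L) {
      stop("malformed gene_info line ", ln, ": expected >= 14 columns, got ",
           length(f))
    }
    taxid <- as.integer(f[1]); geneid <- as.integer(f[2])
    for (cn in names(src)) {
      val <- f[src[[cn]]]
      if (is.na(val) || val == "-" || !nzchar(val)) next
      names_here <- strsplit(val, "|", fixed = TRUE)[[1]]
      if (cn == "dbXrefs") names_here <- sub("^[^:]+:", "", names_here)
      names_here <- names_here[nzchar(names_here)]
      for (nm in names_here) {
        recs[[length(recs) + 1L]] <- list(taxid = taxid, geneid = geneid,
                                          name = nm, column = cn)
      }
    }
  }
  df <- data.frame(
    taxid = vapply(recs, `[[`, 0L, "taxid"),
    geneid = vapply(recs, `[[`, 0L, "geneid"),
    name = vapply(recs, `[[`, "", "name"),
    column = vapply(recs, `[[`, "", "column"),
    stringsAsFactors = FALSE)
  unique(df)
}

#' Load a candidate table (TaxID, GeneID, Name, ColumnHeader[, Score])
#'
#' Reads retrieval-phase candidate lists in the dump layout: tab-separated
#' with a header line.
#'
#' @param path TSV path.
#' @return Candidate data.frame: `taxid`, `geneid`, `name`, `column`,
#'   `score`.
#' @export
load_candidates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  out <- data.frame(taxid = as.integer(sub("^TaxID:", "", df$taxid)),
                    geneid = as.integer(sub("^GeneID:", "", df$geneid)),
                    name = df$name,
                    column = df[["column header"]] %||% df$column,
                    stringsAsFactors = FALSE)
  out$score <- if ("score" %in% names(df)) as.numeric(df$score) else NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a searchable gene-name index
#'
#' Precomputes each record's normalized name and token list. Retrieval
#' scores are Dice token-overlap coefficients under the interchange
#' classes, so a record whose normalized name token-equals the query scores
#' exactly 1 (the maximum); ranking below that is heuristic — the anchored
#' regex filter, not the ranking, determines correctness.
#'
#' @param records Gene record data.frame from [load_gene_info()].
#' @return Object of class `gn_gene_index`.
#' @export
build_gene_index <- function(records) {
  stopifnot(all(c("taxid", "geneid", "name", "column") %in% names(records)))
  records$norm <- normalize_name(records$name)
  records <- records[nzchar(records$norm), , drop = FALSE]
  records$tokens <- strsplit(records$norm, " ", fixed = TRUE)
  rownames(records) <- NULL
  structure(list(records = records), class = "gn_gene_index")
}

#' @export
print.gn_gene_index <- function(x, ...) {
  cat("<gn_gene_index> ", nrow(x$records), " name records, ",
      length(unique(x$records$geneid)), " genes, ",
      length(unique(x$records$taxid)), " taxa\n", sep = "")
  invisible(x)
}

# greedy multiset match count between record tokens and query alternation
# sets (tokens rarely repeat in gene names; greedy equals maximal here)
match_count <- function(rec_tokens, alts) {
  used <- rep(FALSE, length(alts))
  m <- 0L
  for (tok in rec_tokens) {
    for (j in seq_along(alts)) {
      if (!used[j] && tok %in% alts[[j]]) {
        used[j] <- TRUE; m <- m + 1L; break
      }
    }
  }
  m
}

#' Retrieve candidate gene records for a query
#'
#' Records with the query's TaxID sharing at least one token (under the
#' interchange classes) with the query, ranked by Dice token overlap
#' (descending; ties by GeneID then name) and truncated at `cap`.
#'
#' @param index A `gn_gene_index`.
#' @param query A `gn_query`.
#' @param cap Maximum number of candidates (default 50).
#' @return Candidate data.frame: `taxid`, `geneid`, `name`, `column`,
#'   `norm`, `score`.
#' @export
retrieve_candidates <- function(index, query, cap = 50L) {
  stopifnot(inherits(index, "gn_gene_index"), inherits(query, "gn_query"))
  rec <- index$records[index$records$taxid == query$taxid, , drop = FALSE]
  if (!nrow(rec)) return(empty_candidates())
  nq <- length(query$alts)
  m <- vapply(rec$tokens, match_count, 0L, alts = query$alts)
  score <- 2 * m / (lengths(rec$tokens) + nq)
  keep <- m > 0L
  rec <- rec[keep, , drop = FALSE]; score <- score[keep]
  if (!nrow(rec)) return(empty_candidates())
  o <- order(-score, rec$geneid, rec$name)
  o <- o[seq_len(min(cap, length(o)))]
  out <- rec[o, c("taxid", "geneid", "name", "column", "norm"), drop = FALSE]
  out$score <- score[o]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(taxid = integer(), geneid = integer(), name = character(),
             column = character(), norm = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Filter candidates by the query-derived whole-name regex
#'
#' A candidate survives only if its entire normalized name matches the
#' query pattern: all query tokens in order, each through its alternation
#' set, with no extra name tokens (anchored at both ends). This is what
#' removes partial matches such as `IL-1` or `IL-1R-alpha` for the query
#' `IL-1 alpha`.
#'
#' @param candidates Candidate data.frame ([retrieve_candidates()] or
#'   [load_candidates()] output).
#' @param query A `gn_query` (or a variant text string, normalized on the
#'   fly with the TaxID taken from the candidates).
#' @return The retained subset of `candidates`.
#' @export
regex_filter <- function(candidates, query) {
  if (!NROW(candidates)) return(candidates)
  if (is.character(query)) {
    query <- compile_query(query, candidates$taxid[1])
  }
  norm <- candidates$norm %||% normalize_name(candidates$name)
  keep <- grepl(query$pattern, norm, perl = TRUE)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve a filtered candidate list to a single GeneID
#'
#' A unique GeneID in the list is assigned directly. With several GeneIDs,
#' the GeneID of the best-ranked candidate sourced from an authority column
#' (Symbol, AuthorizedSymbol, Symbol/Full name from nomenclature authority)
#' is assigned; if none qualifies the list is ignored.
#'
#' @param filtered Regex-filtered candidate data.frame.
#' @return Integer GeneID, or `NA` if unresolved.
#' @export
resolve_candidates <- function(filtered) {
  if (!NROW(filtered)) return(NA_integer_)
  ids <- unique(filtered$geneid)
  if (length(ids) == 1L) return(ids)
  auth <- filtered[filtered$column %in% AUTHORITY_COLUMNS, , drop = FALSE]
  if (nrow(auth)) return(auth$geneid[1])
  NA_integer_
}

#' Pick one GeneID for a group of overlapping resolved variants
#'
#' At most one GeneID is emitted per overlap group: the GeneID of the
#' longest (by character span) resolved variant; ties prefer the higher
#' confidence score, then the leftmost. The reported score is the winning
#' variant's confidence score.
#'
#' @param group data.frame of overlapping variants with columns `text`,
#'   `start`, `end`, `score`, `geneid` (NA where unresolved).
#' @return `list(geneid=, score=, variant=)` or `NULL` if nothing resolved.
#' @export
disambiguate_overlapping <- function(group) {
  res <- group[!is.na(group$geneid), , drop = FALSE]
  if (!nrow(res)) return(NULL)
  len <- res$end - res$start
  o <- order(-len, -res$score, res$start)
  w <- res[o[1], , drop = FALSE]
  list(geneid = w$geneid, score = w$score, variant = w)
}

# connected components of the span-overlap graph; returns a component id
# per row
overlap_components <- function(spans) {
  n <- nrow(spans)
  comp <- seq_len(n)
  if (n < 2L) return(comp)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (spans_overlap(spans$start[i], spans$end[i], spans$start[j], spans$end[j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Dump a candidate list as TSV (TaxID, GeneID, Name, ColumnHeader, Score)
#'
#' @param candidates Candidate data.frame.
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  out <- data.frame(TaxID = candidates$taxid, GeneID = candidates$geneid,
                    Name = candidates$name,
                    `Column Header` = candidates$column,
                    Score = candidates$score, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
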