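# Species designation: dictionary lookup of species names plus three
# precedence rules assigning a taxonomy identifier (TaxID) to each variant.

DEFAULT_PREFIX_MAP <- c(h = 9606L, y = 4932L, m = 10090L, r = 10116L, d = 7227L)

#' Load a species-name dictionary
#'
#' Two-column tab-separated file: species name, TaxID. `#` starts a comment
#' line. Duplicate names keep the first occurrence (with a warning).
#'
#' @param path TSV file path.
#' @param prefix_map Named integer vector mapping single-letter gene-symbol
#'   prefixes to TaxIDs; default `{h, y, m, r, d}` = human, yeast, mouse,
#'   rat, fruit fly.
#' @return Object of class `gn_species_dict`.
#' @export
load_species_dict <- function(path, prefix_map = DEFAULT_PREFIX_MAP) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty species dictionary: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed species dictionary line ", bad[1])
  df <- data.frame(name = vapply(parts, `[[`, "", 1),
                   taxid = as.integer(vapply(parts, `[[`, "", 2)),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df$name)
  if (any(dup)) {
    warning("duplicate species name(s) ignored: ",
            paste(unique(df$name[dup]), collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  structure(list(names = df, prefix_map = prefix_map),
            class = "gn_species_dict")
}

species_dict_from_df <- function(df, prefix_map = DEFAULT_PREFIX_MAP) {
  structure(list(names = df, prefix_map = prefix_map),
            class = "gn_species_dict")
}

#' @export
print.gn_species_dict <- function(x, ...) {
  cat("<gn_species_dict> ", nrow(x$names), " names, ",
      length(unique(x$names$taxid)), " taxa\n", sep = "")
  invisible(x)
}

# boundary-checked fixed-string occurrences of one name within text;
# case-insensitive for long or multi-word names, case-sensitive for short
# (<= 4 character) abbreviations
find_name_occurrences <- function(text, name) {
  ci <- nchar(name) > 4L || grepl(" ", name, fixed = TRUE)
  hay <- if (ci) tolower(text) else text
  ndl <- if (ci) tolower(name) else name
  m <- gregexpr(ndl, hay, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  starts <- as.integer(m)
  keep <- vapply(starts, function(p) {
    pre <- if (p > 1L) substr(text, p - 1L, p - 1L) else ""
    post <- substr(text, p + nchar(name), p + nchar(name))
    !grepl("[A-Za-z0-9]", pre) && !grepl("[A-Za-z0-9]", post)
  }, logical(1))
  starts[keep] - 1L  # 0-based
}

#' Find species mentions in a document
#'
#' Longest-match dictionary scan over every sentence: names are matched in
#' decreasing length order and shorter names cannot match inside an already
#' matched span ("Saccharomyces cerevisiae" beats "Saccharomyces").
#'
#' @param doc A `gn_document` (or a single sentence object).
#' @param dict A `gn_species_dict`.
#' @return data.frame: `sentence` (flat index), `start`, `end`, `name`,
#'   `taxid`.
#' @export
find_species_mentions <- function(doc, dict) {
  sents <- if (inherits(doc, "gn_document")) doc_sentences(doc) else list(doc)
  nms <- dict$names[order(-nchar(dict$names$name)), , drop = FALSE]
  out <- data.frame(sentence = integer(), start = integer(), end = integer(),
                    name = character(), taxid = integer(),
                    stringsAsFactors = FALSE)
  for (qi in seq_along(sents)) {
    s <- sents[[qi]]
    idx <- if (!is.null(s$index)) s$index else qi
    taken_s <- integer(0); taken_e <- integer(0)
    for (r in seq_len(nrow(nms))) {
      pos <- find_name_occurrences(s$text, nms$name[r])
      for (p in pos) {
        e <- p + nchar(nms$name[r])
        if (length(taken_s) && any(spans_overlap(taken_s, taken_e, p, e))) next
        taken_s <- c(taken_s, p); taken_e <- c(taken_e, e)
        out <- rbind(out, data.frame(sentence = idx, start = p, end = e,
                                     name = nms$name[r], taxid = nms$taxid[r],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$sentence, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# prefix rule: variant starts with a prefix letter followed by an uppercase
# letter or digit (hTAK1, yTAF)
prefix_taxid <- function(text, prefix_map) {
  first <- substr(text, 1, 1)
  if (first %in% names(prefix_map) && grepl("^[A-Z0-9]", substr(text, 2, 2))) {
    return(unname(prefix_map[[first]]))
  }
  NA_integer_
}

#' Designate a taxonomy identifier for one variant
#'
#' Rules, in precedence order:
#' * Rule 1 — a species name inside the variant, else the nearest species
#'   mention earlier in the same sentence, else a single-letter species
#'   prefix (`hTAK1` -> human).
#' * Rule 2 — the species mention nearest to the variant anywhere in the
#'   same sentence.
#' * Rule 3 — the species mentioned most often in the whole article (ties:
#'   the species appearing first), guaranteeing assignment whenever the
#'   article mentions any species.
#'
#' @param variant List/row with `text`, `start`, `end`, `sentence` (flat
#'   sentence index).
#' @param mentions Article-wide [find_species_mentions()] table.
#' @param dict A `gn_species_dict` (for the prefix map).
#' @param rules Integer subset of `c(1, 2, 3)` to apply, in that order.
#' @param default_taxid Fallback when no rule fires (default none).
#' @return `list(taxid=, rule=)`; `taxid` is `NA` (rule `NA`) if unassigned.
#' @export
designate_species <- function(variant, mentions, dict, rules = c(1L, 2L, 3L),
                              default_taxid = NULL) {
  sent <- mentions[mentions$sentence == variant$sentence, , drop = FALSE]
  if (1L %in% rules) {
    inside <- sent[sent$start >= variant$start & sent$end <= variant$end, , drop = FALSE]
    if (nrow(inside)) {
      return(list(taxid = inside$taxid[1], rule = 1L))
    }
    before <- sent[sent$end <= variant$start, , drop = FALSE]
    if (nrow(before)) {
      return(list(taxid = before$taxid[which.max(before$end)], rule = 1L))
    }
    p <- prefix_taxid(variant$text, dict$prefix_map)
    if (!is.na(p)) return(list(taxid = p, rule = 1L))
  }
  if (2L %in% rules && nrow(sent)) {
    mid <- (variant$start + variant$end) / 2
    d <- pmin(abs(sent$start - mid), abs(sent$end - mid))
    return(list(taxid = sent$taxid[which.min(d)], rule = 2L))
  }
  if (3L %in% rules && nrow(mentions)) {
    counts <- table(mentions$taxid)
    top <- as.integer(names(counts)[counts == max(counts)])
    if (length(top) > 1L) {
      firsts <- vapply(top, function(tx) {
        i <- which(mentions$taxid == tx)[1]
        mentions$sentence[i] * 1e9 + mentions$start[i]
      }, 0)
      top <- top[which.min(firsts)]
    }
    return(list(taxid = top[1], rule = 3L))
  }
  if (!is.null(default_taxid)) return(list(taxid = as.integer(default_taxid), rule = NA_integer_))
  list(taxid = NA_integer_, rule = NA_integer_)
}
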