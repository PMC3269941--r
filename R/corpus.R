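# Article model: Document -> Section -> Sentence -> Token, with 0-based
# half-open character offsets at every level.

ABBREV_STOPLIST <- c(
  "al", "e.g", "i.e", "etc", "cf", "vs", "fig", "figs", "dr", "mr", "mrs",
  "no", "st", "ca", "approx", "resp", "ref", "refs", "eq", "eqs", "sp", "spp"
)

#' Fine-grained tokenization
#'
#' Splits text into maximal runs of letters, maximal runs of digits, and
#' single other non-space characters, so that mixed tokens such as `IL2R`
#' become `IL`, `2`, `R`. Whitespace yields no token. Non-ASCII letters
#' (e.g. Greek) count as letters.
#'
#' @param text Character scalar.
#' @return A data.frame with columns `surface`, `start`, `end` (0-based,
#'   half-open offsets into `text`).
#' @export
#' @examples
#' tokenize_fine("Acetyl-CoA carboxylase")$surface
tokenize_fine <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("\\p{L}+|\\p{Nd}+|[^\\p{L}\\p{Nd}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, m, m + len - 1L),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Rule-based sentence segmentation
#'
#' Splits on `.`, `?` or `!` followed by whitespace and an uppercase letter
#' or digit, with a stop-list of common abbreviations (`et al.`, `e.g.`,
#' `Fig.`, ...) that never end a sentence.
#'
#' @param text Character scalar (one section's text).
#' @return data.frame with columns `text`, `start`, `end` (0-based half-open
#'   offsets into `text`, whitespace-trimmed).
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  m <- gregexpr("[.?!]+(?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer()
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      pos <- as.integer(m[i])  # 1-based index of the punctuation
      len <- attr(m, "match.length")[i]
      # word immediately before the punctuation
      before <- sub(".*?([[:alpha:]]+)$", "\\1", substr(text, max(1L, pos - 20L), pos - 1L))
      if (tolower(before) %in% ABBREV_STOPLIST) next
      # single capital letter + "." is usually an initial; don't split
      if (nchar(before) == 1L && before %in% LETTERS && substr(text, pos, pos) == ".") next
      breaks <- c(breaks, pos + len - 1L)  # sentence ends at end of punctuation run
    }
  }
  bounds <- c(0L, breaks, nchar(text))
  out <- empty
  for (i in seq_len(length(bounds) - 1L)) {
    s0 <- bounds[i]; s1 <- bounds[i + 1L]
    raw <- substr(text, s0 + 1L, s1)
    lead <- nchar(raw) - nchar(sub("^\\s+", "", raw))
    trail <- nchar(raw) - nchar(sub("\\s+$", "", raw))
    st <- s0 + lead; en <- s1 - trail
    if (en > st) {
      out <- rbind(out, data.frame(text = substr(text, st + 1L, en),
                                   start = st, end = en,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

new_sentence <- function(text, start, end) {
  list(text = text, start = start, end = end, tokens = tokenize_fine(text))
}

new_section <- function(sec_type, text) {
  sents <- segment_sentences(text)
  sentences <- lapply(seq_len(nrow(sents)), function(i)
    new_sentence(sents$text[i], sents$start[i], sents$end[i]))
  list(sec_type = sec_type, text = text, sentences = sentences)
}

#' Parse a PMC-style XML article or plain text into a Document
#'
#' XML input is read with [xml2::read_xml()]; all `sec` elements under the
#' article body are taken in document order (nested `sec` flattened
#' depth-first, each contributing only its direct `p` children), carrying
#' their `sec-type` attribute when present. Non-XML input falls back to a
#' single untyped section. Each section is segmented into sentences and
#' fine-tokenized.
#'
#' @param xml_text Character scalar: XML or plain text of one article.
#' @param article_id Optional id; defaults to the first `article-id` element,
#'   else `"article"`.
#' @return An object of class `gn_document`: list with `article_id` and
#'   `sections` (each with `sec_type`, `text`, `sentences`).
#' @export
parse_article <- function(xml_text, article_id = NULL) {
  stopifnot(is.character(xml_text), length(xml_text) == 1L)
  if (is.na(xml_text) || !nzchar(trimws(xml_text))) {
    stop("parse error: empty input")
  }
  looks_xml <- grepl("^\\s*<", xml_text)
  if (looks_xml) {
    doc <- tryCatch(xml2::read_xml(xml_text),
                    error = function(e) stop("XML parse error: ", conditionMessage(e),
                                             call. = FALSE))
    if (is.null(article_id)) {
      idn <- xml2::xml_find_first(doc, ".//article-id")
      article_id <- if (inherits(idn, "xml_missing")) "article" else xml2::xml_text(idn)
    }
    body <- xml2::xml_find_first(doc, ".//body")
    root <- if (inherits(body, "xml_missing")) doc else body
    secs <- xml2::xml_find_all(root, ".//sec")
    sections <- list()
    if (length(secs) == 0L) {
      txt <- squeeze_ws(xml2::xml_text(root))
      if (nzchar(txt)) sections <- list(new_section(NA_character_, txt))
    } else {
      for (sec in secs) {
        ps <- xml2::xml_find_all(sec, "./p")
        txt <- squeeze_ws(paste(vapply(ps, xml2::xml_text, ""), collapse = " "))
        if (!nzchar(txt)) next
        st <- xml2::xml_attr(sec, "sec-type")
        sections <- c(sections, list(new_section(st, txt)))
      }
    }
  } else {
    if (is.null(article_id)) article_id <- "article"
    sections <- list(new_section(NA_character_, squeeze_ws(xml_text)))
  }
  structure(list(article_id = article_id, sections = sections),
            class = "gn_document")
}

squeeze_ws <- function(x) trimws(gsub("\\s+", " ", x))

#' Keep only sections without a sec-type attribute
#'
#' Typed sections (Methods, References, Materials, ...) are excluded from
#' the normalization input; untyped body sections are retained. Idempotent.
#'
#' @param doc A `gn_document`.
#' @return A `gn_document` with the typed sections removed.
#' @export
filter_sections <- function(doc) {
  stopifnot(inherits(doc, "gn_document"))
  keep <- vapply(doc$sections, function(s) is.na(s$sec_type) || is.null(s$sec_type),
                 logical(1))
  doc$sections <- doc$sections[keep]
  doc
}

#' @export
print.gn_document <- function(x, ...) {
  nsent <- sum(vapply(x$sections, function(s) length(s$sentences), integer(1)))
  cat("<gn_document> ", x$article_id, ": ", length(x$sections), " section(s), ",
      nsent, " sentence(s)\n", sep = "")
  invisible(x)
}

# All sentences of a document as a flat list with section/sentence indices.
doc_sentences <- function(doc) {
  out <- list()
  for (si in seq_along(doc$sections)) {
    sec <- doc$sections[[si]]
    for (qi in seq_along(sec$sentences)) {
      s <- sec$sentences[[qi]]
      s$section <- si; s$index <- length(out) + 1L
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
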