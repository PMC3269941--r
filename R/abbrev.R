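# Abbreviation-definition detection and the short-form veto rule: a tagged
# short form whose long form was not tagged at the definition site is
# invalid everywhere in the article.

# Schwartz-Hearst right-to-left character alignment of a candidate short
# form into the text preceding its parenthesis. Returns the long form's
# 0-based half-open span within `before`, or NULL.
align_long_form <- function(short, before) {
  sf <- tolower(short); lf <- tolower(before)
  si <- nchar(sf); li <- nchar(lf)
  while (si >= 1L) {
    ch <- substr(sf, si, si)
    if (!grepl("[a-z0-9]", ch)) { si <- si - 1L; next }
    repeat {
      if (li < 1L) return(NULL)
      cur <- substr(lf, li, li)
      # the first short-form character must start a word of the long form
      first_ok <- !(si == 1L && li > 1L && grepl("[a-z0-9]", substr(lf, li - 1L, li - 1L)))
      if (cur == ch && first_ok) break
      li <- li - 1L
    }
    si <- si - 1L; li <- li - 1L
  }
  # extend left to the start of the word containing position li + 1
  start <- li  # 0-based candidate
  while (start > 0L && grepl("[a-z0-9]", substr(lf, start, start))) start <- start - 1L
  end <- nchar(sub("\\s+$", "", before))
  if (end <= start) return(NULL)
  c(start = start, end = end)
}

valid_short_form <- function(sf) {
  n <- nchar(sf)
  n >= 2L && n <= 10L &&
    length(strsplit(trimws(sf), "\\s+")[[1]]) <= 2L &&
    grepl("[A-Za-z]", sf) &&
    grepl("^[A-Za-z0-9]", sf)
}

#' Detect abbreviation / long-form definition pairs in an article
#'
#' Finds parenthesized short forms ("... N-acetyl-aspartate (NAA), ...")
#' and aligns their characters right-to-left into the preceding text
#' (Schwartz-Hearst heuristic): every alphanumeric character of the short
#' form must appear, in order, in the long form, and its first character
#' must begin a long-form word. One pair per distinct (short, long) per
#' article.
#'
#' @param doc A `gn_document`.
#' @return data.frame: `short`, `long`, `section`, `sentence` (flat sentence
#'   index), `short_start`, `short_end`, `long_start`, `long_end` (0-based
#'   half-open offsets in the sentence).
#' @export
detect_abbrev_pairs <- function(doc) {
  stopifnot(inherits(doc, "gn_document"))
  sents <- doc_sentences(doc)
  out <- data.frame(short = character(), long = character(),
                    section = integer(), sentence = integer(),
                    short_start = integer(), short_end = integer(),
                    long_start = integer(), long_end = integer(),
                    stringsAsFactors = FALSE)
  seen <- character(0)
  for (s in sents) {
    m <- gregexpr("\\(([^()]{1,60})\\)", s$text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (i in seq_along(m)) {
      open <- as.integer(m[i])           # 1-based "(" position
      len <- attr(m, "match.length")[i]
      sf <- substr(s$text, open + 1L, open + len - 2L)
      if (!valid_short_form(sf)) next
      before <- substr(s$text, 1L, open - 1L)
      # cap the window: at most min(|sf| + 5, |sf| * 2) words before "("
      words <- gregexpr("\\S+", before)[[1]]
      maxw <- min(nchar(sf) + 5L, nchar(sf) * 2L)
      if (words[1] != -1L && length(words) > maxw) {
        cut <- as.integer(words[length(words) - maxw + 1L]) - 1L
      } else cut <- 0L
      window <- substr(before, cut + 1L, nchar(before))
      sp <- align_long_form(sf, window)
      if (is.null(sp)) next
      long_start <- cut + sp["start"]
      long_end <- cut + sp["end"]
      lf <- substr(s$text, long_start + 1L, long_end)
      if (tolower(lf) == tolower(sf)) next
      key <- paste(sf, lf, sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      out <- rbind(out, data.frame(
        short = sf, long = lf, section = s$section, sentence = s$index,
        short_start = open, short_end = open + nchar(sf),
        long_start = as.integer(long_start), long_end = as.integer(long_end),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Invalidate short-form variants whose long form was not tagged
#'
#' For each detected pair whose definition sentence carries a tagged variant
#' equal to the short form while no tagged variant overlaps the long-form
#' occurrence, every variant in the article whose text equals the short form
#' (case-sensitive) is removed. Removal is article-scoped and exact-text;
#' the output is always a subset of the input.
#'
#' @param variants Article-wide variant data.frame with columns `text`,
#'   `start`, `end`, `sentence` (flat sentence index).
#' @param pairs Output of [detect_abbrev_pairs()].
#' @return Filtered variant data.frame.
#' @export
filter_by_abbrev <- function(variants, pairs) {
  if (!NROW(variants) || !NROW(pairs)) return(variants)
  invalid <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    in_sent <- variants$sentence == p$sentence
    short_tagged <- any(in_sent & variants$text == p$short)
    long_tagged <- any(in_sent & spans_overlap(variants$start, variants$end,
                                               p$long_start, p$long_end))
    if (short_tagged && !long_tagged) invalid <- c(invalid, p$short)
  }
  if (!length(invalid)) return(variants)
  out <- variants[!(variants$text %in% invalid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
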