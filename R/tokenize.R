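#' @include corpus.R
NULL

## punctuation peeled off token edges; '+', '-', '/' stay attached so that
## surface forms like "CD4+", "IL-2" and "TCR/CD3" remain single tokens
PEEL_CHARS <- setdiff(strsplit("!\"#$%&'()*,.:;<=>?@[]\\^_`{}|~", "")[[1]],
                      c("+", "-", "/"))

#' Deterministic rule-based word tokenizer
#'
#' Splits on whitespace, then peels leading and trailing punctuation off each
#' chunk into separate tokens, keeping internal characters and the edge
#' characters \code{+}, \code{-}, \code{/} attached (so \code{"CD4+"} and
#' \code{"IL-2"} stay intact). Character offsets are 0-based half-open into
#' the input text.
#'
#' @param text a single string.
#' @return data.frame(text, char_start, char_end).
#' @export
tokenizeText <- function(text) {
  stopifnot(length(text) == 1L)
  out_text <- character(0); out_s <- integer(0); out_e <- integer(0)
  push <- function(s, e) {
    if (e > s) {
      out_text[length(out_text) + 1L] <<- substr(text, s + 1L, e)
      out_s[length(out_s) + 1L] <<- s
      out_e[length(out_e) + 1L] <<- e
    }
  }
  if (nchar(text)) {
    chars <- strsplit(text, "")[[1]]
    ws <- grepl("[[:space:]]", chars)
    runs <- rle(ws)
    pos <- 0L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      if (!runs$values[k]) {
        s <- pos; e <- pos + len          # chunk [s, e), 0-based
        while (s < e && chars[s + 1L] %in% PEEL_CHARS) { push(s, s + 1L); s <- s + 1L }
        tail_start <- e
        while (tail_start > s && chars[tail_start] %in% PEEL_CHARS)
          tail_start <- tail_start - 1L
        push(s, tail_start)
        while (tail_start < e) { push(tail_start, tail_start + 1L); tail_start <- tail_start + 1L }
      }
      pos <- pos + len
    }
  }
  data.frame(text = out_text, char_start = out_s, char_end = out_e,
             stringsAsFactors = FALSE)
}

#' Tokenize text and align character-offset annotations to token spans
#'
#' Each character annotation (0-based half-open) maps to the minimal token
#' span covering it; boundaries falling strictly inside a token snap outward
#' to that token's boundaries and the resulting mention is flagged
#' \code{snapped}.
#'
#' @param text document text.
#' @param char_annotations data.frame(char_start, char_end, label[,
#'   confidence]); may be NULL/empty.
#' @param doc_id document identifier.
#' @param meta optional metadata list.
#' @return an \code{AnnotatedDocument}.
#' @export
tokenizeAndAlign <- function(text, char_annotations = NULL, doc_id = "doc",
                             meta = list()) {
  tokens <- tokenizeText(text)
  mn <- NULL
  if (!is.null(char_annotations) && nrow(char_annotations)) {
    ca <- char_annotations
    n <- nrow(ca)
    start <- integer(n); end <- integer(n); snapped <- logical(n)
    for (i in seq_len(n)) {
      s0 <- ca$char_start[i]; e0 <- ca$char_end[i]
      if (s0 >= e0)
        stopf("doc %s: zero-length or inverted annotation at chars [%d,%d)",
              doc_id, s0, e0)
      if (e0 > nchar(text) || s0 < 0)
        stopf("doc %s: annotation [%d,%d) beyond text length %d", doc_id, s0,
              e0, nchar(text))
      ov <- which(tokens$char_end > s0 & tokens$char_start < e0)
      if (!length(ov))
        stopf("doc %s: annotation [%d,%d) covers no token", doc_id, s0, e0)
      start[i] <- min(ov); end[i] <- max(ov)
      snapped[i] <- tokens$char_start[start[i]] < s0 ||
        tokens$char_end[end[i]] > e0
    }
    mn <- data.frame(start = start, end = end,
                     label = as.character(ca$label),
                     confidence = if (is.null(ca$confidence)) NA_real_ else
                       as.numeric(ca$confidence),
                     snapped = snapped, stringsAsFactors = FALSE)
  }
  annotatedDocument(doc_id, text, tokens = tokens, mentions = mn, meta = meta)
}

## character slice of a token span (used by serializers)
tokenSpanChars <- function(doc, start, end) {
  c(doc@tokens$char_start[start], doc@tokens$char_end[end])
}
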