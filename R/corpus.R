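#' @include schema.R
NULL

#' A tokenized document with (possibly nested) entity mentions
#'
#' Token spans are 1-based inclusive \code{[start, end]} token indices;
#' character offsets are 0-based half-open into \code{text}. Mentions may nest
#' or overlap; duplicate \code{(start, end, label)} triples are collapsed.
#'
#' @slot docId character document identifier.
#' @slot text the raw document text.
#' @slot tokens data.frame with columns \code{text}, \code{char_start},
#'   \code{char_end} (0-based half-open), sorted and non-overlapping.
#' @slot mentions data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive token indices), \code{label}, \code{confidence} (NA when
#'   unscored) and \code{snapped} (TRUE when a character annotation had to be
#'   widened to token boundaries).
#' @slot meta list of opaque per-document metadata (e.g. PubTator concept
#'   ids).
#' @export
setClass("AnnotatedDocument", representation(
  docId = "character", text = "character", tokens = "data.frame",
  mentions = "data.frame", meta = "list"
))

emptyMentions <- function() {
  data.frame(start = integer(0), end = integer(0), label = character(0),
             confidence = numeric(0), snapped = logical(0),
             stringsAsFactors = FALSE)
}

setValidity("AnnotatedDocument", function(object) {
  tk <- object@tokens
  mn <- object@mentions
  msg <- character(0)
  if (nrow(tk)) {
    if (any(tk$char_start >= tk$char_end)) msg <- c(msg, "empty token span")
    if (is.unsorted(tk$char_start, strictly = TRUE))
      msg <- c(msg, "tokens not sorted by char_start")
    if (any(tk$char_start[-1] < tk$char_end[-nrow(tk)]))
      msg <- c(msg, "overlapping tokens")
    if (any(tk$char_end > nchar(object@text)))
      msg <- c(msg, "token beyond text length")
  }
  if (nrow(mn)) {
    if (any(mn$start < 1L | mn$end > nrow(tk) | mn$start > mn$end))
      msg <- c(msg, "mention token span out of range")
    if (any(mn$label == NONE_LABEL)) msg <- c(msg, "mention labeled NONE")
    if (anyDuplicated(paste(mn$start, mn$end, mn$label)))
      msg <- c(msg, "duplicate (start, end, label) mention")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedDocument
#'
#' @param doc_id document identifier.
#' @param text raw text.
#' @param tokens data.frame(text, char_start, char_end); defaults to running
#'   the package tokenizer on \code{text}.
#' @param mentions data.frame(start, end, label[, confidence][, snapped]).
#' @param meta optional metadata list.
#' @return an \code{AnnotatedDocument}.
#' @export
annotatedDocument <- function(doc_id, text, tokens = NULL, mentions = NULL,
                              meta = list()) {
  if (is.null(tokens)) tokens <- tokenizeText(text)
  mn <- emptyMentions()
  if (!is.null(mentions) && nrow(mentions)) {
    mn <- data.frame(start = as.integer(mentions$start),
                     end = as.integer(mentions$end),
                     label = as.character(mentions$label),
                     confidence = if (is.null(mentions$confidence))
                       NA_real_ else as.numeric(mentions$confidence),
                     snapped = if (is.null(mentions$snapped))
                       FALSE else as.logical(mentions$snapped),
                     stringsAsFactors = FALSE)
    mn <- mn[!duplicated(paste(mn$start, mn$end, mn$label)), , drop = FALSE]
    mn <- mn[order(mn$start, mn$end, mn$label), , drop = FALSE]
    rownames(mn) <- NULL
  }
  new("AnnotatedDocument", docId = as.character(doc_id), text = text,
      tokens = tokens, mentions = mn, meta = meta)
}

#' @describeIn annotatedDocument number of tokens.
#' @param doc an \code{AnnotatedDocument}.
#' @export
nTokens <- function(doc) nrow(doc@tokens)

#' @describeIn annotatedDocument the mention table.
#' @export
mentions <- function(doc) doc@mentions

#' @describeIn annotatedDocument the token table.
#' @export
docTokens <- function(doc) doc@tokens

#' @describeIn annotatedDocument the document id.
#' @export
docId <- function(doc) doc@docId

setMethod("show", "AnnotatedDocument", function(object) {
  cat(sprintf("AnnotatedDocument '%s': %d tokens, %d mentions\n",
              object@docId, nrow(object@tokens), nrow(object@mentions)))
  if (nrow(object@mentions)) {
    m <- object@mentions
    surf <- vapply(seq_len(nrow(m)), function(i)
      paste(object@tokens$text[m$start[i]:m$end[i]], collapse = " "),
      character(1))
    for (i in seq_len(min(5L, nrow(m))))
      cat(sprintf("  [%d,%d] %s: \"%s\"\n", m$start[i], m$end[i], m$label[i],
                  surf[i]))
    if (nrow(m) > 5L) cat(sprintf("  ... and %d more\n", nrow(m) - 5L))
  }
})

## equality on the fields round-trip tests care about
sameAnnotations <- function(a, b) {
  identical(a@docId, b@docId) &&
    identical(a@tokens$text, b@tokens$text) &&
    identical(a@mentions[c("start", "end", "label")],
              b@mentions[c("start", "end", "label")])
}

mentionSurface <- function(doc, start, end) {
  paste(doc@tokens$text[start:end], collapse = " ")
}
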