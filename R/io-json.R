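#' @include tokenize.R
NULL

#' Write a corpus in the internal JSON interchange format
#'
#' The canonical interchange format for all modules: a JSON list of documents
#' \code{{doc_id, text, tokens: [{text, char_start, char_end}], mentions:
#' [{start, end, label, confidence?}]}}. Token spans are 1-based inclusive,
#' character offsets 0-based half-open. Serialization is deterministic
#' (byte-identical for identical corpora).
#'
#' @param docs list of \code{AnnotatedDocument}.
#' @param path output path.
#' @export
writeCorpusJSON <- function(docs, path) {
  out <- lapply(docs, function(doc) {
    m <- doc@mentions
    list(
      doc_id = doc@docId,
      text = doc@text,
      tokens = lapply(seq_len(nTokens(doc)), function(i)
        list(text = doc@tokens$text[i],
             char_start = doc@tokens$char_start[i],
             char_end = doc@tokens$char_end[i])),
      mentions = lapply(seq_len(nrow(m)), function(i) {
        mm <- list(start = m$start[i], end = m$end[i], label = m$label[i])
        if (!is.na(m$confidence[i])) mm$confidence <- m$confidence[i]
        mm
      })
    )
  })
  writeJSONStable(out, path)
}

#' Read a corpus from the internal JSON interchange format
#' @param path JSON corpus path.
#' @return list of \code{AnnotatedDocument}.
#' @export
readCorpusJSON <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path)
  lapply(obj, function(d) {
    tokens <- if (length(d$tokens)) data.frame(
      text = vapply(d$tokens, `[[`, "", "text"),
      char_start = vapply(d$tokens, function(t) as.integer(t$char_start), 1L),
      char_end = vapply(d$tokens, function(t) as.integer(t$char_end), 1L),
      stringsAsFactors = FALSE
    ) else tokenizeText(d$text)
    mn <- if (length(d$mentions)) data.frame(
      start = vapply(d$mentions, function(m) as.integer(m$start), 1L),
      end = vapply(d$mentions, function(m) as.integer(m$end), 1L),
      label = vapply(d$mentions, `[[`, "", "label"),
      confidence = vapply(d$mentions, function(m)
        as.numeric(m$confidence %||% NA_real_), 1.0),
      stringsAsFactors = FALSE
    ) else NULL
    annotatedDocument(d$doc_id, d$text, tokens = tokens, mentions = mn)
  })
}
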