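#' @include bioes.R
NULL

#' Read a CoNLL token-per-line corpus
#'
#' Lines are \code{token<TAB>tag}; blank lines separate sentences and a
#' \code{-DOCSTART-} line (or the file boundary) separates documents. BIO and
#' BIOES tag dialects are both accepted. Document text is reconstructed by
#' joining tokens with single spaces; CoNLL cannot express nesting, so all
#' mentions are flat.
#'
#' @param path CoNLL file path.
#' @param strict logical; passed to \code{\link{bioesToSpans}} (orphan
#'   continuation tags error instead of opening a span).
#' @return list of \code{AnnotatedDocument}.
#' @export
readConll <- function(path, strict = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  docs <- list()
  cur_tokens <- character(0); cur_tags <- character(0)
  sent_breaks <- integer(0)   # token index after which a sentence ends
  n_doc <- 0L
  flush_doc <- function() {
    if (!length(cur_tokens)) return()
    n_doc <<- n_doc + 1L
    ## spans must not cross sentence boundaries: decode per sentence
    bounds <- c(0L, sent_breaks, length(cur_tokens))
    bounds <- sort(unique(bounds))
    mts <- list()
    for (k in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      sp <- bioesToSpans(cur_tags[idx], strict = strict)
      if (nrow(sp)) {
        sp$start <- sp$start + bounds[k]; sp$end <- sp$end + bounds[k]
        mts[[length(mts) + 1L]] <- sp
      }
    }
    mn <- if (length(mts)) do.call(rbind, mts) else NULL
    text <- paste(cur_tokens, collapse = " ")
    ends <- cumsum(nchar(cur_tokens) + 1L) - 1L
    tokens <- data.frame(text = cur_tokens, char_start = ends - nchar(cur_tokens),
                         char_end = ends, stringsAsFactors = FALSE)
    docs[[length(docs) + 1L]] <<- annotatedDocument(
      paste0("conll_", n_doc), text, tokens = tokens, mentions = mn)
    cur_tokens <<- character(0); cur_tags <<- character(0)
    sent_breaks <<- integer(0)
  }
  for (line in lines) {
    if (line == "") { sent_breaks <- c(sent_breaks, length(cur_tokens)); next }
    if (grepl("^-DOCSTART-", line)) { flush_doc(); next }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stopf("malformed CoNLL line: '%s'", line)
    tag <- parts[length(parts)]
    if (tag != "O" && !grepl("^[BIES]-", tag))
      stopf("unknown tag prefix in '%s'", tag)
    cur_tokens <- c(cur_tokens, parts[1])
    cur_tags <- c(cur_tags, tag)
  }
  flush_doc()
  docs
}

#' Write a flat corpus in CoNLL format
#'
#' @param docs list of \code{AnnotatedDocument} with non-overlapping
#'   mentions.
#' @param path output path.
#' @param scheme \code{"bioes"} (default) or \code{"bio"}.
#' @export
writeConll <- function(docs, path, scheme = c("bioes", "bio")) {
  scheme <- match.arg(scheme)
  con <- file(path, "w")
  on.exit(close(con))
  first <- TRUE
  for (doc in docs) {
    if (!first) writeLines("", con)
    writeLines("-DOCSTART-\tO", con)
    writeLines("", con)
    tags <- spansToBioes(doc)
    if (scheme == "bio") {
      tags <- sub("^S-", "B-", tags)
      tags <- sub("^E-", "I-", tags)
    }
    writeLines(paste(doc@tokens$text, tags, sep = "\t"), con)
    first <- FALSE
  }
  invisible(path)
}
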