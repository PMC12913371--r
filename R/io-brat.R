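#' @include tokenize.R
NULL

#' Read a BRAT standoff document (.txt + .ann)
#'
#' Only entity annotations (T-lines of the form
#' \code{"T1<TAB>Type start end<TAB>surface"}) are consumed; character
#' offsets are 0-based half-open into the .txt content. Discontinuous spans
#' (semicolon-separated offsets) are rejected as unsupported.
#'
#' @param txt_path path to the .txt file.
#' @param ann_path path to the .ann file.
#' @param doc_id document id; defaults to the .txt basename.
#' @return an \code{AnnotatedDocument}.
#' @export
readBrat <- function(txt_path, ann_path,
                     doc_id = sub("\\.txt$", "", basename(txt_path))) {
  if (!file.exists(txt_path)) stopf("file not found: %s", txt_path)
  if (!file.exists(ann_path)) stopf("file not found: %s", ann_path)
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  lines <- readLines(ann_path, warn = FALSE)
  tlines <- grep("^T", lines, value = TRUE)
  ann <- NULL
  if (length(tlines)) {
    n <- length(tlines)
    s <- integer(n); e <- integer(n); lab <- character(n)
    for (i in seq_len(n)) {
      parts <- strsplit(tlines[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stopf("malformed T-line: %s", tlines[i])
      span <- parts[2]
      if (grepl(";", span, fixed = TRUE))
        stopf("discontinuous span unsupported: %s", tlines[i])
      fields <- strsplit(span, " ", fixed = TRUE)[[1]]
      if (length(fields) != 3L) stopf("malformed T-line span: %s", tlines[i])
      lab[i] <- fields[1]
      s[i] <- suppressWarnings(as.integer(fields[2]))
      e[i] <- suppressWarnings(as.integer(fields[3]))
      if (is.na(s[i]) || is.na(e[i]) || e[i] <= s[i])
        stopf("invalid offsets in T-line: %s", tlines[i])
      if (length(parts) >= 3L) {
        got <- substr(text, s[i] + 1L, e[i])
        if (got != parts[3])
          stopf("doc %s: .ann surface '%s' does not match .txt slice '%s'",
                doc_id, parts[3], got)
      }
    }
    ann <- data.frame(char_start = s, char_end = e, label = lab,
                      stringsAsFactors = FALSE)
  }
  tokenizeAndAlign(text, ann, doc_id = doc_id)
}

#' Write a BRAT standoff document pair
#' @param doc an \code{AnnotatedDocument}.
#' @param txt_path,ann_path output paths.
#' @export
writeBrat <- function(doc, txt_path, ann_path) {
  writeLines(doc@text, txt_path, sep = "")
  con <- file(ann_path, "w")
  on.exit(close(con))
  m <- doc@mentions
  if (nrow(m)) for (i in seq_len(nrow(m))) {
    cs <- tokenSpanChars(doc, m$start[i], m$end[i])
    writeLines(sprintf("T%d\t%s %d %d\t%s", i, m$label[i], cs[1], cs[2],
                       substr(doc@text, cs[1] + 1L, cs[2])), con)
  }
  invisible(txt_path)
}
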