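#' @include tokenize.R
NULL

#' Read a PubTator corpus
#'
#' Parses the plain-text PubTator dialect used by the NCBI Disease Corpus:
#' per document a \code{PMID|t|Title} line, an optional \code{PMID|a|Abstract}
#' line, then tab-separated annotation lines
#' \code{PMID, start, end, text, type, conceptID} with 0-based half-open
#' character offsets indexing the title and abstract joined by one space;
#' documents are separated by blank lines. Annotation types are kept
#' verbatim (schema filtering is a separate concern); concept ids are
#' preserved as opaque metadata.
#'
#' @param path PubTator file path.
#' @return list of \code{AnnotatedDocument}.
#' @export
readPubtator <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(lines == ""))
  docs <- list()
  for (block in blocks) {
    block <- block[block != ""]
    if (!length(block)) next
    docs[[length(docs) + 1L]] <- parsePubtatorBlock(block)
  }
  docs
}

parsePubtatorBlock <- function(block) {
  tl <- grep("^[^\t|]+\\|t\\|", block, value = TRUE)
  al <- grep("^[^\t|]+\\|a\\|", block, value = TRUE)
  if (length(tl) != 1L)
    stopf("PubTator block without a single title line (near: %s)", block[1])
  pmid <- sub("\\|.*$", "", tl)
  title <- sub("^[^|]+\\|t\\|", "", tl)
  abstract <- if (length(al)) sub("^[^|]+\\|a\\|", "", al[1]) else ""
  text <- if (nzchar(abstract)) paste(title, abstract) else title
  ann_lines <- setdiff(block, c(tl, al))
  ann <- NULL
  concepts <- character(0)
  if (length(ann_lines)) {
    parts <- strsplit(ann_lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 5L)
    if (length(bad))
      stopf("PubTator doc %s: annotation line %d has too few columns", pmid,
            bad[1])
    s <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    e <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
    if (anyNA(s) || anyNA(e))
      stopf("PubTator doc %s: non-integer annotation offsets", pmid)
    if (any(e > nchar(text)))
      stopf("PubTator doc %s: annotation offsets outside text", pmid)
    ann <- data.frame(char_start = s, char_end = e,
                      label = vapply(parts, `[[`, "", 5L),
                      stringsAsFactors = FALSE)
    concepts <- vapply(parts, function(p) if (length(p) >= 6L) p[[6L]] else "-",
                       character(1))
  }
  meta <- list(title = title, abstract = abstract, concept_ids = concepts)
  tokenizeAndAlign(text, ann, doc_id = pmid, meta = meta)
}

#' Write a corpus in PubTator format (inverse of \code{readPubtator})
#'
#' Documents without recorded title/abstract metadata are written with the
#' whole text as the title line. Mention character offsets are reconstructed
#' from token boundaries (0-based half-open).
#'
#' @param docs list of \code{AnnotatedDocument}.
#' @param path output path.
#' @export
writePubtator <- function(docs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (doc in docs) {
    title <- doc@meta$title %||% doc@text
    abstract <- doc@meta$abstract %||% ""
    writeLines(sprintf("%s|t|%s", doc@docId, title), con)
    if (nzchar(abstract)) writeLines(sprintf("%s|a|%s", doc@docId, abstract), con)
    m <- doc@mentions
    if (nrow(m)) for (i in seq_len(nrow(m))) {
      cs <- tokenSpanChars(doc, m$start[i], m$end[i])
      writeLines(paste(doc@docId, cs[1], cs[2],
                       substr(doc@text, cs[1] + 1L, cs[2]), m$label[i], "-",
                       sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
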