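#' @include corpus.R
NULL

#' Convert a flat document's mentions to BIOES tags
#'
#' BIOES can express flat, non-overlapping mentions only; any nested or
#' overlapping pair raises a representability error naming the offenders.
#'
#' @param doc an \code{AnnotatedDocument} with non-overlapping mentions.
#' @return character vector of per-token tags (\code{"O"}, \code{"S-y"},
#'   \code{"B-y"}, \code{"I-y"}, \code{"E-y"}).
#' @export
spansToBioes <- function(doc) {
  m <- doc@mentions
  if (nrow(m) > 1L) {
    for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
      if (m$start[j] <= m$end[i] && m$start[i] <= m$end[j])
        stopf("mentions [%d,%d,%s] and [%d,%d,%s] overlap: not representable in BIOES",
              m$start[i], m$end[i], m$label[i], m$start[j], m$end[j], m$label[j])
    }
  }
  tags <- rep("O", nTokens(doc))
  if (nrow(m)) for (i in seq_len(nrow(m))) {
    s <- m$start[i]; e <- m$end[i]; y <- m$label[i]
    if (s == e) tags[s] <- paste0("S-", y)
    else {
      tags[s] <- paste0("B-", y)
      if (e > s + 1L) tags[(s + 1L):(e - 1L)] <- paste0("I-", y)
      tags[e] <- paste0("E-", y)
    }
  }
  tags
}

#' Convert a BIO/BIOES tag sequence to mention spans
#'
#' Handles both BIO and BIOES dialects. In lenient mode (default) an orphan
#' \code{I-}/\code{E-} tag (no open span of that type) opens a new span, the
#' common repair for glitched corpora; strict mode raises an error instead.
#'
#' @param tags character vector of per-token tags.
#' @param strict logical; error on orphan continuation tags.
#' @return data.frame(start, end, label).
#' @export
bioesToSpans <- function(tags, strict = FALSE) {
  out_s <- integer(0); out_e <- integer(0); out_y <- character(0)
  open_s <- NA_integer_; open_y <- NA_character_
  close_open <- function(end) {
    if (!is.na(open_s)) {
      out_s[length(out_s) + 1L] <<- open_s
      out_e[length(out_e) + 1L] <<- end
      out_y[length(out_y) + 1L] <<- open_y
      open_s <<- NA_integer_; open_y <<- NA_character_
    }
  }
  for (t in seq_along(tags)) {
    tag <- tags[t]
    if (tag == "O") { close_open(t - 1L); next }
    if (!grepl("^[BIOES]-", tag)) stopf("unknown tag prefix: '%s'", tag)
    prefix <- substr(tag, 1L, 1L)
    y <- substr(tag, 3L, nchar(tag))
    if (prefix == "B") { close_open(t - 1L); open_s <- t; open_y <- y }
    else if (prefix == "S") { close_open(t - 1L)
      out_s[length(out_s) + 1L] <- t; out_e[length(out_e) + 1L] <- t
      out_y[length(out_y) + 1L] <- y }
    else if (prefix %in% c("I", "E")) {
      if (is.na(open_s) || open_y != y) {
        if (strict)
          stopf("orphan %s- tag at token %d (strict mode)", prefix, t)
        close_open(t - 1L); open_s <- t; open_y <- y
      }
      if (prefix == "E") close_open(t)
    }
  }
  close_open(length(tags))
  data.frame(start = out_s, end = out_e, label = out_y,
             stringsAsFactors = FALSE)
}
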