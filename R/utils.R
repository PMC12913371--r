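#' @import methods
#' @importFrom stats rbinom runif rnorm setNames
#' @importFrom utils head tail
NULL

NONE_LABEL <- "NONE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and a stream tag
#'
#' Keeps every stochastic stage on its own deterministic stream so that, e.g.,
#' corpus generation and parameter initialisation never share draws. The
#' result always fits in a 32-bit integer.
#'
#' @param seed integer base seed.
#' @param tag character stream name.
#' @return an integer seed.
#' @export
childSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (code in utf8ToInt(as.character(tag))) h <- (h * 31 + code) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

## deterministic token hash (vocabulary-free embedding lookup)
hashToken <- function(token, vocab_size) {
  h <- 0
  for (code in utf8ToInt(token)) h <- (h * 31 + code) %% 1048573
  as.integer(h %% vocab_size) + 1L
}

hashTokens <- function(tokens, vocab_size) {
  vapply(tokens, hashToken, integer(1), vocab_size = vocab_size, USE.NAMES = FALSE)
}

## stable short hash of an R object (config fingerprints in manifests)
configHash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483629
  sprintf("%08x", as.integer(h))
}

softmaxRows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

writeJSONStable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
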