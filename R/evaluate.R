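#' @include corpus.R
NULL

#' Span-level evaluation report
#'
#' Exact-match micro counts and derived metrics, with per-type and
#' nested-subset breakdowns. Precision and recall use the explicit 0/0
#' convention: when a denominator is 0 the metric is 0 and the report is
#' flagged degenerate, so empty-prediction runs are visible rather than
#' silently perfect.
#'
#' @slot tp,fp,fn nonnegative integer counts.
#' @slot precision,recall,f1 reals in [0,1].
#' @slot perType named list of per-label count/metric lists.
#' @slot nestedSubset metrics over gold mentions contained in another gold
#'   mention of the same document.
#' @slot degenerate TRUE when a 0/0 convention fired.
#' @export
setClass("EvalReport", representation(
  tp = "integer", fp = "integer", fn = "integer",
  precision = "numeric", recall = "numeric", f1 = "numeric",
  perType = "list", nestedSubset = "list", degenerate = "logical"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: P %.4f R %.4f F1 %.4f (tp %d fp %d fn %d)%s\n",
              object@precision, object@recall, object@f1, object@tp,
              object@fp, object@fn,
              if (object@degenerate) " [degenerate]" else ""))
  for (y in names(object@perType)) {
    p <- object@perType[[y]]
    cat(sprintf("  %-10s P %.4f R %.4f F1 %.4f (tp %d fp %d fn %d)\n", y,
                p$precision, p$recall, p$f1, p$tp, p$fp, p$fn))
  }
})

#' Exact-match counts between predicted and gold mentions
#'
#' A predicted triple is a true positive iff the identical \code{(start,
#' end, label)} appears in gold (set semantics; duplicates collapse);
#' remaining predictions are false positives and unmatched gold mentions
#' false negatives.
#'
#' @param pred,gold data.frames with columns start, end, label.
#' @return list(tp, fp, fn).
#' @export
matchExact <- function(pred, gold) {
  pk <- unique(paste(pred$start, pred$end, pred$label, sep = "\r"))
  gk <- unique(paste(gold$start, gold$end, gold$label, sep = "\r"))
  tp <- sum(pk %in% gk)
  list(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

prf <- function(tp, fp, fn) {
  degen <- FALSE
  if (tp + fp == 0L) { p <- 0; degen <- TRUE } else p <- tp / (tp + fp)
  if (tp + fn == 0L) { r <- 0; degen <- TRUE } else r <- tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, degenerate = degen)
}

#' Build an evaluation report from counts
#'
#' @param tp,fp,fn micro counts (nonnegative).
#' @param per_type_counts optional named list of lists with tp/fp/fn per
#'   label; micro counts must equal their sums.
#' @param nested_counts optional list(tp, fp, fn) over the nested gold
#'   subset.
#' @return an \code{EvalReport}.
#' @export
evalReport <- function(tp, fp, fn, per_type_counts = list(),
                       nested_counts = NULL) {
  if (tp < 0 || fp < 0 || fn < 0) stopf("negative counts")
  m <- prf(tp, fp, fn)
  per_type <- lapply(per_type_counts, function(ct) {
    mm <- prf(ct$tp, ct$fp, ct$fn)
    c(ct[c("tp", "fp", "fn")], mm[c("precision", "recall", "f1")])
  })
  nested <- if (!is.null(nested_counts)) {
    mm <- prf(nested_counts$tp, nested_counts$fp, nested_counts$fn)
    c(nested_counts[c("tp", "fp", "fn")], mm[c("precision", "recall", "f1")])
  } else list()
  new("EvalReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), precision = m$precision, recall = m$recall,
      f1 = m$f1, perType = per_type, nestedSubset = nested,
      degenerate = m$degenerate)
}

## gold mentions contained in another gold mention of the same document
nestedGoldKeys <- function(gold) {
  if (nrow(gold) < 2L) return(character(0))
  keys <- character(0)
  for (i in seq_len(nrow(gold))) {
    inner <- gold[i, ]
    others <- gold[-i, , drop = FALSE]
    if (any(others$start <= inner$start & inner$end <= others$end))
      keys <- c(keys, paste(inner$start, inner$end, inner$label, sep = "\r"))
  }
  keys
}

#' Evaluate predictions against gold over a corpus
#'
#' Micro-averaged exact-match metrics with per-type and nested-subset
#' breakdowns. Documents are matched by position: \code{pred[[i]]} is the
#' prediction table for \code{gold[[i]]}.
#'
#' @param pred list of data.frame(start, end, label) per document.
#' @param gold list of \code{AnnotatedDocument} (or mention data.frames).
#' @return an \code{EvalReport}.
#' @export
evaluateCorpus <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  tp <- 0L; fp <- 0L; fn <- 0L
  per <- list()
  ntp <- 0L; nfp <- 0L; nfn <- 0L
  bump <- function(tab, y, what) {
    if (is.null(tab[[y]])) tab[[y]] <- list(tp = 0L, fp = 0L, fn = 0L)
    tab[[y]][[what]] <- tab[[y]][[what]] + 1L
    tab
  }
  for (i in seq_along(gold)) {
    g <- if (is(gold[[i]], "AnnotatedDocument")) gold[[i]]@mentions else
      gold[[i]]
    p <- pred[[i]]
    pk <- unique(paste(p$start, p$end, p$label, sep = "\r"))
    gk <- unique(paste(g$start, g$end, g$label, sep = "\r"))
    for (k in pk) {
      y <- strsplit(k, "\r", fixed = TRUE)[[1]][3]
      if (k %in% gk) { tp <- tp + 1L; per <- bump(per, y, "tp") }
      else { fp <- fp + 1L; per <- bump(per, y, "fp") }
    }
    for (k in setdiff(gk, pk)) {
      y <- strsplit(k, "\r", fixed = TRUE)[[1]][3]
      fn <- fn + 1L; per <- bump(per, y, "fn")
    }
    nk <- nestedGoldKeys(g)
    ntp <- ntp + sum(nk %in% pk)
    nfn <- nfn + sum(!nk %in% pk)
  }
  evalReport(tp, fp, fn, per, list(tp = ntp, fp = nfp, fn = nfn))
}

#' Serialize an EvalReport to JSON
#' @param report an \code{EvalReport}.
#' @param path output path.
#' @export
writeEvalReport <- function(report, path) {
  writeJSONStable(list(
    tp = report@tp, fp = report@fp, fn = report@fn,
    precision = report@precision, recall = report@recall, f1 = report@f1,
    degenerate = report@degenerate, per_type = report@perType,
    nested_subset = report@nestedSubset), path)
}
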