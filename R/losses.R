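#' @include encoder.R
NULL

#' Per-type centroids (prototypes) of span representations
#'
#' \eqn{\mu_y} is the mean structure-enhanced representation over the spans
#' whose top-1 predicted label is \eqn{y}; labels without support are absent
#' from the table.
#'
#' @param struct_reprs numeric matrix, one row per span.
#' @param predicted_labels character vector of top-1 labels (never
#'   \code{"NONE"}).
#' @return list(centroids = named list of vectors, support = named integer
#'   vector).
#' @export
typeCentroids <- function(struct_reprs, predicted_labels) {
  stopifnot(nrow(struct_reprs) == length(predicted_labels))
  if (length(predicted_labels) && any(predicted_labels == NONE_LABEL))
    stopf("centroids are defined over entity labels, not NONE")
  labs <- unique(predicted_labels)
  cents <- lapply(labs, function(y)
    colMeans(struct_reprs[predicted_labels == y, , drop = FALSE]))
  names(cents) <- labs
  list(centroids = cents,
       support = setNames(as.integer(table(predicted_labels)[labs]), labs))
}

#' Center loss: summed squared distance to the type centroid
#'
#' \eqn{\sum_i \|\tilde r_i - \mu_{y_i}\|^2}; zero iff every span sits on its
#' centroid.
#'
#' @param struct_reprs numeric matrix, one row per span.
#' @param labels character vector of span labels.
#' @param centroids result of \code{\link{typeCentroids}} (or a compatible
#'   named list under \code{$centroids}).
#' @return nonnegative scalar.
#' @export
centerLoss <- function(struct_reprs, labels, centroids) {
  cents <- centroids$centroids %||% centroids
  missing <- setdiff(unique(labels), names(cents))
  if (length(missing))
    stopf("no centroid for label(s): %s", paste(missing, collapse = ", "))
  if (!length(labels)) return(0)
  sum(vapply(seq_along(labels), function(i)
    sum((struct_reprs[i, ] - cents[[labels[i]]])^2), numeric(1)))
}

#' Margin contrastive loss against competing centroids
#'
#' \eqn{\sum_i \sum_{y' \ne y_i} [\delta + \|\tilde r_i - \mu_{y_i}\|^2 -
#' \|\tilde r_i - \mu_{y'}\|^2]_+} with squared Euclidean distances; zero by
#' vacuity when fewer than two labels have centroids.
#'
#' @param struct_reprs numeric matrix, one row per span.
#' @param labels span labels.
#' @param centroids as in \code{\link{centerLoss}}.
#' @param margin nonnegative margin \eqn{\delta}.
#' @return nonnegative scalar.
#' @export
contrastiveLoss <- function(struct_reprs, labels, centroids, margin = 1) {
  if (margin < 0) stopf("margin must be nonnegative")
  cents <- centroids$centroids %||% centroids
  if (length(cents) < 2L || !length(labels)) return(0)
  total <- 0
  for (i in seq_along(labels)) {
    y <- labels[i]
    if (!y %in% names(cents)) stopf("no centroid for label %s", y)
    d_y <- sum((struct_reprs[i, ] - cents[[y]])^2)
    for (y2 in setdiff(names(cents), y)) {
      d_o <- sum((struct_reprs[i, ] - cents[[y2]])^2)
      total <- total + max(margin + d_y - d_o, 0)
    }
  }
  total
}

## align enumerated spans to gold mentions: label index per span (NONE for
## non-gold); gold mentions wider than L_max are reported in `dropped`
alignGold <- function(spans, doc, labels) {
  C <- length(labels) + 1L
  target <- rep(C, nrow(spans))    # NONE column index
  m <- doc@mentions
  dropped <- 0L
  if (nrow(m)) for (i in seq_len(nrow(m))) {
    hit <- which(spans[, 1] == m$start[i] & spans[, 2] == m$end[i])
    li <- match(m$label[i], labels)
    if (!length(hit) || is.na(li)) { dropped <- dropped + 1L; next }
    target[hit[1]] <- li
  }
  list(target = target, dropped = dropped)
}

## class weights: gold spans weight 1, NONE spans down-weighted by the
## positive-to-negative ratio
goldWeights <- function(target, n_classes) {
  w <- rep(1, length(target))
  is_none <- target == n_classes
  n_pos <- sum(!is_none); n_neg <- sum(is_none)
  if (n_neg > 0) w[is_none] <- max(n_pos, 1) / n_neg
  w
}

#' Composite training loss with per-term breakdown
#'
#' Weighted span cross-entropy over all enumerated spans (gold label or
#' \code{NONE}; non-entity spans are down-weighted by the
#' positive-to-negative span ratio) plus \code{beta} times the center loss
#' and \code{weight_contrast} times the margin contrastive loss, both
#' computed from per-batch predicted-label centroids.
#'
#' @param batch a classified \code{SpanBatch}.
#' @param doc the gold \code{AnnotatedDocument} the batch came from.
#' @param config a \code{\link{trainConfig}}.
#' @return list(total, ce, center, contrast, dropped_gold).
#' @export
totalLoss <- function(batch, doc, config) {
  labels <- batch@labels
  C <- length(labels) + 1L
  ag <- alignGold(batch@spans, doc, labels)
  w <- goldWeights(ag$target, C)
  logp <- log(pmax(batch@typeDist, 1e-12))
  ce <- sum(w * -logp[cbind(seq_along(ag$target), ag$target)]) / sum(w)
  center <- 0; contrast <- 0
  if (config$loss_weight_center > 0 || config$loss_weight_contrast > 0) {
    pred_idx <- max.col(batch@typeDist, ties.method = "first")
    is_ent <- pred_idx < C
    if (any(is_ent)) {
      r <- if (nrow(batch@structRepr)) batch@structRepr else batch@finalRepr
      preds <- labels[pred_idx[is_ent]]
      cents <- typeCentroids(r[is_ent, , drop = FALSE], preds)
      center <- centerLoss(r[is_ent, , drop = FALSE], preds, cents)
      contrast <- contrastiveLoss(r[is_ent, , drop = FALSE], preds, cents,
                                  config$margin)
    }
  }
  total <- ce + config$loss_weight_center * center +
    config$loss_weight_contrast * contrast
  list(total = total, ce = ce, center = center, contrast = contrast,
       dropped_gold = ag$dropped)
}
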