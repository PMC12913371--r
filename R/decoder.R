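#' @include encoder.R
NULL

#' Decoder configuration
#'
#' Weights and thresholds of constraint-guided global span selection. The
#' defaults are package choices (documented here, not taken from any
#' reference corpus): unit weights for the overlap and conflict penalties, a
#' small context-reward weight, similarity threshold 0.7 for span-graph
#' edges, sibling filter threshold 0.5, two propagation rounds and beam
#' width 16.
#'
#' @param lambda1 overlap penalty weight.
#' @param lambda2 type-conflict penalty weight.
#' @param lambda3 context (type-homogeneity) reward weight.
#' @param sim_threshold \eqn{\epsilon} in (0,1): span similarity needed for a
#'   propagation edge (overlapping spans are always connected).
#' @param filter_threshold \eqn{\gamma} in (0,1]: a label is excluded when
#'   any sibling reaches this probability.
#' @param propagation_rounds \eqn{K \ge 0} message-passing rounds (0 leaves
#'   distributions untouched).
#' @param beam_width beam size (>= 1).
#' @param use_propagation,use_filtering,use_nesting_prior ablation switches.
#' @param prune_threshold,prune_top_k candidate pruning before decoding.
#' @param margin_mode \code{"none_margin"} scores a selected span by
#'   \eqn{\log \tilde P(y) - \log \tilde P(NONE)} (default);
#'   \code{"literal"} uses \eqn{\log \tilde P(y)} alone, under which the
#'   empty set dominates whenever \code{lambda3 = 0}.
#' @param overlap_mode \code{"exempt_nested"} (default) exempts nested pairs
#'   licensed by the schema nesting prior from the overlap penalty;
#'   \code{"strict"} penalizes every distinct intersecting pair.
#' @param strict_compatibility reject (never select) structurally related
#'   pairs with inadmissible labels instead of merely penalizing them.
#' @return a list of class \code{"DecodeConfig"}.
#' @export
decodeConfig <- function(lambda1 = 1, lambda2 = 1, lambda3 = 0.1,
                         sim_threshold = 0.7, filter_threshold = 0.5,
                         propagation_rounds = 2L, beam_width = 16L,
                         use_propagation = TRUE, use_filtering = TRUE,
                         use_nesting_prior = TRUE, prune_threshold = 0.5,
                         prune_top_k = 40L,
                         margin_mode = c("none_margin", "literal"),
                         overlap_mode = c("exempt_nested", "strict"),
                         strict_compatibility = FALSE) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0,
            sim_threshold > 0, sim_threshold < 1,
            filter_threshold > 0, filter_threshold <= 1,
            propagation_rounds >= 0, beam_width >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 sim_threshold = sim_threshold,
                 filter_threshold = filter_threshold,
                 propagation_rounds = as.integer(propagation_rounds),
                 beam_width = as.integer(beam_width),
                 use_propagation = use_propagation,
                 use_filtering = use_filtering,
                 use_nesting_prior = use_nesting_prior,
                 prune_threshold = prune_threshold,
                 prune_top_k = as.integer(prune_top_k),
                 margin_mode = match.arg(margin_mode),
                 overlap_mode = match.arg(overlap_mode),
                 strict_compatibility = strict_compatibility),
            class = "DecodeConfig")
}

#' A decoded span selection with its objective breakdown
#'
#' @slot chosen data.frame(start, end, label, confidence).
#' @slot objectiveValue the selection objective at the chosen set.
#' @slot breakdown list(score_sum, overlap_pen, conflict_pen, context_reward,
#'   nesting_reward); the objective equals
#'   \code{score_sum - lambda1*overlap_pen - lambda2*conflict_pen +
#'   lambda3*context_reward + nesting_reward}.
#' @export
setClass("Selection", representation(
  chosen = "data.frame", objectiveValue = "numeric", breakdown = "list"))

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection: %d spans, objective %.4f\n", nrow(object@chosen),
              object@objectiveValue))
})

#' Build the span-level decode graph
#'
#' Connects two candidates when their learned similarity
#' \eqn{\sigma(\tilde r^\top W_{sim} \tilde r')} reaches
#' \code{sim_threshold} or their token intervals overlap. The adjacency is
#' row-normalized for message passing; candidates without representations
#' (decoder-only use) connect through overlap alone.
#'
#' @param cands a \code{CandidateSet}.
#' @param params \code{ModelParams} (for \code{W_sim}); may be \code{NULL}
#'   when no representations are present.
#' @param config a \code{\link{decodeConfig}}.
#' @return list(sim, edge, A) matrices.
#' @export
buildDecodeGraph <- function(cands, params, config) {
  n <- nrow(cands@spans)
  if (nrow(cands@structRepr) && !is.null(params)) {
    r <- cands@structRepr
    sim <- sigmoid(r %*% params$tensors$dec_Wsim %*% t(r))
  } else sim <- matrix(0.5, n, n)
  s <- cands@spans[, 1]; t <- cands@spans[, 2]
  ov <- outer(s, t, `<=`) & outer(t, s, `>=`)
  edge <- (sim >= config$sim_threshold) | ov
  diag(edge) <- FALSE
  A <- edge * 1
  rs <- rowSums(A)
  A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(sim = sim, edge = edge, A = A)
}

#' Graph-guided confidence propagation
#'
#' Message passing over the decode graph:
#' \eqn{z^{(k+1)} = \sigma(A z^{(k)} W + \tilde r U)} starting from the log
#' type distributions, with \eqn{\tilde P = softmax(z^{(K)})} after \eqn{K}
#' rounds. \eqn{K = 0} leaves the distributions bit-identical; isolated
#' candidates receive only the representation term.
#'
#' @param cands a \code{CandidateSet}.
#' @param graph result of \code{\link{buildDecodeGraph}}.
#' @param params \code{ModelParams} (propagation weights); \code{NULL} drops
#'   the representation term and uses an identity mixing matrix.
#' @param K number of rounds.
#' @return the candidate set with \code{refinedDist} updated.
#' @export
propagateCandidates <- function(cands, graph, params, K = 2L) {
  if (K < 0L) stopf("K must be >= 0")
  if (K == 0L) { cands@refinedDist <- cands@typeDist; return(cands) }
  z <- log(pmax(cands@typeDist, 1e-12))
  C <- ncol(z)
  W <- if (!is.null(params)) params$tensors$dec_Wprop else diag(C)
  U <- if (!is.null(params) && nrow(cands@structRepr))
    cands@structRepr %*% params$tensors$dec_Uprop else 0
  for (k in seq_len(K)) z <- sigmoid(graph$A %*% z %*% W + U)
  refined <- softmaxRows(z)
  dimnames(refined) <- dimnames(cands@typeDist)
  cands@refinedDist <- refined
  cands
}

#' Ontology-aware sibling filtering
#'
#' A label \eqn{y} stays admissible for a candidate iff every sibling of
#' \eqn{y} has probability below \code{gamma}; labels without siblings are
#' always admissible. Candidates whose admissible set empties out are
#' dropped from selection (recorded in the \code{"dropped"} attribute).
#'
#' @param cands a \code{CandidateSet} (refined distributions are used when
#'   propagation has run).
#' @param schema the \code{TypeSchema}.
#' @param gamma threshold in (0,1]; nonpositive values are an error (they
#'   would exclude every label vacuously).
#' @return the candidate set with \code{allowedLabels} updated.
#' @export
ontologyFilter <- function(cands, schema, gamma = 0.5) {
  if (gamma <= 0) stopf("filter threshold must be positive")
  labs <- cands@labels
  sib <- lapply(labs, function(y) siblings(schema, y))
  names(sib) <- labs
  dropped <- integer(0)
  for (i in seq_len(nrow(cands@spans))) {
    p <- cands@refinedDist[i, ]
    allowed <- labs[vapply(labs, function(y) {
      s <- sib[[y]]
      !length(s) || all(p[s] < gamma)
    }, logical(1))]
    cands@allowedLabels[[i]] <- allowed
    if (!length(allowed)) dropped <- c(dropped, i)
  }
  attr(cands@allowedLabels, "dropped") <- dropped
  cands
}

#' Ontology-aware projection of span representations into type space
#'
#' A label-space adapter maps each representation to a \eqn{|Y|}-vector,
#' which is projected through the ontology matrix \eqn{\Omega} and
#' softmax-normalized: \eqn{s_{s,t} = softmax(\Omega \cdot adapted(\tilde
#' r))}. Diagnostic output; it enters the selection score with weight 0 by
#' default.
#'
#' @param struct_repr numeric matrix (n x Dr) or single vector.
#' @param projection_matrix \eqn{\Omega} from \code{\link{projectionMatrix}}.
#' @param params \code{ModelParams} holding the adapter weights.
#' @return matrix (n x |Y|) with rows summing to 1.
#' @export
ontologyProject <- function(struct_repr, projection_matrix, params) {
  if (is.null(dim(struct_repr))) struct_repr <- matrix(struct_repr, 1L)
  adapted <- struct_repr %*% params$tensors$ont_W
  if (ncol(adapted) != ncol(projection_matrix))
    stopf("adapter output width %d does not match ontology matrix %d",
          ncol(adapted), ncol(projection_matrix))
  out <- softmaxRows(adapted %*% t(projection_matrix))
  colnames(out) <- colnames(projection_matrix)
  out
}

## -- objective terms ---------------------------------------------------------

selectionDF <- function(start, end, label, alpha = NA_real_) {
  data.frame(start = as.integer(start), end = as.integer(end),
             label = as.character(label), alpha = as.numeric(alpha),
             stringsAsFactors = FALSE)
}

isNestedPair <- function(si, ti, sj, tj) {
  ((si <= sj && tj <= ti) || (sj <= si && ti <= tj)) && !(si == sj && ti == tj)
}

## is the pair an admissible nesting (inner nested in outer with a schema
## nesting-prior entry licensing the label combination)?
isExemptNested <- function(si, ti, yi, sj, tj, yj, schema) {
  keys <- names(schema@nestingPrior)
  if (si <= sj && tj <= ti && !(si == sj && ti == tj))   # j inside i
    if (paste(yj, yi, sep = "|") %in% keys) return(TRUE)
  if (sj <= si && ti <= tj && !(si == sj && ti == tj))   # i inside j
    if (paste(yi, yj, sep = "|") %in% keys) return(TRUE)
  FALSE
}

#' Overlap penalty of a selection
#'
#' Number of unordered pairs of selected triples whose token intervals
#' intersect with distinct \code{(s,t)}; in the default
#' \code{"exempt_nested"} mode pairs standing in a nesting relation licensed
#' by the schema's nesting prior are exempt.
#'
#' @param selection data.frame(start, end, label).
#' @param schema \code{TypeSchema} (needed for the exemption; may be NULL in
#'   strict mode).
#' @param mode \code{"exempt_nested"} or \code{"strict"}.
#' @return nonnegative integer count.
#' @export
overlapPenalty <- function(selection, schema = NULL,
                           mode = c("exempt_nested", "strict")) {
  mode <- match.arg(mode)
  n <- nrow(selection)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    si <- selection$start[i]; ti <- selection$end[i]
    sj <- selection$start[j]; tj <- selection$end[j]
    if (si == sj && ti == tj) next
    if (si > tj || sj > ti) next
    if (mode == "exempt_nested" && !is.null(schema) &&
        isExemptNested(si, ti, selection$label[i], sj, tj,
                       selection$label[j], schema)) next
    cnt <- cnt + 1L
  }
  cnt
}

#' Type-conflict penalty of a selection
#'
#' Counts unordered pairs whose labels are inadmissible together
#' (\eqn{\Psi = -\infty}) and that stand in a structural relation (nested,
#' overlapping or adjacent); unrelated spans never conflict.
#'
#' @param selection data.frame(start, end, label).
#' @param schema \code{TypeSchema}.
#' @param max_gap adjacency gap used for the structural-relation indicator.
#' @return nonnegative integer count.
#' @export
conflictPenalty <- function(selection, schema, max_gap = 0L) {
  n <- nrow(selection)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (isAdmissiblePair(schema, selection$label[i], selection$label[j])) next
    rel <- spanRelation(selection$start[i], selection$end[i],
                        selection$start[j], selection$end[j], max_gap)
    if (nzchar(rel)) cnt <- cnt + 1L
  }
  cnt
}

#' Contextual coherence reward of a selection
#'
#' \eqn{\sum_{y} \eta_y \log(1 + \sum_{(s,t,y)} e^{\alpha_{s,t}})} over the
#' selected triples, with \eqn{\alpha} the candidate entity-ness score and
#' \eqn{\eta_y} the schema frequency prior. Empty selections score 0.
#'
#' @param selection data.frame(start, end, label[, alpha]).
#' @param candidates optional \code{CandidateSet} used to look up
#'   \eqn{\alpha} when the selection has none.
#' @param schema \code{TypeSchema}.
#' @return numeric reward.
#' @export
contextReward <- function(selection, candidates = NULL, schema) {
  if (!nrow(selection)) return(0)
  alpha <- selection$alpha
  if (is.null(alpha) || anyNA(alpha)) {
    stopifnot(!is.null(candidates))
    alpha <- vapply(seq_len(nrow(selection)), function(i) {
      k <- which(candidates@spans[, 1] == selection$start[i] &
                   candidates@spans[, 2] == selection$end[i])[1]
      candidates@entityScore[k]
    }, numeric(1))
  }
  total <- 0
  for (y in unique(selection$label)) {
    idx <- selection$label == y
    total <- total + frequencyPriorOf(schema, y) * log1p(sum(exp(alpha[idx])))
  }
  total
}

## per-(candidate,label) margin scores
candidateMargins <- function(cands, config) {
  logp <- log(pmax(cands@refinedDist, 1e-12))
  C <- ncol(logp)
  if (config$margin_mode == "none_margin")
    logp[, -C, drop = FALSE] - logp[, C] else logp[, -C, drop = FALSE]
}

#' Global selection objective with per-term breakdown
#'
#' \deqn{\sum margin(s,t,y) - \lambda_1 C_{overlap} - \lambda_2 C_{conflict}
#' + \lambda_3 K_{context} + R_{nest}} where the margin is
#' \eqn{\log \tilde P(y) - \log \tilde P(NONE)} (or the literal
#' \eqn{\log \tilde P(y)}), and \eqn{R_{nest}} adds the schema nesting prior
#' \eqn{\gamma_{y,y}} for every same-label nested selected pair when
#' \code{use_nesting_prior} is on.
#'
#' @param selection data.frame(start, end, label) of selected triples; every
#'   triple must reference a candidate with that label admissible.
#' @param cands the \code{CandidateSet}.
#' @param schema \code{TypeSchema}.
#' @param config \code{\link{decodeConfig}}.
#' @return a \code{Selection} (chosen set, objective, breakdown).
#' @export
selectionObjective <- function(selection, cands, schema, config) {
  margins <- candidateMargins(cands, config)
  score_sum <- 0
  alpha <- numeric(nrow(selection))
  conf <- numeric(nrow(selection))
  if (nrow(selection)) for (i in seq_len(nrow(selection))) {
    k <- which(cands@spans[, 1] == selection$start[i] &
                 cands@spans[, 2] == selection$end[i])[1]
    if (is.na(k)) stopf("selected span [%d,%d] is not a candidate",
                        selection$start[i], selection$end[i])
    if (!selection$label[i] %in% cands@allowedLabels[[k]])
      stopf("label %s not allowed for span [%d,%d]", selection$label[i],
            selection$start[i], selection$end[i])
    score_sum <- score_sum + unname(margins[k, selection$label[i]])
    alpha[i] <- cands@entityScore[k]
    conf[i] <- cands@refinedDist[k, selection$label[i]]
  }
  selection$alpha <- alpha
  ov <- overlapPenalty(selection, schema, config$overlap_mode)
  cf <- conflictPenalty(selection, schema)
  ctx <- contextReward(selection, cands, schema)
  nest <- 0
  if (config$use_nesting_prior && nrow(selection) > 1L) {
    for (i in seq_len(nrow(selection) - 1L)) for (j in (i + 1L):nrow(selection)) {
      if (selection$label[i] != selection$label[j]) next
      si <- selection$start[i]; ti <- selection$end[i]
      sj <- selection$start[j]; tj <- selection$end[j]
      if (isNestedPair(si, ti, sj, tj))
        nest <- nest + nestingPriorOf(schema, selection$label[i],
                                      selection$label[j])
    }
  }
  value <- score_sum - config$lambda1 * ov - config$lambda2 * cf +
    config$lambda3 * ctx + nest
  new("Selection",
      chosen = data.frame(start = as.integer(selection$start),
                          end = as.integer(selection$end),
                          label = selection$label, confidence = conf,
                          stringsAsFactors = FALSE),
      objectiveValue = value,
      breakdown = list(score_sum = score_sum, overlap_pen = ov,
                       conflict_pen = cf, context_reward = ctx,
                       nesting_reward = nest))
}

## -- vectorized subset machinery ---------------------------------------------

## Atoms are (candidate, label) pairs with positive margin among the allowed
## labels; precomputed pairwise terms let the subset objective be evaluated
## for many subsets at once.
buildAtoms <- function(cands, schema, config) {
  margins <- candidateMargins(cands, config)
  labs <- cands@labels
  atom <- list()
  for (i in seq_len(nrow(cands@spans))) {
    for (y in cands@allowedLabels[[i]]) {
      if (margins[i, y] > 0)
        atom[[length(atom) + 1L]] <- list(cand = i, s = cands@spans[i, 1],
                                          t = cands@spans[i, 2], y = y,
                                          margin = margins[i, y],
                                          alpha = cands@entityScore[i])
    }
  }
  if (!length(atom))
    return(list(n = 0L))
  n <- length(atom)
  s <- vapply(atom, `[[`, 0, "s"); t <- vapply(atom, `[[`, 0, "t")
  y <- vapply(atom, `[[`, "", "y"); cand <- vapply(atom, `[[`, 0, "cand")
  m <- vapply(atom, `[[`, 0, "margin"); al <- vapply(atom, `[[`, 0, "alpha")
  Fm <- matrix(0, n, n); Pm <- matrix(0, n, n); Gn <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (cand[i] == cand[j]) { Fm[i, j] <- 1; next }
    sameSpan <- s[i] == s[j] && t[i] == t[j]
    if (sameSpan) { Fm[i, j] <- 1; next }   # one label per (s, t)
    intersects <- s[i] <= t[j] && s[j] <= t[i]
    ovp <- intersects &&
      !(config$overlap_mode == "exempt_nested" &&
          isExemptNested(s[i], t[i], y[i], s[j], t[j], y[j], schema))
    cfp <- !isAdmissiblePair(schema, y[i], y[j]) &&
      nzchar(spanRelation(s[i], t[i], s[j], t[j]))
    if (config$strict_compatibility && cfp) Fm[i, j] <- 1
    Pm[i, j] <- config$lambda1 * ovp + config$lambda2 * cfp
    if (config$use_nesting_prior && y[i] == y[j] &&
        isNestedPair(s[i], t[i], s[j], t[j]))
      Gn[i, j] <- nestingPriorOf(schema, y[i], y[j])
  }
  ylevels <- unique(y)
  expA <- matrix(0, n, length(ylevels), dimnames = list(NULL, ylevels))
  expA[cbind(seq_len(n), match(y, ylevels))] <- exp(al)
  eta <- vapply(ylevels, frequencyPriorOf, numeric(1), schema = schema)
  list(n = n, s = s, t = t, y = y, cand = cand, margin = m, alpha = al,
       Fm = Fm, Pm = Pm, Gn = Gn, expA = expA, eta = eta,
       lambda3 = config$lambda3)
}

atomObjective <- function(at, M) {
  score <- as.vector(M %*% at$margin)
  pair <- rowSums((M %*% at$Pm) * M) / 2
  nest <- rowSums((M %*% at$Gn) * M) / 2
  ctx <- as.vector(log1p(M %*% at$expA) %*% at$eta)
  score - pair + nest + at$lambda3 * ctx
}

atomFeasible <- function(at, M) rowSums((M %*% at$Fm) * M) == 0

## deterministic tie-break: fewer spans, then lexicographic (s, t, y) key
atomKey <- function(at, mask) {
  idx <- which(mask > 0)
  if (!length(idx)) return("")
  o <- order(at$s[idx], at$t[idx], at$y[idx])
  paste(at$s[idx][o], at$t[idx][o], at$y[idx][o], collapse = ";")
}

pickBest <- function(at, M, values) {
  best <- max(values)
  tied <- which(values == best)
  if (length(tied) > 1L) {
    sizes <- rowSums(M[tied, , drop = FALSE])
    tied <- tied[sizes == min(sizes)]
    if (length(tied) > 1L) {
      keys <- vapply(tied, function(k) atomKey(at, M[k, ]), character(1))
      tied <- tied[order(keys)]
    }
  }
  tied[1L]
}

maskToSelection <- function(at, mask, cands, schema, config) {
  idx <- which(mask > 0)
  sel <- data.frame(start = at$s[idx], end = at$t[idx], label = at$y[idx],
                    stringsAsFactors = FALSE)
  sel <- sel[order(sel$start, sel$end, sel$label), , drop = FALSE]
  rownames(sel) <- NULL
  selectionObjective(sel, cands, schema, config)
}

#' Exhaustive optimal span selection (oracle)
#'
#' Enumerates every subset of (candidate, label) atoms respecting
#' one-label-per-span and returns the objective maximizer; ties break to
#' fewer spans, then the lexicographically smallest (s, t, y) sequence.
#' Limited to 16 atoms; larger instances must use
#' \code{\link{selectSpansBeam}}.
#'
#' @param cands a \code{CandidateSet} (filtered or not).
#' @param schema \code{TypeSchema}.
#' @param config \code{\link{decodeConfig}}.
#' @return a \code{Selection}.
#' @export
selectSpansExhaustive <- function(cands, schema, config) {
  at <- buildAtoms(cands, schema, config)
  if (at$n == 0L)
    return(new("Selection",
               chosen = data.frame(start = integer(0), end = integer(0),
                                   label = character(0),
                                   confidence = numeric(0),
                                   stringsAsFactors = FALSE),
               objectiveValue = 0,
               breakdown = list(score_sum = 0, overlap_pen = 0,
                                conflict_pen = 0, context_reward = 0,
                                nesting_reward = 0)))
  if (at$n > 16L)
    stopf("%d atoms exceed the exhaustive-search capacity of 16; use selectSpansBeam",
          at$n)
  n <- at$n
  M <- matrix(0, 2^n, n)
  for (j in seq_len(n)) M[, j] <- bitwAnd(0:(2^n - 1L), bitwShiftL(1L, j - 1L)) > 0
  M <- M[atomFeasible(at, M), , drop = FALSE]
  values <- atomObjective(at, M)
  k <- pickBest(at, M, values)
  maskToSelection(at, M[k, ], cands, schema, config)
}

#' Beam-search span selection
#'
#' Atoms ordered by margin descending are decided include/exclude one at a
#' time; partial states are scored by the objective of the partial set plus
#' an optimistic bound (the remaining positive margins), states violating
#' one-label-per-span are pruned immediately and the best
#' \code{beam_width} states survive each step. With \code{beam_width >=
#' 2^n} the search is exhaustive.
#'
#' @inheritParams selectSpansExhaustive
#' @return a \code{Selection}.
#' @export
selectSpansBeam <- function(cands, schema, config) {
  at <- buildAtoms(cands, schema, config)
  if (at$n == 0L)
    return(selectSpansExhaustive(cands, schema, config))
  n <- at$n
  ord <- order(-at$margin, at$s, at$t, at$y)
  rest_bound <- rev(cumsum(rev(pmax(at$margin[ord], 0))))
  rest_bound <- c(rest_bound[-1], 0)
  M <- matrix(0, 1L, n)
  for (step in seq_len(n)) {
    j <- ord[step]
    M2 <- M
    M2[, j] <- 1
    M <- rbind(M, M2)
    M <- M[atomFeasible(at, M), , drop = FALSE]
    if (nrow(M) > config$beam_width) {
      sc <- atomObjective(at, M) + rest_bound[step]
      keys <- vapply(seq_len(nrow(M)), function(k) atomKey(at, M[k, ]),
                     character(1))
      keep <- order(-sc, rowSums(M), keys)[seq_len(config$beam_width)]
      M <- M[keep, , drop = FALSE]
    }
  }
  values <- atomObjective(at, M)
  ## refine every surviving state and keep the overall best: different
  ## beam states sit in different basins of the flip neighborhood
  for (k in seq_len(nrow(M))) {
    M[k, ] <- polishMask(at, M[k, ], values[k])
  }
  values <- atomObjective(at, M)
  k <- pickBest(at, M, values)
  maskToSelection(at, M[k, ], cands, schema, config)
}

## deterministic steepest-ascent refinement over single, pair and (for
## small instances) triple atom flips. Beam search scores partial sets, so
## configurations whose value materializes only jointly - the grouped
## context reward, or a coordinated label swap across spans - can slip
## past a narrow beam; flip passes recover them. All flip candidates of a
## pass are evaluated in one vectorized sweep.
polishMask <- function(at, mask, value, max_passes = 200L) {
  n <- at$n
  flips <- lapply(seq_len(n), function(j) j)
  if (n > 1) flips <- c(flips, combn(n, 2, simplify = FALSE))
  if (n > 2 && n <= 20) flips <- c(flips, combn(n, 3, simplify = FALSE))
  Mflip <- matrix(mask, length(flips), n, byrow = TRUE)
  for (f in seq_along(flips))
    Mflip[f, flips[[f]]] <- 1 - Mflip[f, flips[[f]]]
  for (pass in seq_len(max_passes)) {
    feas <- atomFeasible(at, Mflip)
    if (!any(feas)) return(mask)
    vals <- rep(-Inf, nrow(Mflip))
    vals[feas] <- atomObjective(at, Mflip[feas, , drop = FALSE])
    k <- which.max(vals)
    if (vals[k] <= value + 1e-12) return(mask)
    value <- vals[k]
    mask <- Mflip[k, ]
    Mflip <- matrix(mask, length(flips), n, byrow = TRUE)
    for (f in seq_along(flips))
      Mflip[f, flips[[f]]] <- 1 - Mflip[f, flips[[f]]]
  }
  mask
}

#' Full decoding pipeline for one document
#'
#' Encode, enumerate, aggregate/gate/attend, classify, prune, optionally
#' propagate and filter, then select the globally consistent span set
#' (exhaustive when at most 16 atoms remain, beam search otherwise). Stage
#' switches in the decode config mirror the ablation structure.
#'
#' @param doc an \code{AnnotatedDocument} (empty documents decode to zero
#'   mentions).
#' @param params \code{ModelParams}.
#' @param schema \code{TypeSchema}.
#' @param encoder_config \code{\link{encoderConfig}}.
#' @param decode_config \code{\link{decodeConfig}}.
#' @return data.frame(start, end, label, confidence) of predicted mentions.
#' @export
decodeDocument <- function(doc, params, schema, encoder_config, decode_config) {
  if (nTokens(doc) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  enc <- encodeSpans(doc, params, encoder_config)
  cands <- pruneSpans(enc$batch, decode_config$prune_threshold,
                      decode_config$prune_top_k, doc_id = docId(doc))
  decodeCandidates(cands, schema, decode_config, params)
}

#' Decode a prepared candidate set (standalone decoder entry point)
#'
#' @param cands a \code{CandidateSet} (e.g. from \code{\link{pruneSpans}} or
#'   \code{\link{readCandidatesJSON}}).
#' @param schema \code{TypeSchema}.
#' @param config \code{\link{decodeConfig}}.
#' @param params optional \code{ModelParams} for similarity/propagation
#'   weights.
#' @return data.frame(start, end, label, confidence).
#' @export
decodeCandidates <- function(cands, schema, config, params = NULL) {
  if (!nrow(cands@spans))
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  if (config$use_propagation && config$propagation_rounds > 0L) {
    graph <- buildDecodeGraph(cands, params, config)
    cands <- propagateCandidates(cands, graph, params,
                                 config$propagation_rounds)
  }
  if (config$use_filtering)
    cands <- ontologyFilter(cands, schema, config$filter_threshold)
  at <- buildAtoms(cands, schema, config)
  sel <- if (at$n <= 16L) selectSpansExhaustive(cands, schema, config)
  else selectSpansBeam(cands, schema, config)
  sel@chosen
}

#' Read decoder-only candidates from JSON
#'
#' Format: \code{{doc_id, candidates: [{start, end, dist: {label: prob, ...,
#' NONE: prob}, repr?: [numbers]}]}}. Enables decoder use and oracle testing
#' without the encoder.
#'
#' @param path JSON file path.
#' @param labels schema label ordering for the distribution columns.
#' @return a \code{CandidateSet}.
#' @export
readCandidatesJSON <- function(path, labels) {
  obj <- jsonlite::read_json(path)
  makeCandidateSet(
    spans = do.call(rbind, lapply(obj$candidates, function(c)
      c(as.integer(c$start), as.integer(c$end)))),
    dist = do.call(rbind, lapply(obj$candidates, function(c)
      vapply(c(labels, NONE_LABEL), function(y) as.numeric(c$dist[[y]] %||% 0),
             numeric(1)))),
    labels = labels, doc_id = obj$doc_id %||% "doc",
    repr = if (!is.null(obj$candidates[[1]]$repr))
      do.call(rbind, lapply(obj$candidates, function(c)
        as.numeric(unlist(c$repr)))) else NULL)
}

#' Construct a CandidateSet from plain matrices
#'
#' @param spans integer matrix (n x 2).
#' @param dist probability matrix (n x |Y|+1), NONE column last; rows are
#'   renormalized to sum to 1.
#' @param labels schema labels.
#' @param doc_id document id.
#' @param repr optional representation matrix.
#' @return a \code{CandidateSet}.
#' @export
makeCandidateSet <- function(spans, dist, labels, doc_id = "doc", repr = NULL) {
  spans <- matrix(as.integer(spans), ncol = 2)
  if (anyDuplicated(paste(spans[, 1], spans[, 2])))
    stopf("duplicate candidate span: a candidate set carries one distribution per (s, t)")
  dist <- dist / rowSums(dist)
  colnames(dist) <- c(labels, NONE_LABEL)
  ord <- order(spans[, 1], spans[, 2])
  spans <- spans[ord, , drop = FALSE]
  dist <- dist[ord, , drop = FALSE]
  new("CandidateSet", docId = doc_id, spans = spans, typeDist = dist,
      refinedDist = dist, entityScore = unname(1 - dist[, ncol(dist)]),
      structRepr = if (is.null(repr)) emptyMat() else
        repr[ord, , drop = FALSE],
      allowedLabels = rep(list(labels), nrow(spans)), labels = labels)
}
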