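#' @include encoder-config.R corpus.R
NULL

#' Enumerated candidate spans with staged representations
#'
#' Rows of every matrix slot align with the span list (strictly ordered by
#' start, then end). Representations are filled stage by stage:
#' \code{rawRepr} by multi-channel aggregation, \code{finalRepr} by gating,
#' \code{structRepr} by structural attention / span self-attention, and
#' \code{typeDist} (rows summing to 1 over the labels plus \code{NONE}) by
#' classification.
#'
#' @slot spans integer matrix (n x 2) of 1-based inclusive token spans.
#' @slot rawRepr,lengthEmbed,gate,finalRepr,structRepr numeric matrices.
#' @slot typeDist numeric matrix with one column per label plus "NONE".
#' @slot labels the schema label ordering used by \code{typeDist}.
#' @export
setClass("SpanBatch", representation(
  spans = "matrix", rawRepr = "matrix", lengthEmbed = "matrix",
  gate = "matrix", finalRepr = "matrix", structRepr = "matrix",
  typeDist = "matrix", labels = "character"
))

setMethod("show", "SpanBatch", function(object) {
  cat(sprintf("SpanBatch: %d spans; stages filled: %s\n", nrow(object@spans),
              paste(c("raw", "gate", "struct", "dist")[
                c(nrow(object@rawRepr), nrow(object@gate),
                  nrow(object@structRepr), nrow(object@typeDist)) > 0],
                collapse = ", ")))
})

#' Structural relations between candidate spans
#'
#' @slot relations character matrix (n x n); \code{""}, \code{"nested"},
#'   \code{"overlap"} or \code{"adjacent"}.
#' @slot alpha attention weight matrix of the last structural layer (rows of
#'   non-isolated nodes sum to 1).
#' @export
setClass("SpanGraph", representation(relations = "matrix", alpha = "matrix"))

setMethod("show", "SpanGraph", function(object) {
  r <- object@relations
  cat(sprintf("SpanGraph: %d nodes; %d nested, %d overlap, %d adjacent pairs\n",
              nrow(r), sum(r == "nested") / 2, sum(r == "overlap") / 2,
              sum(r == "adjacent") / 2))
})

#' Encode document tokens
#'
#' The \code{"tiny"} backend sums a hashed seeded token embedding with a
#' positional embedding and applies \code{n_encoder_layers} blocks of
#' multi-head self-attention with feed-forward sublayers (pre-activation
#' identical across runs: the forward pass is deterministic given parameters
#' and input). The \code{"pretrained"} backend calls
#' \code{config$pretrained_fun} and pools the first subword of each word; it
#' raises a capability error when no adapter function is supplied, never a
#' silent fallback.
#'
#' @param doc an \code{AnnotatedDocument} with at least one token.
#' @param params \code{ModelParams}.
#' @param config \code{EncoderConfig}.
#' @return numeric matrix (T x hidden_dim).
#' @export
encodeTokens <- function(doc, params, config) {
  if (nTokens(doc) == 0L) stopf("document '%s' has no tokens", docId(doc))
  if (config$backend == "pretrained") {
    if (is.null(config$pretrained_fun))
      stopf("pretrained backend requested but no pretrained_fun adapter supplied")
    res <- config$pretrained_fun(doc)
    first <- !duplicated(res$word_index)
    H <- res$subword[first, , drop = FALSE][order(res$word_index[first]), ,
                                            drop = FALSE]
    if (nrow(H) != nTokens(doc) || ncol(H) != config$hidden_dim)
      stopf("pretrained adapter returned %d x %d, expected %d x %d", nrow(H),
            ncol(H), nTokens(doc), config$hidden_dim)
    return(H)
  }
  p <- params$tensors
  T_ <- nTokens(doc)
  ids <- hashTokens(doc@tokens$text, config$vocab_size)
  H <- p$emb[ids, , drop = FALSE] +
    p$pos[pmin(seq_len(T_), config$max_seq_len), , drop = FALSE]
  for (l in seq_len(config$n_encoder_layers))
    H <- encoderLayer(H, p, l, config)
  H
}

encoderLayer <- function(H, p, l, config) {
  d <- config$hidden_dim
  nh <- config$n_heads
  dh <- d %/% nh
  Q <- H %*% p[[sprintf("enc%d_Wq", l)]]
  K <- H %*% p[[sprintf("enc%d_Wk", l)]]
  V <- H %*% p[[sprintf("enc%d_Wv", l)]]
  heads <- lapply(seq_len(nh), function(h) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmaxRows(Q[, cols, drop = FALSE] %*%
                       t(K[, cols, drop = FALSE]) / sqrt(dh))
    A %*% V[, cols, drop = FALSE]
  })
  O <- do.call(cbind, heads) %*% p[[sprintf("enc%d_Wo", l)]]
  H <- layerNormRows(H + O, p[[sprintf("enc%d_ln1_g", l)]],
                     p[[sprintf("enc%d_ln1_b", l)]])
  FF <- pmax(sweep(H %*% p[[sprintf("enc%d_ffn_W1", l)]], 2L,
                   as.vector(p[[sprintf("enc%d_ffn_b1", l)]]), `+`), 0) %*%
    p[[sprintf("enc%d_ffn_W2", l)]]
  FF <- sweep(FF, 2L, as.vector(p[[sprintf("enc%d_ffn_b2", l)]]), `+`)
  layerNormRows(H + FF, p[[sprintf("enc%d_ln2_g", l)]],
                p[[sprintf("enc%d_ln2_b", l)]])
}

layerNormRows <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  sweep(sweep(xc * inv, 2L, as.vector(gamma), `*`), 2L, as.vector(beta), `+`)
}

#' Enumerate candidate spans
#'
#' All \code{(s, t)} with \code{1 <= s <= t <= T} and width at most
#' \code{L_max}, strictly ordered by \code{(s, t)}.
#'
#' @param T_ number of tokens (>= 1).
#' @param L_max maximum span width (>= 1).
#' @return integer matrix (n x 2) with columns \code{s}, \code{t}.
#' @export
enumerateSpans <- function(T_, L_max) {
  if (T_ < 1L || L_max < 1L) stopf("enumerateSpans: T and L_max must be >= 1")
  s <- rep(seq_len(T_), each = L_max)
  t <- s + rep(seq_len(L_max) - 1L, times = T_)
  keep <- t <= T_
  cbind(s = s[keep], t = t[keep])
}

#' Token similarity graph from a bilinear similarity
#'
#' \eqn{Sim(i,j) = \sigma(h_i^\top W h_j)}; an edge is present iff
#' \eqn{Sim \ge} threshold and \eqn{i \ne j}. Similarities are returned
#' alongside the adjacency so downstream attention can reuse them.
#'
#' @param H token embedding matrix (T x d).
#' @param W bilinear interaction matrix (d x d).
#' @param threshold edge threshold in (0,1).
#' @return list(sim = numeric matrix, adj = logical matrix).
#' @export
tokenSimilarityGraph <- function(H, W, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  sim <- sigmoid(H %*% W %*% t(H))
  adj <- sim >= threshold
  diag(adj) <- FALSE
  list(sim = sim, adj = adj)
}

#' Graph-augmented token representations
#'
#' \eqn{\tilde h_t = h_t + \sum_j \alpha_{tj} h_j} with \eqn{\alpha} the
#' softmax of cached similarities over \eqn{t}'s neighbors; isolated tokens
#' pass through unchanged.
#'
#' @param H token embeddings (T x d).
#' @param token_graph result of \code{\link{tokenSimilarityGraph}}.
#' @return matrix of the same shape as \code{H}.
#' @export
graphAugmentTokens <- function(H, token_graph) {
  A <- maskedSoftmaxRows(token_graph$sim, token_graph$adj)
  H + A %*% H
}

maskedSoftmaxRows <- function(x, mask) {
  x[!mask] <- -Inf
  m <- apply(x, 1L, max)
  dead <- !is.finite(m)
  m[dead] <- 0
  e <- exp(x - m)
  e[!is.finite(e)] <- 0
  rs <- rowSums(e)
  rs[rs == 0] <- 1
  e / rs
}

#' Multi-channel span aggregation with length embedding
#'
#' Builds the raw span representation
#' \eqn{r_{s,t} = [h_s; h_t; mean_{i=s..t} h_i; max_{i=s..t} h_i; \psi_{s,t}]}
#' with \eqn{\psi_{s,t} = W_{len}[\ell] + b_{len}}, \eqn{\ell = t-s+1} (the
#' length channel is dropped when \code{use_length_embed} is FALSE, giving
#' the 4-channel variant).
#'
#' @param H token embeddings (augmented or not).
#' @param spans integer span matrix from \code{\link{enumerateSpans}}.
#' @param params \code{ModelParams}.
#' @param config \code{EncoderConfig}.
#' @return a \code{SpanBatch} with \code{rawRepr} and \code{lengthEmbed}
#'   filled.
#' @export
aggregateSpans <- function(H, spans, params, config) {
  T_ <- nrow(H)
  if (any(spans[, 1] < 1L | spans[, 2] > T_ | spans[, 1] > spans[, 2]))
    stopf("span out of range for a %d-token document", T_)
  p <- params$tensors
  s <- spans[, 1]; t <- spans[, 2]
  lens <- t - s + 1L
  mean_m <- poolMatrix(spans, T_)
  ch_mean <- mean_m %*% H
  ch_max <- spanMaxPool(H, s, lens)
  psi <- sweep(p$W_len[lens, , drop = FALSE], 2L, as.vector(p$b_len), `+`)
  raw <- cbind(H[s, , drop = FALSE], H[t, , drop = FALSE], ch_mean, ch_max)
  if (config$use_length_embed) raw <- cbind(raw, psi)
  new("SpanBatch", spans = spans, rawRepr = raw, lengthEmbed = psi,
      gate = emptyMat(), finalRepr = emptyMat(), structRepr = emptyMat(),
      typeDist = emptyMat(), labels = character(0))
}

emptyMat <- function() matrix(numeric(0), 0L, 0L)

## averaging matrix: row per span, 1/len over covered token rows
poolMatrix <- function(spans, T_) {
  n <- nrow(spans)
  m <- matrix(0, n, T_)
  for (i in seq_len(n)) {
    idx <- spans[i, 1]:spans[i, 2]
    m[i, idx] <- 1 / length(idx)
  }
  m
}

spanMaxPool <- function(H, starts, lens) {
  v <- H[starts, , drop = FALSE]
  maxlen <- max(lens)
  if (maxlen > 1L) for (k in 1L:(maxlen - 1L)) {
    act <- which(lens > k)
    if (!length(act)) break
    v[act, ] <- pmax(v[act, , drop = FALSE], H[starts[act] + k, , drop = FALSE])
  }
  v
}

#' Channel gating
#'
#' \eqn{g = \sigma(W_g r + b_g)}, \eqn{r^{final} = g \odot r}; gate entries
#' are strictly inside (0,1).
#'
#' @param batch a \code{SpanBatch} with \code{rawRepr} filled.
#' @param params \code{ModelParams}.
#' @return the batch with \code{gate} and \code{finalRepr} filled.
#' @export
gateSpans <- function(batch, params) {
  p <- params$tensors
  g <- sigmoid(sweep(batch@rawRepr %*% p$W_g, 2L, as.vector(p$b_g), `+`))
  batch@gate <- g
  batch@finalRepr <- g * batch@rawRepr
  batch
}

#' Build the span structural-relation graph
#'
#' Pairs are connected when one span is nested in the other, when they
#' overlap without nesting, or when they are adjacent with a token gap of at
#' most \code{max_gap} (0 = abutting). Stored symmetrically.
#'
#' @param spans integer span matrix.
#' @param max_gap adjacency gap tolerance.
#' @return a \code{SpanGraph}.
#' @export
buildSpanGraph <- function(spans, max_gap = 0L) {
  n <- nrow(spans)
  s <- spans[, 1]; t <- spans[, 2]
  S1 <- matrix(s, n, n); T1 <- matrix(t, n, n)   # span i by row
  S2 <- t(S1); T2 <- t(T1)                        # span j by column
  eq <- S1 == S2 & T1 == T2
  nested <- ((S1 <= S2 & T2 <= T1) | (S2 <= S1 & T1 <= T2)) & !eq
  overlap <- S1 <= T2 & S2 <= T1 & !nested & !eq
  gap <- pmax(S2 - T1, S1 - T2) - 1L
  adjacent <- !nested & !overlap & !eq & gap >= 0L & gap <= max_gap
  rel <- matrix("", n, n)
  rel[nested] <- "nested"
  rel[overlap] <- "overlap"
  rel[adjacent] <- "adjacent"
  diag(rel) <- ""
  new("SpanGraph", relations = rel, alpha = matrix(0, n, n))
}

spanRelation <- function(si, ti, sj, tj, max_gap = 0L) {
  if (si == sj && ti == tj) return("")
  if ((si <= sj && tj <= ti) || (sj <= si && ti <= tj)) return("nested")
  if (si <= tj && sj <= ti) return("overlap")
  gap <- if (sj > ti) sj - ti - 1L else si - tj - 1L
  if (gap <= max_gap) return("adjacent")
  ""
}

#' Structural attention over the span graph
#'
#' For each span, a structural context \eqn{c_i = \sum_{j \in N(i)}
#' \alpha_{ij} r_j} with \eqn{\alpha_{ij} = softmax_j(r_i^\top W_a r_j)} over
#' graph neighbors, passed through a feed-forward network and residually
#' combined: \eqn{\tilde r_i = LayerNorm(r_i + FFN(c_i))}. Spans with no
#' neighbors use \eqn{c_i = 0}. Applied \code{n_structural_layers} times.
#'
#' @param batch a \code{SpanBatch} with \code{finalRepr} filled.
#' @param span_graph a \code{SpanGraph} over the batch's spans.
#' @param params \code{ModelParams}.
#' @param config \code{EncoderConfig}.
#' @return list(batch = updated batch with \code{structRepr}, graph = the
#'   graph with the last layer's attention weights in \code{alpha}).
#' @export
structuralAttention <- function(batch, span_graph, params, config) {
  p <- params$tensors
  r <- batch@finalRepr
  adj <- span_graph@relations != ""
  alpha <- matrix(0, nrow(r), nrow(r))
  for (l in seq_len(max(config$n_structural_layers, 0L))) {
    scores <- r %*% p$W_a %*% t(r)
    alpha <- maskedSoftmaxRows(scores, adj)
    ci <- alpha %*% r
    f <- pmax(sweep(ci %*% p$struct_W1, 2L, as.vector(p$struct_b1), `+`), 0) %*%
      p$struct_W2
    f <- sweep(f, 2L, as.vector(p$struct_b2), `+`)
    r <- layerNormRows(r + f, p$struct_ln_g, p$struct_ln_b)
  }
  batch@structRepr <- r
  span_graph@alpha <- alpha
  list(batch = batch, graph = span_graph)
}

#' Span-level self-attention with positional/nesting bias
#'
#' Full pairwise attention over spans with scores
#' \eqn{(r_i W_Q)(r_j W_K)^\top / \sqrt{d_r} + \phi(i,j)}, where \eqn{\phi}
#' is a learned table over bucketed start distance (0, 1, 2, 3-4, 5-8, 9+)
#' and candidate-relative nesting depth difference clipped to [-2, 2]. The
#' single-head layout applies a value projection followed by an output
#' projection, a residual connection and layer normalisation. Applied
#' \code{n_self_attention_layers} times.
#'
#' @param batch a \code{SpanBatch} with \code{structRepr} filled (falls back
#'   to \code{finalRepr} when structural attention was skipped).
#' @param params \code{ModelParams}.
#' @param config \code{EncoderConfig}.
#' @return the batch with refined \code{structRepr}.
#' @export
spanSelfAttention <- function(batch, params, config) {
  p <- params$tensors
  r <- if (nrow(batch@structRepr)) batch@structRepr else batch@finalRepr
  Dr <- ncol(r)
  idx <- phiIndex(batch@spans[, 1], spanDepths(batch@spans))
  for (l in seq_len(max(config$n_self_attention_layers, 0L))) {
    phi <- matrix(p$sa_phi[as.vector(idx)], nrow(idx), ncol(idx))
    scores <- (r %*% p$sa_Wq) %*% t(r %*% p$sa_Wk) / sqrt(Dr) + phi
    A <- softmaxRows(scores)
    out <- (A %*% (r %*% p$sa_Wv)) %*% p$sa_Wo
    r <- layerNormRows(r + out, p$sa_ln_g, p$sa_ln_b)
  }
  batch@structRepr <- r
  batch
}

#' Classify spans into the typed label set
#'
#' \eqn{P(y|s,t,x) = softmax_{y \in Y \cup \{NONE\}}(\theta_y^\top \tilde r +
#' b_y)}; each row sums to 1 and the \code{NONE} column is last.
#'
#' @param batch a \code{SpanBatch} with \code{structRepr} (or
#'   \code{finalRepr}) filled.
#' @param params \code{ModelParams}.
#' @return the batch with \code{typeDist} and \code{labels} filled.
#' @export
classifySpans <- function(batch, params) {
  p <- params$tensors
  r <- if (nrow(batch@structRepr)) batch@structRepr else batch@finalRepr
  logits <- sweep(r %*% p$cls_W, 2L, as.vector(p$cls_b), `+`)
  dist <- softmaxRows(logits)
  colnames(dist) <- c(params$labels, NONE_LABEL)
  batch@typeDist <- dist
  batch@labels <- params$labels
  batch
}

#' Pruned high-confidence candidates entering global decoding
#'
#' @slot docId document id.
#' @slot spans integer matrix (n x 2).
#' @slot typeDist classifier distributions (rows sum to 1).
#' @slot refinedDist propagation-refined distributions (equal to
#'   \code{typeDist} until \code{\link{propagateCandidates}} runs).
#' @slot entityScore entity-ness \eqn{\alpha_{s,t} = 1 - P(NONE)} from the
#'   classifier.
#' @slot structRepr structure-enhanced representations (may have zero rows
#'   for decoder-only use).
#' @slot allowedLabels list of per-candidate admissible label vectors.
#' @slot labels schema label ordering.
#' @export
setClass("CandidateSet", representation(
  docId = "character", spans = "matrix", typeDist = "matrix",
  refinedDist = "matrix", entityScore = "numeric", structRepr = "matrix",
  allowedLabels = "list", labels = "character"
))

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet '%s': %d candidates over %d labels\n",
              object@docId, nrow(object@spans), length(object@labels)))
})

#' Prune enumerated spans to high-confidence candidates
#'
#' Keeps spans whose entity-ness \eqn{1 - P(NONE)} reaches
#' \code{keep_threshold}, then caps at the \code{top_k} best (ties broken by
#' span order). Retained candidates keep their full distributions.
#'
#' @param batch a classified \code{SpanBatch}.
#' @param keep_threshold minimum entity-ness.
#' @param top_k maximum number of candidates (>= 1).
#' @param doc_id document id carried through to the candidate set.
#' @return a \code{CandidateSet}.
#' @export
pruneSpans <- function(batch, keep_threshold = 0.5, top_k = 40L,
                       doc_id = "doc") {
  if (top_k < 1L) stopf("top_k must be >= 1")
  if (!nrow(batch@typeDist)) stopf("classify spans before pruning")
  score <- 1 - batch@typeDist[, NONE_LABEL]
  keep <- which(score >= keep_threshold)
  ord <- keep[order(-score[keep], batch@spans[keep, 1], batch@spans[keep, 2])]
  ord <- head(ord, top_k)
  ord <- sort(ord)   # candidate set stays in (s, t) order
  new("CandidateSet", docId = doc_id,
      spans = batch@spans[ord, , drop = FALSE],
      typeDist = batch@typeDist[ord, , drop = FALSE],
      refinedDist = batch@typeDist[ord, , drop = FALSE],
      entityScore = unname(score[ord]),
      structRepr = if (nrow(batch@structRepr))
        batch@structRepr[ord, , drop = FALSE] else emptyMat(),
      allowedLabels = rep(list(batch@labels), length(ord)),
      labels = batch@labels)
}

#' Run the full span encoder forward pass
#'
#' Token encoding, optional token-graph augmentation, span enumeration,
#' multi-channel aggregation, gating, structural attention, span
#' self-attention and classification, in that order.
#'
#' @param doc an \code{AnnotatedDocument}.
#' @param params \code{ModelParams}.
#' @param config \code{EncoderConfig}.
#' @return list(batch = classified \code{SpanBatch}, graph = \code{SpanGraph},
#'   H = token embeddings).
#' @export
encodeSpans <- function(doc, params, config) {
  H <- encodeTokens(doc, params, config)
  if (config$use_token_graph) {
    tg <- tokenSimilarityGraph(H, params$tensors$W_tok,
                               config$token_sim_threshold)
    H <- graphAugmentTokens(H, tg)
  }
  spans <- enumerateSpans(nTokens(doc), config$max_span_len)
  batch <- aggregateSpans(H, spans, params, config)
  batch <- gateSpans(batch, params)
  graph <- buildSpanGraph(spans, config$adjacency_max_gap)
  sa <- structuralAttention(batch, graph, params, config)
  batch <- spanSelfAttention(sa$batch, params, config)
  batch <- classifySpans(batch, params)
  list(batch = batch, graph = sa$graph, H = H)
}
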