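#' @include utils.R
NULL

## ---------------------------------------------------------------------------
## Minimal reverse-mode automatic differentiation on matrices.
##
## A tape is an environment accumulating nodes; each node stores its value, the
## ids of its parents and a backward closure mapping the output gradient to
## parent gradients. Operations accept either a node id (scalar integer) or a
## plain matrix, which is treated as a constant. Gradients are verified
## against central finite differences in the test suite.
## ---------------------------------------------------------------------------

adTape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

adPush <- function(tape, value, parents = integer(0), backward = NULL) {
  force(value); force(parents); force(backward)   # argument promises may push
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- list(value = value, parents = parents, backward = backward)
  tape$n <- n
  n
}

adVal <- function(tape, x) if (is.matrix(x)) x else tape$nodes[[x]]$value

adInput <- function(tape, value) adPush(tape, value)

isNode <- function(x) !is.matrix(x)

## Run backpropagation from scalar node `root`; returns a list of gradients
## indexed by node id (NULL where no gradient flows).
adBackward <- function(tape, root) {
  grads <- vector("list", tape$n)
  v <- adVal(tape, root)
  grads[[root]] <- matrix(1, nrow(v), ncol(v))
  for (id in seq(root, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

## -- binary helpers ----------------------------------------------------------

adBin <- function(tape, a, b, value, back_a, back_b) {
  parents <- integer(0)
  backs <- list()
  if (isNode(a)) { parents <- c(parents, a); backs <- c(backs, list(back_a)) }
  if (isNode(b)) { parents <- c(parents, b); backs <- c(backs, list(back_b)) }
  adPush(tape, value, parents, function(g) lapply(backs, function(f) f(g)))
}

adMM <- function(tape, a, b) {
  A <- adVal(tape, a); B <- adVal(tape, b)
  adBin(tape, a, b, A %*% B,
        function(g) g %*% t(B), function(g) t(A) %*% g)
}

adAdd <- function(tape, a, b) {
  A <- adVal(tape, a); B <- adVal(tape, b)
  adBin(tape, a, b, A + B, identity, identity)
}

adSub <- function(tape, a, b) {
  A <- adVal(tape, a); B <- adVal(tape, b)
  adBin(tape, a, b, A - B, identity, function(g) -g)
}

adMul <- function(tape, a, b) {
  A <- adVal(tape, a); B <- adVal(tape, b)
  adBin(tape, a, b, A * B, function(g) g * B, function(g) g * A)
}

## add a 1 x d bias row to every row of an n x d matrix
adAddRow <- function(tape, a, bias) {
  A <- adVal(tape, a); B <- adVal(tape, bias)
  v <- sweep(A, 2L, as.vector(B), `+`)
  adBin(tape, a, bias, v, identity,
        function(g) matrix(colSums(g), 1L))
}

adScale <- function(tape, a, k) {
  A <- adVal(tape, a)
  adPush(tape, A * k, a, function(g) list(g * k))
}

## division by a scalar (kept distinct from adScale so the forward value is
## bit-identical to plain `/` code paths)
adDivScale <- function(tape, a, s) {
  A <- adVal(tape, a)
  adPush(tape, A / s, a, function(g) list(g / s))
}

adCols <- function(tape, a, cols) {
  A <- adVal(tape, a)
  adPush(tape, A[, cols, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    out[, cols] <- g
    list(out)
  })
}

adSigmoid <- function(tape, a) {
  v <- sigmoid(adVal(tape, a))
  adPush(tape, v, a, function(g) list(g * v * (1 - v)))
}

adTanh <- function(tape, a) {
  v <- tanh(adVal(tape, a))
  adPush(tape, v, a, function(g) list(g * (1 - v^2)))
}

adLog <- function(tape, a, clamp = 1e-12) {
  A <- pmax(adVal(tape, a), clamp)
  adPush(tape, log(A), a, function(g) list(g / A))
}

adRelu <- function(tape, a) {
  A <- adVal(tape, a)
  v <- pmax(A, 0)
  adPush(tape, v, a, function(g) list(g * (A > 0)))
}

adT <- function(tape, a) {
  adPush(tape, t(adVal(tape, a)), a, function(g) list(t(g)))
}

adSum <- function(tape, a) {
  A <- adVal(tape, a)
  adPush(tape, matrix(sum(A), 1L, 1L), a,
         function(g) list(matrix(g[1L], nrow(A), ncol(A))))
}

adRows <- function(tape, a, idx) {
  A <- adVal(tape, a)
  adPush(tape, A[idx, , drop = FALSE], a,
         function(g) list(scatterRows(g, idx, nrow(A))))
}

adConcatCols <- function(tape, ids) {
  vals <- lapply(ids, adVal, tape = tape)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  node_ids <- ids[vapply(ids, isNode, logical(1))]
  node_pos <- which(vapply(ids, isNode, logical(1)))
  adPush(tape, do.call(cbind, vals), unlist(node_ids), function(g)
    lapply(node_pos, function(k) g[, starts[k]:ends[k], drop = FALSE]))
}

## row-wise softmax with an optional logical mask (FALSE entries excluded);
## rows with no admitted entry yield an all-zero row
adSoftmaxRows <- function(tape, a, mask = NULL) {
  A <- adVal(tape, a)
  x <- A
  if (!is.null(mask)) x[!mask] <- -Inf
  m <- apply(x, 1L, max)
  dead <- !is.finite(m)
  m[dead] <- 0
  e <- exp(x - m)
  e[!is.finite(e)] <- 0
  rs <- rowSums(e)
  rs[rs == 0] <- 1
  v <- e / rs
  adPush(tape, v, a, function(g) list(v * (g - rowSums(g * v))))
}

adLayerNormRows <- function(tape, a, gamma, beta, eps = 1e-5) {
  A <- adVal(tape, a)
  G <- as.vector(adVal(tape, gamma)); B <- as.vector(adVal(tape, beta))
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2L, G, `*`), 2L, B, `+`)
  parents <- integer(0); which_in <- character(0)
  if (isNode(a)) { parents <- c(parents, a); which_in <- c(which_in, "a") }
  if (isNode(gamma)) { parents <- c(parents, gamma); which_in <- c(which_in, "g") }
  if (isNode(beta)) { parents <- c(parents, beta); which_in <- c(which_in, "b") }
  adPush(tape, v, parents, function(g) {
    dxhat <- sweep(g, 2L, G, `*`)
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    out <- list(a = dx, g = matrix(colSums(g * xhat), 1L),
                b = matrix(colSums(g), 1L))
    out[which_in]
  })
}

## gather entries of a parameter matrix by a (possibly repeated) linear index
## matrix; used for the span-distance/nesting-depth attention bias table
adGather <- function(tape, table, idx) {
  TB <- adVal(tape, table)
  v <- matrix(TB[as.vector(idx)], nrow(idx), ncol(idx))
  adPush(tape, v, table, function(g) {
    acc <- rowsum(as.vector(g), group = as.vector(idx))
    out <- matrix(0, nrow(TB), ncol(TB))
    out[as.integer(rownames(acc))] <- acc
    list(out)
  })
}

## max over token rows s..(s+len-1) per span, with argmax routing for the
## gradient; `starts` and `lens` are per-span vectors
adSpanMax <- function(tape, a, starts, lens) {
  A <- adVal(tape, a)
  n <- length(starts); d <- ncol(A)
  v <- A[starts, , drop = FALSE]
  argmax <- matrix(starts, n, d)
  maxlen <- max(lens)
  if (maxlen > 1L) for (k in 1L:(maxlen - 1L)) {
    act <- which(lens > k)
    if (!length(act)) break
    cand <- A[starts[act] + k, , drop = FALSE]
    sub <- v[act, , drop = FALSE]
    upd <- cand > sub
    sub[upd] <- cand[upd]
    v[act, ] <- sub
    am <- argmax[act, , drop = FALSE]
    am[upd] <- (matrix(starts[act] + k, nrow(am), ncol(am)))[upd]
    argmax[act, ] <- am
  }
  adPush(tape, v, a, function(g) {
    acc <- rowsum(as.vector(g),
                  group = as.vector(argmax) + (rep(seq_len(d), each = n) - 1L) * nrow(A))
    out <- numeric(nrow(A) * d)
    out[as.integer(rownames(acc))] <- acc
    list(matrix(out, nrow(A), d))
  })
}

## weighted (class-balanced) cross-entropy of row-wise softmax against integer
## targets; returns a 1 x 1 node
adCrossEntropy <- function(tape, logits, target, w) {
  L <- adVal(tape, logits)
  P <- softmaxRows(L)
  n <- nrow(L)
  pick <- P[cbind(seq_len(n), target)]
  sw <- sum(w)
  v <- sum(w * -log(pmax(pick, 1e-12))) / sw
  adPush(tape, matrix(v, 1L, 1L), logits, function(g) {
    onehot <- matrix(0, n, ncol(L))
    onehot[cbind(seq_len(n), target)] <- 1
    list((P - onehot) * (w / sw) * g[1L])
  })
}

scatterRows <- function(g, idx, n_out) {
  acc <- rowsum(g, group = idx)
  out <- matrix(0, n_out, ncol(g))
  out[as.integer(rownames(acc)), ] <- acc
  out
}
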