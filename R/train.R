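#' @include losses.R autodiff.R
NULL

#' Training configuration
#'
#' Defaults mirror a standard biomedical fine-tuning recipe: decoupled
#' weight-decay Adam with learning rate 3e-5, weight decay 0.01, batch size
#' 16, up to 30 epochs with early stopping after 5 stale validation epochs,
#' sequences capped at 512 tokens and a stratified 70/10/20 document split.
#' The from-scratch tiny backend typically needs a larger learning rate
#' (around 5e-3) than the fine-tuning default.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled weight decay coefficient.
#' @param batch_size documents per optimizer step.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs without validation F1
#'   improvement.
#' @param max_seq_len maximum document length in tokens.
#' @param loss_weight_center center-loss weight \eqn{\beta} (0 disables).
#' @param loss_weight_contrast contrastive-loss weight (0 disables).
#' @param loss_weight_refine weight of the refined-propagation cross-entropy
#'   that trains the decoder's message-passing matrices (0 disables, leaving
#'   them at initialisation).
#' @param margin contrastive margin \eqn{\delta} (squared-distance units).
#' @param grad_clip global gradient norm clip.
#' @param seed integer seed governing splits, shuffling and dropout.
#' @param split_fractions train/validation/test fractions summing to 1.
#' @return a list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(learning_rate = 3e-5, weight_decay = 0.01,
                        batch_size = 16L, max_epochs = 30L, patience = 5L,
                        max_seq_len = 512L, loss_weight_center = 0.001,
                        loss_weight_contrast = 0, loss_weight_refine = 1,
                        margin = 1,
                        grad_clip = 1, seed = 42L,
                        split_fractions = c(0.7, 0.1, 0.2)) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-9, patience <= max_epochs || max_epochs == 0,
            loss_weight_center >= 0, loss_weight_contrast >= 0, margin >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 max_seq_len = as.integer(max_seq_len),
                 loss_weight_center = loss_weight_center,
                 loss_weight_contrast = loss_weight_contrast,
                 loss_weight_refine = loss_weight_refine,
                 margin = margin, grad_clip = grad_clip,
                 seed = as.integer(seed),
                 split_fractions = split_fractions), class = "TrainConfig")
}

## -- document preprocessing (geometry that never changes across epochs) -----

preprocessDoc <- function(doc, config, labels) {
  T_ <- nTokens(doc)
  spans <- enumerateSpans(T_, config$max_span_len)
  ag <- alignGold(spans, doc, labels)
  list(doc = doc,
       ids = hashTokens(doc@tokens$text, config$vocab_size),
       pos_idx = pmin(seq_len(T_), config$max_seq_len),
       spans = spans,
       lens = spans[, 2] - spans[, 1] + 1L,
       pool = poolMatrix(spans, T_),
       adj = buildSpanGraph(spans, config$adjacency_max_gap)@relations != "",
       phi_idx = phiIndex(spans[, 1], spanDepths(spans)),
       target = ag$target, dropped = ag$dropped,
       weights = goldWeights(ag$target, length(labels) + 1L))
}

## -- differentiable forward pass --------------------------------------------
## Mirrors the exported stage functions operation for operation; the test
## suite asserts value parity with encodeSpans().

adForwardDoc <- function(tape, pre, pn, params, config, train = FALSE,
                         drop_seed = NULL) {
  p <- params$tensors
  T_ <- length(pre$ids)
  d <- config$hidden_dim
  dropmask <- NULL
  if (train && config$dropout > 0 && !is.null(drop_seed)) {
    set.seed(drop_seed)
    keep <- 1 - config$dropout
    dropmask <- function(nr, nc)
      matrix(rbinom(nr * nc, 1L, keep) / keep, nr, nc)
  }
  H <- adAdd(tape, adRows(tape, pn$emb, pre$ids),
             adRows(tape, pn$pos, pre$pos_idx))
  for (l in seq_len(config$n_encoder_layers)) {
    H <- adEncoderLayer(tape, H, pn, l, config)
    if (!is.null(dropmask)) H <- adMul(tape, H, dropmask(T_, d))
  }
  if (config$use_token_graph) {
    sim <- adSigmoid(tape, adMM(tape, adMM(tape, H, pn$W_tok), adT(tape, H)))
    adjtok <- adVal(tape, sim) >= config$token_sim_threshold
    diag(adjtok) <- FALSE
    A <- adSoftmaxRows(tape, sim, adjtok)
    H <- adAdd(tape, H, adMM(tape, A, H))
  }
  s <- pre$spans[, 1]; t <- pre$spans[, 2]
  channels <- list(adRows(tape, H, s), adRows(tape, H, t),
                   adMM(tape, pre$pool, H), adSpanMax(tape, H, s, pre$lens))
  if (config$use_length_embed)
    channels <- c(channels, list(adAddRow(tape, adRows(tape, pn$W_len, pre$lens),
                                          pn$b_len)))
  raw <- adConcatCols(tape, channels)
  g <- adSigmoid(tape, adAddRow(tape, adMM(tape, raw, pn$W_g), pn$b_g))
  r <- adMul(tape, g, raw)
  if (!is.null(dropmask))
    r <- adMul(tape, r, dropmask(nrow(pre$spans), ncol(adVal(tape, r))))
  for (l in seq_len(config$n_structural_layers)) {
    scores <- adMM(tape, adMM(tape, r, pn$W_a), adT(tape, r))
    alpha <- adSoftmaxRows(tape, scores, pre$adj)
    ci <- adMM(tape, alpha, r)
    f <- adAddRow(tape, adMM(tape, adRelu(tape, adAddRow(
      tape, adMM(tape, ci, pn$struct_W1), pn$struct_b1)), pn$struct_W2),
      pn$struct_b2)
    r <- adLayerNormRows(tape, adAdd(tape, r, f), pn$struct_ln_g,
                         pn$struct_ln_b)
  }
  Dr <- ncol(adVal(tape, r))
  for (l in seq_len(config$n_self_attention_layers)) {
    phi <- adGather(tape, pn$sa_phi, pre$phi_idx)
    scores <- adAdd(tape, adDivScale(tape, adMM(
      tape, adMM(tape, r, pn$sa_Wq), adT(tape, adMM(tape, r, pn$sa_Wk))),
      sqrt(Dr)), phi)
    A <- adSoftmaxRows(tape, scores)
    out <- adMM(tape, adMM(tape, A, adMM(tape, r, pn$sa_Wv)), pn$sa_Wo)
    r <- adLayerNormRows(tape, adAdd(tape, r, out), pn$sa_ln_g, pn$sa_ln_b)
  }
  logits <- adAddRow(tape, adMM(tape, r, pn$cls_W), pn$cls_b)
  list(H = H, r = r, logits = logits)
}

adEncoderLayer <- function(tape, H, pn, l, config) {
  d <- config$hidden_dim
  nh <- config$n_heads
  dh <- d %/% nh
  Q <- adMM(tape, H, pn[[sprintf("enc%d_Wq", l)]])
  K <- adMM(tape, H, pn[[sprintf("enc%d_Wk", l)]])
  V <- adMM(tape, H, pn[[sprintf("enc%d_Wv", l)]])
  heads <- lapply(seq_len(nh), function(h) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- adSoftmaxRows(tape, adDivScale(tape, adMM(
      tape, adCols(tape, Q, cols), adT(tape, adCols(tape, K, cols))),
      sqrt(dh)))
    adMM(tape, A, adCols(tape, V, cols))
  })
  O <- adMM(tape, adConcatCols(tape, heads), pn[[sprintf("enc%d_Wo", l)]])
  H <- adLayerNormRows(tape, adAdd(tape, H, O),
                       pn[[sprintf("enc%d_ln1_g", l)]],
                       pn[[sprintf("enc%d_ln1_b", l)]])
  FF <- adAddRow(tape, adMM(tape, adRelu(tape, adAddRow(
    tape, adMM(tape, H, pn[[sprintf("enc%d_ffn_W1", l)]]),
    pn[[sprintf("enc%d_ffn_b1", l)]])), pn[[sprintf("enc%d_ffn_W2", l)]]),
    pn[[sprintf("enc%d_ffn_b2", l)]])
  adLayerNormRows(tape, adAdd(tape, H, FF),
                  pn[[sprintf("enc%d_ln2_g", l)]],
                  pn[[sprintf("enc%d_ln2_b", l)]])
}

## refined-prediction cross-entropy: prunes candidates by the current
## classifier, propagates over the overlap graph with the trainable
## mixing/representation matrices, and scores the refined distributions
## against gold. This is what trains W_prop and U_prop; without it the
## decoder's message passing would run on random weights.
adRefineLoss <- function(tape, fwd, pre, pn, tcfg, C,
                         K = 2L, keep_threshold = 0.5, top_k = 40L) {
  dist <- softmaxRows(adVal(tape, fwd$logits))
  score <- 1 - dist[, C]
  sel <- which(score >= keep_threshold)
  sel <- sel[order(-score[sel])]
  sel <- sort(head(sel, top_k))
  if (length(sel) < 1L) return(NULL)
  s <- pre$spans[sel, 1]; t <- pre$spans[sel, 2]
  ov <- outer(s, t, `<=`) & outer(t, s, `>=`)
  diag(ov) <- FALSE
  A <- ov * 1
  rs <- rowSums(A)
  A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
  z <- adLog(tape, adSoftmaxRows(tape, adRows(tape, fwd$logits, sel)))
  r_sel <- adRows(tape, fwd$r, sel)
  for (k in seq_len(K))
    z <- adSigmoid(tape, adAdd(tape, adMM(tape, adMM(tape, A, z), pn$dec_Wprop),
                               adMM(tape, r_sel, pn$dec_Uprop)))
  adCrossEntropy(tape, z, pre$target[sel],
                 goldWeights(pre$target[sel], C))
}

## loss head on top of adForwardDoc: weighted CE + refined-propagation CE +
## detached-centroid center and contrastive regularizers
adLossDoc <- function(tape, fwd, pre, params, tcfg, pn = NULL) {
  C <- length(params$labels) + 1L
  if (is.null(pn))
    pn <- list(dec_Wprop = adInput(tape, params$tensors$dec_Wprop),
               dec_Uprop = adInput(tape, params$tensors$dec_Uprop))
  loss <- adCrossEntropy(tape, fwd$logits, pre$target, pre$weights)
  terms <- list(ce = adVal(tape, loss)[1L], refine = 0, center = 0,
                contrast = 0)
  if (tcfg$loss_weight_refine > 0) {
    rl <- adRefineLoss(tape, fwd, pre, pn, tcfg, C)
    if (!is.null(rl)) {
      terms$refine <- adVal(tape, rl)[1L]
      loss <- adAdd(tape, loss, adScale(tape, rl, tcfg$loss_weight_refine))
    }
  }
  if (tcfg$loss_weight_center > 0 || tcfg$loss_weight_contrast > 0) {
    dist <- softmaxRows(adVal(tape, fwd$logits))
    pred_idx <- max.col(dist, ties.method = "first")
    sel <- which(pred_idx < C)
    if (length(sel) >= 1L) {
      rv <- adVal(tape, fwd$r)
      preds <- params$labels[pred_idx[sel]]
      cents <- typeCentroids(rv[sel, , drop = FALSE], preds)$centroids
      Mown <- do.call(rbind, cents[preds])
      selr <- adRows(tape, fwd$r, sel)
      diff <- adSub(tape, selr, Mown)
      sq <- adMul(tape, diff, diff)
      center <- adSum(tape, sq)
      terms$center <- adVal(tape, center)[1L]
      if (tcfg$loss_weight_center > 0)
        loss <- adAdd(tape, loss, adScale(tape, center, tcfg$loss_weight_center))
      if (tcfg$loss_weight_contrast > 0 && length(cents) >= 2L) {
        ones <- matrix(1, ncol(Mown), 1L)
        d_own <- adMM(tape, sq, ones)
        contrast <- NULL
        for (y2 in names(cents)) {
          rows <- which(preds != y2)
          if (!length(rows)) next
          My2 <- matrix(cents[[y2]], length(rows), length(cents[[y2]]),
                        byrow = TRUE)
          diff2 <- adSub(tape, adRows(tape, selr, rows), My2)
          d_other <- adMM(tape, adMul(tape, diff2, diff2), ones)
          hinge <- adRelu(tape, adAdd(tape, adSub(
            tape, adRows(tape, d_own, rows), d_other),
            matrix(tcfg$margin, length(rows), 1L)))
          h <- adSum(tape, hinge)
          contrast <- if (is.null(contrast)) h else adAdd(tape, contrast, h)
        }
        if (!is.null(contrast)) {
          terms$contrast <- adVal(tape, contrast)[1L]
          loss <- adAdd(tape, loss, adScale(tape, contrast,
                                            tcfg$loss_weight_contrast))
        }
      }
    }
  }
  list(loss = loss, terms = terms)
}

## -- optimizer ---------------------------------------------------------------

adamwInit <- function(tensors) {
  list(m = lapply(tensors, function(x) x * 0),
       v = lapply(tensors, function(x) x * 0), t = 0L)
}

adamwStep <- function(tensors, grads, state, lr, wd, clip,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    tensors[[nm]] <- tensors[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                             wd * tensors[[nm]])
  }
  list(tensors = tensors, state = state)
}

## -- splitting ---------------------------------------------------------------

#' Stratified document split
#'
#' Documents are grouped by the multiset of labels they contain (hashed) and
#' each group is partitioned into train/validation/test at the configured
#' fractions after a seeded shuffle.
#'
#' @param corpus list of \code{AnnotatedDocument}.
#' @param fractions length-3 numeric summing to 1.
#' @param seed integer seed.
#' @return list(train, val, test) of index vectors into \code{corpus}.
#' @export
splitCorpus <- function(corpus, fractions = c(0.7, 0.1, 0.2), seed = 42L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  keys <- vapply(corpus, function(d)
    configHash(sort(d@mentions$label)), character(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "split"))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_val <- round(fractions[2] * n)
    n_test <- round(fractions[3] * n)
    n_train <- n - n_val - n_test
    out$train <- c(out$train, idx[seq_len(n_train)])
    out$val <- c(out$val, idx[n_train + seq_len(n_val)])
    out$test <- c(out$test, idx[n_train + n_val + seq_len(n_test)])
  }
  lapply(out, sort)
}

## argmax-threshold baseline predictions from classifier distributions
baselineMentions <- function(dist, spans, labels, threshold = 0.5) {
  C <- length(labels) + 1L
  score <- 1 - dist[, C]
  pred <- max.col(dist, ties.method = "first")
  keep <- which(score >= threshold & pred < C)
  data.frame(start = spans[keep, 1], end = spans[keep, 2],
             label = labels[pred[keep]], confidence = score[keep],
             stringsAsFactors = FALSE)
}

## -- training loop -----------------------------------------------------------

#' Train the span model
#'
#' Stratified split, minibatched AdamW with gradient clipping, per-epoch
#' validation by span-level exact-match F1 (argmax-threshold predictions) and
#' early stopping on stale validation F1. Fully deterministic given the
#' seeds in the configs. Documents are the splitting unit.
#'
#' @param corpus nonempty list of \code{AnnotatedDocument}.
#' @param schema the run's \code{TypeSchema}.
#' @param encoder_config an \code{\link{encoderConfig}}.
#' @param train_config a \code{\link{trainConfig}}.
#' @param quiet suppress per-epoch messages.
#' @return list(params = best-on-validation \code{ModelParams}, log =
#'   data.frame of per-epoch records, split = index lists).
#' @export
trainModel <- function(corpus, schema, encoder_config, train_config,
                       quiet = TRUE) {
  if (!length(corpus)) stopf("empty corpus")
  tcfg <- train_config; ecfg <- encoder_config
  if (sum(vapply(corpus, function(d) nrow(d@mentions), integer(1))) == 0L)
    warning("corpus has zero mentions; training a degenerate classifier")
  labels <- typeLabels(schema)
  params <- initParams(ecfg, schema)
  split <- splitCorpus(corpus, tcfg$split_fractions, tcfg$seed)
  pre_train <- lapply(corpus[split$train], preprocessDoc, config = ecfg,
                      labels = labels)
  pre_val <- lapply(corpus[split$val], preprocessDoc, config = ecfg,
                    labels = labels)
  n_dropped <- sum(vapply(pre_train, `[[`, 0L, "dropped"))
  if (n_dropped > 0L && !quiet)
    message(sprintf("%d gold mentions exceed max_span_len and are excluded",
                    n_dropped))
  state <- adamwInit(params$tensors)
  log <- data.frame()
  best <- list(f1 = -Inf, tensors = params$tensors)
  stall <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (epoch in seq_len(tcfg$max_epochs)) {
    set.seed(childSeed(tcfg$seed, paste0("epoch", epoch)))
    order_idx <- sample.int(length(pre_train))
    ep <- list(loss = 0, ce = 0, refine = 0, center = 0, contrast = 0)
    batch_grads <- NULL; batch_n <- 0L
    for (i in order_idx) {
      pre <- pre_train[[i]]
      tape <- adTape()
      pn <- lapply(params$tensors, adInput, tape = tape)
      fwd <- adForwardDoc(tape, pre, pn, params, ecfg, train = TRUE,
                          drop_seed = childSeed(tcfg$seed,
                                                paste0("drop", epoch, "_", i)))
      lo <- adLossDoc(tape, fwd, pre, params, tcfg, pn)
      ep$loss <- ep$loss + adVal(tape, lo$loss)[1L]
      ep$ce <- ep$ce + lo$terms$ce
      ep$refine <- ep$refine + lo$terms$refine
      ep$center <- ep$center + lo$terms$center
      ep$contrast <- ep$contrast + lo$terms$contrast
      grads <- adBackward(tape, lo$loss)
      gd <- lapply(pn, function(id) grads[[id]])
      gd <- gd[!vapply(gd, is.null, logical(1))]
      batch_grads <- if (is.null(batch_grads)) gd else {
        for (nm in names(gd)) batch_grads[[nm]] <-
            if (is.null(batch_grads[[nm]])) gd[[nm]] else batch_grads[[nm]] + gd[[nm]]
        batch_grads
      }
      batch_n <- batch_n + 1L
      if (batch_n >= tcfg$batch_size) {
        upd <- adamwStep(params$tensors,
                         lapply(batch_grads, function(g) g / batch_n), state,
                         tcfg$learning_rate, tcfg$weight_decay, tcfg$grad_clip)
        params$tensors <- upd$tensors; state <- upd$state
        batch_grads <- NULL; batch_n <- 0L
      }
    }
    if (batch_n > 0L) {
      upd <- adamwStep(params$tensors,
                       lapply(batch_grads, function(g) g / batch_n), state,
                       tcfg$learning_rate, tcfg$weight_decay, tcfg$grad_clip)
      params$tensors <- upd$tensors; state <- upd$state
    }
    val <- evalOnPre(pre_val, params, ecfg,
                     refined = tcfg$loss_weight_refine > 0)
    n_tr <- length(pre_train)
    rec <- data.frame(epoch = epoch, train_loss = ep$loss / n_tr,
                      ce = ep$ce / n_tr, refine = ep$refine / n_tr,
                      center = ep$center / n_tr,
                      contrast = ep$contrast / n_tr,
                      val_p = val$precision, val_r = val$recall,
                      val_f1 = val$f1)
    log <- rbind(log, rec)
    if (!quiet)
      message(sprintf("epoch %d: loss %.4f val_f1 %.4f", epoch,
                      rec$train_loss, rec$val_f1))
    if (length(pre_val)) {
      if (val$f1 > best$f1 + 1e-12) {
        best <- list(f1 = val$f1, tensors = params$tensors)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= tcfg$patience) break
    } else best <- list(f1 = NA_real_, tensors = params$tensors)
  }
  params$tensors <- best$tensors
  list(params = params, log = log, split = split, best_val_f1 = best$f1)
}

## validation metric: exact-match micro F1 of argmax-threshold predictions.
## When the refine term is active the metric is computed on the
## propagation-refined distributions (the ones full decoding consumes), so
## early stopping tracks the decode-relevant quality, not just the raw
## classifier.
evalOnPre <- function(pre_list, params, ecfg, refined = TRUE,
                      K = 2L, keep_threshold = 0.5, top_k = 40L) {
  if (!length(pre_list))
    return(list(precision = NA_real_, recall = NA_real_, f1 = NA_real_))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (pre in pre_list) {
    tape <- adTape()
    pn <- lapply(params$tensors, adInput, tape = tape)
    fwd <- adForwardDoc(tape, pre, pn, params, ecfg, train = FALSE)
    dist <- softmaxRows(adVal(tape, fwd$logits))
    spans <- pre$spans
    if (refined) {
      C <- ncol(dist)
      score <- 1 - dist[, C]
      sel <- which(score >= keep_threshold)
      sel <- sort(head(sel[order(-score[sel])], top_k))
      if (length(sel)) {
        s <- spans[sel, 1]; t <- spans[sel, 2]
        ov <- outer(s, t, `<=`) & outer(t, s, `>=`)
        diag(ov) <- FALSE
        A <- ov * 1
        rs <- rowSums(A)
        A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
        z <- log(pmax(dist[sel, , drop = FALSE], 1e-12))
        r_sel <- adVal(tape, fwd$r)[sel, , drop = FALSE]
        for (k in seq_len(K))
          z <- sigmoid(A %*% z %*% params$tensors$dec_Wprop +
                         r_sel %*% params$tensors$dec_Uprop)
        dist <- softmaxRows(z)
        spans <- spans[sel, , drop = FALSE]
      } else dist <- dist[0, , drop = FALSE]
    }
    pred <- baselineMentions(dist, spans, params$labels)
    m <- matchExact(pred, pre$doc@mentions)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  rep <- evalReport(tp, fp, fn)
  list(precision = rep@precision, recall = rep@recall, f1 = rep@f1)
}

#' Write a training log as JSON-lines
#' @param log data.frame from \code{\link{trainModel}}.
#' @param path output path.
#' @export
writeTrainLog <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}
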