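#' @include schema.R autodiff.R
NULL

#' Span encoder configuration
#'
#' Collects every tunable dimension and switch of the span encoder. The
#' \code{"tiny"} backend is a seeded, from-scratch token embedding plus a
#' small multi-head self-attention stack living entirely in this package; the
#' \code{"pretrained"} backend is an adapter contract (see
#' \code{\link{encodeTokens}}) for plugging in an external subword encoder.
#'
#' @param hidden_dim token representation width \eqn{d}.
#' @param max_span_len maximum candidate span width \eqn{L_{max}} in tokens.
#' @param length_embed_dim width of the learned span-length embedding
#'   \eqn{\psi}; defaults to \code{hidden_dim}.
#' @param token_sim_threshold threshold in (0,1) on the sigmoid bilinear token
#'   similarity above which token-graph edges are created.
#' @param n_encoder_layers self-attention layers in the tiny backend (0 gives
#'   pure position-plus-embedding lookup, i.e. context window 0).
#' @param n_heads attention heads in the tiny backend.
#' @param n_self_attention_layers span-level self-attention layers.
#' @param n_structural_layers structural (span-graph) attention layers.
#' @param dropout dropout rate in [0,1), applied only during training.
#' @param use_length_embed include the length channel (the 4-channel
#'   aggregation ablation sets this FALSE).
#' @param use_token_graph apply token-graph augmentation before aggregation.
#' @param adjacency_max_gap token gap up to which two spans count as adjacent
#'   in the span graph (0 = strict abutment).
#' @param vocab_size hashed vocabulary size of the tiny backend.
#' @param max_seq_len positional embedding capacity.
#' @param backend \code{"tiny"} or \code{"pretrained"}.
#' @param pretrained_fun for the pretrained backend: a function taking an
#'   \code{AnnotatedDocument} and returning \code{list(subword = matrix,
#'   word_index = integer)} mapping each subword row to its word token.
#' @param seed integer seed for parameter initialisation.
#' @return a validated list of class \code{"EncoderConfig"}.
#' @export
encoderConfig <- function(hidden_dim = 64L, max_span_len = 5L,
                          length_embed_dim = hidden_dim,
                          token_sim_threshold = 0.7,
                          n_encoder_layers = 2L, n_heads = 2L,
                          n_self_attention_layers = 1L,
                          n_structural_layers = 1L, dropout = 0.1,
                          use_length_embed = TRUE, use_token_graph = TRUE,
                          adjacency_max_gap = 0L, vocab_size = 4096L,
                          max_seq_len = 512L,
                          backend = c("tiny", "pretrained"),
                          pretrained_fun = NULL, seed = 42L) {
  backend <- match.arg(backend)
  stopifnot(hidden_dim > 0, max_span_len > 0, length_embed_dim > 0,
            token_sim_threshold > 0, token_sim_threshold < 1,
            n_encoder_layers >= 0, n_heads > 0, hidden_dim %% n_heads == 0,
            n_self_attention_layers >= 0, n_structural_layers >= 0,
            dropout >= 0, dropout < 1, vocab_size > 0, max_seq_len > 0)
  structure(list(
    hidden_dim = as.integer(hidden_dim), max_span_len = as.integer(max_span_len),
    length_embed_dim = as.integer(length_embed_dim),
    token_sim_threshold = token_sim_threshold,
    n_encoder_layers = as.integer(n_encoder_layers),
    n_heads = as.integer(n_heads),
    n_self_attention_layers = as.integer(n_self_attention_layers),
    n_structural_layers = as.integer(n_structural_layers),
    dropout = dropout, use_length_embed = use_length_embed,
    use_token_graph = use_token_graph,
    adjacency_max_gap = as.integer(adjacency_max_gap),
    vocab_size = as.integer(vocab_size), max_seq_len = as.integer(max_seq_len),
    backend = backend, pretrained_fun = pretrained_fun,
    seed = as.integer(seed)), class = "EncoderConfig")
}

## span representation width
reprDim <- function(config) {
  4L * config$hidden_dim +
    if (config$use_length_embed) config$length_embed_dim else 0L
}

schemaFingerprint <- function(schema) {
  configHash(list(schema@types$id, schema@types$parent))
}

## distance buckets for the span self-attention positional bias
PHI_DIST_BREAKS <- c(0, 1, 2, 4, 8, Inf)   # |s_i - s_j| <= break -> bucket
PHI_N_DIST <- 6L
PHI_N_DEPTH <- 5L                          # depth difference clipped to [-2, 2]

phiIndex <- function(starts, depths) {
  n <- length(starts)
  dist <- abs(outer(starts, starts, `-`))
  bucket <- matrix(findInterval(dist, c(1, 2, 3, 5, 9)) + 1L, n, n)
  dd <- outer(depths, depths, `-`)
  dd <- pmin(pmax(dd, -2L), 2L) + 3L
  bucket + (dd - 1L) * PHI_N_DIST
}

## nesting depth of each span among the enumerated candidates: number of
## candidate spans strictly containing it
spanDepths <- function(spans) {
  n <- nrow(spans)
  vapply(seq_len(n), function(i) {
    sum(spans[, 1] <= spans[i, 1] & spans[i, 2] <= spans[, 2] &
          !(spans[, 1] == spans[i, 1] & spans[, 2] == spans[i, 2]))
  }, integer(1))
}

#' Initialise model parameters
#'
#' All trainable tensors of the encoder, the training objectives and the
#' decoder refinement stages, drawn from a seeded normal with small scale;
#' layer-norm gains start at 1 and shifts at 0. The returned object carries
#' the configuration and a schema fingerprint so that checkpoints cannot be
#' silently loaded against a different label inventory.
#'
#' @param config an \code{\link{encoderConfig}}.
#' @param schema the run's \code{TypeSchema}.
#' @return a named list of parameter matrices of class \code{"ModelParams"}.
#' @export
initParams <- function(config, schema) {
  d <- config$hidden_dim
  Dr <- reprDim(config)
  K <- length(typeLabels(schema))
  C <- K + 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(config$seed, "init"))
  rn <- function(nr, nc, scale = 0.05) matrix(rnorm(nr * nc, sd = scale), nr, nc)
  ones <- function(nc) matrix(1, 1L, nc)
  zeros <- function(nc) matrix(0, 1L, nc)
  p <- list(
    emb = rn(config$vocab_size, d, 0.3),
    pos = rn(config$max_seq_len, d, 0.05),
    W_tok = rn(d, d),
    W_len = rn(config$max_span_len, config$length_embed_dim, 0.3),
    b_len = zeros(config$length_embed_dim),
    W_g = rn(Dr, Dr, 0.02), b_g = zeros(Dr),
    W_a = rn(Dr, Dr, 0.02),
    struct_W1 = rn(Dr, Dr, 0.02), struct_b1 = zeros(Dr),
    struct_W2 = rn(Dr, Dr, 0.02), struct_b2 = zeros(Dr),
    struct_ln_g = ones(Dr), struct_ln_b = zeros(Dr),
    sa_Wq = rn(Dr, Dr, 0.02), sa_Wk = rn(Dr, Dr, 0.02),
    sa_Wv = rn(Dr, Dr, 0.02), sa_Wo = rn(Dr, Dr, 0.02),
    sa_phi = matrix(0, PHI_N_DIST, PHI_N_DEPTH),
    sa_ln_g = ones(Dr), sa_ln_b = zeros(Dr),
    cls_W = rn(Dr, C, 0.1), cls_b = zeros(C),
    dec_Wsim = rn(Dr, Dr, 0.02),
    dec_Wprop = rn(C, C, 0.1), dec_Uprop = rn(Dr, C, 0.1),
    ont_W = rn(Dr, K, 0.1)
  )
  for (l in seq_len(config$n_encoder_layers)) {
    p[[sprintf("enc%d_Wq", l)]] <- rn(d, d)
    p[[sprintf("enc%d_Wk", l)]] <- rn(d, d)
    p[[sprintf("enc%d_Wv", l)]] <- rn(d, d)
    p[[sprintf("enc%d_Wo", l)]] <- rn(d, d)
    p[[sprintf("enc%d_ln1_g", l)]] <- ones(d)
    p[[sprintf("enc%d_ln1_b", l)]] <- zeros(d)
    p[[sprintf("enc%d_ffn_W1", l)]] <- rn(d, 2L * d)
    p[[sprintf("enc%d_ffn_b1", l)]] <- zeros(2L * d)
    p[[sprintf("enc%d_ffn_W2", l)]] <- rn(2L * d, d)
    p[[sprintf("enc%d_ffn_b2", l)]] <- zeros(d)
    p[[sprintf("enc%d_ln2_g", l)]] <- ones(d)
    p[[sprintf("enc%d_ln2_b", l)]] <- zeros(d)
  }
  structure(list(tensors = p, config = config,
                 schema_fingerprint = schemaFingerprint(schema),
                 labels = typeLabels(schema)),
            class = "ModelParams")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Save model parameters to a versioned text checkpoint
#'
#' Tensors are serialized with 17 significant digits, which round-trips IEEE
#' doubles bit-exactly through \code{\link{loadCheckpoint}}.
#'
#' @param params a \code{ModelParams}.
#' @param path output path.
#' @export
saveCheckpoint <- function(params, path) {
  obj <- list(
    format = "nestNER-checkpoint", version = 1L,
    schema_fingerprint = params$schema_fingerprint,
    labels = params$labels,
    config = params$config[setdiff(names(params$config), "pretrained_fun")],
    tensors = lapply(params$tensors, function(m)
      list(dim = dim(m), values = sprintf("%.17g", as.vector(m))))
  )
  writeJSONStable(obj, path)
}

#' Load model parameters from a checkpoint
#'
#' @param path checkpoint path.
#' @param schema the run's \code{TypeSchema}; loading against a schema whose
#'   fingerprint differs from the one embedded at save time is an error.
#' @return a \code{ModelParams}.
#' @export
loadCheckpoint <- function(path, schema) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path), error = function(e)
    stopf("corrupt checkpoint %s: %s", path, conditionMessage(e)))
  if (!identical(obj$format, "nestNER-checkpoint"))
    stopf("corrupt checkpoint %s: unrecognized format", path)
  if (!identical(obj$schema_fingerprint, schemaFingerprint(schema)))
    stopf("checkpoint %s was saved for a different schema (fingerprint %s)",
          path, obj$schema_fingerprint)
  cfgl <- obj$config
  cfgl$backend <- cfgl$backend %||% "tiny"
  cfg <- do.call(encoderConfig, cfgl[intersect(names(cfgl),
                                               names(formals(encoderConfig)))])
  tensors <- lapply(obj$tensors, function(t)
    matrix(as.numeric(unlist(t$values)), unlist(t$dim)[1], unlist(t$dim)[2]))
  structure(list(tensors = tensors, config = cfg,
                 schema_fingerprint = obj$schema_fingerprint,
                 labels = as.character(unlist(obj$labels))),
            class = "ModelParams")
}
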