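test_that("span enumeration matches the closed-form count and ordering", {
  expect_identical(nrow(enumerateSpans(5, 2)), 9L)
  expect_identical(nrow(enumerateSpans(3, 5)), 6L)
  expect_identical(enumerateSpans(1, 1), cbind(s = 1L, t = 1L))
  for (T_ in c(1, 2, 7, 23, 50)) for (L in c(1, 3, 10)) {
    sp <- enumerateSpans(T_, L)
    closed <- sum(T_ - seq_len(min(L, T_)) + 1)
    expect_identical(nrow(sp), as.integer(closed))
    expect_true(all(sp[, 1] <= sp[, 2]))
    expect_true(all(sp[, 2] - sp[, 1] + 1 <= L))
    expect_false(is.unsorted(sp[, 1]))
  }
  expect_error(enumerateSpans(0, 1), ">= 1")
})

test_that("token encoding is deterministic with local context control", {
  cfg <- tiny_encoder_config()
  params <- initParams(cfg, toy_schema)
  doc1 <- annotatedDocument("a", "x")
  H <- encodeTokens(doc1, params, cfg)
  expect_identical(dim(H), c(1L, cfg$hidden_dim))
  expect_identical(H, encodeTokens(doc1, params, cfg))
  ## with zero attention layers each row depends only on its own token
  cfg0 <- tiny_encoder_config(n_encoder_layers = 0L)
  p0 <- initParams(cfg0, toy_schema)
  a <- encodeTokens(annotatedDocument("a", "one two three four"), p0, cfg0)
  b <- encodeTokens(annotatedDocument("b", "one two OTHER four"), p0, cfg0)
  expect_identical(a[1:2, ], b[1:2, ])
  expect_identical(a[4, ], b[4, ])
  expect_error(encodeTokens(annotatedDocument("e", ""), params, cfg),
               "no tokens")
})

test_that("the pretrained backend is an explicit adapter contract", {
  cfg <- tiny_encoder_config(backend = "pretrained")
  params <- initParams(cfg, toy_schema)
  expect_error(encodeTokens(tiny_doc(), params, cfg), "adapter")
  ## first-subword pooling through a fake adapter
  fake <- function(doc) {
    T_ <- nTokens(doc)
    sub <- matrix(rep(seq_len(T_), each = 2), ncol = 1)[, rep(1, 8)]
    list(subword = sub * 1.0, word_index = rep(seq_len(T_), each = 2))
  }
  cfg2 <- tiny_encoder_config(backend = "pretrained", pretrained_fun = fake)
  H <- encodeTokens(tiny_doc("a b c"), params, cfg2)
  expect_identical(H[, 1], c(1, 2, 3))
})

test_that("token similarity graph thresholds a sigmoid bilinear score", {
  H <- matrix(rnorm(12), 4, 3)
  g <- tokenSimilarityGraph(H, matrix(0, 3, 3), 0.6)
  expect_true(all(g$sim == 0.5))
  expect_false(any(g$adj))
  g2 <- tokenSimilarityGraph(H, matrix(0, 3, 3), 0.4)
  expect_true(all(g2$adj[upper.tri(g2$adj)]))   # complete minus self-loops
  expect_false(any(diag(g2$adj)))
  Wsym <- crossprod(matrix(rnorm(9), 3, 3))
  gs <- tokenSimilarityGraph(H, Wsym, 0.5)
  expect_equal(gs$sim, t(gs$sim))
})

test_that("graph augmentation mixes neighbors by softmax of similarity", {
  H <- matrix(rnorm(15), 5, 3)
  empty <- list(sim = matrix(0, 5, 5), adj = matrix(FALSE, 5, 5))
  expect_identical(graphAugmentTokens(H, empty), H)
  ## single neighbor: h1 becomes h1 + h2 exactly
  adj <- matrix(FALSE, 5, 5); adj[1, 2] <- TRUE
  one <- list(sim = matrix(0.9, 5, 5), adj = adj)
  expect_equal(graphAugmentTokens(H, one)[1, ], H[1, ] + H[2, ])
  ## two neighbors with equal similarity average equally
  adj2 <- matrix(FALSE, 5, 5); adj2[1, c(2, 3)] <- TRUE
  two <- list(sim = matrix(0.7, 5, 5), adj = adj2)
  expect_equal(graphAugmentTokens(H, two)[1, ],
               H[1, ] + 0.5 * H[2, ] + 0.5 * H[3, ])
})

test_that("multi-channel aggregation fills the documented channel layout", {
  cfg <- tiny_encoder_config()
  params <- initParams(cfg, toy_schema)
  d <- cfg$hidden_dim
  set.seed(1)
  H <- matrix(rnorm(5 * d), 5, d)
  spans <- enumerateSpans(5, 3)
  batch <- aggregateSpans(H, spans, params, cfg)
  ## single-token span: first four channels all equal h_s
  i <- which(spans[, 1] == 2 & spans[, 2] == 2)
  r <- batch@rawRepr[i, ]
  for (ch in 0:3) expect_equal(unname(r[ch * d + 1:d]), unname(H[2, ]))
  ## two-token span: mean and max channels from direct arithmetic
  i <- which(spans[, 1] == 2 & spans[, 2] == 3)
  r <- batch@rawRepr[i, ]
  expect_equal(unname(r[2 * d + 1:d]), unname((H[2, ] + H[3, ]) / 2))
  expect_equal(unname(r[3 * d + 1:d]), unname(pmax(H[2, ], H[3, ])))
  ## length embedding appended: psi = W_len[len] + b_len
  expect_equal(unname(r[4 * d + seq_len(cfg$length_embed_dim)]),
               unname(params$tensors$W_len[2, ] +
                        as.vector(params$tensors$b_len)))
  ## constant H: content channels constant across spans
  Hc <- matrix(1, 4, d)
  bc <- aggregateSpans(Hc, enumerateSpans(4, 2), params, cfg)
  expect_true(all(abs(bc@rawRepr[, 1:(4 * d)] - 1) < 1e-12))
  expect_error(aggregateSpans(H, cbind(1, 9), params, cfg), "out of range")
  ## the 4-channel ablation drops the length channel
  cfg4 <- tiny_encoder_config(use_length_embed = FALSE)
  b4 <- aggregateSpans(H, spans, initParams(cfg4, toy_schema), cfg4)
  expect_identical(ncol(b4@rawRepr), 4L * d)
})

test_that("gating squashes channels through a strict (0,1) sigmoid gate", {
  cfg <- tiny_encoder_config()
  params <- initParams(cfg, toy_schema)
  H <- matrix(rnorm(4 * cfg$hidden_dim), 4)
  batch <- aggregateSpans(H, enumerateSpans(4, 2), params, cfg)
  Dr <- ncol(batch@rawRepr)
  p0 <- params; p0$tensors$W_g <- matrix(0, Dr, Dr); p0$tensors$b_g <- matrix(0, 1, Dr)
  g0 <- gateSpans(batch, p0)
  expect_equal(g0@finalRepr, 0.5 * batch@rawRepr)
  pbig <- p0; pbig$tensors$b_g <- matrix(50, 1, Dr)
  expect_equal(gateSpans(batch, pbig)@finalRepr, batch@rawRepr,
               tolerance = 1e-12)
  zb <- batch; zb@rawRepr <- batch@rawRepr * 0
  expect_true(all(gateSpans(zb, params)@finalRepr == 0))
  g <- gateSpans(batch, params)@gate
  expect_true(all(g > 0 & g < 1))
})

test_that("span graph relations agree with a brute-force interval oracle", {
  sg <- buildSpanGraph(rbind(c(1, 4), c(2, 3)))
  expect_identical(sg@relations[1, 2], "nested")
  sg <- buildSpanGraph(rbind(c(1, 3), c(2, 5)))
  expect_identical(sg@relations[1, 2], "overlap")
  sg <- buildSpanGraph(rbind(c(1, 2), c(3, 4), c(6, 7)))
  expect_identical(sg@relations[1, 2], "adjacent")
  expect_identical(sg@relations[2, 3], "")   # gap 1 under strict abutment
  expect_identical(buildSpanGraph(rbind(c(1, 2), c(4, 5)),
                                  max_gap = 1L)@relations[1, 2], "adjacent")
  for (T_ in c(3, 5, 8)) for (L in c(2, 4)) {
    spans <- enumerateSpans(T_, L)
    rel <- buildSpanGraph(spans)@relations
    for (i in seq_len(nrow(spans))) for (j in seq_len(nrow(spans)))
      if (i != j)
        expect_identical(rel[i, j],
                         oracle_relation(spans[i, 1], spans[i, 2],
                                         spans[j, 1], spans[j, 2]))
  }
})

test_that("structural attention respects isolation, singletons and normalization", {
  cfg <- tiny_encoder_config(n_structural_layers = 1L)
  params <- initParams(cfg, toy_schema)
  H <- matrix(rnorm(6 * cfg$hidden_dim), 6)
  spans <- rbind(c(1, 2), c(4, 5))   # disjoint, non-adjacent: no edges
  batch <- gateSpans(aggregateSpans(H, spans, params, cfg), params)
  graph <- buildSpanGraph(spans)
  pz <- params
  Dr <- ncol(batch@finalRepr)
  pz$tensors$struct_W1 <- matrix(0, Dr, Dr); pz$tensors$struct_b1 <- matrix(0, 1, Dr)
  pz$tensors$struct_W2 <- matrix(0, Dr, Dr); pz$tensors$struct_b2 <- matrix(0, 1, Dr)
  out <- structuralAttention(batch, graph, pz, cfg)
  expect_equal(out$batch@structRepr,
               nestNER:::layerNormRows(batch@finalRepr,
                                       params$tensors$struct_ln_g,
                                       params$tensors$struct_ln_b))
  ## attention rows of non-isolated nodes sum to 1
  spans2 <- rbind(c(1, 3), c(2, 4), c(2, 5))
  b2 <- gateSpans(aggregateSpans(H, spans2, params, cfg), params)
  g2 <- buildSpanGraph(spans2)
  o2 <- structuralAttention(b2, g2, params, cfg)
  expect_equal(unname(rowSums(o2$graph@alpha)), rep(1, 3), tolerance = 1e-6)
})

test_that("span self-attention handles singletons and symmetric inputs", {
  cfg <- tiny_encoder_config(n_self_attention_layers = 1L,
                             n_structural_layers = 0L)
  params <- initParams(cfg, toy_schema)
  H <- matrix(rnorm(3 * cfg$hidden_dim), 3)
  one <- gateSpans(aggregateSpans(H, cbind(1L, 1L), params, cfg), params)
  out <- spanSelfAttention(one, params, cfg)
  p <- params$tensors
  manual <- nestNER:::layerNormRows(
    one@finalRepr + (one@finalRepr %*% p$sa_Wv) %*% p$sa_Wo,
    p$sa_ln_g, p$sa_ln_b)
  expect_equal(out@structRepr, manual)
  ## identical span contents + phi = 0: outputs identical across spans
  Hc <- matrix(rep(rnorm(cfg$hidden_dim), each = 4), 4)
  spans <- rbind(c(1, 1), c(2, 2), c(3, 3))
  bc <- gateSpans(aggregateSpans(Hc, spans, params, cfg), params)
  oc <- spanSelfAttention(bc, params, cfg)
  expect_equal(oc@structRepr[1, ], oc@structRepr[2, ])
  expect_equal(oc@structRepr[2, ], oc@structRepr[3, ])
})

test_that("classification yields proper distributions with NONE last", {
  cfg <- tiny_encoder_config()
  params <- initParams(cfg, toy_schema)
  doc <- tiny_doc()
  enc <- encodeSpans(doc, params, cfg)
  dist <- enc$batch@typeDist
  expect_equal(unname(rowSums(dist)), rep(1, nrow(dist)), tolerance = 1e-6)
  expect_identical(colnames(dist)[ncol(dist)], "NONE")
  ## zero classifier: uniform over |Y| + 1 classes
  pz <- params
  pz$tensors$cls_W <- params$tensors$cls_W * 0
  pz$tensors$cls_b <- params$tensors$cls_b * 0
  dz <- classifySpans(enc$batch, pz)@typeDist
  expect_true(all(abs(dz - 1 / ncol(dz)) < 1e-12))
  ## saturating the NONE bias drives NONE probability to 1
  pn <- pz
  pn$tensors$cls_b[1, ncol(dz)] <- 100
  expect_true(all(classifySpans(enc$batch, pn)@typeDist[, "NONE"] > 0.999))
})

test_that("relabeling types permutes classifier columns with no hidden order", {
  cfg <- tiny_encoder_config()
  schema_a <- typeSchema(c("CELL", "CYTOKINE", "DISEASE"))
  schema_b <- typeSchema(c("DISEASE", "CELL", "CYTOKINE"))
  pa <- initParams(cfg, schema_a)
  pb <- pa
  perm <- match(c(typeLabels(schema_b), "NONE"), c(typeLabels(schema_a), "NONE"))
  pb$tensors$cls_W <- pa$tensors$cls_W[, perm]
  pb$tensors$cls_b <- pa$tensors$cls_b[, perm, drop = FALSE]
  pb$labels <- typeLabels(schema_b)
  doc <- tiny_doc()
  da <- classifySpans(encodeSpans(doc, pa, cfg)$batch, pa)@typeDist
  db <- classifySpans(encodeSpans(doc, pb, cfg)$batch, pb)@typeDist
  expect_equal(unname(db), unname(da[, perm]))
  expect_identical(colnames(db), colnames(da)[perm])
})

test_that("pruning keeps confident spans up to top_k with stable ties", {
  labs <- c("A", "B")
  batch <- new("SpanBatch", spans = cbind(c(1L, 2L, 3L), c(1L, 2L, 3L)),
               rawRepr = matrix(0), lengthEmbed = matrix(0),
               gate = matrix(0), finalRepr = matrix(0),
               structRepr = matrix(numeric(0), 0, 0),
               typeDist = cbind(A = c(0.85, 0.3, 0.55), B = c(0.05, 0.1, 0.05),
                                NONE = c(0.1, 0.6, 0.4)),
               labels = labs)
  cs <- pruneSpans(batch, 0.5, 10)
  expect_identical(nrow(cs@spans), 2L)   # scores 0.9, 0.4, 0.6 -> keep 2
  expect_equal(cs@entityScore, c(0.9, 0.6))
  expect_identical(nrow(pruneSpans(batch, 0, 10)@spans), 3L)
  certain <- batch
  certain@typeDist <- cbind(A = c(0, 0, 0), B = c(0, 0, 0), NONE = c(1, 1, 1))
  expect_identical(nrow(pruneSpans(certain, 0.1, 10)@spans), 0L)
  expect_identical(nrow(pruneSpans(batch, 0, 1)@spans), 1L)
  expect_error(pruneSpans(batch, 0.5, 0), "top_k")
})

test_that("the full forward pass is reproducible and internally normalized", {
  cfg <- tiny_encoder_config(n_structural_layers = 1L,
                             n_self_attention_layers = 1L)
  params <- initParams(cfg, toy_schema)
  doc <- tiny_doc()
  a <- encodeSpans(doc, params, cfg)
  b <- encodeSpans(doc, params, cfg)
  expect_identical(a$batch@typeDist, b$batch@typeDist)
  expect_identical(a$batch@structRepr, b$batch@structRepr)
  expect_true(all(a$batch@gate > 0 & a$batch@gate < 1))
  expect_equal(unname(rowSums(a$batch@typeDist)),
               rep(1, nrow(a$batch@spans)), tolerance = 1e-6)
})
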