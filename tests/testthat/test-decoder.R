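## a 2-candidate set with hand-set distributions for graph/propagation tests
two_cands <- function(spans = rbind(c(1, 2), c(5, 6)),
                      pA = c(0.7, 0.6), pNONE = c(0.2, 0.3)) {
  dist <- cbind(A = pA, B = 1 - pA - pNONE, NONE = pNONE)
  makeCandidateSet(spans, dist, c("A", "B"))
}
ab_schema <- typeSchema(c("A", "B"))

test_that("decode graph connects by similarity or overlap and row-normalizes", {
  ## no representations: similarity is 0.5 < 0.7, disjoint spans: edgeless
  g <- buildDecodeGraph(two_cands(), NULL, decodeConfig())
  expect_false(any(g$edge))
  expect_true(all(g$A == 0))
  ## overlapping candidates connect regardless of similarity
  g2 <- buildDecodeGraph(two_cands(spans = rbind(c(1, 3), c(2, 5))), NULL,
                         decodeConfig())
  expect_true(g2$edge[1, 2])
  expect_equal(unname(rowSums(g2$A)), c(1, 1))
  ## low threshold connects everything
  g3 <- buildDecodeGraph(two_cands(), NULL, decodeConfig(sim_threshold = 0.4))
  expect_true(all(g3$edge[upper.tri(g3$edge)]))
})

test_that("propagation at K = 0 is the identity and otherwise renormalizes", {
  cands <- two_cands()
  g <- buildDecodeGraph(cands, NULL, decodeConfig())
  out0 <- propagateCandidates(cands, g, NULL, K = 0L)
  expect_identical(out0@refinedDist, cands@typeDist)
  ## edgeless graph, no representation term, identity mixing: uniform
  out1 <- propagateCandidates(cands, g, NULL, K = 1L)
  expect_true(all(abs(out1@refinedDist - 1 / 3) < 1e-12))
  expect_equal(unname(rowSums(out1@refinedDist)), c(1, 1))
  expect_error(propagateCandidates(cands, g, NULL, K = -1L), ">= 0")
})

test_that("sibling filtering masks confident-competitor labels", {
  ## CYTOKINE and DISEASE are siblings in the toy schema
  labs <- concrete_labels
  dist <- matrix(0.01, 1, length(labs) + 1)
  dist[1, match("DISEASE", labs)] <- 0.9
  cands <- makeCandidateSet(cbind(1, 2), dist, labs)
  out <- ontologyFilter(cands, toy_schema, 0.5)
  expect_false("CYTOKINE" %in% out@allowedLabels[[1]])   # sibling at 0.9
  expect_true("DISEASE" %in% out@allowedLabels[[1]])
  expect_true("T_CELL" %in% out@allowedLabels[[1]])      # no siblings
  ## unreachable threshold allows everything
  out1 <- ontologyFilter(cands, toy_schema, 1.0)
  expect_setequal(out1@allowedLabels[[1]], labs)
  ## schema without siblings never filters
  lonely <- typeSchema(data.frame(id = c("P", "C"), parent = c(NA, "P")))
  c2 <- makeCandidateSet(cbind(1, 1), matrix(c(0.5, 0.4, 0.1), 1), c("P", "C"))
  expect_setequal(ontologyFilter(c2, lonely, 0.3)@allowedLabels[[1]],
                  c("P", "C"))
  expect_error(ontologyFilter(cands, toy_schema, 0), "positive")
})

test_that("the allowed-label set grows monotonically in the filter threshold", {
  set.seed(12)
  for (k in 1:10) {
    inst <- random_instance(900 + k)
    prev <- NULL
    for (g in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
      out <- ontologyFilter(inst, toy_schema, g)@allowedLabels
      if (!is.null(prev))
        for (i in seq_along(out)) expect_true(all(prev[[i]] %in% out[[i]]))
      prev <- out
    }
  }
})

test_that("ontology projection aligns scores with the hierarchy", {
  cfg <- tiny_encoder_config()
  params <- initParams(cfg, chain_schema)
  pm <- projectionMatrix(chain_schema)
  Dr <- nestNER:::reprDim(cfg)
  ## uniform adapted scores through the identity-like matrix stay uniform
  pz <- params
  pz$tensors$ont_W <- matrix(0, Dr, 3)
  out <- ontologyProject(rnorm(Dr), diag(3), pz)
  expect_equal(unname(out[1, ]), rep(1 / 3, 3))
  expect_equal(sum(ontologyProject(rnorm(Dr), pm, params)), 1)
  ## chain A <- B <- C: C's row sees its own and both ancestors' mass
  r <- rnorm(Dr)
  adapted <- as.vector(r %*% params$tensors$ont_W)
  manual <- nestNER:::softmaxRows(rbind(as.vector(pm %*% adapted)))
  expect_equal(unname(ontologyProject(r, pm, params)[1, ]),
               unname(manual[1, ]))
  expect_error(ontologyProject(rnorm(Dr), diag(5), params), "match")
})

test_that("overlap penalty counts intersecting distinct pairs with exemptions", {
  sel <- data.frame(start = c(1, 4), end = c(2, 5), label = c("A", "B"))
  expect_identical(overlapPenalty(sel, ab_schema), 0L)
  sel2 <- data.frame(start = c(1, 2), end = c(3, 5), label = c("A", "B"))
  expect_identical(overlapPenalty(sel2, ab_schema), 1L)
  sel3 <- data.frame(start = c(1, 2, 3), end = c(3, 4, 5),
                     label = c("A", "B", "A"))
  expect_identical(overlapPenalty(sel3, ab_schema), 3L)
  ## schema-licensed nesting is exempt by default, counted in strict mode
  nested <- data.frame(start = c(1, 2), end = c(4, 3),
                       label = c("CELL", "T_CELL"))
  expect_identical(overlapPenalty(nested, toy_schema), 0L)
  expect_identical(overlapPenalty(nested, toy_schema, mode = "strict"), 1L)
  ## unlicensed nesting is penalized
  bad <- data.frame(start = c(1, 2), end = c(4, 3),
                    label = c("GENE", "DISEASE"))
  expect_identical(overlapPenalty(bad, toy_schema), 1L)
  ## brute-force oracle over random selections (strict mode)
  set.seed(5)
  for (k in 1:20) {
    n <- sample(2:5, 1)
    s <- sample(1:8, n, TRUE)
    sel <- data.frame(start = s, end = s + sample(0:3, n, TRUE),
                      label = sample(c("A", "B"), n, TRUE))
    manual <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sel$start[i] == sel$start[j] && sel$end[i] == sel$end[j]) next
      if (max(sel$start[i], sel$start[j]) <= min(sel$end[i], sel$end[j]))
        manual <- manual + 1L
    }
    expect_identical(overlapPenalty(sel, ab_schema, mode = "strict"), manual)
  }
})

test_that("conflict penalty fires only for related inadmissible pairs", {
  ## CYTOKINE + DISEASE is the toy schema's inadmissible pair
  ok <- data.frame(start = c(1, 5), end = c(2, 6), label = c("CELL", "GENE"))
  expect_identical(conflictPenalty(ok, toy_schema), 0L)
  far <- data.frame(start = c(1, 8), end = c(2, 9),
                    label = c("CYTOKINE", "DISEASE"))
  expect_identical(conflictPenalty(far, toy_schema), 0L)   # no relation
  nested <- data.frame(start = c(1, 2), end = c(5, 3),
                       label = c("DISEASE", "CYTOKINE"))
  expect_identical(conflictPenalty(nested, toy_schema), 1L)
  adjacent <- data.frame(start = c(1, 3), end = c(2, 4),
                         label = c("CYTOKINE", "DISEASE"))
  expect_identical(conflictPenalty(adjacent, toy_schema), 1L)
})

test_that("context reward follows the log-sum-exp form", {
  empty <- data.frame(start = integer(0), end = integer(0),
                      label = character(0))
  expect_identical(contextReward(empty, schema = toy_schema), 0)
  one <- data.frame(start = 1, end = 2, label = "CELL", alpha = 0)
  expect_equal(contextReward(one, schema = toy_schema), log(2))
  zero_eta <- typeSchema(c("A", "B"), frequency_prior = c(A = 0, B = 0))
  sel <- data.frame(start = c(1, 4), end = c(2, 5), label = c("A", "B"),
                    alpha = c(0.5, 0.9))
  expect_identical(contextReward(sel, schema = zero_eta), 0)
  ## grouped by type: two same-type spans share one log1p
  two <- data.frame(start = c(1, 4), end = c(2, 5), label = c("A", "A"),
                    alpha = c(0.2, 0.4))
  expect_equal(contextReward(two, schema = typeSchema(c("A"))),
               log1p(exp(0.2) + exp(0.4)))
})

test_that("the selection objective decomposes into its reported terms", {
  set.seed(77)
  cfg <- decodeConfig()
  for (k in 1:25) {
    inst <- random_instance(k)
    sel <- selectSpansExhaustive(inst, toy_schema, cfg)
    b <- sel@breakdown
    expect_equal(sel@objectiveValue,
                 b$score_sum - cfg$lambda1 * b$overlap_pen -
                   cfg$lambda2 * b$conflict_pen +
                   cfg$lambda3 * b$context_reward + b$nesting_reward,
                 tolerance = 1e-9)
    ## term-by-term re-evaluation with the standalone exported functions
    if (nrow(sel@chosen)) {
      chosen <- sel@chosen[, c("start", "end", "label")]
      expect_identical(b$overlap_pen, overlapPenalty(chosen, toy_schema))
      expect_identical(b$conflict_pen, conflictPenalty(chosen, toy_schema))
      expect_equal(b$context_reward,
                   contextReward(chosen, inst, toy_schema))
      margins <- nestNER:::candidateMargins(inst, cfg)
      manual <- sum(vapply(seq_len(nrow(chosen)), function(i) {
        ci <- which(inst@spans[, 1] == chosen$start[i] &
                      inst@spans[, 2] == chosen$end[i])[1]
        unname(margins[ci, chosen$label[i]])
      }, numeric(1)))
      expect_equal(b$score_sum, manual)
    }
  }
  ## empty selection scores exactly zero
  empty <- makeCandidateSet(cbind(1, 1), rbind(c(0.01, 0.01, 0.98)),
                            c("A", "B"))
  sel <- selectSpansExhaustive(empty, ab_schema, cfg)
  expect_identical(nrow(sel@chosen), 0L)
  expect_identical(sel@objectiveValue, 0)
})

test_that("exhaustive selection picks dominant atoms and respects caps", {
  cfg <- decodeConfig(lambda3 = 0)
  ## one confident candidate gets selected
  one <- makeCandidateSet(cbind(1, 2), rbind(c(0.8, 0.1, 0.1)), c("A", "B"))
  sel <- selectSpansExhaustive(one, ab_schema, cfg)
  expect_identical(sel@chosen$label, "A")
  ## same span, two labels: the higher margin wins (one label per span)
  two <- makeCandidateSet(cbind(1, 2), rbind(c(0.55, 0.35, 0.10)),
                          c("A", "B"))
  sel <- selectSpansExhaustive(two, ab_schema, cfg)
  expect_identical(nrow(sel@chosen), 1L)
  expect_identical(sel@chosen$label, "A")
  ## crossing spans under a heavy overlap penalty: keep only the stronger
  crossing <- makeCandidateSet(rbind(c(1, 3), c(2, 5)),
                               rbind(c(0.8, 0.05, 0.15),
                                     c(0.7, 0.05, 0.25)), c("A", "B"))
  sel <- selectSpansExhaustive(crossing, ab_schema,
                               decodeConfig(lambda1 = 10, lambda3 = 0))
  expect_identical(nrow(sel@chosen), 1L)
  expect_identical(unlist(sel@chosen[1, c("start", "end")],
                          use.names = FALSE), c(1L, 3L))
  expect_error(selectSpansExhaustive(random_instance(1, max_atoms = 99),
                                     toy_schema,
                                     decodeConfig(margin_mode = "literal")),
               NA)   # literal mode usually has few positive atoms
})

test_that("beam search equals the exhaustive oracle when wide enough", {
  cfg_ex <- decodeConfig()
  for (k in 1:60) {
    inst <- random_instance(k)
    n_at <- instance_atoms(inst, toy_schema, cfg_ex)
    if (n_at > 10 || n_at == 0) next
    e <- selectSpansExhaustive(inst, toy_schema, cfg_ex)
    b <- selectSpansBeam(inst, toy_schema,
                         decodeConfig(beam_width = 2^n_at))
    expect_identical(b@chosen, e@chosen, info = paste("instance", k))
    expect_equal(b@objectiveValue, e@objectiveValue)
  }
})

test_that("widening the beam never lowers the achieved objective", {
  for (k in 1:15) {
    inst <- random_instance(300 + k)
    vals <- vapply(c(1, 4, 16), function(w)
      selectSpansBeam(inst, toy_schema,
                      decodeConfig(beam_width = w))@objectiveValue,
      numeric(1))
    expect_true(all(diff(vals) >= -1e-12), info = paste("instance", k))
  }
})

test_that("decoding produces valid, schema-consistent output", {
  cfg <- tiny_encoder_config()
  params <- initParams(cfg, toy_schema)
  dcfg <- decodeConfig(prune_threshold = 0.1)
  empty <- annotatedDocument("e", "")
  expect_identical(nrow(decodeDocument(empty, params, toy_schema, cfg, dcfg)),
                   0L)
  for (seed in 1:5) {
    doc <- generateCorpus(genConfig(n_docs = 1, seed = seed),
                          toy_schema)[[1]]
    mn <- decodeDocument(doc, params, toy_schema, cfg, dcfg)
    expect_identical(anyDuplicated(paste(mn$start, mn$end)), 0L)
    expect_true(all(mn$label %in% typeLabels(toy_schema)))
    expect_true(all(mn$start <= mn$end))
    expect_true(all(mn$end <= nTokens(doc)))
  }
})

test_that("with all constraints off, decoding is the argmax-threshold baseline", {
  cfg <- tiny_encoder_config()
  params <- initParams(cfg, toy_schema)
  plain <- decodeConfig(lambda1 = 0, lambda2 = 0, lambda3 = 0,
                        use_propagation = FALSE, use_filtering = FALSE,
                        use_nesting_prior = FALSE, prune_threshold = 0.5,
                        prune_top_k = 10000L)
  for (seed in 11:14) {
    doc <- generateCorpus(genConfig(n_docs = 1, seed = seed), toy_schema)[[1]]
    enc <- encodeSpans(doc, params, cfg)
    base <- nestNER:::baselineMentions(enc$batch@typeDist, enc$batch@spans,
                                       params$labels, 0.5)
    ccd <- decodeDocument(doc, params, toy_schema, cfg, plain)
    expect_identical(ccd[, c("start", "end", "label")],
                     base[order(base$start, base$end),
                          c("start", "end", "label")])
  }
})

test_that("a heavy overlap penalty removes injected crossing false positives", {
  ## gold-like confident candidates plus a crossing distractor
  spans <- rbind(c(2, 4), c(3, 6), c(8, 9))
  dist <- rbind(c(0.85, 0.05, 0.10),   # gold A at (2,4)
                c(0.55, 0.05, 0.40),   # crossing distractor
                c(0.05, 0.80, 0.15))   # gold B at (8,9)
  cands <- makeCandidateSet(spans, dist, c("A", "B"))
  strict <- decodeConfig(lambda1 = 10, use_propagation = FALSE,
                         use_filtering = FALSE)
  out <- decodeCandidates(cands, ab_schema, strict)
  expect_identical(nrow(out), 2L)
  for (i in seq_len(nrow(out) - 1)) for (j in (i + 1):nrow(out))
    expect_identical(oracle_relation(out$start[i], out$end[i],
                                     out$start[j], out$end[j]), "")
  ## without the penalty the distractor survives
  loose <- decodeConfig(lambda1 = 0, lambda3 = 0, use_propagation = FALSE,
                        use_filtering = FALSE)
  expect_identical(nrow(decodeCandidates(cands, ab_schema, loose)), 3L)
})

test_that("decoder-only candidates round-trip through JSON", {
  inst <- random_instance(42)
  f <- withr::local_tempfile(fileext = ".json")
  obj <- list(doc_id = inst@docId, candidates = lapply(
    seq_len(nrow(inst@spans)), function(i) list(
      start = inst@spans[i, 1], end = inst@spans[i, 2],
      dist = as.list(inst@typeDist[i, ]))))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  back <- readCandidatesJSON(f, inst@labels)
  expect_equal(back@typeDist, inst@typeDist)
  expect_identical(back@spans, unname(inst@spans))
  dcfg <- decodeConfig(use_propagation = FALSE)
  expect_equal(decodeCandidates(back, toy_schema, dcfg),
               decodeCandidates(inst, toy_schema, dcfg))
})
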