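## Shared fixtures: all built in code, no stored data.

toy_schema <- makeToySchema()
concrete_labels <- setdiff(typeLabels(toy_schema), "ENTITY")

## a small schema with a 3-type chain for hierarchy tests
chain_schema <- typeSchema(data.frame(
  id = c("A", "B", "C"), name = c("A", "B", "C"),
  parent = c(NA, "A", "B"), stringsAsFactors = FALSE))

flat_schema <- typeSchema(c("CELL", "CYTOKINE", "DISEASE"))

tiny_encoder_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_dim = 8L, length_embed_dim = 4L, n_encoder_layers = 1L,
         n_heads = 2L, vocab_size = 256L, dropout = 0, seed = 11L),
    list(...))
  do.call(encoderConfig, args)
}

tiny_doc <- function(text = "CD4+ T cell activation in lupus patients") {
  annotatedDocument("t1", text)
}

## random decoder instance with at most `max_atoms` (candidate, label) atoms;
## distributions are peaked so one or two labels carry positive margin
random_instance <- function(seed, max_atoms = 10L, schema = toy_schema) {
  set.seed(seed)
  labs <- setdiff(typeLabels(schema), "ENTITY")
  n_cand <- sample(2:min(6L, max_atoms), 1L)
  ## distinct candidate spans (a candidate set has one entry per span)
  pool <- expand.grid(s = 1:10, l = 0:3)
  pick <- pool[sample.int(nrow(pool), n_cand), ]
  spans <- cbind(pick$s, pick$s + pick$l)
  dist <- NULL
  for (i in seq_len(n_cand)) {
    p <- rep(0.02, length(labs) + 1L)
    hot <- sample(seq_along(labs), sample(1:2, 1L))
    p[hot] <- runif(length(hot), 0.3, 0.8)
    p[length(labs) + 1L] <- runif(1, 0.05, 0.4)
    dist <- rbind(dist, p / sum(p))
  }
  makeCandidateSet(spans, dist, labs, doc_id = sprintf("inst%d", seed))
}

## count atoms the decoder would build for an instance
instance_atoms <- function(cands, schema, config) {
  nestNER:::buildAtoms(cands, schema, config)$n
}

## brute-force interval relation, written independently of the package logic
oracle_relation <- function(si, ti, sj, tj, max_gap = 0L) {
  if (si == sj && ti == tj) return("")
  inner_i <- sj <= si && ti <= tj
  inner_j <- si <= sj && tj <= ti
  if (inner_i || inner_j) return("nested")
  if (max(si, sj) <= min(ti, tj)) return("overlap")
  gap <- max(si - tj, sj - ti) - 1L
  if (gap >= 0 && gap <= max_gap) return("adjacent")
  ""
}
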