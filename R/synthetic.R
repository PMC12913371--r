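#' @include corpus.R schema.R
NULL

#' Synthetic corpus generator configuration
#'
#' Controls a seeded generator of immunology-flavored documents with
#' template-based entity mentions (1-5 tokens), optional gold nested inner
#' mentions, context-cued ambiguous surface forms and label-noise corruption
#' standing in for weak supervision.
#'
#' @param n_docs number of documents.
#' @param sent_len_range (min, max) tokens per document; min >= 3.
#' @param mention_rate expected mentions per 10 tokens.
#' @param nest_rate probability that a nestable mention emits its inner span
#'   as gold.
#' @param ambiguity_rate probability a mention uses a type-ambiguous surface
#'   form (disambiguated by a context cue within 2 tokens).
#' @param label_noise_rate probability a gold label is corrupted (flip to a
#'   sibling or drop), applied by \code{\link{corruptLabels}}.
#' @param seed integer seed; corpora are byte-identical for identical
#'   (config, seed).
#' @return a list of class \code{"GenConfig"}.
#' @export
genConfig <- function(n_docs = 100L, sent_len_range = c(15L, 30L),
                      mention_rate = 1.5, nest_rate = 0.3,
                      ambiguity_rate = 0.2, label_noise_rate = 0,
                      seed = 42L) {
  stopifnot(n_docs >= 1, length(sent_len_range) == 2,
            sent_len_range[1] >= 3, sent_len_range[1] <= sent_len_range[2],
            mention_rate >= 0, nest_rate >= 0, nest_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            label_noise_rate >= 0, label_noise_rate <= 1)
  structure(list(n_docs = as.integer(n_docs),
                 sent_len_range = as.integer(sent_len_range),
                 mention_rate = mention_rate, nest_rate = nest_rate,
                 ambiguity_rate = ambiguity_rate,
                 label_noise_rate = label_noise_rate,
                 seed = as.integer(seed)), class = "GenConfig")
}

#' The fixed toy immunology schema
#'
#' Five concrete types under an abstract ENTITY root: CELL (with child
#' T_CELL), CYTOKINE, DISEASE and GENE. All cross-type co-occurrences are
#' admissible except the deliberately inadmissible pair
#' \{CYTOKINE, DISEASE\} (used by conflict tests); the nesting prior
#' licenses T_CELL inside CELL and CELL inside CELL; frequency priors are
#' uniform.
#'
#' @return a \code{TypeSchema}.
#' @export
makeToySchema <- function() {
  types <- data.frame(
    id = c("ENTITY", "CELL", "T_CELL", "CYTOKINE", "DISEASE", "GENE"),
    name = c("Entity", "Immune cell", "T cell", "Cytokine", "Disease", "Gene"),
    parent = c(NA, "ENTITY", "CELL", "ENTITY", "ENTITY", "ENTITY"),
    stringsAsFactors = FALSE)
  concrete <- c("CELL", "T_CELL", "CYTOKINE", "DISEASE", "GENE")
  pairs <- list()
  for (i in seq_along(concrete)) for (j in seq_along(concrete)) {
    if (i > j) next
    p <- sort(c(concrete[i], concrete[j]))
    if (identical(p, c("CYTOKINE", "DISEASE"))) next
    pairs[[length(pairs) + 1L]] <- p
  }
  typeSchema(types, pairs,
             nesting_prior = c("T_CELL|CELL" = 0.5, "CELL|CELL" = 0.3),
             frequency_prior = setNames(rep(1, length(concrete)), concrete))
}

## mention templates; "@" marks the inner T_CELL sub-span of CELL templates
synTemplates <- function() {
  list(
    CELL = list(
      list(tokens = c("CD4+", "T", "cell"), inner = c(2L, 3L)),
      list(tokens = c("CD8+", "T", "cell"), inner = c(2L, 3L)),
      list(tokens = c("regulatory", "T", "cell"), inner = c(2L, 3L)),
      list(tokens = c("natural", "killer", "cell"), inner = NULL),
      list(tokens = c("dendritic", "cell"), inner = NULL),
      list(tokens = c("B", "cell"), inner = NULL),
      list(tokens = c("memory", "helper", "T", "cell", "subset"),
           inner = c(3L, 4L))),
    CYTOKINE = list(
      list(tokens = c("IL-2"), inner = NULL),
      list(tokens = c("IL-6"), inner = NULL),
      list(tokens = c("interferon", "gamma"), inner = NULL),
      list(tokens = c("tumor", "necrosis", "factor", "alpha"), inner = NULL),
      list(tokens = c("TGF", "beta"), inner = NULL)),
    DISEASE = list(
      list(tokens = c("lupus"), inner = NULL),
      list(tokens = c("rheumatoid", "arthritis"), inner = NULL),
      list(tokens = c("psoriasis"), inner = NULL),
      list(tokens = c("multiple", "sclerosis"), inner = NULL),
      list(tokens = c("type", "1", "diabetes"), inner = NULL),
      list(tokens = c("inflammatory", "bowel", "disease"), inner = NULL)),
    GENE = list(
      list(tokens = c("FOXP3"), inner = NULL),
      list(tokens = c("CTLA-4"), inner = NULL),
      list(tokens = c("HLA-B27"), inner = NULL),
      list(tokens = c("STAT3"), inner = NULL),
      list(tokens = c("IL2RA"), inner = NULL))
  )
}

## surfaces shared between GENE and CYTOKINE; the cue token placed right
## after the mention resolves the type deterministically
synAmbiguous <- function() {
  list(surfaces = list(c("TNF"), c("LTA")),
       cues = c(GENE = "locus", CYTOKINE = "signaling"))
}

synFiller <- function() {
  c("the", "of", "in", "patients", "with", "expression", "levels", "was",
    "were", "increased", "decreased", "observed", "response", "analysis",
    "showed", "significant", "activation", "during", "chronic", "serum",
    "a", "study", "compared", "to", "baseline", "after", "treatment",
    "measured", "samples", "and")
}

MENTION_TYPES <- c("CELL", "CYTOKINE", "DISEASE", "GENE")

#' Generate a synthetic annotated corpus
#'
#' Documents are assembled from a filler vocabulary with mentions inserted
#' from per-type template lists. The per-document mention count is
#' binomial: \code{Binomial(L, mention_rate/10)} over the target length
#' \code{L}, so the expected count is \code{L * mention_rate / 10}. Gold
#' mentions never cross (nesting only): CELL templates containing a T-cell
#' sub-phrase emit it as a gold inner T_CELL mention with probability
#' \code{nest_rate}; GENE and CYTOKINE mentions use a shared ambiguous
#' surface with probability \code{ambiguity_rate}, disambiguated by a
#' deterministic cue token placed directly after the mention. The
#' \code{"manifest"} attribute records realized counts.
#'
#' @param config a \code{\link{genConfig}}.
#' @param schema the \code{TypeSchema} (defaults to
#'   \code{\link{makeToySchema}}).
#' @return list of \code{AnnotatedDocument} with a manifest attribute.
#' @export
generateCorpus <- function(config, schema = makeToySchema()) {
  tmpl <- synTemplates()
  amb <- synAmbiguous()
  filler <- synFiller()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(config$seed, "corpus"))
  docs <- vector("list", config$n_docs)
  counts <- setNames(rep(0L, length(c(MENTION_TYPES, "T_CELL"))),
                     c(MENTION_TYPES, "T_CELL"))
  nested_pairs <- 0L; ambiguous <- 0L
  for (d in seq_len(config$n_docs)) {
    lens <- config$sent_len_range[1]:config$sent_len_range[2]
    L <- lens[sample.int(length(lens), 1L)]
    m <- rbinom(1L, L, min(config$mention_rate / 10, 1))
    pieces <- list()   # each: list(tokens, label | NA, inner)
    for (k in seq_len(m)) {
      ty <- sample(MENTION_TYPES, 1L)
      use_amb <- ty %in% c("GENE", "CYTOKINE") &&
        runif(1) < config$ambiguity_rate
      if (use_amb) {
        surf <- amb$surfaces[[sample.int(length(amb$surfaces), 1L)]]
        pieces[[length(pieces) + 1L]] <-
          list(tokens = surf, label = ty, inner = NULL,
               cue = amb$cues[[ty]])
        ambiguous <- ambiguous + 1L
      } else {
        tp <- tmpl[[ty]][[sample.int(length(tmpl[[ty]]), 1L)]]
        emit_inner <- !is.null(tp$inner) && runif(1) < config$nest_rate
        pieces[[length(pieces) + 1L]] <-
          list(tokens = tp$tokens, label = ty,
               inner = if (emit_inner) tp$inner else NULL, cue = NULL)
      }
    }
    mention_tokens <- sum(vapply(pieces, function(p)
      length(p$tokens) + !is.null(p$cue), integer(1)))
    n_fill <- max(L - mention_tokens, length(pieces))
    if (m > 0 && n_fill < 1)
      stopf("mention_rate %.2f forces more mention tokens than sentence length %d",
            config$mention_rate, L)
    fill_tokens <- sample(filler, n_fill, replace = TRUE)
    slots <- sort(sample.int(n_fill, length(pieces)))
    toks <- character(0)
    ments <- list()
    pi <- 1L; prev <- 0L
    for (sl in seq_along(slots)) {
      toks <- c(toks, fill_tokens[(prev + 1L):slots[sl]])
      prev <- slots[sl]
      p <- pieces[[pi]]; pi <- pi + 1L
      s <- length(toks) + 1L
      toks <- c(toks, p$tokens)
      e <- length(toks)
      ments[[length(ments) + 1L]] <- data.frame(
        start = s, end = e, label = p$label, stringsAsFactors = FALSE)
      counts[p$label] <- counts[p$label] + 1L
      if (!is.null(p$inner)) {
        ments[[length(ments) + 1L]] <- data.frame(
          start = s + p$inner[1] - 1L, end = s + p$inner[2] - 1L,
          label = "T_CELL", stringsAsFactors = FALSE)
        counts["T_CELL"] <- counts["T_CELL"] + 1L
        nested_pairs <- nested_pairs + 1L
      }
      if (!is.null(p$cue)) toks <- c(toks, p$cue)
    }
    if (prev < n_fill) toks <- c(toks, fill_tokens[(prev + 1L):n_fill])
    text <- paste(toks, collapse = " ")
    ends <- cumsum(nchar(toks) + 1L) - 1L
    tokens <- data.frame(text = toks, char_start = ends - nchar(toks),
                         char_end = ends, stringsAsFactors = FALSE)
    docs[[d]] <- annotatedDocument(
      sprintf("syn_%04d", d), text, tokens = tokens,
      mentions = if (length(ments)) do.call(rbind, ments) else NULL)
  }
  manifest <- list(n_docs = config$n_docs,
                   mentions_per_type = as.list(counts),
                   nested_pairs = nested_pairs,
                   ambiguous_mentions = ambiguous,
                   seed = config$seed,
                   config_hash = configHash(unclass(config)))
  if (config$label_noise_rate > 0)
    docs <- corruptLabels(docs, config$label_noise_rate, schema,
                          childSeed(config$seed, "noise"))
  attr(docs, "manifest") <- manifest
  docs
}

#' Corrupt gold labels (weak-supervision stand-in)
#'
#' Each gold mention independently, with probability \code{rate}, is either
#' flipped to a uniformly random sibling type (50\%) or dropped (50\%;
#' mentions whose type has no siblings are always dropped). Pure function:
#' the input corpus is untouched; the corruption log is attached as the
#' \code{"corruption_log"} attribute.
#'
#' @param corpus list of \code{AnnotatedDocument}.
#' @param rate corruption probability in [0,1].
#' @param schema \code{TypeSchema} supplying sibling sets.
#' @param seed integer seed.
#' @return a new corpus with the corruption log attribute.
#' @export
corruptLabels <- function(corpus, rate, schema, seed = 42L) {
  stopifnot(rate >= 0, rate <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, "corrupt"))
  log <- list()
  out <- lapply(corpus, function(doc) {
    m <- doc@mentions
    if (!nrow(m)) return(doc)
    keep <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(m))) {
      if (runif(1) >= rate) next
      sibs <- siblings(schema, m$label[i])
      if (runif(1) < 0.5 && length(sibs)) {
        new_label <- sibs[sample.int(length(sibs), 1L)]
        log[[length(log) + 1L]] <<- list(doc_id = doc@docId,
                                         start = m$start[i], end = m$end[i],
                                         action = "flip",
                                         from = m$label[i], to = new_label)
        m$label[i] <- new_label
      } else {
        log[[length(log) + 1L]] <<- list(doc_id = doc@docId,
                                         start = m$start[i], end = m$end[i],
                                         action = "drop", from = m$label[i],
                                         to = NA_character_)
        keep[i] <- FALSE
      }
    }
    annotatedDocument(doc@docId, doc@text, tokens = doc@tokens,
                      mentions = m[keep, , drop = FALSE], meta = doc@meta)
  })
  attr(out, "manifest") <- attr(corpus, "manifest")
  attr(out, "corruption_log") <- log
  out
}
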