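#' @include utils.R
NULL

#' Entity type schema with hierarchy, co-occurrence and priors
#'
#' A \code{TypeSchema} holds the label inventory of a run together with the
#' knowledge used by constraint-guided decoding: a subclass hierarchy (each
#' type may name one parent), the set \eqn{C} of admissible unordered label
#' pairs that may legally co-occur in one sentence region, a nesting prior
#' \eqn{\gamma_{y,y'}} rewarding an inner mention of type \eqn{y} nested in an
#' outer mention of type \eqn{y'}, and a nonnegative frequency prior
#' \eqn{\eta_y} weighting the contextual-coherence reward.
#'
#' The reserved label \code{"NONE"} (non-entity) is never a schema type and
#' never appears in pairs or priors.
#'
#' @slot types data.frame with columns \code{id}, \code{name}, \code{parent}
#'   (\code{NA} for root types).
#' @slot admissiblePairs character matrix with two columns, one row per
#'   unordered admissible pair; a zero-row matrix with attribute
#'   \code{saturated = TRUE} means every pair is admissible.
#' @slot nestingPrior named numeric; names are \code{"inner|outer"} label
#'   pairs.
#' @slot frequencyPrior named numeric, values \eqn{\ge 0}; labels absent from
#'   it default to 1.
#' @export
setClass("TypeSchema", representation(
  types = "data.frame",
  admissiblePairs = "matrix",
  nestingPrior = "numeric",
  frequencyPrior = "numeric"
))

setValidity("TypeSchema", function(object) {
  tt <- object@types
  msg <- character(0)
  if (!all(c("id", "name", "parent") %in% names(tt)))
    return("types must have columns id, name, parent")
  ids <- tt$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate type ids")
  if (NONE_LABEL %in% ids) msg <- c(msg, "reserved label NONE used as a type")
  dangling <- setdiff(tt$parent[!is.na(tt$parent)], ids)
  if (length(dangling))
    msg <- c(msg, paste0("parent refers to unknown type: ",
                         paste(dangling, collapse = ", ")))
  cyc <- schemaFindCycle(tt)
  if (!is.null(cyc))
    msg <- c(msg, paste0("cycle in hierarchy: ", paste(cyc, collapse = " -> ")))
  refd <- c(as.vector(object@admissiblePairs),
            unlist(strsplit(names(object@nestingPrior) %||% character(0),
                            "|", fixed = TRUE)),
            names(object@frequencyPrior))
  bad <- setdiff(refd, ids)
  if (length(bad))
    msg <- c(msg, paste0("pair/prior refers to unknown label: ",
                         paste(unique(bad), collapse = ", ")))
  if (any(object@frequencyPrior < 0)) msg <- c(msg, "frequency prior < 0")
  if (length(msg)) msg else TRUE
})

schemaFindCycle <- function(tt) {
  parent <- setNames(tt$parent, tt$id)
  for (start in tt$id) {
    seen <- character(0)
    cur <- start
    while (!is.na(parent[[cur]] %||% NA_character_)) {
      if (cur %in% seen) return(c(seen[match(cur, seen):length(seen)], cur))
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (!cur %in% tt$id) break
    }
  }
  NULL
}

#' Construct a TypeSchema
#'
#' @param types data.frame with columns \code{id}, \code{name} (defaults to
#'   id), \code{parent} (NA for roots).
#' @param admissible_pairs character matrix (n x 2) or list of length-2
#'   character vectors; \code{NULL} or zero rows means all pairs admissible.
#' @param nesting_prior named numeric, names \code{"inner|outer"}.
#' @param frequency_prior named numeric, nonnegative.
#' @return a validated \code{TypeSchema}.
#' @export
typeSchema <- function(types, admissible_pairs = NULL, nesting_prior = numeric(0),
                       frequency_prior = numeric(0)) {
  if (is.character(types)) types <- data.frame(id = types)
  if (is.null(types$name)) types$name <- types$id
  if (is.null(types$parent)) types$parent <- NA_character_
  types <- data.frame(id = as.character(types$id), name = as.character(types$name),
                      parent = as.character(types$parent),
                      stringsAsFactors = FALSE)
  saturated <- is.null(admissible_pairs) || length(admissible_pairs) == 0L
  if (saturated) {
    ap <- matrix(character(0), ncol = 2)
  } else {
    if (is.list(admissible_pairs))
      admissible_pairs <- do.call(rbind, admissible_pairs)
    ap <- matrix(as.character(admissible_pairs), ncol = 2)
    ## canonical unordered storage
    ap <- t(apply(ap, 1L, sort))
    ap <- ap[!duplicated(paste(ap[, 1], ap[, 2], sep = "\r")), , drop = FALSE]
  }
  attr(ap, "saturated") <- saturated
  np <- as.numeric(nesting_prior); names(np) <- names(nesting_prior)
  fp <- as.numeric(frequency_prior); names(fp) <- names(frequency_prior)
  new("TypeSchema", types = types, admissiblePairs = ap,
      nestingPrior = np, frequencyPrior = fp)
}

#' @describeIn typeSchema the ordered label inventory (fixed documented
#'   ordering: order of declaration).
#' @param schema a \code{TypeSchema}.
#' @export
typeLabels <- function(schema) schema@types$id

setMethod("show", "TypeSchema", function(object) {
  cat(sprintf("TypeSchema with %d types: %s\n", nrow(object@types),
              paste(object@types$id, collapse = ", ")))
  sat <- isTRUE(attr(object@admissiblePairs, "saturated"))
  cat(sprintf("  admissible pairs: %s\n",
              if (sat) "all (saturated)" else nrow(object@admissiblePairs)))
  cat(sprintf("  nesting priors: %d; frequency priors: %d\n",
              length(object@nestingPrior), length(object@frequencyPrior)))
})

checkLabel <- function(schema, y) {
  if (!y %in% schema@types$id)
    stopf("unknown label '%s' (schema types: %s)", y,
          paste(schema@types$id, collapse = ", "))
  invisible(y)
}

#' Load a type schema from its JSON file
#'
#' The schema dialect is a single JSON document with top-level keys
#' \code{types} (list of \code{{id, name, parent?}}), \code{admissible_pairs}
#' (list of two-label arrays), \code{nesting_prior} (map \code{"inner|outer"}
#' to number) and \code{frequency_prior} (map label to number). Only
#' \code{types} is required.
#'
#' @param path path to the schema JSON file.
#' @return a validated \code{TypeSchema}.
#' @export
loadSchema <- function(path) {
  if (!file.exists(path)) stopf("schema file not found: %s", path)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stopf("schema parse failure in %s: %s",
                                            path, conditionMessage(e)))
  if (is.null(obj$types)) stopf("schema %s: missing required key 'types'", path)
  types <- do.call(rbind, lapply(obj$types, function(t) {
    if (is.null(t$id)) stopf("schema %s: a type entry lacks 'id'", path)
    data.frame(id = t$id, name = t$name %||% t$id,
               parent = t$parent %||% NA_character_, stringsAsFactors = FALSE)
  }))
  ap <- if (length(obj$admissible_pairs))
    lapply(obj$admissible_pairs, function(p) {
      if (length(p) != 2L)
        stopf("schema %s: admissible pair with %d labels", path, length(p))
      as.character(unlist(p))
    }) else NULL
  np <- unlist(obj$nesting_prior) %||% numeric(0)
  fp <- unlist(obj$frequency_prior) %||% numeric(0)
  typeSchema(types, ap, np, fp)
}

#' Write a schema to its JSON file (inverse of \code{loadSchema})
#' @param schema a \code{TypeSchema}.
#' @param path output path.
#' @export
writeSchema <- function(schema, path) {
  tt <- schema@types
  out <- list(
    types = lapply(seq_len(nrow(tt)), function(i) {
      t <- list(id = tt$id[i], name = tt$name[i])
      if (!is.na(tt$parent[i])) t$parent <- tt$parent[i]
      t
    }),
    nesting_prior = as.list(schema@nestingPrior),
    frequency_prior = as.list(schema@frequencyPrior)
  )
  if (!isTRUE(attr(schema@admissiblePairs, "saturated")))
    out$admissible_pairs <- apply(schema@admissiblePairs, 1L, as.list)
  writeJSONStable(out, path)
}

#' Label co-occurrence compatibility \eqn{\Psi(y, y')}
#'
#' Returns 1 if the unordered pair is admissible and \code{-Inf} otherwise.
#' Same-label pairs are always admissible; with a saturated pair set every
#' query returns 1. Symmetric in its arguments.
#'
#' @param schema a \code{TypeSchema}.
#' @param y,y2 schema labels (never \code{"NONE"}).
#' @return 1 or \code{-Inf}.
#' @export
compatibility <- function(schema, y, y2) {
  checkLabel(schema, y); checkLabel(schema, y2)
  if (isAdmissiblePair(schema, y, y2)) 1 else -Inf
}

isAdmissiblePair <- function(schema, y, y2) {
  if (y == y2) return(TRUE)
  if (isTRUE(attr(schema@admissiblePairs, "saturated"))) return(TRUE)
  p <- sort(c(y, y2))
  ap <- schema@admissiblePairs
  any(ap[, 1] == p[1] & ap[, 2] == p[2])
}

#' Strict ancestor test on the type hierarchy
#'
#' \code{TRUE} iff \code{ancestor} is reachable from \code{descendant} by one
#' or more parent links; a type is never its own ancestor.
#'
#' @param schema a \code{TypeSchema}.
#' @param ancestor,descendant schema labels.
#' @return logical scalar.
#' @export
isAncestor <- function(schema, ancestor, descendant) {
  checkLabel(schema, ancestor); checkLabel(schema, descendant)
  parent <- setNames(schema@types$parent, schema@types$id)
  cur <- parent[[descendant]]
  while (!is.na(cur)) {
    if (cur == ancestor) return(TRUE)
    cur <- parent[[cur]]
  }
  FALSE
}

#' Sibling types (same parent; root types share a virtual root)
#'
#' @param schema a \code{TypeSchema}.
#' @param y a schema label.
#' @return character vector of sibling labels (never contains \code{y}).
#' @export
siblings <- function(schema, y) {
  checkLabel(schema, y)
  tt <- schema@types
  p <- tt$parent[match(y, tt$id)]
  same <- if (is.na(p)) is.na(tt$parent) else !is.na(tt$parent) & tt$parent == p
  setdiff(tt$id[same], y)
}

#' Ontology projection matrix \eqn{\Omega}
#'
#' Square binary matrix over the schema's fixed label ordering with entry
#' \eqn{(i, j) = 1} iff type \eqn{y_i} is a strict descendant of \eqn{y_j};
#' the diagonal is set to 1 so projection preserves a type's own score mass
#' (a root type would otherwise project to the zero vector).
#'
#' @param schema a \code{TypeSchema}.
#' @return binary matrix with dimnames set to the label ordering.
#' @export
projectionMatrix <- function(schema) {
  ids <- typeLabels(schema)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && isAncestor(schema, ids[j], ids[i])) m[i, j] <- 1
  diag(m) <- 1
  m
}

nestingPriorOf <- function(schema, inner, outer) {
  v <- unname(schema@nestingPrior[paste(inner, outer, sep = "|")])
  if (length(v) != 1L || is.na(v)) 0 else v
}

frequencyPriorOf <- function(schema, y) {
  v <- unname(schema@frequencyPrior[y])
  if (length(v) != 1L || is.na(v)) 1 else v
}
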