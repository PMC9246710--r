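# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` on exit so seeded package internals
#' never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Counter-based substream: deterministic per-index seed derived from a base
# seed, independent of the order in which subjects are generated.
# Kept below 2^31 - 1 (R integer range).
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer(x)
}

# Canonical undirected edge matrix: 2 columns, i < j, integer indices.
as_edge_matrix <- function(edges) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must be a 2-column matrix")
  storage.mode(edges) <- "integer"
  swap <- edges[, 1] > edges[, 2]
  if (any(swap)) edges[swap, ] <- edges[swap, c(2, 1)]
  edges
}

# Map an edge matrix given as labels or indices onto integer indices of
# `labels`, validating membership.
resolve_edges <- function(edges, labels) {
  if (is.null(dim(edges)) && length(edges) == 0)
    return(matrix(integer(0), 0, 2))
  if (is.matrix(edges) && nrow(edges) == 0)
    return(matrix(integer(0), 0, 2))
  if (is.character(edges) ||
      (is.matrix(edges) && is.character(edges[1, 1]))) {
    em <- matrix(match(as.vector(as.matrix(edges)), labels),
                 ncol = 2)
    if (anyNA(em)) stop("edge endpoints not found among region labels")
    as_edge_matrix(em)
  } else {
    em <- as_edge_matrix(edges)
    if (any(em < 1L) || any(em > length(labels)))
      stop("edge index outside the node set")
    em
  }
}

# Union-find over nodes touched by `edges` (integer 2-col matrix).
# Returns an integer component id per row of `edges`.
edge_components <- function(edges) {
  n_edges <- nrow(edges)
  if (n_edges == 0L) return(integer(0))
  nodes <- sort(unique(as.vector(edges)))
  idx <- match(edges, nodes)
  dim(idx) <- dim(edges)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_len(n_edges)) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(idx[, 1], find, integer(1))
  match(roots, unique(roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
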