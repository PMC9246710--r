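# Weighted modularity, Louvain-style partitioning with restarts,
# agreement-matrix consensus community structure, node strengths and
# within-module edge proportions.

#' Partition container
#'
#' @param membership integer module id per node (made contiguous from 1).
#' @param region_labels node labels.
#' @param q_w weighted modularity of the partition (may be `NA` for
#'   degenerate graphs).
#' @return an object of class `partition`.
#' @export
partition <- function(membership, region_labels = names(membership),
                      q_w = NA_real_) {
  membership <- as.integer(factor(membership, levels = unique(membership)))
  if (is.null(region_labels))
    region_labels <- sprintf("r%03d", seq_along(membership))
  names(membership) <- region_labels
  structure(list(region_labels = region_labels, module_of = membership,
                 q_w = q_w),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes in %d modules, Q_w = %s\n",
              length(x$module_of), length(unique(x$module_of)),
              ifelse(is.na(x$q_w), "NA", format(round(x$q_w, 4)))))
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' Evaluates
#' \eqn{Q_w = \frac{1}{l(w)} \sum_{ij} \left[w_{ij} -
#'   \frac{K_i K_j}{l(w)}\right] \delta_{m_i m_j}}
#' with \eqn{l(w)} the total weight (sum over the full weight matrix, i.e.
#' twice the upper-triangle sum) and \eqn{K_i} the node strength. This is
#' standard Newman weighted modularity; it is invariant to a positive
#' rescaling of the weights.
#'
#' @param W nonnegative symmetric weight matrix (zero diagonal).
#' @param part a [partition] (or an integer membership vector).
#' @return scalar `Q_w` in `[-1, 1]`.
#' @export
modularity_value <- function(W, part) {
  W <- as.matrix(W)
  m <- if (inherits(part, "partition")) part$module_of else as.integer(part)
  if (length(m) != nrow(W)) stop("partition must cover all nodes")
  tw <- sum(W)
  if (tw <= 0) stop("modularity undefined for an all-zero weight matrix")
  K <- rowSums(W)
  delta <- outer(m, m, `==`)
  sum((W - outer(K, K) / tw) * delta) / tw
}

# One igraph Louvain pass under a random node relabelling (so distinct seeds
# explore distinct greedy orders); returns a membership vector.
louvain_once <- function(W, labels) {
  n <- nrow(W)
  perm <- sample.int(n)
  g <- igraph::graph_from_adjacency_matrix(W[perm, perm, drop = FALSE],
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- igraph::membership(igraph::cluster_louvain(g))
  out <- integer(n)
  out[perm] <- as.integer(memb)
  out
}

#' Best-of-restarts Louvain partition
#'
#' Runs greedy multi-level modularity maximisation `n_runs` times under
#' seeded random node orders and returns the run with the highest
#' [modularity_value()] (ties broken by first occurrence). An all-zero
#' matrix yields the degenerate singleton partition with `q_w = NA`.
#'
#' @param W nonnegative symmetric weight matrix.
#' @param n_runs number of restarts (default 100).
#' @param seed integer seed (deterministic result).
#' @return a [partition].
#' @export
louvain_partition <- function(W, n_runs = 100, seed = 1) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("weights must be nonnegative")
  labels <- rownames(W) %||% sprintf("r%03d", seq_len(nrow(W)))
  if (sum(W) <= 0)
    return(partition(seq_len(nrow(W)), labels, q_w = NA_real_))
  with_seed(seed, {
    best <- NULL; best_q <- -Inf
    for (run in seq_len(n_runs)) {
      memb <- louvain_once(W, labels)
      q <- modularity_value(W, memb)
      if (q > best_q + 1e-15) {
        best_q <- q; best <- memb
      }
    }
    partition(best, labels, q_w = best_q)
  })
}

#' Agreement (co-assignment) matrix of a set of partitions
#'
#' Entry (i, j) is the fraction of partitions in which nodes i and j share
#' a module; the diagonal is 1.
#'
#' @param partitions list of [partition] on a common node set.
#' @return an `agreement_matrix` (labelled matrix, entries in `[0, 1]`).
#' @export
agreement_matrix <- function(partitions) {
  if (length(partitions) < 1) stop("need at least one partition")
  labels <- partitions[[1]]$region_labels
  n <- length(labels)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  for (p in partitions) {
    if (!identical(p$region_labels, labels))
      stop("partitions must share a common node set")
    A <- A + outer(p$module_of, p$module_of, `==`)
  }
  A <- A / length(partitions)
  class(A) <- c("agreement_matrix", "matrix")
  A
}

#' Consensus partition via thresholded agreement iteration
#'
#' Builds the agreement matrix of the input partitions, zeroes entries at or
#' below `tau` (strictly-greater retention), and repeatedly re-clusters the
#' thresholded matrix with single Louvain runs until the induced agreement
#' matrix is binary (all co-assignment frequencies 0 or 1), returning the
#' stable partition. A fully disconnected thresholded matrix yields the
#' degenerate every-node-its-own-module partition.
#'
#' @param partitions list of [partition] on a common node set (>= 2).
#' @param tau agreement threshold (default 0.64: retain pairs co-assigned
#'   in more than 64% of partitions).
#' @param n_runs Louvain repetitions per consensus iteration (default 100).
#' @param seed integer seed.
#' @param max_iter iteration cap (default 50).
#' @return a [partition]; `q_w` is evaluated on the original agreement
#'   matrix.
#' @export
consensus_partition <- function(partitions, tau = 0.64, n_runs = 100,
                                seed = 1, max_iter = 50) {
  if (length(partitions) < 2) stop("need at least 2 partitions")
  A0 <- agreement_matrix(partitions)
  labels <- partitions[[1]]$region_labels
  n <- length(labels)
  A <- unclass(A0)
  final <- NULL
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      thr <- A
      # strictly-greater retention; certain co-assignment (frequency 1)
      # survives any threshold
      thr[thr <= tau & thr < 1] <- 0
      diag(thr) <- 0
      if (sum(thr) == 0) {
        final <- partition(seq_len(n), labels, q_w = NA_real_)
        break
      }
      membs <- replicate(n_runs, louvain_once(thr, labels), simplify = FALSE)
      counts <- matrix(0, n, n)
      for (m in membs) counts <- counts + outer(m, m, `==`)
      A_new <- counts / n_runs
      if (all(A_new %in% c(0, 1))) {
        final <- partition(membs[[1]], labels)
        break
      }
      A <- A_new
    }
    if (is.null(final)) {
      # cap reached: take the clustering of the last thresholded matrix
      thr <- A
      thr[thr <= tau & thr < 1] <- 0
      diag(thr) <- 0
      final <- partition(louvain_once(thr, labels), labels)
    }
  })
  q <- tryCatch(modularity_value(unclass(A0), final), error = function(e) NA_real_)
  final$q_w <- q
  final
}

#' Node strengths, optionally restricted and max-normalized
#'
#' \eqn{K_i} is the sum of retained edge weights incident to node i. When
#' `restrict_edges` is given only those edges are retained (the NBS
#' component); with `normalize = TRUE` retained weights are first divided by
#' the maximum retained weight of this matrix (per-subject normalisation),
#' so the largest retained weight becomes exactly 1.
#'
#' @param W a [connectivity_matrix] (or symmetric matrix).
#' @param restrict_edges optional 2-column edge matrix (indices or labels).
#' @param normalize divide retained weights by their maximum (default FALSE).
#' @return named numeric vector of strengths over all nodes of `W` (zero for
#'   nodes with no retained edge). An empty restriction yields a zero vector
#'   with a warning.
#' @export
node_strength <- function(W, restrict_edges = NULL, normalize = FALSE) {
  W <- as.matrix(W)
  labels <- rownames(W) %||% sprintf("r%03d", seq_len(nrow(W)))
  if (!is.null(restrict_edges)) {
    em <- resolve_edges(restrict_edges, labels)
    if (nrow(em) == 0) {
      warning("empty edge restriction; returning zero strengths")
      return(stats::setNames(numeric(nrow(W)), labels))
    }
    R <- matrix(0, nrow(W), ncol(W))
    R[em] <- W[em]
    R[em[, c(2, 1), drop = FALSE]] <- W[em]
    W <- R
  }
  if (normalize) {
    mx <- max(W)
    if (mx > 0) W <- W / mx
  }
  stats::setNames(rowSums(W), labels)
}

#' Proportion of within-module edges
#'
#' Percentage of the listed edges whose two endpoints belong to the same
#' module of `part` (e.g. the share of NBS connections that are
#' within-module under a group's consensus partition).
#'
#' @param edges 2-column edge matrix (indices or labels).
#' @param part a [partition] covering all endpoints.
#' @return scalar percentage in `[0, 100]`.
#' @export
within_module_proportion <- function(edges, part) {
  stopifnot(inherits(part, "partition"))
  em <- resolve_edges(edges, part$region_labels)
  if (nrow(em) == 0) stop("empty edge list")
  m <- part$module_of
  100 * mean(m[em[, 1]] == m[em[, 2]])
}
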