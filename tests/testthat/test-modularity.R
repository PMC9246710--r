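# Weighted modularity, Louvain restarts, consensus clustering, strengths.

two_cliques <- function() {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  W
}

test_that("two disconnected 4-cliques have Q_w = 0.5 at the clique partition", {
  W <- two_cliques()
  memb <- rep(1:2, each = 4)
  expect_equal(modularity_value(W, memb), 0.5)
  # brute force over all partitions of 8 nodes confirms optimality
  best <- max(vapply(all_partitions(8), function(m) modularity_value(W, m),
                     numeric(1)))
  expect_equal(best, 0.5, tolerance = 1e-12)
  # Louvain recovers the optimum
  p <- louvain_partition(W, n_runs = 10, seed = 1)
  expect_equal(p$q_w, 0.5)
  expect_equal(length(unique(p$module_of)), 2)
})

test_that("complete uniform graph in one module has Q_w = 0; Q_w is scale-free", {
  W <- matrix(0.3, 5, 5); diag(W) <- 0
  expect_equal(modularity_value(W, rep(1, 5)), 0, tolerance = 1e-12)
  set.seed(2)
  for (k in 1:10) {
    W <- unclass(random_connectivity(6))
    m <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_value(W, m), modularity_value(W * 7.3, m),
                 tolerance = 1e-12)
  }
  expect_error(modularity_value(matrix(0, 4, 4), rep(1, 4)), "all-zero")
})

test_that("modularity_value matches the double-loop oracle on random graphs", {
  set.seed(3)
  for (k in 1:100) {
    n <- sample(4:8, 1)
    W <- unclass(random_connectivity(n))
    m <- sample(seq_len(sample(2:4, 1)), n, replace = TRUE)
    expect_equal(modularity_value(W, m), oracle_modularity(W, m),
                 tolerance = 1e-12)
    # igraph as an independent cross-check
    g <- igraph::graph_from_adjacency_matrix(W, "undirected", weighted = TRUE)
    expect_equal(modularity_value(W, m),
                 igraph::modularity(g, m, weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
  }
})

test_that("Louvain attains the exhaustive optimum on small graphs", {
  set.seed(4)
  hits <- 0; n_fix <- 60
  parts6 <- all_partitions(6)
  for (k in seq_len(n_fix)) {
    W <- unclass(random_connectivity(6, lo = 0, hi = 1))
    W[W < 0.45] <- 0  # sparsify so real module structure exists
    if (sum(W) == 0) W[1, 2] <- W[2, 1] <- 0.5
    best <- max(vapply(parts6, function(m) modularity_value(W, m), numeric(1)))
    p <- louvain_partition(W, n_runs = 40, seed = k)
    expect_gte(p$q_w + 1e-9,
               modularity_value(W, rep(1, 6)))  # never below one-module
    if (abs(p$q_w - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_fix, 0.95)
})

test_that("Louvain is deterministic given a seed", {
  W <- unclass(random_connectivity(12))
  p1 <- louvain_partition(W, n_runs = 5, seed = 42)
  p2 <- louvain_partition(W, n_runs = 5, seed = 42)
  expect_identical(p1, p2)
})

test_that("agreement matrix counts co-assignments exactly", {
  labs <- letters[1:4]
  ps <- list(partition(c(1, 1, 2, 2), labs), partition(c(1, 1, 2, 2), labs),
             partition(c(1, 1, 1, 2), labs), partition(c(1, 2, 2, 2), labs))
  A <- agreement_matrix(ps)
  expect_equal(A["a", "b"], 3 / 4)  # co-assigned in 3 of 4, survives tau 0.64
  expect_equal(A["a", "c"], 1 / 4)
  expect_equal(A["c", "d"], 3 / 4)
  expect_equal(diag(unclass(A)), setNames(rep(1, 4), labs))
  expect_gt(A["a", "b"], 0.64)
})

test_that("consensus of identical partitions is that partition; idempotent", {
  labs <- sprintf("r%02d", 1:9)
  base <- partition(rep(1:3, each = 3), labs)
  cons <- consensus_partition(rep(list(base), 5), seed = 1, n_runs = 10)
  expect_equal(unname(cons$module_of[base$module_of == 1]),
               rep(cons$module_of[[1]], 3))
  # same grouping structure as the input
  expect_equal(outer(cons$module_of, cons$module_of, "=="),
               outer(base$module_of, base$module_of, "=="))
  again <- consensus_partition(rep(list(cons), 5), seed = 2, n_runs = 10)
  expect_equal(outer(again$module_of, again$module_of, "=="),
               outer(cons$module_of, cons$module_of, "=="))
})

test_that("tau = 1 keeps only always-co-assigned pairs; disconnection degrades gracefully", {
  labs <- letters[1:4]
  ps <- list(partition(c(1, 1, 2, 2), labs), partition(c(1, 1, 1, 2), labs))
  cons <- consensus_partition(ps, tau = 1, seed = 3, n_runs = 10)
  # only {a, b} always together
  expect_equal(cons$module_of[["a"]], cons$module_of[["b"]])
  expect_length(unique(cons$module_of[c("c", "d")]), 2)
  # fully disagreeing partitions + high tau -> singletons
  ps2 <- list(partition(c(1, 2, 1, 2), labs), partition(c(1, 1, 2, 2), labs))
  cons2 <- consensus_partition(ps2, tau = 0.9, seed = 4, n_runs = 10)
  expect_length(unique(cons2$module_of), 4)
})

test_that("node strengths honour restriction and per-matrix max normalization", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- W["b", "a"] <- 0.2
  W["a", "c"] <- W["c", "a"] <- 0.4
  k <- node_strength(W, normalize = TRUE)
  expect_equal(unname(k["a"]), 0.5 + 1.0)  # weights / max(0.4)
  # star graph, uniform weights
  n <- 6; w <- 0.3
  S <- matrix(0, n, n); S[1, 2:n] <- S[2:n, 1] <- w
  ks <- node_strength(S)
  expect_equal(unname(ks[1]), (n - 1) * w)
  expect_equal(unname(ks[2]), w)
  # restriction: only retained edges count, max is over retained weights
  kr <- node_strength(W, restrict_edges = rbind(c("a", "b")), normalize = TRUE)
  expect_equal(unname(kr), c(1, 1, 0))
  expect_warning(kz <- node_strength(W, restrict_edges = matrix(0, 0, 2)),
                 "empty")
  expect_equal(unname(kz), rep(0, 3))
})

test_that("within-module proportion reproduces the reference percentages", {
  labs <- sprintf("r%02d", 1:20)
  part <- partition(rep(1:4, each = 5), labs)
  within <- rbind(c(1, 2), c(2, 3), c(6, 7), c(11, 12), c(16, 17))  # 5 within
  between <- cbind(seq(1, 13), seq(6, 18))                          # 13 between
  edges18 <- rbind(within, between)
  expect_equal(round(within_module_proportion(edges18, part), 2), 27.78)
  edges18b <- rbind(within[1:3, , drop = FALSE], between,
                    rbind(c(1, 6), c(2, 7)))
  expect_equal(round(within_module_proportion(edges18b, part), 2), 16.67)
  expect_equal(within_module_proportion(rbind(c(1, 2), c(3, 4)), part), 100)
  expect_error(within_module_proportion(matrix(0, 0, 2), part), "empty")
})
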