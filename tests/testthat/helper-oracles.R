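# Independent brute-force oracles and small fixture builders. These
# deliberately use naive loops / explicit formulas so they share no code
# path with the implementations they check.

# Naive WPLI: loop over pairs, bins and epochs.
oracle_wpli <- function(coef, tol = 1e-12) {
  d <- dim(coef)
  n_ep <- d[1]; n <- d[2]; nf <- d[3]; nt <- d[4]
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    acc <- 0
    for (fi in seq_len(nf)) for (ti in seq_len(nt)) {
      imx <- numeric(n_ep)
      for (e in seq_len(n_ep)) {
        imx[e] <- Im(coef[e, i, fi, ti] * Conj(coef[e, j, fi, ti]))
      }
      den <- mean(abs(imx))
      acc <- acc + if (den > tol) abs(mean(imx)) / den else 0
    }
    W[i, j] <- acc / (nf * nt)
  }
  W
}

# Direct double-loop Newman weighted modularity.
oracle_modularity <- function(W, memb) {
  tw <- sum(W)
  K <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W))) {
    if (memb[i] == memb[j]) q <- q + W[i, j] - K[i] * K[j] / tw
  }
  unname(q / tw)
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(1L, 1L)
  out
}

# Partial F for the group term via explicit normal equations.
oracle_partial_f <- function(y, gind, covars) {
  Xf <- cbind(1, gind, covars)
  Xr <- cbind(1, covars)
  bf <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  br <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
  rss1 <- sum((y - Xf %*% bf)^2)
  rss0 <- sum((y - Xr %*% br)^2)
  df2 <- length(y) - ncol(Xf)
  (rss0 - rss1) / (rss1 / df2)
}

# Exact Mann-Whitney tail probability by enumerating group assignments.
oracle_mwu_p <- function(x, y, alternative) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(m + n, m), 2, u_of)
  p_less <- mean(us <= u_obs)
  p_greater <- mean(us >= u_obs)
  switch(alternative,
         less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# Exact Spearman permutation p by full enumeration (n small).
oracle_spearman_p <- function(x, y, alternative) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  pm <- wplinbs:::all_perms(n)
  rhos <- apply(pm, 1, function(p) stats::cor(rx, ry[p]))
  eps <- 1e-12
  switch(alternative,
         greater = mean(rhos >= rho_obs - eps),
         less = mean(rhos <= rho_obs + eps),
         two.sided = mean(abs(rhos) >= abs(rho_obs) - eps))
}

# Wilks' Lambda via eigenvalues of W^{-1} B (independent algebraic route).
oracle_wilks_lambda <- function(X, group) {
  g <- factor(group)
  p <- ncol(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  grand <- colMeans(X)
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    mu <- colMeans(Xi)
    W <- W + crossprod(sweep(Xi, 2, mu))
    B <- B + nrow(Xi) * tcrossprod(mu - grand)
  }
  ev <- Re(eigen(solve(W) %*% B, only.values = TRUE)$values)
  prod(1 / (1 + ev))
}

# Random symmetric connectivity-like matrix in [lo, hi], zero diagonal.
random_connectivity <- function(n, lo = 0.05, hi = 0.4, labels = NULL) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, lo, hi)
  W <- W + t(W)
  connectivity_matrix(W, labels %||% sprintf("r%03d", seq_len(n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Matrix-level null cohort stack: iid matrices, iid covariate, arbitrary
# group split (exchangeable by construction).
null_stack <- function(n_regions, n_a, n_b) {
  n_sub <- n_a + n_b
  mats <- lapply(seq_len(n_sub), function(s) random_connectivity(n_regions))
  cohort_stack(mats, rep(c("A", "B"), c(n_a, n_b)),
               data.frame(MMSE = stats::rnorm(n_sub, 24, 4)))
}

# Small epoched sinusoid + noise fixture.
sinusoid_ts <- function(n_epochs, freq, fs = 256, len_s = 2, lag_s = 0,
                        noise = 0) {
  t <- seq(0, len_s - 1 / fs, by = 1 / fs)
  data <- array(0, c(n_epochs, 2, length(t)))
  for (e in seq_len(n_epochs)) {
    data[e, 1, ] <- sin(2 * pi * freq * t) + noise * stats::rnorm(length(t))
    data[e, 2, ] <- sin(2 * pi * freq * (t - lag_s)) +
      noise * stats::rnorm(length(t))
  }
  epoched_ts(data, fs)
}

jaccard_edges <- function(e1, e2) {
  k1 <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  k2 <- paste(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  length(intersect(k1, k2)) / length(union(k1, k2))
}
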