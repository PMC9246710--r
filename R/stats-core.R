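# Statistical primitives used throughout the pipeline. These are deliberately
# self-contained (exact enumeration branches, tie handling and the Holm
# step-down are part of the package contract) and are validated against
# independent oracles in the test suite.

#' Construct a test-result record
#'
#' Light container used by every hypothesis test in the package.
#'
#' @param test test name.
#' @param statistic scalar test statistic.
#' @param tail one of `"two.sided"`, `"less"`, `"greater"`.
#' @param p_value p-value in `[0, 1]` (or `NA` when undefined).
#' @param n sample size(s) involved.
#' @param ... further named fields stored verbatim (e.g. `df`, `method`).
#' @return an object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, tail, p_value, n, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(list(test = test, statistic = statistic, tail = tail,
                 p_value = p_value, n = n, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, %s, p = %.4g\n",
              x$test, x$statistic, x$tail, x$p_value))
  invisible(x)
}

# Exact null distribution of the Mann-Whitney U statistic (no ties):
# counts[u + 1] = number of arrangements of m x's among m + n values with
# U = u, via the standard lattice recursion.
mwu_exact_counts <- function(m, n) {
  umax <- m * n
  # 2-D DP over (number of x's, number of y's); appending an x that beats
  # all j y's so far shifts the U distribution by j.
  f <- vector("list", m + 1)
  for (i in 0:m) f[[i + 1]] <- matrix(0, nrow = n + 1, ncol = umax + 1)
  for (j in 0:n) f[[1]][j + 1, 1] <- 1
  for (i in 1:m) {
    f[[i + 1]][1, 1] <- 1
    for (j in 1:n) {
      a <- f[[i + 1]][j, ]                       # last value is a y
      b <- f[[i]][j + 1, ]                       # last value is an x
      shifted <- c(rep(0, j), b)[1:(umax + 1)]   # that x beats all j y's
      f[[i + 1]][j + 1, ] <- a + shifted
    }
  }
  f[[m + 1]][n + 1, ]
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location shift between two independent samples.
#' The statistic is \eqn{U = \#\{(i,j): x_i > y_j\} + \tfrac12\#\{x_i = y_j\}}.
#' For samples of at most 10 each without ties the p-value is exact (full
#' enumeration of the U null distribution); otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x stochastically smaller) or
#'   `"greater"`.
#' @param exact_max largest per-group size for the exact branch (default 10).
#' @return a [stat_result] with fields `statistic` (U), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           exact_max = 10) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # U for x
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && m <= exact_max && n <= exact_max) {
    counts <- mwu_exact_counts(m, n)
    total <- sum(counts)
    p_less <- sum(counts[seq_len(u + 1)]) / total
    p_greater <- sum(counts[(u + 1):(m * n + 1)]) / total
    p <- switch(alternative,
                less = p_less, greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    method <- "exact"
  } else {
    nn <- m + n
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma2 <- m * n / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      warning("all observations tied; p-value set to 1")
      return(stat_result("mann_whitney_u", u, alternative, 1, c(m, n),
                         method = "degenerate"))
    }
    mu <- m * n / 2
    sd0 <- sqrt(sigma2)
    p_less <- stats::pnorm((u - mu + 0.5) / sd0)
    p_greater <- stats::pnorm((u - mu - 0.5) / sd0, lower.tail = FALSE)
    p <- switch(alternative,
                less = p_less, greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    method <- "normal-approx"
  }
  stat_result("mann_whitney_u", u, alternative, p, c(m, n), method = method)
}

# All permutations of 1..n as a matrix (n! rows); n kept small by callers.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Correlation of mid-ranks with an exact permutation p-value for
#' \eqn{n \le 8} and the t approximation otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param exact_max largest n for the exact permutation branch (default 8).
#' @return a [stat_result] with `statistic` = rho. A constant input yields
#'   `NA` with a warning.
#' @export
spearman_rho <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must be paired")
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman rho undefined")
    return(stat_result("spearman_rho", NA_real_, alternative, NA_real_, n,
                       method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    pm <- all_perms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    stats_perm <- (matrix(ryc[pm], nrow(pm)) %*% rxc) / denom
    eps <- 1e-12
    p <- switch(alternative,
                greater = mean(stats_perm >= rho - eps),
                less = mean(stats_perm <= rho + eps),
                two.sided = mean(abs(stats_perm) >= abs(rho) - eps))
    method <- "exact-permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p_greater <- stats::pt(tt, df = n - 2, lower.tail = FALSE)
    p <- switch(alternative,
                greater = p_greater,
                less = 1 - p_greater,
                two.sided = min(1, 2 * min(p_greater, 1 - p_greater)))
    method <- "t-approx"
  }
  stat_result("spearman_rho", rho, alternative, p, n, method = method)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending, compares \eqn{p_{(k)}} with
#' \eqn{\alpha/(m-k+1)} and rejects until the first failure. Adjusted
#' p-values are the running maximum of \eqn{(m-k+1) p_{(k)}}, capped at 1.
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error level (default 0.05).
#' @return list with `reject` (logical, original order), `p_adjusted`
#'   (original order), and `alpha`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  m <- length(p)
  ord <- order(p)
  mult <- m - seq_len(m) + 1
  adj_sorted <- pmin(1, cummax(mult * p[ord]))
  reject_sorted <- logical(m)
  for (k in seq_len(m)) {
    if (!is.na(p[ord][k]) && p[ord][k] <= alpha / (m - k + 1)) {
      reject_sorted[k] <- TRUE
    } else break
  }
  reject <- logical(m); p_adj <- numeric(m)
  reject[ord] <- reject_sorted
  p_adj[ord] <- adj_sorted
  list(reject = reject, p_adjusted = p_adj, alpha = alpha)
}

# Residual sum of squares of y on design X via QR; rank-checked.
rss_fit <- function(y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient design (collinear terms)")
  res <- qr.resid(qr_x, y)
  sum(res^2)
}

#' One-way analysis of covariance for a group effect
#'
#' Partial F test for the group term in the linear model
#' `y ~ intercept + group + covariate`, i.e. the group contrast adjusted for
#' the covariate(s).
#'
#' @param y numeric response.
#' @param group two-level factor/labels.
#' @param covariate numeric vector or matrix of covariates.
#' @return a [stat_result] with `statistic` = F, `df` = c(df1, df2).
#' @export
ancova_group <- function(y, group, covariate) {
  y <- as.numeric(y)
  g <- as.integer(factor(group))
  covariate <- as.matrix(covariate)
  n <- length(y)
  if (n <= ncol(covariate) + 2) stop("too few observations for ANCOVA")
  if (any(apply(covariate, 2, stats::sd) == 0)) stop("constant covariate")
  glev <- sort(unique(g))
  if (length(glev) != 2) stop("group must have exactly 2 levels")
  gind <- as.numeric(g == glev[2])
  X_full <- cbind(1, gind, covariate)
  X_red <- cbind(1, covariate)
  rss1 <- rss_fit(y, X_full)
  rss0 <- rss_fit(y, X_red)
  df2 <- n - ncol(X_full)
  tol <- 1e-12 * (sum(y^2) + 1)
  f <- if (rss1 <= tol) {
    if (rss0 - rss1 <= tol) 0 else Inf
  } else {
    max(0, (rss0 - rss1)) / (rss1 / df2)
  }
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  stat_result("ancova_group", f, "two.sided", p, n, df = c(1, df2))
}

#' Wilks' Lambda multivariate two-group test
#'
#' \eqn{\Lambda = \det(W)/\det(W+B)} from within- and between-group scatter
#' matrices; for two groups the exact F transform
#' \eqn{F = \frac{1-\Lambda}{\Lambda}\,\frac{n-p-1}{p}} with
#' \eqn{(p,\, n-p-1)} degrees of freedom is used.
#'
#' @param X numeric matrix, subjects x variables.
#' @param group two-level labels.
#' @return a [stat_result] with `statistic` = F, plus `lambda` and `df`.
#' @export
wilks_lambda <- function(X, group) {
  X <- as.matrix(X)
  g <- factor(group)
  if (nlevels(g) != 2) stop("wilks_lambda implements the two-group test")
  n <- nrow(X); p <- ncol(X)
  if (n - p - 1 < 1)
    stop("pooled scatter not invertible: reduce dimensionality ",
         "(need n > p + 1)")
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    mu <- colMeans(Xi)
    Ci <- sweep(Xi, 2, mu)
    W <- W + crossprod(Ci)
    d <- mu - grand
    B <- B + nrow(Xi) * tcrossprod(d)
  }
  detW <- det(W); detT <- det(W + B)
  if (!is.finite(detW) || !is.finite(detT) || detW <= 0 || detT <= 0)
    stop("singular scatter matrix: reduce dimensionality before testing")
  lambda <- detW / detT
  f <- (1 - lambda) / lambda * (n - p - 1) / p
  pval <- stats::pf(f, p, n - p - 1, lower.tail = FALSE)
  stat_result("wilks_lambda", f, "two.sided", pval, n,
              lambda = lambda, df = c(p, n - p - 1))
}
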