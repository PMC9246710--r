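# Network-Based Statistics: covariate-adjusted edgewise tests, connected
# suprathreshold components with intensity-based size, and permutation
# family-wise error control on the maximum component size.

#' Cohort stack of connectivity matrices
#'
#' Bundles per-subject connectivity matrices with group labels and a
#' covariate table for group-level network statistics.
#'
#' @param matrices list of [connectivity_matrix] with identical node sets
#'   and ordering.
#' @param group per-subject labels (two levels, each with >= 2 members).
#' @param covariates data.frame of named covariates, complete (no `NA`),
#'   one row per subject; may have zero columns.
#' @param subject_id optional identifiers.
#' @return an object of class `cohort_stack`.
#' @export
cohort_stack <- function(matrices, group, covariates = NULL,
                         subject_id = NULL) {
  n_sub <- length(matrices)
  if (n_sub < 4) stop("need at least 4 subjects")
  labels <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), labels))
      stop("all matrices must share the same node set and ordering")
  }
  group <- as.character(group)
  if (length(group) != n_sub) stop("one group label per subject required")
  if (length(unique(group)) != 2 || min(table(group)) < 2)
    stop("exactly two groups with >= 2 members each are required")
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n_sub))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n_sub) stop("one covariate row per subject required")
  if (anyNA(covariates)) stop("covariates must be complete (no missing values)")
  if (is.null(subject_id)) subject_id <- sprintf("sub%03d", seq_len(n_sub))
  structure(list(subject_id = subject_id, group = group,
                 covariates = covariates, matrices = matrices,
                 region_labels = labels),
            class = "cohort_stack")
}

#' Build a cohort stack from a simulated cohort
#'
#' Runs [band_connectivity()] on every subject of a [simulate_cohort()]
#' result.
#'
#' @param cohort a `cohort`.
#' @param band a [band_spec] (default: the cohort's configured band).
#' @param hop window-centre spacing passed to [windowed_fourier()].
#' @return a [cohort_stack] (covariate column `MMSE`).
#' @export
compute_connectivity <- function(cohort, band = cohort$config$band,
                                 hop = 0.25) {
  mats <- lapply(cohort$ts, band_connectivity, band = band, hop = hop)
  cohort_stack(mats, cohort$subjects$group,
               cohort$subjects[, "MMSE", drop = FALSE],
               cohort$subjects$subject_id)
}

# Stack the upper triangle of every matrix into subjects x edges.
stack_edges <- function(stack) {
  n <- length(stack$region_labels)
  ut <- which(upper.tri(matrix(0, n, n)))
  Y <- t(vapply(stack$matrices, function(m) as.matrix(m)[ut], numeric(length(ut))))
  list(Y = Y, ut = ut, n = n)
}

edge_f_from_design <- function(Y, X_full, rss0, df2) {
  qr_f <- qr(X_full)
  if (qr_f$rank < ncol(X_full))
    stop("rank-deficient design (covariate collinear with group)")
  rss1 <- colSums(qr.resid(qr_f, Y)^2)
  f <- (rss0 - rss1) / (rss1 / df2)
  # edges with (numerically) zero variance or zero residuals get statistic 0
  tol <- 1e-12 * (colSums(Y^2) + 1)
  f[rss1 <= tol & rss0 - rss1 <= tol] <- 0
  f[!is.finite(f) | f < 0] <- 0
  f
}

#' Edgewise covariate-adjusted F statistics
#'
#' For every undirected edge, fits `weight ~ intercept + group + covariates`
#' and returns the partial F statistic for the group term. Edges with zero
#' variance across subjects receive statistic 0. With no covariates the
#' statistic equals the square of the pooled-variance two-sample t.
#'
#' @param stack a [cohort_stack].
#' @param covariate_names columns of `stack$covariates` to adjust for
#'   (default: all).
#' @param stat `"f"` (default) returns the partial F; `"t"` returns its
#'   square root, the absolute t-value of the group contrast, for
#'   thresholds quoted on the t scale.
#' @return an `edge_stat_matrix`: list with `S` (symmetric n x n matrix of
#'   statistic values, zero diagonal), `df` (numerator, denominator),
#'   `stat`, `region_labels`.
#' @export
edge_glm_f <- function(stack, covariate_names = names(stack$covariates),
                       stat = c("f", "t")) {
  stat <- match.arg(stat)
  stopifnot(inherits(stack, "cohort_stack"))
  se <- stack_edges(stack)
  n_sub <- nrow(se$Y)
  covars <- as.matrix(stack$covariates[, covariate_names, drop = FALSE])
  if (n_sub <= ncol(covars) + 2) stop("too few subjects for the design")
  gind <- as.numeric(stack$group == sort(unique(stack$group))[2])
  X_red <- cbind(1, covars)
  qr_r <- qr(X_red)
  if (qr_r$rank < ncol(X_red)) stop("rank-deficient reduced design")
  rss0 <- colSums(qr.resid(qr_r, se$Y)^2)
  df2 <- n_sub - (2 + ncol(covars))
  f <- edge_f_from_design(se$Y, cbind(1, gind, covars), rss0, df2)
  if (stat == "t") f <- sqrt(f)
  S <- matrix(0, se$n, se$n,
              dimnames = list(stack$region_labels, stack$region_labels))
  S[se$ut] <- f
  S <- S + t(S)
  structure(list(S = S, df = c(1, df2), stat = stat,
                 region_labels = stack$region_labels),
            class = "edge_stat_matrix")
}

#' Suprathreshold connected components
#'
#' Thresholds the edgewise statistic matrix at `t_th` (strict inequality)
#' and decomposes the surviving edges into connected components. Component
#' size is the intensity: the sum of suprathreshold statistics over the
#' component's edges.
#'
#' @param S an `edge_stat_matrix` (or plain symmetric statistic matrix).
#' @param t_th positive statistic threshold.
#' @return list of `network_component` objects (fields `edges`, `nodes`,
#'   `size`, `p_fwe = NA`), sorted by decreasing size; empty list when no
#'   edge survives.
#' @export
suprathreshold_components <- function(S, t_th) {
  if (t_th <= 0) stop("t_th must be positive")
  mat <- if (inherits(S, "edge_stat_matrix")) S$S else as.matrix(S)
  labels <- rownames(mat) %||% sprintf("r%03d", seq_len(nrow(mat)))
  n <- nrow(mat)
  ut <- which(upper.tri(mat) & mat > t_th, arr.ind = TRUE)
  if (nrow(ut) == 0) return(list())
  comp_id <- edge_components(ut)
  comps <- lapply(unique(comp_id), function(cid) {
    em <- ut[comp_id == cid, , drop = FALSE]
    em <- as_edge_matrix(em)
    nodes <- sort(unique(as.vector(em)))
    structure(list(edges = em, nodes = nodes,
                   size = sum(mat[em]),
                   p_fwe = NA_real_, region_labels = labels),
              class = "network_component")
  })
  comps[order(vapply(comps, `[[`, numeric(1), "size"), decreasing = TRUE)]
}

#' @export
print.network_component <- function(x, ...) {
  cat(sprintf("network_component: %d nodes, %d edges, size = %.3f, p_fwe = %s\n",
              length(x$nodes), nrow(x$edges), x$size,
              ifelse(is.na(x$p_fwe), "NA", format(x$p_fwe))))
  invisible(x)
}

#' Statistic threshold from the F distribution
#'
#' Convenience helper: the `1 - p` quantile of the edgewise null F
#' distribution, a principled way to set the NBS threshold.
#'
#' @param p upper tail probability (e.g. 0.001).
#' @param df length-2 degrees of freedom (as in `edge_stat_matrix$df`).
#' @return scalar threshold.
#' @export
nbs_threshold <- function(p, df) stats::qf(p, df[1], df[2], lower.tail = FALSE)

#' Network-Based Statistics permutation test
#'
#' Computes the observed suprathreshold components, then permutes group
#' labels (covariates stay attached to their subjects) `n_perm` times,
#' recording the maximum component size of each permutation. The family-wise
#' error corrected p-value of a component of size `s` is the fraction of
#' permutations whose maximum size is `>= s`. When fewer than 10 distinct
#' label arrangements exist, all arrangements are enumerated instead (with a
#' warning).
#'
#' @param stack a [cohort_stack].
#' @param covariate_names covariates to adjust for (default: all).
#' @param t_th statistic threshold (see [nbs_threshold()]).
#' @param n_perm number of permutations (default 5000, minimum 100).
#' @param alpha significance level recorded in the result (default 0.05).
#' @param seed integer seed; results are reproducible.
#' @param stat edgewise statistic scale, `"f"` (default) or `"t"`; component
#'   size sums the chosen statistic over suprathreshold edges.
#' @return list of `network_component`s with `p_fwe` filled in, sorted by
#'   decreasing size, with attributes `perm_max` (permutation distribution),
#'   `t_th`, `alpha`, `df`.
#' @export
nbs_test <- function(stack, covariate_names = names(stack$covariates),
                     t_th, n_perm = 5000, alpha = 0.05, seed = 1,
                     stat = c("f", "t")) {
  stat <- match.arg(stat)
  stopifnot(inherits(stack, "cohort_stack"))
  se <- stack_edges(stack)
  n_sub <- nrow(se$Y)
  covars <- as.matrix(stack$covariates[, covariate_names, drop = FALSE])
  if (n_sub <= ncol(covars) + 2) stop("too few subjects for the design")
  gvec <- as.numeric(stack$group == sort(unique(stack$group))[2])
  X_red <- cbind(1, covars)
  qr_r <- qr(X_red)
  if (qr_r$rank < ncol(X_red)) stop("rank-deficient reduced design")
  rss0 <- colSums(qr.resid(qr_r, se$Y)^2)
  df2 <- n_sub - (2 + ncol(covars))
  f_obs <- edge_f_from_design(se$Y, cbind(1, gvec, covars), rss0, df2)
  if (stat == "t") f_obs <- sqrt(f_obs)
  S <- matrix(0, se$n, se$n,
              dimnames = list(stack$region_labels, stack$region_labels))
  S[se$ut] <- f_obs
  S <- S + t(S)
  comps <- suprathreshold_components(S, t_th)

  max_size_for <- function(g_perm) {
    f <- edge_f_from_design(se$Y, cbind(1, g_perm, covars), rss0, df2)
    if (stat == "t") f <- sqrt(f)
    surv <- which(f > t_th)
    if (length(surv) == 0) return(0)
    em <- arrayInd(se$ut[surv], c(se$n, se$n))
    cid <- edge_components(em)
    max(vapply(split(f[surv], cid), sum, numeric(1)))
  }

  n_arrangements <- choose(n_sub, sum(gvec == 1))
  if (n_arrangements < 10) {
    warning("fewer than 10 distinct label arrangements; ",
            "enumerating all of them exactly")
    combs <- utils::combn(n_sub, sum(gvec == 1))
    perm_max <- apply(combs, 2, function(ix) {
      g <- numeric(n_sub); g[ix] <- 1
      max_size_for(g)
    })
  } else {
    if (n_perm < 100) stop("n_perm must be at least 100")
    perm_max <- with_seed(seed, {
      vapply(seq_len(n_perm), function(p) max_size_for(sample(gvec)),
             numeric(1))
    })
  }
  comps <- lapply(comps, function(cp) {
    cp$p_fwe <- mean(perm_max >= cp$size)
    cp
  })
  attr(comps, "perm_max") <- perm_max
  attr(comps, "t_th") <- t_th
  attr(comps, "alpha") <- alpha
  attr(comps, "df") <- c(1, df2)
  comps
}
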