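# Streamline-count matrices: symmetrization, tract summaries and the
# structure-function statistical battery.

#' Symmetrize a streamline-count matrix
#'
#' Probabilistic tractography cannot resolve streamline directionality, so
#' each (i, j) element is replaced with the average of itself and the
#' (j, i) element; the diagonal is zeroed. Averaged half-counts are kept as
#' reals (not re-rounded). Idempotent.
#'
#' @param M a [structural_matrix] (or nonnegative square matrix).
#' @return a [structural_matrix] with `M = t(M)`.
#' @export
symmetrize_structural <- function(M) {
  labels <- rownames(M)
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  if (any(M < 0)) stop("negative streamline counts")
  S <- (M + t(M)) / 2
  diag(S) <- 0
  structural_matrix(S, labels)
}

#' Tract summaries from a structural matrix
#'
#' Extracts the three structural features the pipeline compares and
#' correlates: `wm_nbs`, the mean streamline count over the functionally
#' affected cortico-cortical edges; `thal_cortex` and `nbm_cortex`, the
#' total streamline counts between the thalamus / nucleus basalis of
#' Meynert rows and the cortical nodes.
#'
#' @param M a symmetrized [structural_matrix].
#' @param cortical_edges 2-column edge matrix over cortical labels/indices
#'   (the NBS component's edges).
#' @param cortical_nodes cortical labels entering the subcortical totals
#'   (default: every cortical label of `M`; pass the NBS node set to match a
#'   component-restricted matrix).
#' @return named list `wm_nbs`, `thal_cortex`, `nbm_cortex`.
#' @export
tract_summaries <- function(M, cortical_edges, cortical_nodes = NULL) {
  labels <- rownames(M)
  n <- nrow(M) - 2
  cortical <- labels[seq_len(n)]
  if (is.null(cortical_nodes)) cortical_nodes <- cortical
  if (is.numeric(cortical_nodes)) cortical_nodes <- cortical[cortical_nodes]
  if (!all(cortical_nodes %in% cortical)) stop("unknown cortical labels")
  em <- resolve_edges(cortical_edges, labels)
  if (any(em > n)) stop("cortical_edges must reference cortical labels only")
  list(wm_nbs = mean(M[em]),
       thal_cortex = sum(M["THAL", cortical_nodes]),
       nbm_cortex = sum(M["NBM", cortical_nodes]))
}

#' Group comparison of tract summaries
#'
#' Three one-tailed Mann-Whitney tests (alternative: group A < group B) on
#' `wm_nbs`, `thal_cortex` and `nbm_cortex`, Holm-Bonferroni corrected as a
#' family of three.
#'
#' @param summaries data.frame with columns `wm_nbs`, `thal_cortex`,
#'   `nbm_cortex`, one row per subject.
#' @param group per-subject labels; the first sorted level is the deficit
#'   group tested as stochastically smaller.
#' @param alpha family-wise level for the Holm correction (default 0.05).
#' @return data.frame with one row per tract: `feature`, `statistic` (U),
#'   `p_value`, `p_adjusted`, `reject`.
#' @export
tract_group_tests <- function(summaries, group, alpha = 0.05) {
  feats <- c("wm_nbs", "thal_cortex", "nbm_cortex")
  stopifnot(all(feats %in% names(summaries)))
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2) stop("exactly two groups required")
  res <- lapply(feats, function(f) {
    mann_whitney_u(summaries[[f]][group == lev[1]],
                   summaries[[f]][group == lev[2]],
                   alternative = "less")
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  hb <- holm_bonferroni(p, alpha)
  data.frame(feature = feats,
             statistic = vapply(res, `[[`, numeric(1), "statistic"),
             p_value = p, p_adjusted = hb$p_adjusted, reject = hb$reject,
             stringsAsFactors = FALSE)
}

#' Structure-function correlation battery
#'
#' Per group and per structural feature (`wm_nbs`, `thal_cortex`,
#' `nbm_cortex`), Spearman rank correlations against each EEG feature:
#' `wpli_nbs` right-tailed (structure and function decline together) and
#' `q_w` left-tailed (segregation rises as structure declines).
#' Holm-Bonferroni is applied within each 6-test family (one family per EEG
#' metric: 2 groups x 3 structural features).
#'
#' @param eeg data.frame with columns `wpli_nbs` and `q_w`, one row per
#'   subject.
#' @param struct data.frame with columns `wm_nbs`, `thal_cortex`,
#'   `nbm_cortex`, one row per subject.
#' @param group per-subject labels.
#' @param alpha family-wise level per family (default 0.05).
#' @return data.frame with columns `eeg_feature`, `struct_feature`, `group`,
#'   `rho`, `tail`, `p_value`, `p_adjusted`, `reject`.
#' @export
struct_func_correlations <- function(eeg, struct, group, alpha = 0.05) {
  stopifnot(all(c("wpli_nbs", "q_w") %in% names(eeg)),
            nrow(eeg) == nrow(struct), nrow(eeg) == length(group))
  sfeats <- c("wm_nbs", "thal_cortex", "nbm_cortex")
  levs <- sort(unique(as.character(group)))
  out <- list()
  for (ef in c("wpli_nbs", "q_w")) {
    tail <- if (ef == "wpli_nbs") "greater" else "less"
    fam <- list()
    for (g in levs) {
      for (sf in sfeats) {
        sel <- group == g
        r <- spearman_rho(struct[[sf]][sel], eeg[[ef]][sel],
                          alternative = tail)
        fam[[length(fam) + 1]] <- data.frame(
          eeg_feature = ef, struct_feature = sf, group = g,
          rho = r$statistic, tail = tail, p_value = r$p_value,
          stringsAsFactors = FALSE)
      }
    }
    fam <- do.call(rbind, fam)
    hb <- holm_bonferroni(fam$p_value, alpha)
    fam$p_adjusted <- hb$p_adjusted
    fam$reject <- hb$reject
    out[[ef]] <- fam
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
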