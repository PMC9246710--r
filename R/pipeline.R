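# End-to-end orchestration: cohort -> connectivity -> NBS -> network
# summaries -> modularity / consensus -> structure-function battery, with a
# machine-readable report.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"matrices"`
#'   (load precomputed connectivity matrices from `stack_dir`).
#' @param sim a [simulation_config] (simulate mode).
#' @param stack_dir directory readable by [read_cohort_stack()] (matrices
#'   mode).
#' @param structural optional list of [structural_matrix] (matrices mode);
#'   in simulate mode structural matrices are generated.
#' @param t_th vector of statistic thresholds for NBS (default `c(14, 15.4)`).
#' @param n_perm NBS permutations (default 5000).
#' @param covariate_names covariates adjusted for in the NBS design and the
#'   modularity comparison (default `"MMSE"`).
#' @param tau consensus agreement threshold (default 0.64).
#' @param alpha significance level (default 0.05).
#' @param louvain_runs Louvain restarts per subject network (default 100).
#' @param force_posthoc run post hoc node-strength tests even when the
#'   multivariate omnibus is not significant (default FALSE).
#' @param seed master seed; every stage draws from deterministic substreams.
#' @param out_dir optional output directory for the JSON report and TSV
#'   tables.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "matrices"),
                            sim = simulation_config(),
                            stack_dir = NULL, structural = NULL,
                            t_th = c(14, 15.4), n_perm = 5000,
                            covariate_names = "MMSE", tau = 0.64,
                            alpha = 0.05, louvain_runs = 100,
                            force_posthoc = FALSE, seed = 1,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (length(t_th) < 1) stop("t_th list must be nonempty")
  if (mode == "matrices" && (is.null(stack_dir) || !dir.exists(stack_dir)))
    stop("matrices mode requires an existing stack_dir")
  structure(list(mode = mode, sim = sim, stack_dir = stack_dir,
                 structural = structural, t_th = sort(t_th), n_perm = n_perm,
                 covariate_names = covariate_names, tau = tau, alpha = alpha,
                 louvain_runs = louvain_runs, force_posthoc = force_posthoc,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate connectivity inputs
#'
#' Non-mutating diagnostics on a set of connectivity matrices and an
#' optional covariate table: symmetry (max `|W - t(W)|`), value range,
#' zero diagonal, label consistency, covariate completeness.
#'
#' @param matrices list of (putative) connectivity matrices.
#' @param covariates optional data.frame of covariates.
#' @return list with `ok` (logical) and `diagnostics` (character vector;
#'   empty when clean).
#' @export
validate_inputs <- function(matrices, covariates = NULL) {
  diags <- character(0)
  labels <- rownames(matrices[[1]])
  for (s in seq_along(matrices)) {
    M <- as.matrix(matrices[[s]])
    asym <- max(abs(M - t(M)))
    if (asym > 1e-8)
      diags <- c(diags, sprintf("matrix %d: asymmetry max |W - t(W)| = %.3g",
                                s, asym))
    if (min(M) < 0 || max(M) > 1)
      diags <- c(diags, sprintf(
        "matrix %d: value range violation [%.3g, %.3g] outside [0, 1]",
        s, min(M), max(M)))
    if (any(diag(M) != 0))
      diags <- c(diags, sprintf("matrix %d: nonzero diagonal", s))
    if (!identical(rownames(M), labels))
      diags <- c(diags, sprintf("matrix %d: label mismatch with matrix 1", s))
  }
  if (!is.null(covariates) && anyNA(covariates)) {
    bad <- which(is.na(as.matrix(covariates)), arr.ind = TRUE)
    diags <- c(diags, sprintf("covariate completeness violation at row %d, column %d",
                              bad[, 1], bad[, 2]))
  }
  list(ok = length(diags) == 0, diagnostics = diags)
}

# ANCOVA when covariates are present, one-way F otherwise.
group_effect_test <- function(y, group, covars) {
  if (ncol(covars) > 0) {
    ancova_group(y, group, covars)
  } else {
    g <- as.integer(factor(group))
    X_full <- cbind(1, as.numeric(g == max(g)))
    rss1 <- rss_fit(y, X_full)
    rss0 <- rss_fit(y, matrix(1, length(y)))
    df2 <- length(y) - 2
    f <- max(0, rss0 - rss1) / (rss1 / df2)
    stat_result("anova_group", f, "two.sided",
                stats::pf(f, 1, df2, lower.tail = FALSE), length(y),
                df = c(1, df2))
  }
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain the cohort (simulated or loaded), estimate
#' band-limited WPLI matrices, run NBS at every threshold in `t_th`, then —
#' anchored to the component from the lowest threshold — compare the mean
#' component connectivity (WPLI_NBS) between groups, test normalized node
#' strengths (Wilks' Lambda omnibus, then Holm-corrected post hoc
#' Mann-Whitney tests), compare weighted modularity via covariate-adjusted
#' ANCOVA, derive per-group consensus partitions and within-module NBS-edge
#' proportions, and (when structural matrices are available) run the
#' streamline tract comparisons and structure-function correlations.
#'
#' @param config a [pipeline_config].
#' @return an object of class `pipeline_report`; see the fields in the
#'   returned list. When `config$out_dir` is set, a JSON report and TSV
#'   tables are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- NULL
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$sim)
    stack <- compute_connectivity(cohort)
    structural <- simulate_structural(cohort, stack$matrices, config$sim)
  } else {
    stack <- read_cohort_stack(config$stack_dir)
    structural <- config$structural
  }
  covariate_names <- intersect(config$covariate_names, names(stack$covariates))
  covars <- as.matrix(stack$covariates[, covariate_names, drop = FALSE])
  group <- stack$group
  lev <- sort(unique(group))
  n_sub <- length(group)

  nbs <- list()
  for (k in seq_along(config$t_th)) {
    nbs[[sprintf("t_th=%g", config$t_th[k])]] <-
      nbs_test(stack, covariate_names, config$t_th[k],
               n_perm = config$n_perm, alpha = config$alpha,
               seed = substream_seed(seed, 100 + k))
  }

  # primary component: lowest threshold, significant if possible
  primary <- NULL; primary_significant <- FALSE
  low <- nbs[[1]]
  if (length(low) > 0) {
    sig <- Filter(function(cp) !is.na(cp$p_fwe) && cp$p_fwe < config$alpha, low)
    if (length(sig) > 0) {
      primary <- sig[[1]]; primary_significant <- TRUE
    } else {
      primary <- low[[1]]
    }
  }

  wpli_nbs <- rep(NA_real_, n_sub)
  strength_block <- NULL
  if (!is.null(primary)) {
    wpli_nbs <- vapply(stack$matrices, mean_component_connectivity,
                       numeric(1), edges = primary$edges)
    wpli_test <- mann_whitney_u(wpli_nbs[group == lev[1]],
                                wpli_nbs[group == lev[2]], "two.sided")
    K <- t(vapply(stack$matrices, function(W) {
      node_strength(W, restrict_edges = primary$edges, normalize = TRUE)
    }, numeric(length(stack$region_labels))))
    K_comp <- K[, primary$nodes, drop = FALSE]
    colnames(K_comp) <- stack$region_labels[primary$nodes]
    k_av <- rowMeans(K_comp)
    omnibus <- tryCatch(wilks_lambda(K_comp, group),
                        error = function(e) {
                          stat_result("wilks_lambda", NA_real_, "two.sided",
                                      NA_real_, n_sub, note = conditionMessage(e))
                        })
    posthoc <- NULL
    if (config$force_posthoc ||
        (!is.na(omnibus$p_value) && omnibus$p_value < config$alpha)) {
      pvals <- apply(K_comp, 2, function(k) {
        mann_whitney_u(k[group == lev[1]], k[group == lev[2]],
                       "two.sided")$p_value
      })
      hb <- holm_bonferroni(pvals, config$alpha)
      posthoc <- data.frame(node = colnames(K_comp), p_value = pvals,
                            p_adjusted = hb$p_adjusted, reject = hb$reject,
                            stringsAsFactors = FALSE, row.names = NULL)
    }
    strength_block <- list(K = K_comp, k_av = k_av,
                           k_av_by_group = tapply(k_av, group, mean),
                           wpli_test = wpli_test, omnibus = omnibus,
                           posthoc = posthoc)
  }

  # modularity: per-subject optimal partition and Q_w
  parts <- lapply(seq_len(n_sub), function(s) {
    louvain_partition(stack$matrices[[s]], n_runs = config$louvain_runs,
                      seed = substream_seed(seed, 3000000 + s))
  })
  q_w <- vapply(parts, `[[`, numeric(1), "q_w")
  q_test <- group_effect_test(q_w, group, covars)

  consensus <- list(); wm_prop <- c()
  for (gi in seq_along(lev)) {
    cp <- consensus_partition(parts[group == lev[gi]], tau = config$tau,
                              n_runs = config$louvain_runs,
                              seed = substream_seed(seed, 4000000 + gi))
    consensus[[lev[gi]]] <- cp
    if (!is.null(primary)) {
      wm_prop[lev[gi]] <- within_module_proportion(primary$edges, cp)
    }
  }

  struct_block <- NULL
  if (!is.null(structural) && !is.null(primary)) {
    sym <- lapply(structural, symmetrize_structural)
    comp_nodes <- stack$region_labels[primary$nodes]
    summaries <- do.call(rbind, lapply(sym, function(M) {
      as.data.frame(tract_summaries(M, primary$edges,
                                    cortical_nodes = comp_nodes))
    }))
    tract_tests <- tract_group_tests(summaries, group, config$alpha)
    eeg_feat <- data.frame(wpli_nbs = wpli_nbs, q_w = q_w)
    correlations <- struct_func_correlations(eeg_feat, summaries, group,
                                             config$alpha)
    struct_block <- list(summaries = summaries, tract_tests = tract_tests,
                         correlations = correlations)
  }

  report <- structure(list(
    config = config,
    groups = lev,
    n_subjects = as.list(table(group)),
    nbs = nbs,
    primary_component = primary,
    primary_significant = primary_significant,
    wpli_nbs = wpli_nbs,
    wpli_nbs_by_group = if (!is.null(primary)) tapply(wpli_nbs, group, mean),
    strengths = strength_block,
    q_w = q_w,
    q_w_by_group = tapply(q_w, group, mean),
    q_w_test = q_test,
    consensus = consensus,
    within_module_pct = wm_prop,
    structure_function = struct_block,
    ground_truth = if (!is.null(cohort)) cohort$layout,
    seed = seed
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  groups: %s (n = %s)\n", paste(x$groups, collapse = " / "),
              paste(unlist(x$n_subjects), collapse = " / ")))
  for (nm in names(x$nbs)) {
    comps <- x$nbs[[nm]]
    if (length(comps) == 0) {
      cat(sprintf("  NBS %s: no suprathreshold component\n", nm))
    } else {
      cat(sprintf("  NBS %s: top component %d nodes / %d edges, size %.1f, p_fwe = %.4g\n",
                  nm, length(comps[[1]]$nodes), nrow(comps[[1]]$edges),
                  comps[[1]]$size, comps[[1]]$p_fwe))
    }
  }
  if (!is.null(x$wpli_nbs_by_group))
    cat(sprintf("  WPLI_NBS by group: %s\n",
                paste(sprintf("%s = %.4f", names(x$wpli_nbs_by_group),
                              x$wpli_nbs_by_group), collapse = ", ")))
  cat(sprintf("  Q_w by group: %s (F = %.3g, p = %.4g)\n",
              paste(sprintf("%s = %.4f", names(x$q_w_by_group),
                            x$q_w_by_group), collapse = ", "),
              x$q_w_test$statistic, x$q_w_test$p_value))
  if (length(x$within_module_pct) > 0)
    cat(sprintf("  within-module NBS edges: %s\n",
                paste(sprintf("%s = %.2f%%", names(x$within_module_pct),
                              x$within_module_pct), collapse = ", ")))
  invisible(x)
}

# Serializable subset of a report (drops bulky matrices).
report_as_list <- function(report) {
  comp_to_list <- function(cp) {
    if (is.null(cp)) return(NULL)
    list(nodes = cp$region_labels[cp$nodes],
         edges = cbind(cp$region_labels[cp$edges[, 1]],
                       cp$region_labels[cp$edges[, 2]]),
         size = cp$size, p_fwe = cp$p_fwe)
  }
  sr_to_list <- function(s) {
    if (is.null(s)) return(NULL)
    list(test = s$test, statistic = s$statistic, tail = s$tail,
         p_value = s$p_value)
  }
  list(
    schema = "wplinbs-report-1",
    seed = report$seed,
    groups = report$groups,
    n_subjects = report$n_subjects,
    nbs = lapply(report$nbs, function(comps) lapply(comps, comp_to_list)),
    primary_component = comp_to_list(report$primary_component),
    primary_significant = report$primary_significant,
    wpli_nbs_by_group = as.list(report$wpli_nbs_by_group),
    wpli_test = sr_to_list(report$strengths$wpli_test),
    strength_omnibus = sr_to_list(report$strengths$omnibus),
    strength_posthoc = report$strengths$posthoc,
    q_w = report$q_w,
    q_w_by_group = as.list(report$q_w_by_group),
    q_w_test = sr_to_list(report$q_w_test),
    within_module_pct = as.list(report$within_module_pct),
    tract_tests = report$structure_function$tract_tests,
    correlations = report$structure_function$correlations
  )
}

#' Write a pipeline report to disk
#'
#' `report.json` (full machine-readable report), plus TSV tables for the
#' per-subject features and the statistical batteries.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_as_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  feats <- data.frame(wpli_nbs = report$wpli_nbs, q_w = report$q_w)
  utils::write.table(feats, file.path(dir, "subject_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$structure_function)) {
    utils::write.table(report$structure_function$tract_tests,
                       file.path(dir, "tract_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report$structure_function$correlations,
                       file.path(dir, "correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
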