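# Synthetic two-group cohort generator.
#
# Signal model: each region carries a private narrowband (band-limited
# Gaussian) oscillation plus white noise. Phase coupling is injected through
# shared analytic narrowband sources mixed into several regions with fixed
# complex weights: every planted edge owns one source whose two endpoints
# receive it at a consistent nonzero phase offset (so WPLI, which is blind to
# zero-lag synchrony, can see it), and (optionally) every background module
# owns one source shared by its member regions at region-specific phase
# offsets. The planted-edge mixing weight is `coupling_base` in group B and
# `coupling_base - coupling_deficit` in group A; the background modular
# structure is identical in both groups, so with a zero deficit the groups
# are exchangeable.

#' Simulation configuration for a two-group cohort
#'
#' Defaults emulate the study conditions the pipeline was designed around:
#' 25 vs 17 subjects, 2-s epochs at 256 Hz, alpha-band (8-13.5 Hz) sources,
#' a planted 19-node/18-edge differential subnetwork whose coupling is
#' halved in group A, an MMSE-like covariate with a near-significant group
#' trend (means 23.04 vs 24.88, sd 3.9), and group-A subcortical streamline
#' deficits. The region count defaults to a desk-scale 32 (the full-cohort
#' cortical parcellation of 148 regions is available by setting
#' `n_regions = 148`).
#'
#' @param n_regions number of cortical regions (default 32).
#' @param n_group_a,n_group_b group sizes (defaults 25 and 17; group A is
#'   the deficit group).
#' @param n_epochs epochs per subject (default 50).
#' @param epoch_len_s epoch length in seconds (default 2).
#' @param fs sampling rate in Hz (default 256); must exceed `2 * band$f_hi`.
#' @param band a [band_spec] (default alpha 8-13.5 Hz).
#' @param planted_nodes,planted_edges size of the planted connected
#'   subnetwork (defaults 19 and 18, i.e. a spanning tree).
#' @param coupling_base planted phase-coupling mixing weight in `[0, 1]`
#'   (group B; default 0.6).
#' @param coupling_deficit reduction of the planted weight in group A, in
#'   `[0, coupling_base]` (default `0.5 * coupling_base`).
#' @param module_coupling background within-module coupling weight shared by
#'   both groups (default 0.55); 0 disables the background modular
#'   structure, leaving non-planted pairs with no shared phase source.
#' @param n_modules number of background modules (default 6).
#' @param coupling_competition fraction of the planted-coupling power lost
#'   to the deficit that is redistributed into module synchrony, uniformly
#'   across regions (default 0.25). Models homeostatic local compensation:
#'   the group with weakened long-range coupling shows slightly stronger
#'   within-module synchrony. Spread over all module pairs, the per-edge
#'   group difference stays far below edgewise-test thresholds; aggregate
#'   segregation measures (Q_w) see it. Total narrowband power per region
#'   stays at 1. Set to 0 to disable.
#' @param noise_sd white-noise standard deviation in signal-amplitude units
#'   (default 0.5; private narrowband amplitude is of order 1).
#' @param coupling_jitter_sd subject-level lognormal jitter (sdlog) on the
#'   planted coupling weight (default 0.05).
#' @param covariate_mean_a,covariate_mean_b,covariate_sd MMSE-like covariate
#'   distribution per group (defaults 23.04, 24.88, 3.9).
#' @param sf_coupling_rho target Spearman correlation between subject-mean
#'   planted-edge WPLI and planted-edge streamline counts (default 0.6).
#' @param tract_deficit multiplicative reduction of group-A thalamo-/
#'   basalo-cortical streamline counts, in `(0, 1]` (default 0.7).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_regions = 32, n_group_a = 25, n_group_b = 17,
                              n_epochs = 50, epoch_len_s = 2, fs = 256,
                              band = band_preset("alpha"),
                              planted_nodes = 19, planted_edges = 18,
                              coupling_base = 0.6,
                              coupling_deficit = 0.5 * coupling_base,
                              module_coupling = 0.55, n_modules = 6,
                              coupling_competition = 0.25,
                              noise_sd = 0.5, coupling_jitter_sd = 0.05,
                              covariate_mean_a = 23.04,
                              covariate_mean_b = 24.88,
                              covariate_sd = 3.9,
                              sf_coupling_rho = 0.6, tract_deficit = 0.7,
                              seed = 42) {
  stopifnot(inherits(band, "band_spec"))
  counts <- c(n_regions, n_group_a, n_group_b, n_epochs, planted_nodes,
              planted_edges, n_modules)
  if (any(counts < 1)) stop("all counts must be positive")
  if (planted_nodes > n_regions) stop("planted_nodes exceeds n_regions")
  if (fs <= 2 * band$f_hi) stop("fs violates Nyquist for the band")
  if (coupling_base < 0 || coupling_base > 1)
    stop("coupling_base must lie in [0, 1]")
  if (coupling_deficit < 0 || coupling_deficit > coupling_base)
    stop("coupling_deficit must lie in [0, coupling_base]")
  if (tract_deficit <= 0 || tract_deficit > 1)
    stop("tract_deficit must lie in (0, 1]")
  if (coupling_competition < 0 || coupling_competition > 1)
    stop("coupling_competition must lie in [0, 1]")
  if (abs(sf_coupling_rho) > 1) stop("sf_coupling_rho must lie in [-1, 1]")
  structure(list(n_regions = n_regions, n_group_a = n_group_a,
                 n_group_b = n_group_b, n_epochs = n_epochs,
                 epoch_len_s = epoch_len_s, fs = fs, band = band,
                 planted_nodes = planted_nodes, planted_edges = planted_edges,
                 coupling_base = coupling_base,
                 coupling_deficit = coupling_deficit,
                 module_coupling = module_coupling, n_modules = n_modules,
                 coupling_competition = coupling_competition,
                 noise_sd = noise_sd, coupling_jitter_sd = coupling_jitter_sd,
                 covariate_mean_a = covariate_mean_a,
                 covariate_mean_b = covariate_mean_b,
                 covariate_sd = covariate_sd,
                 sf_coupling_rho = sf_coupling_rho,
                 tract_deficit = tract_deficit, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Plant a connected differential subnetwork
#'
#' Draws `n_nodes` distinct regions and a connected undirected graph with
#' exactly `n_edges` edges on them (a uniform random spanning tree plus
#' uniformly sampled extra edges). With `n_edges = n_nodes - 1` the result
#' is a spanning tree, the shape of the component the pipeline is designed
#' to recover.
#'
#' @param n_regions total number of regions.
#' @param n_nodes nodes in the planted subnetwork (`<= n_regions`).
#' @param n_edges edges in the planted subnetwork; must satisfy
#'   `n_nodes - 1 <= n_edges <= n_nodes * (n_nodes - 1) / 2`.
#' @param seed integer seed (deterministic output).
#' @return integer 2-column edge matrix (node indices, `i < j`), with
#'   attribute `nodes` (the planted node set).
#' @export
plant_subnetwork <- function(n_regions, n_nodes, n_edges, seed = 1) {
  if (n_nodes > n_regions) stop("n_nodes exceeds n_regions")
  if (n_nodes < 2) stop("need at least 2 nodes")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < n_nodes - 1 || n_edges > max_edges)
    stop(sprintf(
      "infeasible edge count: a connected subgraph on %d nodes needs between %d and %d edges",
      n_nodes, n_nodes - 1, max_edges))
  with_seed(seed, {
    nodes <- sort(sample.int(n_regions, n_nodes))
    ord <- sample(nodes)
    tree <- cbind(ord[-1], vapply(2:n_nodes, function(k) {
      ord[sample.int(k - 1, 1)]
    }, numeric(1)))
    edges <- as_edge_matrix(tree)
    extra_needed <- n_edges - nrow(edges)
    if (extra_needed > 0) {
      all_pairs <- t(utils::combn(nodes, 2))
      key <- paste(all_pairs[, 1], all_pairs[, 2])
      used <- paste(edges[, 1], edges[, 2])
      avail <- which(!(key %in% used))
      pick <- avail[sample.int(length(avail), extra_needed)]
      edges <- as_edge_matrix(rbind(edges, all_pairs[pick, , drop = FALSE]))
    }
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    attr(edges, "nodes") <- nodes
    edges
  })
}

#' Cohort-level coupling layout
#'
#' Draws, once per cohort, everything that must be shared across subjects:
#' the background module assignment, the planted edge set (a long-range
#' differential subnetwork: a connected spanning tree plus extras whose
#' edges connect nodes of *different* background modules, emulating an
#' affected component dominated by between-module connections), a fixed
#' phase lag per planted edge (uniform in `[pi/8, 3*pi/8]`, fixed sign,
#' avoiding WPLI's zero-lag blind spot), and per-region module phase
#' offsets. With `module_coupling = 0` the cross-module constraint is moot
#' and the planted set is an unconstrained connected subgraph.
#'
#' @param config a [simulation_config].
#' @return a `cohort_layout` list: `planted` (edge matrix), `planted_phase`,
#'   `module_of`, `module_phase`, `region_labels`.
#' @export
cohort_layout <- function(config) {
  with_seed(substream_seed(config$seed, 999), {
    module_of <- sample(rep(seq_len(config$n_modules),
                            length.out = config$n_regions))
    planted <- if (config$module_coupling > 0 && config$n_modules > 1) {
      cross_module_subnetwork(config$n_regions, config$planted_nodes,
                              config$planted_edges, module_of)
    } else {
      plant_subnetwork(config$n_regions, config$planted_nodes,
                       config$planted_edges, seed = config$seed)
    }
    planted_phase <- stats::runif(nrow(planted), pi / 8, 3 * pi / 8)
    module_phase <- stats::runif(config$n_regions, 0, pi / 2)
    structure(list(planted = planted, planted_phase = planted_phase,
                   module_of = module_of, module_phase = module_phase,
                   region_labels = sprintf("r%03d", seq_len(config$n_regions))),
              class = "cohort_layout")
  })
}

# Connected subgraph whose edges all cross module boundaries (uses the
# caller's RNG stream). Falls back to unconstrained pairs if the requested
# edge count exceeds the available cross-module pairs.
cross_module_subnetwork <- function(n_regions, n_nodes, n_edges, module_of) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < n_nodes - 1 || n_edges > max_edges)
    stop(sprintf(
      "infeasible edge count: a connected subgraph on %d nodes needs between %d and %d edges",
      n_nodes, n_nodes - 1, max_edges))
  nodes <- sort(sample.int(n_regions, n_nodes))
  ord <- sample(nodes)
  edges <- matrix(0L, 0, 2)
  deg <- stats::setNames(integer(n_nodes), ord)
  for (k in 2:n_nodes) {
    prev <- ord[seq_len(k - 1)]
    # prefer cross-module anchors of low degree (degree <= 2 keeps the
    # per-node planted power within the unit-power budget)
    cand <- prev[module_of[prev] != module_of[ord[k]] &
                   deg[as.character(prev)] < 2]
    if (length(cand) == 0)
      cand <- prev[deg[as.character(prev)] < 2]
    if (length(cand) == 0)
      cand <- prev
    anchor <- cand[sample.int(length(cand), 1)]
    deg[as.character(anchor)] <- deg[as.character(anchor)] + 1L
    deg[as.character(ord[k])] <- deg[as.character(ord[k])] + 1L
    edges <- rbind(edges, c(ord[k], anchor))
  }
  edges <- as_edge_matrix(edges)
  extra_needed <- n_edges - nrow(edges)
  if (extra_needed > 0) {
    all_pairs <- t(utils::combn(nodes, 2))
    cross <- module_of[all_pairs[, 1]] != module_of[all_pairs[, 2]]
    key <- paste(all_pairs[, 1], all_pairs[, 2])
    used <- paste(edges[, 1], edges[, 2])
    avail <- which(!(key %in% used) & cross)
    if (length(avail) < extra_needed)
      avail <- which(!(key %in% used))
    pick <- avail[sample.int(length(avail), extra_needed)]
    edges <- as_edge_matrix(rbind(edges, all_pairs[pick, , drop = FALSE]))
  }
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  attr(edges, "nodes") <- nodes
  edges
}

# Analytic band-limited Gaussian sources: n_samples x k complex matrix with
# spectral support restricted to [f_lo, f_hi], unit variance of the real part.
narrowband_sources <- function(k, n_samples, fs, f_lo, f_hi) {
  freqs <- (seq_len(n_samples) - 1) * fs / n_samples
  idx <- which(freqs >= f_lo & freqs <= f_hi & freqs < fs / 2)
  spec <- matrix(complex(real = 0), n_samples, k)
  spec[idx, ] <- complex(real = stats::rnorm(length(idx) * k),
                         imaginary = stats::rnorm(length(idx) * k))
  z <- stats::mvfft(spec, inverse = TRUE)
  z / sqrt(length(idx))   # Re(z) has unit variance
}

#' Simulate one subject's epoched source time series
#'
#' @param config a [simulation_config].
#' @param group `"A"` (deficit group) or `"B"`.
#' @param layout a [cohort_layout()] (shared across subjects of a cohort).
#' @param seed integer seed for this subject's private stream.
#' @param subject_id identifier for the output container.
#' @return an [epoched_ts].
#' @export
simulate_subject <- function(config, group, layout = cohort_layout(config),
                             seed = config$seed, subject_id = "subject") {
  stopifnot(inherits(config, "simulation_config"))
  if (!group %in% c("A", "B")) stop("group must be 'A' or 'B'")
  n <- config$n_regions
  n_samples <- round(config$epoch_len_s * config$fs)
  planted <- layout$planted
  n_pe <- nrow(planted)
  use_modules <- config$module_coupling > 0
  n_mod <- if (use_modules) config$n_modules else 0L
  k_src <- n + n_pe + n_mod
  coupling <- config$coupling_base -
    if (group == "A") config$coupling_deficit else 0
  mc <- if (use_modules) config$module_coupling else 0
  with_seed(seed, {
    jitter <- exp(stats::rnorm(1, 0, config$coupling_jitter_sd))
    w_edge <- rep(min(1, coupling * jitter), n_pe)
    # Complex mixing matrix: rows = sources (private, planted, modules),
    # columns = regions; phase offsets live in the complex weights. Every
    # region is normalised to exactly unit narrowband power in both groups
    # (planted power per node is capped and the private source absorbs the
    # remainder), so group membership changes phase-coupling consistency
    # only, never signal power.
    M <- matrix(complex(real = 0), k_src, n)
    planted_power <- numeric(n)
    for (e in seq_len(n_pe)) {
      planted_power[planted[e, 1]] <- planted_power[planted[e, 1]] + w_edge[e]^2
      planted_power[planted[e, 2]] <- planted_power[planted[e, 2]] + w_edge[e]^2
    }
    cap <- max(0, 0.95 - mc^2)
    node_scale <- ifelse(planted_power > cap & planted_power > 0,
                         sqrt(cap / pmax(planted_power, 1e-12)), 1)
    for (e in seq_len(n_pe)) {
      i <- planted[e, 1]; j <- planted[e, 2]
      M[n + e, i] <- w_edge[e] * node_scale[i]
      M[n + e, j] <- w_edge[e] * node_scale[j] *
        exp(-1i * layout$planted_phase[e])
    }
    pp <- pmin(planted_power, cap)
    # long-range/local compensation: coupling power missing from the
    # planted (long-range) edges relative to the full-coupling reference is
    # partially redistributed into module synchrony, uniformly across
    # regions. Spread over all module pairs the per-edge group difference
    # is far below any edgewise threshold; only aggregate segregation
    # measures see it.
    mc_s <- mc
    if (use_modules && config$coupling_competition > 0) {
      pp_at <- function(w) {
        ppw <- numeric(n)
        for (e in seq_len(n_pe)) {
          ppw[planted[e, 1]] <- ppw[planted[e, 1]] + w^2
          ppw[planted[e, 2]] <- ppw[planted[e, 2]] + w^2
        }
        mean(pmin(ppw, cap))
      }
      deficit_power <- pp_at(config$coupling_base) - pp_at(coupling)
      mc_s <- mc * sqrt(1 + config$coupling_competition * deficit_power)
    }
    if (use_modules) {
      for (r in seq_len(n)) {
        m <- layout$module_of[r]
        M[n + n_pe + m, r] <- mc_s * exp(-1i * layout$module_phase[r])
      }
    }
    w_priv <- sqrt(pmax(0.05, 1 - mc_s^2 - pp))
    M[cbind(seq_len(n), seq_len(n))] <- w_priv
    data <- array(0, dim = c(config$n_epochs, n, n_samples))
    for (ep in seq_len(config$n_epochs)) {
      Z <- narrowband_sources(k_src, n_samples, config$fs,
                              config$band$f_lo, config$band$f_hi)
      S <- Re(Z %*% M) +
        config$noise_sd * matrix(stats::rnorm(n_samples * n), n_samples, n)
      data[ep, , ] <- t(S)
    }
    epoched_ts(data, config$fs, layout$region_labels, subject_id)
  })
}

#' Simulate a full two-group cohort
#'
#' Generates `n_group_a + n_group_b` subjects (group A first) with per-subject
#' epoched time series, group labels, an MMSE-like covariate, and the planted
#' edge list as ground truth. Each subject draws from a deterministic
#' substream of the cohort seed, so the cohort is bit-reproducible and
#' independent of generation order.
#'
#' @param config a [simulation_config].
#' @return an object of class `cohort`: list with `subjects` (data.frame:
#'   `subject_id`, `group`, `MMSE`), `ts` (list of [epoched_ts]), `layout`
#'   (ground truth), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- cohort_layout(config)
  n_tot <- config$n_group_a + config$n_group_b
  group <- rep(c("A", "B"), c(config$n_group_a, config$n_group_b))
  ids <- sprintf("sub%03d", seq_len(n_tot))
  covariate <- with_seed(substream_seed(config$seed, 0), {
    mu <- ifelse(group == "A", config$covariate_mean_a, config$covariate_mean_b)
    stats::rnorm(n_tot, mu, config$covariate_sd)
  })
  ts <- vector("list", n_tot)
  for (s in seq_len(n_tot)) {
    ts[[s]] <- simulate_subject(config, group[s], layout,
                                seed = substream_seed(config$seed, s),
                                subject_id = ids[s])
  }
  structure(list(subjects = data.frame(subject_id = ids, group = group,
                                       MMSE = covariate,
                                       stringsAsFactors = FALSE),
                 ts = ts, layout = layout, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d A / %d B), %d regions, %d epochs\n",
              nrow(x$subjects), sum(x$subjects$group == "A"),
              sum(x$subjects$group == "B"), x$config$n_regions,
              x$config$n_epochs))
  invisible(x)
}

#' Structural streamline-count matrix container
#'
#' @param M nonnegative `(n+2) x (n+2)` matrix; the last two labels must be
#'   `THAL` and `NBM`.
#' @param labels row/column labels.
#' @return an object of class `structural_matrix`.
#' @export
structural_matrix <- function(M, labels = rownames(M)) {
  M <- as.matrix(M)
  if (is.null(labels)) stop("structural matrices need labels")
  if (any(M < 0) || !all(is.finite(M))) stop("streamline counts must be nonnegative and finite")
  if (!identical(utils::tail(labels, 2), c("THAL", "NBM")))
    stop("last two labels must be THAL and NBM")
  dimnames(M) <- list(labels, labels)
  class(M) <- c("structural_matrix", "matrix")
  M
}

#' Simulate per-subject streamline-count matrices
#'
#' Produces an `(n+2) x (n+2)` nonnegative integer matrix per subject
#' (cortical regions plus `THAL` and `NBM` seed rows), as unsymmetrized
#' seed-by-target counts (rounded log-normal draws, right-skewed like
#' probabilistic-tractography output). Planted cortico-cortical edges carry a
#' subject-level multiplier constructed so the subject-mean planted count has
#' Spearman correlation close to `sf_coupling_rho` with the subject-mean
#' planted-edge WPLI of `functional` (Gaussian-copula construction with
#' Pearson coupling `2 sin(pi * rho / 6)` on normal scores). `THAL`/`NBM`
#' rows of group-A subjects are scaled by `tract_deficit`.
#'
#' @param cohort a [simulate_cohort()] result (or any object with `subjects`
#'   and `layout` of the same shape).
#' @param functional list of [connectivity_matrix], one per subject, same
#'   node set as the cohort.
#' @param config a [simulation_config].
#' @return list of [structural_matrix], one per subject.
#' @export
simulate_structural <- function(cohort, functional, config = cohort$config) {
  subjects <- cohort$subjects
  n_sub <- nrow(subjects)
  if (length(functional) != n_sub)
    stop("need one functional matrix per subject")
  labels <- cohort$layout$region_labels
  n <- length(labels)
  if (!all(vapply(functional, nrow, 0L) == n))
    stop("functional matrix dimension mismatch with cohort regions")
  planted <- cohort$layout$planted
  f_mean <- vapply(seq_len(n_sub), function(s) {
    mean_component_connectivity(functional[[s]], planted)
  }, numeric(1))
  # Gaussian-copula subject factor targeting the requested Spearman rho.
  r_pearson <- 2 * sin(pi * config$sf_coupling_rho / 6)
  z <- stats::qnorm((rank(f_mean) - 0.5) / n_sub)
  g <- with_seed(substream_seed(config$seed, 5000), {
    r_pearson * z + sqrt(max(0, 1 - r_pearson^2)) * stats::rnorm(n_sub)
  })
  lab_all <- c(labels, "THAL", "NBM")
  lapply(seq_len(n_sub), function(s) {
    with_seed(substream_seed(config$seed, 2000000 + s), {
      M <- matrix(0, n + 2, n + 2, dimnames = list(lab_all, lab_all))
      # cortico-cortical background counts (asymmetric seed x target draws)
      base <- matrix(stats::rlnorm((n + 2)^2, meanlog = log(20), sdlog = 0.5),
                     n + 2, n + 2)
      M[seq_len(n), seq_len(n)] <- base[seq_len(n), seq_len(n)]
      # planted edges: subject factor + small edge-level noise
      mult <- exp(0.5 * g[s])
      for (e in seq_len(nrow(planted))) {
        i <- planted[e, 1]; j <- planted[e, 2]
        v <- 150 * mult * exp(stats::rnorm(2, 0, 0.1))
        M[i, j] <- v[1]; M[j, i] <- v[2]
      }
      # subcortical seed rows/target columns
      deficit <- if (subjects$group[s] == "A") config$tract_deficit else 1
      thal <- stats::rlnorm(2 * n, log(40), 0.5) * deficit
      nbm <- stats::rlnorm(2 * n, log(30), 0.5) * deficit
      M[n + 1, seq_len(n)] <- thal[seq_len(n)]
      M[seq_len(n), n + 1] <- thal[n + seq_len(n)]
      M[n + 2, seq_len(n)] <- nbm[seq_len(n)]
      M[seq_len(n), n + 2] <- nbm[n + seq_len(n)]
      M[n + 1, n + 2] <- M[n + 2, n + 1] <- stats::rlnorm(1, log(10), 0.3)
      diag(M) <- 0
      structural_matrix(round(M), lab_all)
    })
  })
}
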