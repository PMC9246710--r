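# Synthetic cohort generator: planted subnetworks, determinism, coupling.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_regions = 8, n_group_a = 4, n_group_b = 3,
         n_epochs = 6, epoch_len_s = 1, fs = 128,
         planted_nodes = 4, planted_edges = 3,
         n_modules = 2, seed = 5),
    list(...))
  do.call(simulation_config, args)
}

test_that("plant_subnetwork produces connected subgraphs of the requested shape", {
  # 2 nodes, 1 edge: the only connected shape
  e1 <- plant_subnetwork(10, 2, 1, seed = 1)
  expect_equal(dim(e1), c(1, 2))
  expect_true(e1[1, 1] != e1[1, 2])
  # 4 nodes, 6 edges: forced K4
  e2 <- plant_subnetwork(10, 4, 6, seed = 7)
  expect_equal(nrow(e2), 6)
  expect_length(unique(as.vector(e2)), 4)
  expect_equal(nrow(unique(e2)), 6)
  # 19 nodes, 18 edges: a spanning tree (connected, no cycles)
  e3 <- plant_subnetwork(32, 19, 18, seed = 3)
  expect_equal(nrow(e3), 18)
  nodes <- unique(as.vector(e3))
  expect_length(nodes, 19)
  expect_length(unique(wplinbs:::edge_components(e3)), 1)  # one component
  # determinism
  expect_identical(plant_subnetwork(32, 19, 18, seed = 3), e3)
  # infeasible requests
  expect_error(plant_subnetwork(10, 4, 2, seed = 1), "infeasible")
  expect_error(plant_subnetwork(10, 4, 7, seed = 1), "infeasible")
  expect_error(plant_subnetwork(5, 9, 8, seed = 1), "exceeds")
})

test_that("cohort layout plants a connected cross-module subnetwork", {
  cfg <- simulation_config(seed = 11)
  lay <- cohort_layout(cfg)
  expect_equal(nrow(lay$planted), 18)
  expect_length(unique(as.vector(lay$planted)), 19)
  expect_length(unique(wplinbs:::edge_components(lay$planted)), 1)
  # phase lags avoid the zero-lag blind spot
  expect_true(all(lay$planted_phase >= pi / 8 & lay$planted_phase <= 3 * pi / 8))
  # planted edges predominantly cross module boundaries
  cross <- lay$module_of[lay$planted[, 1]] != lay$module_of[lay$planted[, 2]]
  expect_gte(mean(cross), 0.9)
})

test_that("simulate_cohort: sizes, labels, and bit-level determinism", {
  cfg <- tiny_config()
  coh1 <- simulate_cohort(cfg)
  expect_equal(nrow(coh1$subjects), 7)
  expect_equal(sum(coh1$subjects$group == "A"), 4)
  expect_equal(sum(coh1$subjects$group == "B"), 3)
  expect_length(coh1$ts, 7)
  expect_equal(dim(coh1$ts[[1]]$data), c(6, 8, 128))
  coh2 <- simulate_cohort(tiny_config())
  expect_identical(coh1$ts, coh2$ts)
  expect_identical(coh1$subjects, coh2$subjects)
  # full-size default config keeps the documented group sizes
  cfg_def <- simulation_config()
  expect_equal(cfg_def$n_group_a + cfg_def$n_group_b, 42)
})

test_that("null covariate difference rejects at the nominal rate", {
  pvals <- sapply(1:200, function(sd) {
    cfg <- simulation_config(n_regions = 2, n_group_a = 10, n_group_b = 8,
                             n_epochs = 2, epoch_len_s = 1, fs = 128,
                             planted_nodes = 2, planted_edges = 1,
                             n_modules = 1, covariate_mean_a = 24,
                             covariate_mean_b = 24, seed = sd)
    coh <- simulate_cohort(cfg)
    t.test(MMSE ~ group, data = coh$subjects)$p.value
  })
  rate <- mean(pvals <= 0.05)
  expect_gte(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("groups are exchangeable in distribution when the deficit is zero", {
  cfg <- tiny_config(coupling_deficit = 0)
  coh <- simulate_cohort(cfg)
  stack <- cohort_stack(lapply(coh$ts, band_connectivity,
                               band = cfg$band),
                        coh$subjects$group,
                        coh$subjects[, "MMSE", drop = FALSE])
  S <- edge_glm_f(stack)
  f_planted <- S$S[coh$layout$planted]
  # no systematic group contrast on planted edges (F far from the planted
  # regime, which sits in the tens)
  expect_lt(median(f_planted), qf(0.95, 1, 4))
})

test_that("planted-edge WPLI is monotone in coupling strength", {
  lay_cfg <- tiny_config(module_coupling = 0)
  lay <- cohort_layout(lay_cfg)
  mean_planted <- sapply(c(0, 0.4, 0.8), function(cb) {
    mean(sapply(1:4, function(sd) {
      cfg <- tiny_config(module_coupling = 0, coupling_base = cb,
                         coupling_deficit = 0)
      ts <- simulate_subject(cfg, "B", lay, seed = 100 + sd)
      W <- band_connectivity(ts, cfg$band)
      mean(W[lay$planted])
    }))
  })
  expect_true(all(diff(mean_planted) > 0))
})

test_that("strong coupling separates planted from background pairs", {
  cfg <- tiny_config(module_coupling = 0, coupling_base = 0.9,
                     coupling_deficit = 0, n_epochs = 20, noise_sd = 0.3)
  lay <- cohort_layout(cfg)
  ts <- simulate_subject(cfg, "B", lay, seed = 1)
  W <- band_connectivity(ts, cfg$band)
  planted_mean <- mean(W[lay$planted])
  bg <- upper.tri(W); bg[lay$planted] <- FALSE
  expect_gt(planted_mean, mean(W[bg]) + 0.2)
  # with no coupling injected the two sets are indistinguishable
  cfg0 <- tiny_config(module_coupling = 0, coupling_base = 0,
                      coupling_deficit = 0, n_epochs = 20)
  W0 <- band_connectivity(simulate_subject(cfg0, "B", lay, seed = 1), cfg0$band)
  expect_lt(abs(mean(W0[lay$planted]) - mean(W0[bg])), 0.1)
})

test_that("structural matrices have the documented interface and determinism", {
  cfg <- tiny_config()
  coh <- simulate_cohort(cfg)
  mats <- lapply(coh$ts, band_connectivity, band = cfg$band)
  str1 <- simulate_structural(coh, mats)
  expect_length(str1, 7)
  M <- str1[[1]]
  expect_equal(dim(M), c(10, 10))
  expect_equal(tail(rownames(M), 2), c("THAL", "NBM"))
  expect_true(all(M >= 0) && all(M == round(M)))
  expect_identical(simulate_structural(coh, mats), str1)
  # group A subcortical totals are reduced by the tract deficit
  thal_tot <- sapply(str1, function(m) sum(m["THAL", 1:8]))
  g <- coh$subjects$group
  expect_lt(mean(thal_tot[g == "A"]), mean(thal_tot[g == "B"]))
  # symmetrized output is accepted by the downstream battery unchanged
  sym <- symmetrize_structural(M)
  expect_silent(tract_summaries(sym, coh$layout$planted))
  expect_error(simulate_structural(coh, mats[1:3]), "one functional matrix")
})

test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(n_regions = 10, planted_nodes = 19),
               "exceeds")
  expect_error(simulation_config(fs = 20), "Nyquist")
  expect_error(simulation_config(coupling_base = 0.5, coupling_deficit = 0.7),
               "coupling_deficit")
  expect_error(simulation_config(tract_deficit = 0), "tract_deficit")
  expect_error(simulation_config(n_epochs = 0), "positive")
})
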