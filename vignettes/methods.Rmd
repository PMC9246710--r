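---
title: "Band-limited WPLI networks, NBS and consensus modularity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited WPLI networks, NBS and consensus modularity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wplinbs)
```

# What the package computes

`wplinbs` analyses group differences in region-level electrophysiological
connectivity. Its canonical use case is a two-group clinical cohort (here
called group A, the deficit group, and group B) with source-reconstructed,
band-limited EEG signals per cortical region, and — optionally — per-subject
streamline-count matrices from probabilistic tractography that include
thalamic (`THAL`) and basal-forebrain (`NBM`) seed rows. The pipeline
chains five stages:

1. **Spectral connectivity.** Windowed Fourier cross-spectra on a band grid,
   summarised per subject by the weighted phase lag index (WPLI).
2. **Network-Based Statistics (NBS).** Covariate-adjusted edgewise F tests,
   suprathreshold connected components scored by intensity, and permutation
   family-wise error control on the maximum component size.
3. **Component summaries.** Mean component connectivity (`WPLI_NBS`) and
   max-normalised node strengths, compared between groups with a Wilks'
   Lambda omnibus followed by Holm-corrected post hoc rank tests.
4. **Modularity and consensus.** Weighted modularity `Q_w` per subject
   (ANCOVA-adjusted group comparison), agreement-matrix consensus partitions
   per group, and the share of component edges that fall within consensus
   modules.
5. **Structure-function coupling.** Symmetrised streamline matrices, tract
   summaries (`wm_nbs`, `thal_cortex`, `nbm_cortex`), one-tailed rank tests
   of the group deficit, and one-tailed Spearman correlations between
   structural and functional features.

# The WPLI estimator

For two signals with cross-spectrum $X$ at a time-frequency bin, the
estimator is

$$\mathrm{WPLI} \;=\; \frac{\bigl|\,E_e[\operatorname{Im} X]\,\bigr|}
{E_e\bigl[|\operatorname{Im} X|\bigr]},$$

where the expectation $E_e$ runs across epochs. Values span 0 (no
consistently lagged synchronisation) to 1 (a perfectly consistent nonzero
lag). Because only the imaginary part of the cross-spectrum enters, zero-lag
synchrony — the signature of volume conduction in EEG — cannot raise the
estimate.

Estimation choices:

* **Window placement.** For each analysis frequency $f$ the window spans
  $\mathrm{cycles}(f)/f$ seconds, with the cycle count ramping linearly
  from 3 at the lower band edge to 10 at the upper edge, on a 0.5 Hz grid
  (alpha band 8–13.5 Hz by default; theta 4.6–7 Hz and beta 15–20 Hz
  presets are provided). Window centres sit on a common grid (default hop
  0.25 s) restricted so that the longest window fits, which keeps time bins
  aligned across regions and frequencies.
* **Taper.** A Hann taper, amplitude-normalised so that coefficient
  magnitudes are comparable across window widths. WPLI itself is invariant
  to this normalisation; it matters only for inspecting raw coefficients.
* **Bin aggregation.** The epoch-wise expectation is taken first, per
  time-frequency bin; bin-level WPLI values are then averaged into one
  matrix per subject.
* **Vanishing denominator.** A bin whose mean $|\operatorname{Im} X|$ falls
  below `1e-12` has no lagged synchronisation to weigh; its WPLI is defined
  as 0 and a diagnostic counter (`n_zero_denom`) is incremented. Two
  analytically convenient consequences, used as acceptance anchors: a
  constant quarter-cycle lag yields exactly 1, and duplicated (zero-lag)
  channels yield exactly 0.
* **Known small-sample bias.** The plain estimator is biased towards 1 when
  few epochs are available (with one epoch it is identically 1). The
  package deliberately implements the plain rather than the debiased
  variant; tests therefore check *concentration* with growing epoch counts,
  not monotone growth of the mean.

# Network-Based Statistics

Every undirected edge is tested with the linear model
`weight ~ intercept + group + covariates`; the partial F statistic for the
group term is the edgewise statistic (with no covariates it reduces to the
squared pooled-variance t). Edges whose statistic strictly exceeds the
threshold `t_th` form a graph; its connected components are scored by
intensity, the sum of their suprathreshold F values. Group labels are then
permuted (covariates stay with their subjects) and the maximum component
size recorded per permutation; a component's family-wise-error-corrected
p-value is the fraction of permutations whose maximum reaches its size.
Conventions worth noting:

* The observed statistic is *not* added to the permutation distribution, so
  p-values of exactly 0 can occur; they lie on the grid `k / n_perm`.
* `t_th` is an arbitrary sensitivity knob by construction. The helper
  `nbs_threshold(p, df)` expresses it as an upper quantile of the edgewise
  null F distribution; the pipeline default `c(14, 15.4)` matches the
  conventional strict choice for a design with roughly 40 error degrees of
  freedom (the 99.9th percentile of F(1, 39) is about 13.1).
* With fewer than 10 distinct label arrangements the permutation is replaced
  by exact enumeration of all arrangements, with a warning.
* Component discovery uses union–find over suprathreshold edges, so node
  ordering cannot influence the result.

# Modularity and consensus

Weighted modularity follows the standard Newman form,
$Q_w = l(w)^{-1} \sum_{ij} [w_{ij} - l(w)^{-1} K_i K_j]\,\delta_{m_i m_j}$,
with $l(w)$ the total weight (twice the upper-triangle sum) and $K_i$ the
node strength. It is invariant to a positive rescaling of the weights and is
validated against exhaustive partition enumeration on small graphs.
Optimisation is greedy multi-level (Louvain) with seeded random node-order
restarts (default 100), keeping the restart with the highest $Q_w$; the
all-zero matrix degenerates to singleton modules with `q_w = NA`.

Group-level consensus follows the agreement-matrix iteration: co-assignment
frequencies across subjects' partitions, thresholded at `tau = 0.64`
(strictly greater; certain co-assignment survives any threshold), are
re-clustered with independent Louvain runs until the induced co-assignment
matrix is binary. A fully disconnected thresholded matrix yields the
documented degenerate result of singleton modules. The iteration is capped
at 50 rounds.

Node strengths within a component divide retained weights by the subject's
maximum retained weight (per-subject normalisation; a flagless design
choice — the scope of "the maximum" is otherwise ambiguous), so the largest
retained weight is exactly 1 for every subject.

# Statistical primitives

The rank and multivariate tests the pipeline quotes are implemented in the
package and validated against brute-force oracles and base R:

* Mann–Whitney U: exact enumeration (dynamic programming over the U lattice)
  for both groups up to 10 without ties, otherwise a normal approximation
  with tie and continuity corrections.
* Spearman rank correlation: Pearson correlation of mid-ranks; exact
  permutation p for $n \le 8$, t approximation beyond. The switchover sizes
  are configurable; defaults keep the exact branch affordable.
* Holm–Bonferroni: step-down rejections and adjusted p-values (running
  maximum of $(m-k+1)p_{(k)}$, capped at 1). Families follow the analysis
  design: 3 tract tests; 6 correlations per EEG metric; post hoc strength
  tests corrected for the number of component nodes.
* ANCOVA: partial F for the group term given covariates, via QR residuals.
* Wilks' Lambda: $\Lambda = \det(W)/\det(W+B)$ with the exact two-group F
  transform $F = \frac{1-\Lambda}{\Lambda}\frac{n-p-1}{p}$ on
  $(p,\,n-p-1)$ degrees of freedom. Post hoc tests are suppressed unless
  the omnibus is significant (a `force_posthoc` flag overrides).

# The synthetic cohort generator

Because patient EEG/MRI data cannot ship with the package, every stage is
exercised on synthetic cohorts whose statistical structure mirrors the
target study design: 25 vs 17 subjects, 50 two-second epochs at 256 Hz,
alpha-band sources, an MMSE-like covariate with a near-significant group
trend (means 23.04 vs 24.88, sd 3.9), a planted 19-node/18-edge
differential subnetwork, and streamline matrices whose subcortical rows are
reduced in the deficit group.

**Signal model.** Each region mixes, at unit total narrowband power:

* a private band-limited Gaussian source;
* one shared source per *planted edge*, received by the two endpoints at a
  fixed phase offset drawn from $[\pi/8, 3\pi/8]$ (avoiding WPLI's zero-lag
  blind spot), mixed with weight `coupling_base` in group B and
  `coupling_base - coupling_deficit` in group A (defaults 0.6 and 0.3);
* one shared source per background *module* (6 modules by default, weight
  0.55, region-specific phase offsets), identical in both groups;
* white measurement noise.

Design decisions that required judgement:

* **Background modular structure.** A planted subnetwork alone does not pin
  down how group differences in *network segregation* should behave: real
  cortical alpha networks are modular, and the phenomenon being emulated is
  the weakening of long-range, predominantly between-module connections.
  The generator therefore gives all subjects a common modular background
  and plants the differential subnetwork on *cross-module* edges (a
  degree-bounded spanning path plus extras). Setting `module_coupling = 0`
  recovers the bare model in which non-planted pairs share no phase source;
  properties that rely on that bare contract are tested there.
* **Unit-power normalisation and local compensation.** Group membership
  must change phase-coupling consistency, not signal power, or every edge
  touching a planted node becomes trivially group-different. Mixing weights
  are therefore renormalised to unit narrowband power per region, with
  per-node planted power capped. On top of this, a fraction
  (`coupling_competition`, default 0.25) of the coupling power the deficit
  group loses on its long-range edges is redistributed into module
  synchrony, uniformly across regions — homeostatic local compensation, a
  pattern repeatedly described in dementia electrophysiology (long-range
  disconnection with relatively preserved or increased local synchrony).
  This is the generator's second channel for the segregation contrast: the
  deficit group has both lighter between-module edges and slightly heavier
  module interiors, hence higher $Q_w$. Because the compensation is spread
  uniformly over all within-module pairs, the per-edge group difference it
  induces is an order of magnitude below the NBS edge threshold, so the
  detected component remains the planted subnetwork.
* **Subject substreams.** One cohort seed expands into per-subject seeds by
  a counter-based scheme, so any subject can be regenerated independently
  of iteration order, and the whole cohort is byte-reproducible.
* **Epoch counts.** Real preprocessing discards varying numbers of epochs
  per subject; the generator keeps epoch counts equal by default (the
  estimator handles unequal counts subject-wise, since WPLI is computed per
  subject).
* **WPLI noise floor.** With 50 epochs the per-bin null bias of the plain
  estimator puts a floor of about 0.16 under every matrix entry; this is a
  property of the estimator, not of the generator, and it is why group
  contrasts in $Q_w$ are small in absolute terms (about +0.01 for the
  deficit group at default settings).

**Structural model.** Streamline counts are rounded log-normal draws
(right-skewed, nonnegative, asymmetric seed-by-target until symmetrised,
like probabilistic-tractography output). Planted cortico-cortical entries
carry a subject-level factor built by a Gaussian copula on the subject's
mean planted-edge WPLI with Pearson coupling $2\sin(\pi\rho_S/6)$, so the
subject-mean planted count attains a target Spearman correlation
(`sf_coupling_rho`, default 0.6) with functional connectivity. `THAL` and
`NBM` rows of deficit-group subjects are scaled by `tract_deficit`
(default 0.7, a moderate deficit detectable at these sample sizes).

# What the tests do and do not show

The test suite validates the estimators against brute-force oracles,
checks the analytic WPLI bounds, calibrates the NBS family-wise error on
null cohorts, and verifies planted-component recovery plus the qualitative
direction of all group effects on simulated cohorts. Problem sizes used by
the heavier studies are: 200 null cohorts of 16 regions and 10 vs 8
subjects at 500 permutations for FWE calibration (null cohorts are drawn
directly at the connectivity-matrix level — permutation validity depends
only on exchangeability, which matrix-level nulls satisfy by construction);
50 signal-level cohorts at the full default design (32 regions, 42
subjects, 500 permutations, 12 Louvain restarts) for recovery and
direction-of-effect; 100 seeds for structure-function recovery at n = 25;
200 null batteries for the correction families. Passing these says the
machinery is calibrated and sensitive under the generator's assumptions —
stationary narrowband Gaussian sources, fixed phase lags, equal epoch
counts, no source leakage. It does not certify performance on real source
reconstructions, where leakage, nonstationarity and heavy-tailed artefacts
are material.

# Reproducibility

Every stochastic entry point takes a seed and restores the caller's RNG
state. `run_pipeline()` derives per-stage substreams from its master seed;
identical configuration plus seed yields an identical serialised report.
The desk-scale default of 32 regions keeps the full pipeline tractable on a
single CPU; the full 148-region parcellation is a configuration switch
(`n_regions = 148`), with permutation NBS remaining feasible but slow.
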