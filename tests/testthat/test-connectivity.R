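# Windowed Fourier estimation and the WPLI estimator.

test_that("band grid and adaptive windows follow the band spec", {
  b <- band_preset("alpha")
  expect_equal(b$f_lo, 8); expect_equal(b$f_hi, 13.5)
  sp <- windowed_fourier(sinusoid_ts(2, 10), b)
  expect_equal(sp$freqs, seq(8, 13.5, by = 0.5))
  expect_length(sp$freqs, 12)
  expect_equal(band_preset("theta")$f_lo, 4.6)
  expect_equal(band_preset("beta")$f_hi, 20)
})

test_that("spectral concentration: a grid-frequency sinusoid peaks at its own bin", {
  ts <- sinusoid_ts(1, 10)
  sp <- windowed_fourier(ts, band_preset("alpha"))
  a <- abs(sp$coef[1, 1, , ])
  for (ti in seq_along(sp$times)) {
    expect_equal(which.max(a[, ti]), which(sp$freqs == 10))
  }
})

test_that("windowed Fourier is linear in the signal", {
  ts <- sinusoid_ts(3, 9.5, noise = 0)
  sp1 <- windowed_fourier(ts, band_preset("alpha"))
  ts$data <- ts$data * 3.7
  sp2 <- windowed_fourier(ts, band_preset("alpha"))
  expect_equal(sp2$coef, sp1$coef * 3.7, tolerance = 1e-12)
})

test_that("too-short epochs raise a configuration error naming the minimum", {
  short <- epoched_ts(array(rnorm(2 * 2 * 64), c(2, 2, 64)), fs = 256)
  expect_error(windowed_fourier(short, band_preset("alpha")), "epoch too short")
  expect_error(windowed_fourier(sinusoid_ts(2, 10, fs = 20), band_preset("alpha")),
               "Nyquist")
})

test_that("WPLI bin arithmetic: epoch-wise Im(X) of {+2,-1,+1} gives 0.5", {
  coef <- array(complex(real = 0), c(3, 2, 1, 1))
  coef[, 1, 1, 1] <- 1 + 0i
  coef[, 2, 1, 1] <- c(-2i, 1i, -1i)  # Im(a1 * Conj(a2)) = 2, -1, 1
  sp <- structure(list(freqs = 10, times = 1, coef = coef,
                       region_labels = c("a", "b"), subject_id = "toy"),
                  class = "epoch_spectra")
  W <- wpli_matrix(sp)
  expect_equal(W["a", "b"], 0.5)  # |2 - 1 + 1| / (2 + 1 + 1)
})

test_that("constant quarter-cycle lag gives WPLI 1; zero lag gives 0", {
  W <- band_connectivity(sinusoid_ts(20, 10, lag_s = 0.025), band_preset("alpha"))
  expect_equal(W[1, 2], 1, tolerance = 1e-9)
  W0 <- band_connectivity(sinusoid_ts(20, 10, lag_s = 0), band_preset("alpha"))
  expect_equal(W0[1, 2], 0)
  expect_gt(attr(W0, "n_zero_denom"), 0)  # vanishing-denominator convention
})

test_that("wpli_matrix matches the brute-force oracle on random spectra", {
  set.seed(5)
  for (k in 1:40) {
    d <- c(sample(2:6, 1), sample(2:4, 1), sample(1:3, 1), sample(1:2, 1))
    coef <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
    sp <- structure(list(freqs = seq_len(d[3]), times = seq_len(d[4]),
                         coef = coef,
                         region_labels = sprintf("r%d", seq_len(d[2])),
                         subject_id = "x"),
                    class = "epoch_spectra")
    W <- wpli_matrix(sp)
    expect_equal(unclass(W), oracle_wpli(coef), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("WPLI outputs are symmetric, zero-diagonal, and inside [0, 1]", {
  set.seed(6)
  data <- array(rnorm(5 * 3 * 512), c(5, 3, 512))
  W <- band_connectivity(epoched_ts(data, 256), band_preset("alpha"))
  expect_equal(unclass(W), t(unclass(W)), ignore_attr = TRUE)
  expect_equal(diag(W), setNames(rep(0, 3), rownames(W)))
  expect_true(all(W >= 0 & W <= 1))
  expect_error(wpli_matrix(windowed_fourier(
    epoched_ts(array(rnorm(512 * 2), c(1, 2, 512)), 256),
    band_preset("alpha"))), "at least 2 epochs")
})

test_that("WPLI is invariant to single-region amplitude rescaling", {
  set.seed(8)
  data <- array(rnorm(6 * 3 * 512), c(6, 3, 512))
  W1 <- band_connectivity(epoched_ts(data, 256), band_preset("alpha"))
  data[, 2, ] <- data[, 2, ] * 40
  W2 <- band_connectivity(epoched_ts(data, 256), band_preset("alpha"))
  expect_equal(unclass(W1), unclass(W2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-lag common signal does not inflate WPLI beyond baseline noise", {
  set.seed(9)
  diffs <- replicate(20, {
    t <- seq(0, 1 - 1 / 256, by = 1 / 256)
    base <- array(rnorm(8 * 2 * length(t)), c(8, 2, length(t)))
    W_base <- band_connectivity(epoched_ts(base, 256), band_preset("alpha"))[1, 2]
    withcommon <- base
    for (e in 1:8) {
      common <- 3 * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
      withcommon[e, 1, ] <- withcommon[e, 1, ] + common
      withcommon[e, 2, ] <- withcommon[e, 2, ] + common
    }
    W_c <- band_connectivity(epoched_ts(withcommon, 256), band_preset("alpha"))[1, 2]
    W_c - W_base
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("WPLI on a consistent-lag pair concentrates near 1 as epochs grow", {
  # The plain (non-debiased) estimator is biased towards 1 in small samples,
  # so the mean does not rise with the epoch count; what consistency buys is
  # concentration: replicate spread shrinks and the estimate stays high.
  set.seed(10)
  t <- seq(0, 2 - 1 / 256, by = 1 / 256)
  make <- function(n_ep, noise) {
    data <- array(0, c(n_ep, 2, length(t)))
    for (e in seq_len(n_ep)) {
      ph <- runif(1, 0, 2 * pi)
      data[e, 1, ] <- sin(2 * pi * 10 * t + ph) + noise * rnorm(length(t))
      data[e, 2, ] <- sin(2 * pi * 10 * t + ph - pi / 2) +
        noise * rnorm(length(t))
    }
    band_connectivity(epoched_ts(data, 256), band_preset("alpha"))[1, 2]
  }
  reps <- lapply(c(5, 20, 80), function(n_ep) replicate(6, make(n_ep, 0.8)))
  means <- vapply(reps, mean, numeric(1))
  sds <- vapply(reps, sd, numeric(1))
  expect_true(all(means > 0.75))
  expect_lt(sds[3], sds[1])          # concentration with more epochs
  # near-noiseless consistent lag: WPLI pinned at 1 for any epoch count
  expect_gt(make(5, 0.01), 0.999)
  expect_gt(make(40, 0.01), 0.999)
})

test_that("mean component connectivity averages listed edges once", {
  W <- connectivity_matrix(matrix(c(0, .3, .2, .3, 0, .4, .2, .4, 0), 3),
                           c("a", "b", "c"))
  expect_equal(mean_component_connectivity(W, rbind(c("a", "b"))), 0.3)
  expect_equal(mean_component_connectivity(W, rbind(c(1, 2), c(2, 3))), 0.35)
  expect_error(mean_component_connectivity(W, matrix(0, 0, 2)), "empty")
  U <- connectivity_matrix(matrix(0.25, 3, 3) - diag(0.25, 3), c("a", "b", "c"))
  expect_equal(mean_component_connectivity(U, rbind(c(1, 3), c(1, 2))), 0.25)
})
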