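# Band-limited WPLI connectivity from epoched region-level time series.
#
# Estimation path: sliding tapered Fourier windows per analysis frequency
# (window length = cycles(f)/f with the cycle count ramping linearly across
# the band), cross-spectra per epoch and time-frequency bin, the weighted
# phase lag index per bin as |E_epochs[Im X]| / E_epochs[|Im X|], and finally
# an average over all time-frequency bins -> one connectivity matrix per
# subject.

#' Frequency-band specification
#'
#' Defines the analysis grid for windowed Fourier estimation: frequencies
#' from `f_lo` to `f_hi` in steps of `f_step`, with an adaptive window of
#' `cycles(f)/f` seconds where the cycle count ramps linearly from
#' `cycles_lo` at `f_lo` to `cycles_hi` at `f_hi`.
#'
#' @param name band name (e.g. `"alpha"`).
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @param f_step frequency step in Hz (default 0.5).
#' @param cycles_lo,cycles_hi window width in cycles at the band edges
#'   (defaults 3 and 10).
#' @return an object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 13.5)
#' @export
band_spec <- function(name, f_lo, f_hi, f_step = 0.5,
                      cycles_lo = 3, cycles_hi = 10) {
  stopifnot(f_lo > 0, f_hi > f_lo, f_step > 0, cycles_lo <= cycles_hi)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi, f_step = f_step,
                 cycles_lo = cycles_lo, cycles_hi = cycles_hi),
            class = "band_spec")
}

#' Preset analysis bands
#'
#' The three bands used by the pipeline: alpha 8-13.5 Hz (primary),
#' theta 4.6-7 Hz and beta 15-20 Hz (exploratory).
#'
#' @param name one of `"alpha"`, `"theta"`, `"beta"`.
#' @return a [band_spec].
#' @export
band_preset <- function(name = c("alpha", "theta", "beta")) {
  name <- match.arg(name)
  switch(name,
         alpha = band_spec("alpha", 8, 13.5),
         theta = band_spec("theta", 4.6, 7),
         beta  = band_spec("beta", 15, 20))
}

band_freqs <- function(band) seq(band$f_lo, band$f_hi, by = band$f_step)

band_cycles <- function(band, f) {
  if (band$f_hi == band$f_lo) return(rep(band$cycles_lo, length(f)))
  band$cycles_lo + (band$cycles_hi - band$cycles_lo) *
    (f - band$f_lo) / (band$f_hi - band$f_lo)
}

#' Epoched region-level time series
#'
#' @param data numeric array `n_epochs x n_regions x n_samples`, all finite.
#' @param fs sampling rate in Hz.
#' @param region_labels character vector, one label per region.
#' @param subject_id subject identifier.
#' @return an object of class `epoched_ts`.
#' @export
epoched_ts <- function(data, fs, region_labels = NULL, subject_id = "subject") {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  if (is.null(region_labels))
    region_labels <- sprintf("r%03d", seq_len(dim(data)[2]))
  if (length(region_labels) != dim(data)[2])
    stop("region_labels length must match the region dimension")
  if (!all(is.finite(data))) stop("non-finite values in time series")
  structure(list(subject_id = subject_id, region_labels = region_labels,
                 fs = fs, data = data),
            class = "epoched_ts")
}

#' @export
print.epoched_ts <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoched_ts '%s': %d epochs x %d regions x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Sliding-window Fourier coefficients on a band grid
#'
#' Computes Hann-tapered Fourier coefficients at each analysis frequency of
#' `band`, using a window of `cycles(f)/f` seconds. Window centres are placed
#' on a common grid (spacing `hop` seconds) chosen so every window fits at
#' every frequency, so time bins are aligned across regions and frequencies.
#'
#' @param ts an [epoched_ts].
#' @param band a [band_spec]; `fs` must exceed twice `f_hi` (Nyquist).
#' @param hop spacing of window centres in seconds (default 0.25).
#' @return an `epoch_spectra` object: `freqs`, `times` (window centres, s),
#'   `coef` (complex array `epochs x regions x freqs x times`), and
#'   `region_labels`.
#' @export
windowed_fourier <- function(ts, band, hop = 0.25) {
  stopifnot(inherits(ts, "epoched_ts"), inherits(band, "band_spec"))
  fs <- ts$fs
  if (fs <= 2 * band$f_hi)
    stop(sprintf("sampling rate %g Hz violates Nyquist for f_hi = %g Hz",
                 fs, band$f_hi))
  d <- dim(ts$data)
  n_epochs <- d[1]; n_regions <- d[2]; n_samples <- d[3]
  freqs <- band_freqs(band)
  cycles <- band_cycles(band, freqs)
  win_len <- pmax(3L, round(cycles / freqs * fs))        # samples per window
  half <- floor(win_len / 2)
  max_half <- max(half)
  min_len_s <- max(cycles / freqs)
  if (n_samples < max(win_len))
    stop(sprintf(
      "epoch too short: need at least %.3f s (%d samples) for the %g Hz window",
      min_len_s, max(win_len), freqs[which.max(win_len)]))
  hop_samp <- max(1L, round(hop * fs))
  centres <- seq(max_half + 1L, n_samples - max_half, by = hop_samp)
  if (length(centres) == 0)
    stop(sprintf(
      "epoch too short for any window centre: need at least %.3f s", min_len_s))
  n_freqs <- length(freqs); n_times <- length(centres)
  coef <- array(complex(real = 0), dim = c(n_epochs, n_regions, n_freqs, n_times))
  # Flatten epochs x regions once; per frequency a single real matmul pair.
  flat <- matrix(aperm(ts$data, c(3, 1, 2)), nrow = n_samples)  # samples x (epoch*region)
  for (fi in seq_len(n_freqs)) {
    nw <- win_len[fi]
    h <- half[fi]
    taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))  # Hann
    taper <- taper / sum(taper)   # amplitude-normalised across window widths
    offs <- seq(-h, length.out = nw)
    t_rel <- offs / fs
    bc <- taper * cos(2 * pi * freqs[fi] * t_rel)
    bs <- taper * sin(2 * pi * freqs[fi] * t_rel)
    Bre <- matrix(0, n_samples, n_times)
    Bim <- matrix(0, n_samples, n_times)
    for (ti in seq_len(n_times)) {
      rows <- centres[ti] + offs
      Bre[rows, ti] <- bc
      Bim[rows, ti] <- bs
    }
    cre <- crossprod(flat, Bre)    # (epoch*region) x times
    cim <- -crossprod(flat, Bim)   # e^{-i 2 pi f t}
    coef[, , fi, ] <- array(complex(real = cre, imaginary = cim),
                            dim = c(n_epochs, n_regions, n_times))
  }
  structure(list(freqs = freqs, times = centres / fs, coef = coef,
                 region_labels = ts$region_labels,
                 subject_id = ts$subject_id),
            class = "epoch_spectra")
}

#' Symmetric connectivity matrix container
#'
#' @param W symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1]`.
#' @param region_labels node labels (defaults to rownames of `W`).
#' @param ... attributes stored on the object (diagnostics).
#' @return an object of class `connectivity_matrix` (a labelled matrix).
#' @export
connectivity_matrix <- function(W, region_labels = rownames(W), ...) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (is.null(region_labels)) region_labels <- sprintf("r%03d", seq_len(n))
  if (ncol(W) != n) stop("W must be square")
  if (!all(is.finite(W))) stop("non-finite connectivity values")
  if (max(abs(W - t(W))) > 1e-8) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("diagonal must be exactly 0")
  if (min(W) < -1e-12 || max(W) > 1 + 1e-12)
    stop("connectivity values must lie in [0, 1]")
  W <- (W + t(W)) / 2
  W[W < 0] <- 0; W[W > 1] <- 1
  dimnames(W) <- list(region_labels, region_labels)
  extra <- list(...)
  for (nm in names(extra)) attr(W, nm) <- extra[[nm]]
  class(W) <- c("connectivity_matrix", "matrix")
  W
}

#' Weighted phase lag index from epoch spectra
#'
#' Per region pair and time-frequency bin,
#' \eqn{\mathrm{WPLI} = |E_e[\mathrm{Im}\,X]| \,/\, E_e[|\mathrm{Im}\,X|]}
#' where \eqn{X} is the cross-spectrum and the expectation runs over epochs;
#' bins are then averaged into a single matrix. A bin whose denominator is
#' below `tol` (purely real cross-spectrum, i.e. zero-lag synchrony) is
#' assigned 0 and counted in the `n_zero_denom` attribute.
#'
#' @param spectra an `epoch_spectra` from [windowed_fourier()] with at least
#'   2 epochs.
#' @param tol vanishing-denominator tolerance (default 1e-12).
#' @return a [connectivity_matrix] with attribute `n_zero_denom` (count of
#'   off-diagonal pair-bin combinations hitting the convention).
#' @export
wpli_matrix <- function(spectra, tol = 1e-12) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  dims <- dim(spectra$coef)
  n_epochs <- dims[1]; n <- dims[2]; n_freqs <- dims[3]; n_times <- dims[4]
  if (n_epochs < 2)
    stop("WPLI needs at least 2 epochs (expectation across epochs)")
  if (!all(is.finite(Re(spectra$coef))) || !all(is.finite(Im(spectra$coef))))
    stop("non-finite spectral coefficients")
  idx_i <- rep(seq_len(n), times = n)
  idx_j <- rep(seq_len(n), each = n)
  acc <- matrix(0, n, n)
  zero_bins <- 0L
  off_diag <- idx_i != idx_j
  for (fi in seq_len(n_freqs)) {
    for (ti in seq_len(n_times)) {
      A <- spectra$coef[, , fi, ti, drop = TRUE]
      dim(A) <- c(n_epochs, n)
      aRe <- Re(A); aIm <- Im(A)
      # Im(a_i conj(a_j)) summed over epochs, all pairs at once.
      num <- crossprod(aIm, aRe) - crossprod(aRe, aIm)
      imx <- aIm[, idx_i] * aRe[, idx_j] - aRe[, idx_i] * aIm[, idx_j]
      den <- matrix(colSums(abs(imx)), n, n)
      ok <- den > tol * n_epochs
      w <- matrix(0, n, n)
      w[ok] <- abs(num[ok]) / den[ok]
      zero_bins <- zero_bins + sum(!ok & off_diag)
      acc <- acc + w
    }
  }
  W <- acc / (n_freqs * n_times)
  diag(W) <- 0
  connectivity_matrix(W, spectra$region_labels, n_zero_denom = zero_bins)
}

#' Band-limited WPLI connectivity for one subject
#'
#' Composition of [windowed_fourier()] and [wpli_matrix()]: one symmetric
#' zero-diagonal connectivity matrix per subject.
#'
#' @inheritParams windowed_fourier
#' @inheritParams wpli_matrix
#' @return a [connectivity_matrix].
#' @export
band_connectivity <- function(ts, band, hop = 0.25, tol = 1e-12) {
  wpli_matrix(windowed_fourier(ts, band, hop = hop), tol = tol)
}

#' Mean connectivity over an edge set
#'
#' Arithmetic mean of the connectivity weights over the listed undirected
#' edges, each counted once (the WPLI_NBS summary of a subnetwork).
#'
#' @param W a [connectivity_matrix] (or plain symmetric matrix).
#' @param edges 2-column matrix of node indices or labels.
#' @return scalar mean weight.
#' @export
mean_component_connectivity <- function(W, edges) {
  labels <- rownames(W) %||% sprintf("r%03d", seq_len(nrow(W)))
  em <- resolve_edges(edges, labels)
  if (nrow(em) == 0) stop("empty edge list")
  mean(W[cbind(em[, 1], em[, 2])])
}
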