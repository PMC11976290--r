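# Morlet-wavelet time-frequency decomposition of LFP traces, baseline
# z-scoring of power, delay-window spectra with peak selection, and
# assignment of oscillation phase to spike times.
#
# Phase convention (shared by every module): the coefficient argument is 0
# at the peak of a cosine at the wavelet's center frequency, increasing with
# time at 2*pi*f rad/s.

#' The theta-band analysis frequency grid
#'
#' Log-spaced center frequencies spanning the 1.5-8 Hz theta range used for
#' all spike-phase analyses.
#' @return numeric vector of 12 frequencies (Hz).
#' @export
theta_grid <- function() {
  c(1.5, 1.75, 2.03, 2.37, 2.8, 3.2, 3.7, 4.4, 5.1, 5.9, 6.9, 8)
}

# complex Morlet wavelet with c cycles: gaussian envelope sd = c / (2*pi*f),
# truncated at +/- 3.5 sd, L2-normalized up to a real constant (phase and
# relative power are what downstream analyses consume)
morlet_wavelet <- function(f, fs, c = 7) {
  sd_t <- c / (2 * pi * f)
  half <- ceiling(3.5 * sd_t * fs)
  t <- seq(-half, half) / fs
  w <- exp(-t^2 / (2 * sd_t^2)) * exp(1i * 2 * pi * f * t)
  # scale so a unit-amplitude tone at f has |coef| ~ 1
  w / (sum(exp(-t^2 / (2 * sd_t^2))) / 2)
}

# linear cross-correlation of a real signal with a complex kernel via FFT;
# returns the coefficient aligned to each sample of x
xcorr_complex <- function(x, w) {
  n <- length(x); m <- length(w); half <- (m - 1L) / 2L
  L <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, L - n)))
  W <- stats::fft(c(w, rep(0, L - m)))
  full <- stats::fft(X * Conj(W), inverse = TRUE) / L
  # correlation lag 0 at index 1; lags -half..(n-1-half) wrap around
  idx <- ((seq_len(n) - 1L - half) %% L) + 1L
  full[idx]
}

#' Morlet time-frequency decomposition
#'
#' Convolves the trace with complex Morlet wavelets (default c = 7 cycles)
#' at each grid frequency, using reflect padding at the edges plus a
#' validity mask marking samples within half a wavelet support of either
#' edge.
#'
#' @param trace an `lfp_trace` (see [lfp_trace()]) or numeric vector.
#' @param grid center frequencies (Hz); default [theta_grid()].
#' @param c wavelet cycles (default 7).
#' @param fs sampling rate, required when `trace` is a bare vector.
#' @return list of class `spectral_decomposition`: `coef` (complex,
#'   frequency x time), `freq`, `fs`, `t0`, `c`, `valid` (logical,
#'   frequency x time).
#' @export
morlet_transform <- function(trace, grid = theta_grid(), c = 7, fs = NULL) {
  if (inherits(trace, "lfp_trace")) {
    x <- trace$samples; fs <- trace$fs; t0 <- trace$t0
  } else {
    if (is.null(fs)) stop_param("morlet_transform: fs required")
    x <- as.numeric(trace); t0 <- 0
  }
  if (any(grid <= 0) || any(grid >= fs / 2))
    stop_param("morlet_transform: grid frequencies must lie in (0, fs/2)")
  if (is.unsorted(grid, strictly = TRUE))
    stop_param("morlet_transform: grid must be strictly increasing")
  n <- length(x)
  coef <- matrix(0i, length(grid), n)
  valid <- matrix(TRUE, length(grid), n)
  for (k in seq_along(grid)) {
    w <- morlet_wavelet(grid[k], fs, c)
    half <- (length(w) - 1L) / 2L
    if (2L * half + 1L > 2L * n)
      stop_param("morlet_transform: trace shorter than wavelet support at ",
                 grid[k], " Hz")
    pad <- pmin(half, n - 1L)
    xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
    co <- xcorr_complex(xp, w)[pad + seq_len(n)]
    coef[k, ] <- co
    if (half >= 1L) {
      bad <- seq_len(min(half, n))
      valid[k, bad] <- FALSE
      valid[k, n + 1L - bad] <- FALSE
    }
  }
  structure(list(coef = coef, freq = grid, fs = fs, t0 = t0, c = c,
                 valid = valid),
            class = "spectral_decomposition")
}

#' Instantaneous power from a decomposition
#' @param dec a `spectral_decomposition`.
#' @return matrix (frequency x time) of squared coefficient magnitude.
#' @export
power_of <- function(dec) Mod(dec$coef)^2

# sample indices covered by a [from, to) time window
window_index <- function(dec, window) {
  n <- ncol(dec$coef)
  t <- dec$t0 + (seq_len(n) - 1L) / dec$fs
  idx <- which(t >= window[1] & t < window[2])
  if (length(idx) == 0L)
    stop_param("window [", window[1], ", ", window[2], ") outside trace")
  idx
}

#' Z-score power relative to a baseline window
#'
#' Per frequency, subtracts the baseline-window mean and divides by the
#' baseline-window standard deviation, so baseline samples have mean 0 /
#' s.d. 1 by construction.
#'
#' @param dec a `spectral_decomposition`.
#' @param baseline_window c(from, to) in seconds (same clock as the trace).
#' @return matrix (frequency x time) of z-scored power.
#' @export
zscore_power <- function(dec, baseline_window) {
  P <- power_of(dec)
  idx <- window_index(dec, baseline_window)
  mu <- rowMeans(P[, idx, drop = FALSE])
  sd_ <- apply(P[, idx, drop = FALSE], 1L, stats::sd)
  if (any(sd_ <= 0))
    stop_param("zscore_power: zero baseline variance at some frequency")
  (P - mu) / sd_
}

#' Delay-window spectrum and peak frequency
#'
#' Averages z-scored power over the window ending at probe onset (default
#' the last 1.5 s before it) and selects the peak frequency, optionally
#' within a band; exact ties break toward the lowest frequency.
#'
#' @param dec a `spectral_decomposition`.
#' @param probe_on probe onset time (s).
#' @param baseline_window c(from, to) baseline for z-scoring.
#' @param window_pre_probe window length before probe onset (s, default 1.5).
#' @param band optional c(lo, hi) restricting peak selection (Hz).
#' @return list with `spectrum` (per grid frequency), `peak_freq`,
#'   `peak_value`.
#' @export
delay_spectrum <- function(dec, probe_on, baseline_window,
                           window_pre_probe = 1.5, band = NULL) {
  Z <- zscore_power(dec, baseline_window)
  idx <- window_index(dec, c(probe_on - window_pre_probe, probe_on))
  spec <- rowMeans(Z[, idx, drop = FALSE])
  sel <- if (is.null(band)) seq_along(dec$freq)
         else which(dec$freq >= band[1] & dec$freq <= band[2])
  if (length(sel) == 0L) stop_param("delay_spectrum: empty band")
  k <- sel[which.max(spec[sel])]   # which.max returns first max: lowest freq
  list(spectrum = stats::setNames(spec, dec$freq),
       peak_freq = dec$freq[k], peak_value = spec[k])
}

#' Oscillation phase at spike times
#'
#' Looks up the coefficient argument at the sample nearest each spike time
#' (at 1 kHz and <= 8 Hz the discretization error is < 3 degrees). Spikes
#' outside the window or in invalid edge margins are excluded and counted.
#'
#' @param spike_times spike times (s, same clock as the trace).
#' @param dec a `spectral_decomposition`.
#' @param frequency one frequency from the grid (Hz).
#' @param window optional c(from, to) restricting spikes (s).
#' @return list with `phases` (radians in `[0, 2*pi)`), `n_excluded`,
#'   `spike_times` (the retained times).
#' @export
spike_phases <- function(spike_times, dec, frequency, window = NULL) {
  k <- match(frequency, dec$freq)
  if (is.na(k)) stop_param("spike_phases: frequency not in grid")
  n <- ncol(dec$coef)
  keep <- rep(TRUE, length(spike_times))
  if (!is.null(window))
    keep <- spike_times >= window[1] & spike_times < window[2]
  idx <- round((spike_times - dec$t0) * dec$fs) + 1L
  inside <- idx >= 1L & idx <= n
  ok <- keep & inside
  ok[ok] <- dec$valid[k, idx[ok]]
  list(phases = wrap_angle(Arg(dec$coef[k, idx[ok]])),
       n_excluded = sum(!ok), spike_times = spike_times[ok])
}
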