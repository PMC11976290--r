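# Synthetic LFP: 1/f-like background noise plus a theta-band sinusoid
# whose amplitude is boosted during the delay window, emulating the
# sustained theta power increase seen during memory maintenance.

#' Construct an LFP trace
#' @param samples numeric vector.
#' @param fs sampling rate (Hz, > 0).
#' @param t0 time of the first sample (s, default 0).
#' @param channel_id,trial_id identifiers.
#' @return list of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs, t0 = 0, channel_id = 1L, trial_id = NA) {
  if (fs <= 0) stop_param("lfp_trace: fs must be > 0")
  if (any(!is.finite(samples))) stop_param("lfp_trace: non-finite samples")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0,
                 channel_id = channel_id, trial_id = trial_id),
            class = "lfp_trace")
}

# 1/f^exponent noise via spectral shaping of white Gaussian noise
pink_noise <- function(n, exponent = 1) {
  if (n < 2L) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1L))                 # avoid DC blowup
  fold <- pmin(f, n - f + 1)
  X <- X * fold^(-exponent / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate per-trial LFP traces
#'
#' Each trace is background 1/f noise plus a theta cosine whose amplitude
#' is multiplied by `delay_power_boost` inside the trial's delay window.
#' Each trial gets an independent uniform theta phase offset, recorded in
#' the trace (`theta_phase0`) so the generator's spike module can lock to
#' the true phase.
#'
#' @param trials a `trial_table`.
#' @param theta_freq theta frequency (Hz), must lie below fs/2.
#' @param delay_power_boost amplitude multiplier during delay (1 = no
#'   boost; default 3).
#' @param noise_spectrum_params list(amp, exponent) of the background
#'   (amp = 0 gives a pure tone).
#' @param theta_amp theta amplitude outside the delay (default 1).
#' @param fs sampling rate (Hz, default 1000).
#' @param seed integer seed.
#' @param post_probe extra time simulated after probe onset (s, default 0.5).
#' @return list of `lfp_trace`, one per trial.
#' @export
generate_lfp <- function(trials, theta_freq = 2.8, delay_power_boost = 3,
                         noise_spectrum_params = list(amp = 1, exponent = 1),
                         theta_amp = 1, fs = 1000, seed = 1L,
                         post_probe = 0.5) {
  if (theta_freq <= 0 || theta_freq >= fs / 2)
    stop_param("generate_lfp: theta_freq must lie in (0, fs/2)")
  amp <- noise_spectrum_params$amp
  expo <- if (is.null(noise_spectrum_params$exponent)) 1
          else noise_spectrum_params$exponent
  with_seed(substream_seed(seed, "lfp"), {
    lapply(seq_len(nrow(trials)), function(i) {
      t_end <- trials$probe_on[i] + post_probe
      n <- ceiling(t_end * fs)
      t <- (seq_len(n) - 1L) / fs
      phi0 <- stats::runif(1, 0, 2 * pi)
      a <- theta_amp *
        ifelse(t >= trials$delay_on[i] & t < trials$probe_on[i],
               delay_power_boost, 1)
      x <- a * cos(2 * pi * theta_freq * t + phi0)
      if (amp > 0) x <- x + amp * pink_noise(n, expo)
      tr <- lfp_trace(x, fs = fs, t0 = 0, trial_id = trials$trial_id[i])
      tr$theta_phase0 <- phi0
      tr$theta_freq <- theta_freq
      tr
    })
  })
}
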