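test_that("Morlet transform recovers a pure tone: peak frequency, phase
          ramp, and quadratic power scaling", {
  fs <- 500; t <- (0:4999) / fs
  x <- cos(2 * pi * 2.8 * t)
  dec <- morlet_transform(x, fs = fs)
  P <- power_of(dec)

  pm <- vapply(seq_along(dec$freq), function(k)
    mean(P[k, dec$valid[k, ]]), numeric(1))
  expect_equal(dec$freq[which.max(pm)], 2.8)

  # unwrapped phase advances at 2*pi*f rad/s within 1%
  k <- match(2.8, dec$freq)
  ph <- Arg(dec$coef[k, dec$valid[k, ]])
  dph <- atan2(sin(diff(ph)), cos(diff(ph)))
  slope <- mean(dph) * fs
  expect_lt(abs(slope - 2 * pi * 2.8) / (2 * pi * 2.8), 0.01)

  dec2 <- morlet_transform(3 * x, fs = fs)
  expect_equal(mean(power_of(dec2)[k, dec$valid[k, ]]) /
                 mean(P[k, dec$valid[k, ]]), 9, tolerance = 1e-6)

  # zero signal -> zero power
  z <- morlet_transform(rep(0, 2000), fs = fs)
  expect_true(all(power_of(z) == 0))
})

test_that("transform validates inputs", {
  expect_error(morlet_transform(rnorm(100), grid = c(2, 300), fs = 500),
               "fs/2")
  expect_error(morlet_transform(rnorm(50), grid = c(1.5), fs = 500),
               "support")
})

test_that("z-scored power is 0/1 on the baseline by construction and flags
          planted delay boosts", {
  set.seed(41)
  s <- small_session(delay_power_boost = 3)
  dec <- morlet_transform(s$lfp[[1]])
  bl <- c(0, 1)
  Z <- zscore_power(dec, bl)
  idx <- seqphase:::window_index(dec, bl)
  expect_equal(max(abs(rowMeans(Z[, idx]))), 0, tolerance = 1e-10)
  sds <- apply(Z[, idx], 1, sd)
  expect_equal(sds, rep(1, length(sds)), tolerance = 1e-10)

  ds <- delay_spectrum(dec, probe_on = s$trials$probe_on[1],
                       baseline_window = bl)
  expect_equal(ds$peak_freq, 2.8)
  expect_gt(ds$peak_value, 1)
})

test_that("no planted boost leaves delay z-power near zero on average", {
  cfg <- default_session_config(n_trials = 24L, n_units = 1L, fs = 250,
                                delay_power_boost = 1)
  s <- generate_session(cfg, seed = 3)
  zs <- vapply(seq_len(24), function(i) {
    dec <- morlet_transform(s$lfp[[i]])
    ds <- delay_spectrum(dec, probe_on = s$trials$probe_on[i],
                         baseline_window = c(0, 1))
    k <- match(2.8, theta_grid())
    ds$spectrum[k]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 1)  # centered near 0 across trials
})

test_that("flat spectra break peak ties toward the lowest frequency", {
  set.seed(42)
  # white-noise trace: no systematic peak; determinism of the tie rule is
  # what matters (which.max takes the first = lowest frequency on ties)
  x <- rnorm(3000)
  dec <- morlet_transform(x, fs = 250)
  Z <- zscore_power(dec, c(0, 4))
  spec <- rowMeans(Z)
  spec[] <- 1  # force an exact tie
  expect_equal(dec$freq[which.max(spec)], dec$freq[1])
})

test_that("spike phases follow the documented cosine convention and recover
          planted von Mises locking", {
  fs <- 250; f <- 2.8
  t <- (0:2499) / fs
  dec <- morlet_transform(cos(2 * pi * f * t), fs = fs)

  # spikes at cosine peaks (t = k/f) -> phase 0
  peaks <- (6:24) / f
  sp <- spike_phases(peaks, dec, f)
  cm <- circular_mean(sp$phases)
  expect_gt(cm$R, 0.99)
  expect_lt(min(cm$mean, 2 * pi - cm$mean) * 180 / pi, 3)

  # uniformly timed spikes -> near-uniform phases
  sp_u <- spike_phases(seq(1, 9, by = 0.103), dec, f)
  expect_lt(circular_mean(sp_u$phases)$R, 0.15)

  # spikes planted at a von Mises phase offset are recovered within 10 deg
  set.seed(43)
  ph_target <- rvonmises(300, pi / 2, 2)
  # convert phases to times on the tone: t = phase / (2 pi f) + k/f
  times <- ph_target / (2 * pi * f) + sample(2:20, 300, TRUE) / f
  sp_v <- spike_phases(times, dec, f)
  err <- atan2(sin(circular_mean(sp_v$phases)$mean - pi / 2),
               cos(circular_mean(sp_v$phases)$mean - pi / 2))
  expect_lt(abs(err) * 180 / pi, 10)

  # out-of-range spikes are excluded and counted (the trace is 10 s and
  # the wavelet edge margin at 2.8 Hz is ~1.4 s)
  sp_x <- spike_phases(c(-5, 3, 4, 1e4), dec, f)
  expect_equal(sp_x$n_excluded, 2L)
})
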