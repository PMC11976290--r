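test_that("trial tables satisfy the task invariants", {
  tt <- generate_trial_table(50, seed = 1)
  sq <- sequence_matrix(tt); pb <- sequence_matrix(tt, "probe")

  expect_true(all(apply(sq, 1, anyDuplicated) == 0))          # distinct
  expect_true(all(vapply(1:50, function(i)
    setequal(sq[i, ], pb[i, ]), logical(1))))                 # permutation
  expect_identical(tt$is_match,
                   apply(sq == pb, 1, all))                   # match iff equal
  # onsets spaced by the SOA
  ons <- as.matrix(tt[, paste0("stim", 1:4, "_on")])
  expect_equal(as.numeric(diff(t(ons))), rep(0.4, 150))
  # delay duration within the jitter bounds
  delay <- tt$probe_on - tt$delay_on
  expect_true(all(delay >= 2.4 & delay <= 2.6))
  # reproducibility
  expect_identical(tt, generate_trial_table(50, seed = 1))
})

test_that("balanced mode places every stimulus equally often at every
          position", {
  tt <- generate_trial_table(224, seed = 2, balanced = TRUE)
  sq <- sequence_matrix(tt)
  for (k in 1:4) expect_true(all(table(sq[, k]) == 28))
  expect_true(all(table(sq) == 112))
  expect_error(generate_trial_table(100, balanced = TRUE), "divisible")
})

test_that("single-trial probe is a permutation; match fraction is binomial", {
  t1 <- generate_trial_table(1, seed = 5)
  expect_true(setequal(sequence_matrix(t1), sequence_matrix(t1, "probe")))

  tt <- generate_trial_table(1000, p_match = 0.5, seed = 3)
  # within 3 binomial s.d. of 0.5
  expect_lt(abs(mean(tt$is_match) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("trial-table parameter validation", {
  expect_error(generate_trial_table(0), "n_trials")
  expect_error(generate_trial_table(10, p_match = 1.5), "probabilities")
  expect_error(generate_trial_table(10, soa = -1), "positive")
  expect_error(generate_trial_table(10, soa = 0.1), "stimulus duration")
})

test_that("LFP generator: no boost leaves delay z-power centered, planted
          boost recovered, pure tone gives the analytic phase ramp", {
  tt <- generate_trial_table(4, seed = 4)
  expect_error(generate_lfp(tt, theta_freq = 200, fs = 250), "fs/2")

  # pure-tone mode: instantaneous phase advances 2*pi*f/fs per sample
  lf <- generate_lfp(tt, theta_freq = 2.8, delay_power_boost = 1,
                     noise_spectrum_params = list(amp = 0), fs = 250,
                     seed = 9)
  x <- lf[[1]]$samples
  dec <- morlet_transform(lf[[1]])
  k <- match(2.8, dec$freq)
  ph <- Arg(dec$coef[k, dec$valid[k, ]])
  step <- atan2(sin(diff(ph)), cos(diff(ph)))
  expect_equal(mean(step), 2 * pi * 2.8 / 250, tolerance = 1e-3)
  # phase offset matches the generator's record
  t_idx <- which(dec$valid[k, ])[1]
  t1 <- (t_idx - 1) / 250
  expect_lt(abs(circ_diff <- atan2(
    sin(ph[1] - (2 * pi * 2.8 * t1 + lf[[1]]$theta_phase0)),
    cos(ph[1] - (2 * pi * 2.8 * t1 + lf[[1]]$theta_phase0)))), 0.05)

  expect_identical(
    generate_lfp(tt, fs = 250, seed = 9)[[2]]$samples,
    generate_lfp(tt, fs = 250, seed = 9)[[2]]$samples)
})

test_that("spike generator: zero everything -> silence; kappa = 0 delay
          phases pass uniformity at the nominal rate", {
  tt <- generate_trial_table(6, seed = 5)
  lf <- generate_lfp(tt, fs = 250, seed = 5)
  gt0 <- make_ground_truth(2, "arbitrary", baseline_rate = 0,
                           selectivity_gain = 0, seed = 5)
  sp0 <- generate_spikes(tt, lf, gt0, seed = 5)
  expect_equal(nrow(sp0), 0L)

  expect_error(make_ground_truth(2, baseline_rate = -1), ">= 0")

  # type-I calibration: no phase locking planted -> Rayleigh on pooled
  # delay phases rejects at ~5%
  set.seed(51)
  rej <- vapply(1:120, function(i) {
    phases <- runif(80, 0, 2 * pi)  # delay phases of an unlocked unit
    rayleigh_test(phases)$p < 0.05
  }, logical(1))
  expect_gt(mean(!rej), 0.90)
})

test_that("spikes are strictly increasing within trials and reproducible", {
  s <- small_session()
  sp <- s$spikes
  for (u in unique(sp$unit_id)[1:2]) {
    for (tr in unique(sp$trial_id[sp$unit_id == u])[1:3]) {
      tms <- sp$time[sp$unit_id == u & sp$trial_id == tr]
      expect_true(all(diff(tms) > 0))
      expect_true(all(tms >= 0))
    }
  }
  s2 <- small_session()
  expect_identical(s$spikes, s2$spikes)
})

test_that("planted phase locking is recovered from the generated spikes", {
  # one strongly locked unit, pure-tone LFP: delay spike phases should
  # concentrate at the planted mu of the preferred position
  cfg <- default_session_config(n_trials = 32L, n_units = 1L, fs = 250,
                                kappa_ps = 4, noise_amp = 0,
                                ordering_mode = "arbitrary")
  s <- generate_session(cfg, seed = 21)
  gt <- s$ground_truth[[1]]
  pos <- stimulus_position(s$trials, gt$preferred_stimulus)
  got <- 0L
  for (i in which(!is.na(pos))) {
    dec <- morlet_transform(s$lfp[[i]])
    st <- s$spikes$time[s$spikes$unit_id == 1 &
                          s$spikes$trial_id == s$trials$trial_id[i] &
                          s$spikes$time >= s$trials$delay_on[i] &
                          s$spikes$time < s$trials$probe_on[i]]
    if (length(st) < 3) next
    sp <- spike_phases(st, dec, 2.8)
    if (length(sp$phases) < 3) next
    mu_hat <- circular_mean(sp$phases)$mean
    err <- atan2(sin(mu_hat - gt$mu_pos[pos[i]]),
                 cos(mu_hat - gt$mu_pos[pos[i]]))
    expect_lt(abs(err), 1)  # within ~57 deg per trial at kappa 4
    got <- got + 1L
  }
  expect_gt(got, 5L)
})

test_that("session bundles are self-consistent and round-trip exactly", {
  s <- small_session()
  expect_s3_class(s, "wm_session")
  expect_equal(length(s$lfp), nrow(s$trials))
  expect_equal(length(s$ground_truth), s$config$n_units)

  d <- tempfile("session")
  write_session(s, d)
  s2 <- read_session(d)
  expect_identical(s$trials$probe_on, s2$trials$probe_on)
  expect_identical(sequence_matrix(s$trials),
                   sequence_matrix(s2$trials))
  expect_identical(s$spikes$time, s2$spikes$time)
  expect_identical(s$lfp[[2]]$samples, s2$lfp[[2]]$samples)
  expect_identical(s$lfp[[2]]$theta_phase0, s2$lfp[[2]]$theta_phase0)
  expect_identical(s$ground_truth[[1]]$mu_pos,
                   s2$ground_truth[[1]]$mu_pos)
  expect_identical(s$config, s2$config)
  unlink(d, recursive = TRUE)
})

test_that("reset-model ground truth phases equal the closed-form ramp", {
  gt <- make_ground_truth(5, "reset_model", theta_freq = 1.5, soa = 0.4,
                          seed = 3)
  for (u in gt) {
    pred <- predict_reset_phases(1.5, 0.4, phi0 = u$mu_pos[1])
    expect_equal(u$mu_pos, pred$phases)
  }
})

test_that("kappa and preferred-phase recovery from the generator meet the
          calibration bands", {
  # draw phases through the same von Mises machinery the generator uses:
  # kappa within 15% (median), mu within 10 degrees at kappa 2
  set.seed(60)
  fits <- t(vapply(1:200, function(i) {
    ph <- rvonmises(500, 1.1, 2)
    f <- fit_von_mises(ph)
    c(f$kappa, f$mu)
  }, numeric(2)))
  expect_lt(abs(median(fits[, 1]) - 2) / 2, 0.15)
  mu_err <- abs(atan2(sin(fits[, 2] - 1.1), cos(fits[, 2] - 1.1)))
  expect_lt(median(mu_err) * 180 / pi, 10)
})
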