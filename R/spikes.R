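# Spike generation: inhomogeneous Poisson by thinning with rate
#   r(t) = r_base * g_stim(t) * exp(kappa(t) * cos(theta(t) - mu(t))) / I0(kappa)
# The von Mises factor is normalized by I0(kappa) so the mean rate over a
# cycle does not depend on kappa: phase coding is planted without a rate
# confound, matching the empirical picture of phase effects with flat delay
# rates across positions.

#' Ground truth for a population of synthetic units
#'
#' Defines, per unit, the preferred stimulus, rate parameters (baseline,
#' selectivity gain, primacy gradient over encoding positions) and delay
#' phase-locking parameters (kappa and preferred phase per position of the
#' preferred stimulus). The preferred phases follow `ordering_mode`:
#' `"forward"` / `"reverse"` place positions at ascending / descending
#' phases (step `phase_step`), `"arbitrary"` draws them uniformly, and
#' `"reset_model"` takes them from [predict_reset_phases()] at the unit's
#' theta frequency and the task SOA.
#'
#' @param n_units number of units.
#' @param ordering_mode one of forward, reverse, arbitrary, reset_model.
#' @param theta_freq theta frequency (Hz); scalar or per unit.
#' @param soa task SOA (s), used by reset_model mode.
#' @param kappa_ps delay concentration on preferred-stimulus trials
#'   (scalar or length 4; default 2).
#' @param kappa_nps delay concentration on trials without the preferred
#'   stimulus (free parameter; default 0.5).
#' @param baseline_rate baseline firing rate (Hz, default 3).
#' @param selectivity_gain evoked multiplicative gain at the preferred
#'   stimulus (default 4).
#' @param primacy evoked-gain multipliers for encoding positions 1-4
#'   (default c(1, 0.85, 0.7, 0.55), a primacy gradient).
#' @param phase_step phase separation between adjacent positions for
#'   forward/reverse modes (radians, default 40 degrees).
#' @param seed integer seed.
#' @return data-frame-free list of class `ground_truth`; one element per
#'   unit.
#' @export
make_ground_truth <- function(n_units, ordering_mode = c("forward", "reverse",
                                                         "arbitrary",
                                                         "reset_model"),
                              theta_freq = 2.8, soa = 0.4, kappa_ps = 2,
                              kappa_nps = 0.5, baseline_rate = 3,
                              selectivity_gain = 4,
                              primacy = c(1, 0.85, 0.7, 0.55),
                              phase_step = deg2rad(40), seed = 1L) {
  ordering_mode <- match.arg(ordering_mode)
  if (any(kappa_ps < 0) || kappa_nps < 0)
    stop_param("make_ground_truth: kappa must be >= 0")
  if (baseline_rate < 0 || selectivity_gain < 0 || any(primacy < 0))
    stop_param("make_ground_truth: rates and gains must be >= 0")
  kappa_pos <- if (length(kappa_ps) == 1L) rep(kappa_ps, 4L) else kappa_ps
  tf <- rep(theta_freq, length.out = n_units)
  units <- with_seed(substream_seed(seed, "ground_truth"), {
    lapply(seq_len(n_units), function(u) {
      mu0 <- stats::runif(1, 0, 2 * pi)
      mu_pos <- switch(ordering_mode,
        forward  = wrap_angle(mu0 + (0:3) * phase_step),
        reverse  = wrap_angle(mu0 - (0:3) * phase_step),
        arbitrary = stats::runif(4, 0, 2 * pi),
        reset_model = predict_reset_phases(tf[u], soa, phi0 = mu0)$phases)
      list(unit_id = u,
           preferred_stimulus = sample(0:7, 1L),
           baseline_rate = baseline_rate,
           selectivity_gain = selectivity_gain,
           primacy = primacy,
           kappa_pos = kappa_pos,
           kappa_nps = kappa_nps,
           mu_pos = mu_pos,
           mu_nps = mu0,
           ordering_mode = ordering_mode,
           theta_freq = tf[u])
    })
  })
  structure(units, class = "ground_truth")
}

# instantaneous rate of one unit on one trial, vectorized over times
unit_rate <- function(t, unit, trial, stim_duration) {
  r <- rep(unit$baseline_rate, length(t))
  sq <- unlist(trial[paste0("seq", 1:4)], use.names = FALSE)
  ps_pos <- match(unit$preferred_stimulus, sq)
  # stimulus-evoked gain at the preferred stimulus, scaled by primacy
  if (!is.na(ps_pos)) {
    on <- trial[[paste0("stim", ps_pos, "_on")]]
    win <- t >= on & t < on + stim_duration
    r[win] <- r[win] * (1 + unit$selectivity_gain * unit$primacy[ps_pos])
  }
  # delay-period phase locking
  del <- t >= trial$delay_on & t < trial$probe_on
  if (any(del)) {
    if (!is.na(ps_pos)) {
      kap <- unit$kappa_pos[ps_pos]; mu <- unit$mu_pos[ps_pos]
    } else {
      kap <- unit$kappa_nps; mu <- unit$mu_nps
    }
    if (kap > 0) {
      th <- attr(t, "theta_phase")[del]
      r[del] <- r[del] * exp(kap * cos(th - mu)) / besselI(kap, 0)
    }
  }
  r
}

#' Generate spike trains by Poisson thinning
#'
#' @param trials a `trial_table`.
#' @param lfp list of `lfp_trace` from [generate_lfp()] (provides the true
#'   theta phase each spike is locked to).
#' @param ground_truth a `ground_truth` population.
#' @param seed integer seed.
#' @return data.frame of class `spike_train_set` with `unit_id`,
#'   `trial_id`, `time` (s, strictly increasing within unit x trial).
#' @export
generate_spikes <- function(trials, lfp, ground_truth, seed = 1L) {
  stim_duration <- attr(trials, "stim_duration")
  if (is.null(stim_duration)) stim_duration <- 0.2
  out <- with_seed(substream_seed(seed, "spikes"), {
    res <- vector("list", length(ground_truth) * nrow(trials))
    k <- 0L
    for (unit in ground_truth) {
      # ceiling for thinning: all multiplicative factors at their max
      r_max <- unit$baseline_rate *
        (1 + unit$selectivity_gain * max(unit$primacy)) *
        exp(max(c(unit$kappa_pos, unit$kappa_nps))) /
        besselI(max(c(unit$kappa_pos, unit$kappa_nps)), 0)
      for (i in seq_len(nrow(trials))) {
        trial <- trials[i, ]
        tr <- lfp[[i]]
        t_end <- tr$t0 + length(tr$samples) / tr$fs
        k <- k + 1L
        if (r_max <= 0) next
        n_cand <- stats::rpois(1L, r_max * t_end)
        if (n_cand == 0L) next
        tc <- sort(stats::runif(n_cand, 0, t_end))
        attr(tc, "theta_phase") <-
          2 * pi * tr$theta_freq * tc + tr$theta_phase0
        r <- unit_rate(tc, unit, trial, stim_duration)
        keep <- stats::runif(n_cand) < r / r_max
        if (!any(keep)) next
        res[[k]] <- data.frame(unit_id = unit$unit_id,
                               trial_id = trial$trial_id,
                               time = tc[keep])
      }
    }
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
  })
  if (is.null(out))
    out <- data.frame(unit_id = integer(), trial_id = integer(),
                      time = numeric())
  rownames(out) <- NULL
  class(out) <- c("spike_train_set", "data.frame")
  out
}
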