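# Orchestration: the empirical pipeline chains session generation ->
# spectral phase extraction -> V_ex permutation tests -> order analysis ->
# decoding; the model pipeline chains network building -> training ->
# evaluation -> model phase analysis -> reset-model order prediction.
# Reports are plain lists of data.frames; pass `out_dir` to also write CSV
# and JSON artifacts.

#' Estimate each unit's preferred stimulus from spike counts
#'
#' The preferred stimulus (PS) is the one with the largest mean evoked
#' rate over its presentation windows; responsiveness is a paired Wilcoxon
#' signed-rank test of per-trial stimulus-period versus baseline rates.
#'
#' @param spikes a `spike_train_set`.
#' @param trials a `trial_table`.
#' @param p_threshold responsiveness threshold (default 0.001).
#' @return data.frame with `unit_id`, `preferred`, `p_responsive`,
#'   `responsive`.
#' @export
estimate_preferred_stimulus <- function(spikes, trials,
                                        p_threshold = 0.001) {
  stim_duration <- attr(trials, "stim_duration")
  if (is.null(stim_duration)) stim_duration <- 0.2
  units <- sort(unique(spikes$unit_id))
  sq <- sequence_matrix(trials)
  out <- lapply(units, function(u) {
    su <- spikes[spikes$unit_id == u, ]
    by_tr <- split(su$time, factor(su$trial_id, levels = trials$trial_id))
    base_dur <- trials$stim1_on[1]
    stim_dur_tot <- 4 * stim_duration
    rate_b <- rate_s <- numeric(nrow(trials))
    ev_cnt <- ev_dur <- numeric(8)
    for (i in seq_len(nrow(trials))) {
      tt <- by_tr[[i]]
      rate_b[i] <- sum(tt < trials$stim1_on[i]) / base_dur
      n_stim <- 0
      for (k in 1:4) {
        on <- trials[[paste0("stim", k, "_on")]][i]
        cnt <- sum(tt >= on & tt < on + stim_duration)
        n_stim <- n_stim + cnt
        s <- sq[i, k] + 1L
        ev_cnt[s] <- ev_cnt[s] + cnt
        ev_dur[s] <- ev_dur[s] + stim_duration
      }
      rate_s[i] <- n_stim / stim_dur_tot
    }
    p <- if (all(rate_s == rate_b)) 1 else
      suppressWarnings(stats::wilcox.test(rate_s, rate_b, paired = TRUE,
                                          alternative = "greater")$p.value)
    ev_rate <- ifelse(ev_dur > 0, ev_cnt / ev_dur, -Inf)
    data.frame(unit_id = u, preferred = which.max(ev_rate) - 1L,
               p_responsive = p, responsive = p < p_threshold)
  })
  do.call(rbind, out)
}

#' Per-trial mean phase samples for one unit across the frequency grid
#'
#' For trials whose sequence contains the unit's preferred stimulus, takes
#' the unit's delay-window spikes, assigns each its oscillation phase at
#' each grid frequency, and averages circularly per trial. Trials without
#' delay spikes are excluded (their fraction is reported).
#'
#' @param spikes a `spike_train_set` (one unit's rows are selected).
#' @param unit_id which unit.
#' @param preferred the unit's preferred stimulus id.
#' @param trials a `trial_table`.
#' @param decs list of `spectral_decomposition`, one per trial.
#' @param delay_window_length analysis window ending at probe onset
#'   (s, default 2).
#' @return list with `samples` (list of [phase_sample_set()] per
#'   frequency), `excluded_fraction` (zero-spike PS trials / PS trials).
#' @export
unit_phase_samples <- function(spikes, unit_id, preferred, trials, decs,
                               delay_window_length = 2) {
  su <- spikes[spikes$unit_id == unit_id, ]
  pos <- stimulus_position(trials, preferred)
  ps_trials <- which(!is.na(pos))
  grid <- decs[[1]]$freq
  acc <- lapply(grid, function(f) list(phase = numeric(0),
                                       cond = integer(0),
                                       w = numeric(0)))
  n_zero <- 0L
  for (i in ps_trials) {
    win <- c(max(trials$delay_on[i],
                 trials$probe_on[i] - delay_window_length),
             trials$probe_on[i])
    st <- su$time[su$trial_id == trials$trial_id[i] &
                    su$time >= win[1] & su$time < win[2]]
    if (length(st) == 0L) { n_zero <- n_zero + 1L; next }
    for (k in seq_along(grid)) {
      sp <- spike_phases(st, decs[[i]], grid[k])
      if (length(sp$phases) == 0L) next
      cm <- circular_mean(sp$phases)
      if (cm$undefined) next
      acc[[k]]$phase <- c(acc[[k]]$phase, cm$mean)
      acc[[k]]$cond <- c(acc[[k]]$cond, pos[i])
      acc[[k]]$w <- c(acc[[k]]$w, length(sp$phases))
    }
  }
  samples <- lapply(seq_along(grid), function(k)
    if (length(acc[[k]]$phase) == 0L) NULL
    else phase_sample_set(acc[[k]]$phase, acc[[k]]$cond, weight = acc[[k]]$w,
                          unit_id = unit_id, frequency = grid[k]))
  names(samples) <- as.character(grid)
  list(samples = samples,
       excluded_fraction = if (length(ps_trials)) n_zero /
         length(ps_trials) else NA_real_)
}

#' Run the full empirical pipeline on a synthetic session
#'
#' Chains: session generation, Morlet decomposition per trial, per-unit
#' per-frequency V_ex permutation tests (two-frequency significance rule),
#' phase-order classification at each unit's best-V_ex frequency,
#' reset-model order prediction from that frequency and the task SOA, and
#' position decoding from phase with a label-shuffle null.
#'
#' @param config session config from [default_session_config()].
#' @param seed session seed.
#' @param n_perm V_ex permutations (default 499).
#' @param n_shuffles decoding label shuffles (default 101).
#' @param alpha significance level.
#' @param grid frequency grid (default [theta_grid()]).
#' @param decode logical: run the decoding stage (default TRUE).
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return list of class `empirical_report`: `vex_table`, `unit_summary`,
#'   `order_table`, `order_categories`, `chance`, `decoding`,
#'   `excluded_zero_spike_fraction`, `session_seed`, `config`.
#' @export
run_empirical_pipeline <- function(config = default_session_config(),
                                   seed = 1L, n_perm = 499L,
                                   n_shuffles = 101L, alpha = 0.05,
                                   grid = theta_grid(), decode = TRUE,
                                   out_dir = NULL) {
  session <- generate_session(config, seed = seed)
  trials <- session$trials
  decs <- lapply(session$lfp, morlet_transform, grid = grid)
  ps <- estimate_preferred_stimulus(session$spikes, trials)
  vex_rows <- list(); order_rows <- list(); dec_rows <- list()
  excl <- numeric(0)
  sample_sets_best <- list()
  for (j in seq_len(nrow(ps))) {
    u <- ps$unit_id[j]
    ups <- unit_phase_samples(session$spikes, u, ps$preferred[j], trials,
                              decs)
    excl <- c(excl, ups$excluded_fraction)
    res <- lapply(ups$samples, function(s) {
      if (is.null(s) || length(unique(s$condition)) < 2L ||
          min(table(s$condition)) < 2L) return(NULL)
      vt <- try(vex_permutation_test(s, n_perm = n_perm,
                                     seed = substream_seed(seed, paste0(
                                       "perm_u", u, "_f",
                                       attr(s, "frequency"))),
                                     keep_null = FALSE), silent = TRUE)
      if (inherits(vt, "try-error")) NULL else vt
    })
    ok <- !vapply(res, is.null, logical(1))
    if (!any(ok)) next
    vex_rows[[length(vex_rows) + 1L]] <- data.frame(
      unit_id = u, frequency = grid[ok],
      Vex = vapply(res[ok], `[[`, numeric(1), "Vex"),
      p = vapply(res[ok], `[[`, numeric(1), "p"))
    pvals <- rep(NA_real_, length(grid)); pvals[ok] <-
      vapply(res[ok], `[[`, numeric(1), "p")
    vexs <- rep(NA_real_, length(grid)); vexs[ok] <-
      vapply(res[ok], `[[`, numeric(1), "Vex")
    best_k <- which.max(vexs)
    s_best <- ups$samples[[best_k]]
    sample_sets_best[[as.character(u)]] <- s_best
    # per-position preferred phases at the best frequency
    mu_pos <- vapply(sort(unique(s_best$condition)), function(cd)
      circular_mean(s_best$phase[s_best$condition == cd])$mean, numeric(1))
    if (length(mu_pos) == 4L && !any(is.na(mu_pos))) {
      anc <- anchor_phases(mu_pos)
      po <- phase_order(mu_pos)
      # reference phase at first stimulus onset, per trial, circular mean
      # reference phase at first stimulus onset: measured at a mid-delay
      # time (clear of wavelet edge margins) and projected back along the
      # oscillation, then averaged circularly across trials
      f_best <- grid[best_k]
      phi0s <- vapply(seq_len(nrow(trials)), function(i) {
        t_ref <- trials$probe_on[i] - 1
        sp <- spike_phases(t_ref, decs[[i]], f_best)
        if (!length(sp$phases)) return(NA_real_)
        wrap_angle(sp$phases -
                     2 * pi * f_best * (t_ref - trials$stim1_on[i]))
      }, numeric(1))
      phi0s <- phi0s[!is.na(phi0s)]
      phi0 <- if (length(phi0s)) circular_mean(phi0s)$mean else 0
      pred <- predict_reset_phases(f_best, trials$soa[1], phi0 = phi0)
      order_rows[[length(order_rows) + 1L]] <- data.frame(
        unit_id = u, frequency = f_best,
        t(stats::setNames(anc$anchored, paste0("anchored", 1:4))),
        order = paste(po$order, collapse = ""),
        canonical = po$canonical, category = po$category,
        predicted = pred$canonical,
        match = po$canonical == pred$canonical)
    }
    if (decode && !is.null(s_best) &&
        min(table(s_best$condition)) >= 4L &&
        length(unique(s_best$condition)) == 4L) {
      sn <- shuffle_null(phase_features(s_best$phase), s_best$condition,
                         n_shuffles = n_shuffles,
                         seed = substream_seed(seed, paste0("dec_u", u)))
      dec_rows[[length(dec_rows) + 1L]] <- data.frame(
        unit_id = u, accuracy = sn$observed$accuracy,
        null_mean = sn$null_mean, p = sn$p)
    }
  }
  vex_table <- do.call(rbind, vex_rows)
  order_table <- do.call(rbind, order_rows)
  decoding <- do.call(rbind, dec_rows)
  unit_summary <- if (!is.null(vex_table)) {
    do.call(rbind, lapply(split(vex_table, vex_table$unit_id), function(d)
      data.frame(unit_id = d$unit_id[1],
                 n_freq = nrow(d),
                 best_Vex = max(d$Vex),
                 significant = unit_significant(d$p, alpha = alpha))))
  } else NULL
  cats <- if (!is.null(order_table))
    table(factor(order_table$category,
                 levels = c("forward", "reverse", "other"))) else NULL
  report <- structure(list(
    vex_table = vex_table, unit_summary = unit_summary,
    order_table = order_table,
    order_categories = cats, chance = chance_probabilities(4L),
    decoding = decoding,
    sample_sets_best = sample_sets_best,
    excluded_zero_spike_fraction = mean(excl, na.rm = TRUE),
    session_seed = seed, config = config), class = "empirical_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("vex_table", "unit_summary", "order_table", "decoding")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(out_dir,
                                               paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  summ <- list(
    n_units_significant = if (!is.null(report$unit_summary))
      sum(report$unit_summary$significant) else 0,
    n_units = if (!is.null(report$unit_summary))
      nrow(report$unit_summary) else 0,
    order_categories = as.list(report$order_categories),
    chance = report$chance,
    excluded_zero_spike_fraction = report$excluded_zero_spike_fraction,
    session_seed = report$session_seed)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Normalized oscillation magnitude of an LFP segment at one frequency
#'
#' The modulus of the Fourier component of the (mean/sd)-normalized LFP
#' (i.e. minus [reg_osc()]), evaluated at arbitrary frequencies; used to
#' locate the LFP spectral peak on a fine grid.
#'
#' @param lfp numeric vector.
#' @param freqs frequencies to evaluate (Hz).
#' @param dt sample step (s).
#' @return numeric vector, one magnitude per frequency.
#' @export
osc_magnitude <- function(lfp, freqs, dt) {
  vapply(freqs, function(f) -reg_osc(lfp, f, dt), numeric(1))
}

#' LFP spectral peak of a simulated batch
#'
#' Per-trial delay-window LFP oscillation magnitudes averaged across
#' trials; the peak frequency is the argmax over a fine grid.
#'
#' @param traj an `rnn_trajectory`.
#' @param batch its `task_batch`.
#' @param freqs search grid (Hz, default 0.5-6 by 0.05).
#' @param window `"delay"` (default) or `"all"`.
#' @return list with `freqs`, `magnitude` (grid average), `peak_freq`,
#'   `peak_magnitude`.
#' @export
lfp_peak_frequency <- function(traj, batch,
                               freqs = seq(0.5, 6, by = 0.05),
                               window = c("delay", "all")) {
  window <- match.arg(window)
  idx <- if (window == "delay")
    which(batch$times >= batch$delay_on & batch$times < batch$delay_off)
  else seq_len(batch$T)
  # frequencies need at least one cycle inside the window
  freqs <- freqs[freqs >= 1 / (length(idx) * batch$dt)]
  if (length(freqs) == 0L)
    stop_param("lfp_peak_frequency: window shorter than one cycle of ",
               "every requested frequency")
  mags <- sapply(seq_len(ncol(traj$lfp)), function(b)
    osc_magnitude(traj$lfp[idx, b], freqs, batch$dt))
  avg <- rowMeans(mags)
  k <- which.max(avg)
  list(freqs = freqs, magnitude = avg, peak_freq = freqs[k],
       peak_magnitude = avg[k])
}

#' Run the model pipeline: train, evaluate, analyze phases
#'
#' Builds a Dale network, trains it with the oscillation regularizer,
#' simulates an evaluation set (224 unique trials, half match), locates
#' the delay LFP spectral peak (success = within 0.5 Hz of the
#' regularization frequency), extracts phase samples of selective units
#' against the reference oscillation (sine anchored at the last sample
#' stimulus onset, at the peak frequency), runs the V_ex permutation test
#' per unit, classifies phase orders and compares them with the
#' reset-model prediction.
#'
#' @param net_config list passed to [build_network()].
#' @param train_config list from [default_train_config()].
#' @param seed integer seed.
#' @param n_eval evaluation trials (default 224).
#' @param n_perm V_ex permutations (default 199).
#' @param out_dir optional artifact directory.
#' @return list of class `model_report`: `fit` (training result),
#'   `peak_freq`, `success`, `osc_magnitude_at_f`, `vex_table`,
#'   `order_table`, `match_rate`, `n_selective`, `eval_accuracy`.
#' @export
run_model_pipeline <- function(net_config = list(), train_config =
                                 default_train_config(), seed = 1L,
                               n_eval = 224L, n_perm = 199L,
                               out_dir = NULL) {
  params <- do.call(build_network,
                    c(net_config, list(seed = substream_seed(seed, "net"))))
  fit <- train_rnn(params, train_config, seed = seed)
  ev <- evaluate_model(fit$params, train_config, seed = seed,
                       n_eval = n_eval, n_perm = n_perm,
                       soa = train_config$soa)
  report <- structure(c(list(fit = fit), ev,
                        list(f_osc = train_config$f_osc,
                             success = abs(ev$peak_freq -
                                             train_config$f_osc) <= 0.5)),
                      class = "model_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$vex_table))
      utils::write.csv(report$vex_table,
                       file.path(out_dir, "model_vex.csv"),
                       row.names = FALSE)
    if (!is.null(report$order_table))
      utils::write.csv(report$order_table,
                       file.path(out_dir, "model_order.csv"),
                       row.names = FALSE)
  }
  report
}

#' Evaluate a trained network at one SOA
#'
#' Simulation + phase analysis only (no training), so a trained model can
#' be probed at SOAs other than the training SOA.
#'
#' @param params trained `rnn_params`.
#' @param train_config the training config (timing fields are reused).
#' @param seed integer seed.
#' @param n_eval evaluation trials.
#' @param n_perm V_ex permutations.
#' @param soa probe SOA (s).
#' @return list with `eval_accuracy`, `peak_freq`, `osc_magnitude_at_f`,
#'   `n_selective`, `vex_table`, `order_table`, `match_rate`,
#'   `modal_class`, `predicted_class`.
#' @export
evaluate_model <- function(params, train_config, seed = 1L, n_eval = 224L,
                           n_perm = 199L, soa = NULL) {
  if (is.null(soa)) soa <- train_config$soa
  batch <- make_task_batch(n_eval, soa = soa, delay = train_config$delay,
                           dt = params$dt,
                           seed = substream_seed(seed, "eval"),
                           evaluation = TRUE,
                           stim_duration = train_config$stim_duration,
                           baseline_dur = train_config$baseline_dur,
                           decision_dur = train_config$decision_dur)
  traj <- simulate_rnn(params, batch,
                       noise_seed = substream_seed(seed, "eval_noise"))
  acc <- decision_accuracy(traj, batch)
  pk <- lfp_peak_frequency(traj, batch)
  mag_at_f <- mean(vapply(seq_len(ncol(traj$lfp)), function(b)
    -reg_osc(traj$lfp[, b], train_config$f_osc, batch$dt), numeric(1)))
  sel <- selective_units(traj, batch)
  ref <- model_reference_oscillation(pk$peak_freq, batch$stim_on[4])
  sets <- model_phase_analysis(traj, batch, ref, sel)
  vex_rows <- list(); order_rows <- list()
  # prediction: phases are anchored at the last stimulus onset, so the
  # reference phase at the first stimulus onset is -2 pi f 3 soa
  phi0 <- wrap_angle(-2 * pi * pk$peak_freq * 3 * soa)
  pred <- predict_reset_phases(pk$peak_freq, soa, phi0 = phi0)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (length(unique(s$condition)) < 2L || min(table(s$condition)) < 2L)
      next
    vt <- try(vex_permutation_test(s, n_perm = n_perm,
                                   seed = substream_seed(seed, paste0(
                                     "mperm", nm)), keep_null = FALSE),
              silent = TRUE)
    if (inherits(vt, "try-error")) next
    vex_rows[[length(vex_rows) + 1L]] <- data.frame(
      unit = as.integer(nm), Vex = vt$Vex, p = vt$p)
    if (length(unique(s$condition)) == 4L) {
      mu_pos <- vapply(1:4, function(cd)
        circular_mean(s$phase[s$condition == cd])$mean, numeric(1))
      po <- phase_order(mu_pos)
      order_rows[[length(order_rows) + 1L]] <- data.frame(
        unit = as.integer(nm), canonical = po$canonical,
        category = po$category, predicted = pred$canonical,
        match = po$canonical == pred$canonical)
    }
  }
  vex_table <- do.call(rbind, vex_rows)
  order_table <- do.call(rbind, order_rows)
  modal <- if (!is.null(order_table) && nrow(order_table))
    names(sort(table(order_table$canonical), decreasing = TRUE))[1]
  else NA_character_
  list(eval_accuracy = acc, peak_freq = pk$peak_freq,
       osc_magnitude_at_f = mag_at_f, n_selective = nrow(sel),
       vex_table = vex_table, order_table = order_table,
       match_rate = if (!is.null(order_table) && nrow(order_table))
         mean(order_table$match) else NA_real_,
       modal_class = modal, predicted_class = pred$canonical)
}
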