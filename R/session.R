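# Session bundles: one call generates a self-consistent (trials, LFP,
# spikes, ground truth) bundle from a config and a single seed; bundles
# serialize to a directory of plain CSV/JSON files and reload to equal
# values.

#' Default session configuration
#'
#' Values mirror the human task: 224 trials, 4-of-8 stimulus sequences,
#' SOA 0.4 s, 200 ms stimuli, delay 2.5 s +/- 0.1 s, half match trials;
#' theta at 2.8 Hz with a 3x delay amplitude boost over 1/f background.
#'
#' @param ... overrides of any default field.
#' @return named list.
#' @export
default_session_config <- function(...) {
  cfg <- list(
    n_trials = 224L, soa = 0.4, delay_mean = 2.5, delay_jitter = 0.1,
    p_match = 0.5, p_correct = 0.77, balanced = TRUE, stim_duration = 0.2,
    fixation_duration = 1,
    n_units = 20L, ordering_mode = "forward", theta_freq = 2.8,
    kappa_ps = 2, kappa_nps = 0.5, baseline_rate = 3, selectivity_gain = 4,
    primacy = c(1, 0.85, 0.7, 0.55), phase_step = deg2rad(40),
    delay_power_boost = 3, noise_amp = 1, noise_exponent = 1,
    theta_amp = 1, fs = 1000, post_probe = 0.5)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop_param("default_session_config: unknown fields: ",
               paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Generate a full synthetic session
#'
#' @param config list from [default_session_config()].
#' @param seed single session seed; trials, LFP and spikes draw from named
#'   substreams of it.
#' @return list of class `wm_session` with `trials`, `lfp`, `spikes`,
#'   `ground_truth`, `config`, `seed`.
#' @export
generate_session <- function(config = default_session_config(), seed = 1L) {
  need <- names(default_session_config())
  if (!all(need %in% names(config)))
    stop_param("generate_session: config missing fields: ",
               paste(setdiff(need, names(config)), collapse = ", "))
  trials <- generate_trial_table(
    n_trials = config$n_trials, soa = config$soa,
    delay_mean = config$delay_mean, delay_jitter = config$delay_jitter,
    p_match = config$p_match, seed = seed, balanced = config$balanced,
    p_correct = config$p_correct, stim_duration = config$stim_duration,
    fixation_duration = config$fixation_duration)
  lfp <- generate_lfp(
    trials, theta_freq = config$theta_freq,
    delay_power_boost = config$delay_power_boost,
    noise_spectrum_params = list(amp = config$noise_amp,
                                 exponent = config$noise_exponent),
    theta_amp = config$theta_amp, fs = config$fs, seed = seed,
    post_probe = config$post_probe)
  gt <- make_ground_truth(
    n_units = config$n_units, ordering_mode = config$ordering_mode,
    theta_freq = config$theta_freq, soa = config$soa,
    kappa_ps = config$kappa_ps, kappa_nps = config$kappa_nps,
    baseline_rate = config$baseline_rate,
    selectivity_gain = config$selectivity_gain, primacy = config$primacy,
    phase_step = config$phase_step, seed = seed)
  spikes <- generate_spikes(trials, lfp, gt, seed = seed)
  structure(list(trials = trials, lfp = lfp, spikes = spikes,
                 ground_truth = gt, config = config, seed = seed),
            class = "wm_session")
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a session bundle to a directory of plain-text files
#'
#' Layout: `trials.csv`, `spikes.csv`, `lfp.csv` (long: trial_id, sample),
#' `lfp_meta.csv`, `ground_truth.json`, `config.json`. Numbers are written
#' with 17 significant digits so the reload reproduces the doubles exactly.
#'
#' @param session a `wm_session`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, file) {
    num <- vapply(d, is.double, logical(1))
    d[num] <- lapply(d[num], fmt_num)
    utils::write.csv(d, file.path(dir, file), row.names = FALSE)
  }
  tr <- as.data.frame(session$trials)
  wr(tr, "trials.csv")
  wr(as.data.frame(session$spikes), "spikes.csv")
  lfp_long <- do.call(rbind, lapply(session$lfp, function(x)
    data.frame(trial_id = x$trial_id, sample = x$samples)))
  wr(lfp_long, "lfp.csv")
  meta <- do.call(rbind, lapply(session$lfp, function(x)
    data.frame(trial_id = x$trial_id, channel_id = x$channel_id,
               fs = x$fs, t0 = x$t0, theta_phase0 = x$theta_phase0,
               theta_freq = x$theta_freq)))
  wr(meta, "lfp_meta.csv")
  # serializeJSON keeps doubles bit-exact across the round trip
  writeLines(jsonlite::serializeJSON(unclass(session$ground_truth),
                                     digits = 17),
             file.path(dir, "ground_truth.json"))
  writeLines(jsonlite::serializeJSON(
    c(session$config, list(seed = session$seed),
      stim_duration_attr = attr(session$trials, "stim_duration")),
    digits = 17),
    file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#' @param dir directory.
#' @return a `wm_session`.
#' @export
read_session <- function(dir) {
  cfg <- jsonlite::unserializeJSON(
    paste(readLines(file.path(dir, "config.json")), collapse = "\n"))
  seed <- cfg$seed
  stim_dur_attr <- cfg$stim_duration_attr
  cfg$seed <- NULL; cfg$stim_duration_attr <- NULL
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  attr(trials, "stim_duration") <- stim_dur_attr
  class(trials) <- c("trial_table", "data.frame")
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  class(spikes) <- c("spike_train_set", "data.frame")
  lfp_long <- utils::read.csv(file.path(dir, "lfp.csv"))
  meta <- utils::read.csv(file.path(dir, "lfp_meta.csv"))
  lfp <- lapply(seq_len(nrow(meta)), function(i) {
    tr <- lfp_trace(lfp_long$sample[lfp_long$trial_id == meta$trial_id[i]],
                    fs = meta$fs[i], t0 = meta$t0[i],
                    channel_id = meta$channel_id[i],
                    trial_id = meta$trial_id[i])
    tr$theta_phase0 <- meta$theta_phase0[i]
    tr$theta_freq <- meta$theta_freq[i]
    tr
  })
  gt <- jsonlite::unserializeJSON(
    paste(readLines(file.path(dir, "ground_truth.json")), collapse = "\n"))
  class(gt) <- "ground_truth"
  structure(list(trials = trials, lfp = lfp, spikes = spikes,
                 ground_truth = gt, config = as.list(cfg), seed = seed),
            class = "wm_session")
}
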