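# Trial-table generation for the sequence working-memory task: on each
# trial four of eight stimuli are shown in sequence (200 ms each, onsets
# separated by the SOA), followed by a jittered delay and a probe that
# repeats the four stimuli in the same order (match) or a different order.

#' Generate a trial table
#'
#' @param n_trials number of trials (>= 1).
#' @param soa stimulus onset asynchrony in seconds (default 0.4).
#' @param delay_mean mean delay duration (s, default 2.5).
#' @param delay_jitter half-width of the uniform delay jitter (s, default
#'   0.1, i.e. delays in 2.4-2.6 s).
#' @param p_match probability that the probe order matches (default 0.5).
#' @param seed integer seed.
#' @param balanced if TRUE (requires `n_trials` divisible by 8), each of
#'   the 8 stimuli appears exactly equally often at each of the 4 positions;
#'   otherwise sequences are drawn uniformly (equal in expectation).
#' @param p_correct probability a trial is answered correctly (default
#'   0.77, the typical observed performance level).
#' @param stim_duration stimulus duration (s, default 0.2).
#' @param fixation_duration fixation period before the first stimulus
#'   (s, default 1).
#' @return data.frame of class `trial_table`: `trial_id`, `seq1..seq4`,
#'   `probe1..probe4` (stimulus ids 0-7), `is_match`, `correct`,
#'   `fixation_on`, `stim1_on..stim4_on`, `delay_on`, `probe_on`, `soa`.
#'   Times in seconds, 0 at fixation onset; event windows are `[on, off)`.
#' @export
generate_trial_table <- function(n_trials, soa = 0.4, delay_mean = 2.5,
                                 delay_jitter = 0.1, p_match = 0.5,
                                 seed = 1L, balanced = FALSE,
                                 p_correct = 0.77, stim_duration = 0.2,
                                 fixation_duration = 1) {
  if (n_trials < 1L) stop_param("generate_trial_table: n_trials must be >= 1")
  if (p_match < 0 || p_match > 1 || p_correct < 0 || p_correct > 1)
    stop_param("generate_trial_table: probabilities must lie in [0, 1]")
  if (soa <= 0) stop_param("generate_trial_table: soa must be positive")
  if (soa < stim_duration)
    stop_param("generate_trial_table: soa shorter than stimulus duration")
  if (balanced && n_trials %% 8L != 0L)
    stop_param("generate_trial_table: balanced mode needs n_trials ",
               "divisible by 8")
  with_seed(substream_seed(seed, "trials"), {
    seqs <- if (balanced) balanced_sequences(n_trials)
            else t(replicate(n_trials, sample(0:7, 4L)))
    is_match <- stats::runif(n_trials) < p_match
    probes <- seqs
    for (i in which(!is_match)) {
      repeat {
        p <- sample(4L)
        if (any(p != 1:4)) break
      }
      probes[i, ] <- seqs[i, p]
    }
    delay <- stats::runif(n_trials, delay_mean - delay_jitter,
                          delay_mean + delay_jitter)
    correct <- stats::runif(n_trials) < p_correct
    stim1 <- fixation_duration
    d <- data.frame(trial_id = seq_len(n_trials))
    for (k in 1:4) d[[paste0("seq", k)]] <- seqs[, k]
    for (k in 1:4) d[[paste0("probe", k)]] <- probes[, k]
    d$is_match <- is_match
    d$correct <- correct
    d$fixation_on <- 0
    for (k in 1:4) d[[paste0("stim", k, "_on")]] <- stim1 + (k - 1) * soa
    d$delay_on <- stim1 + 3 * soa + stim_duration
    d$probe_on <- d$delay_on + delay
    d$soa <- soa
    attr(d, "stim_duration") <- stim_duration
    class(d) <- c("trial_table", "data.frame")
    d
  })
}

# exact balanced design: each stimulus appears n/8 times at each position;
# start from per-position balanced shuffles, then repair within-row
# duplicates by swapping entries between rows (preserves column counts)
balanced_sequences <- function(n_trials) {
  per <- n_trials / 8L
  m <- sapply(1:4, function(k) sample(rep(0:7, per)))
  for (pass in 1:1000) {
    bad <- which(apply(m, 1L, anyDuplicated) > 0L)
    if (length(bad) == 0L) break
    for (i in bad) {
      dup_col <- anyDuplicated(m[i, ])
      j <- sample(n_trials, 1L)
      v <- m[i, dup_col]; m[i, dup_col] <- m[j, dup_col]; m[j, dup_col] <- v
    }
  }
  if (any(apply(m, 1L, anyDuplicated) > 0L))
    stop("balanced_sequences: could not repair duplicates")
  m
}

#' Sequence matrix of a trial table
#' @param trials a `trial_table`.
#' @param what `"seq"` or `"probe"`.
#' @return integer matrix, n_trials x 4.
#' @export
sequence_matrix <- function(trials, what = c("seq", "probe")) {
  what <- match.arg(what)
  as.matrix(trials[, paste0(what, 1:4)])
}

#' Sequence position of a stimulus on each trial
#' @param trials a `trial_table`.
#' @param stimulus stimulus id (0-7).
#' @return integer vector (NA where the stimulus was not shown).
#' @export
stimulus_position <- function(trials, stimulus) {
  sq <- sequence_matrix(trials)
  pos <- apply(sq, 1L, function(s) match(stimulus, s))
  as.integer(pos)
}
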