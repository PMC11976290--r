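# Small fixtures shared across tests; everything is generated in code.

small_session <- function(seed = 7, ...) {
  cfg <- default_session_config(n_trials = 32L, n_units = 4L, fs = 250,
                                ...)
  generate_session(cfg, seed = seed)
}

# per-trial mean phases drawn directly from von Mises distributions:
# the minimal input to the V_ex / decoding machinery
planted_phase_set <- function(mu, kappa, n_per = 28L, seed = 1L) {
  stopifnot(length(mu) >= 2L)
  set.seed(seed)
  phase_sample_set(
    unlist(lapply(seq_along(mu), function(k) rvonmises(n_per, mu[k], kappa))),
    rep(seq_along(mu), each = n_per))
}
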