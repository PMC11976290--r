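# Dale-constrained firing-rate RNN for the sequence match/non-match task.
#
# Dynamics (continuous time):
#   tau dx/dt = -x + J phi(x) + I u(t) + sqrt(2 tau sigma_xi^2) xi(t)
# simulated with the Euler update (alpha_i = dt / tau_i):
#   x^{n+1} = (1-alpha) x^n + alpha (J phi(x^n) + I u^n)
#             + sqrt(2 alpha sigma_xi^2) eps,  eps ~ N(0, 1)
# Readout y^n = w' phi(x^n) (linear readout of the firing rates); LFP proxy
# LFP^n = sum_ij |J_ij| phi(x_j^n) (summed absolute synaptic input). The
# training loss is a decision-period masked MSE plus an L2 rate penalty and
# an oscillation regularizer, reg_osc = -|Fourier component at f_osc of the
# (mean/sd)-normalized LFP| (see reg_osc()).
#
# The activation is a rectified tanh (0 below 0, tanh above): rates are
# nonnegative and saturate, which the rate penalty keeps in a plausible
# range.

phi_rect_tanh <- function(x) {
  y <- tanh(x); y[x < 0] <- 0; y
}
phi_rect_tanh_deriv <- function(x) {
  d <- 1 - tanh(x)^2; d[x < 0] <- 0; d
}

#' Build a Dale-constrained network
#'
#' Recurrent weights are Gaussian, sign-constrained per column so each
#' unit's outgoing connections share one sign (excitatory or inhibitory),
#' with inhibitory columns scaled to balance excitation; J is then rescaled
#' to the requested spectral radius. The diagonal is zero.
#'
#' @param n number of units (default 200).
#' @param n_in input channels (default 8).
#' @param frac_excitatory fraction of excitatory units (default 0.8).
#' @param spectral_radius target spectral radius of J (default 1.5).
#' @param tau time constant(s), seconds (default 0.1; recycled to n).
#' @param dt Euler step (s, default 0.02).
#' @param sigma_noise intrinsic noise scale sigma_xi (default 0.05).
#' @param readout `"currents"` (default): y = w'x, the linear readout as
#'   printed in the model definition; `"rates"`: y = w'phi(x).
#' @param seed integer seed.
#' @return list of class `rnn_params`: `J`, `I`, `w`, `sign` (+1/-1 per
#'   unit), `tau`, `dt`, `sigma_noise`, `n`, `n_in`, `phi = "rect_tanh"`,
#'   `readout`.
#' @export
build_network <- function(n = 200L, n_in = 8L, frac_excitatory = 0.8,
                          spectral_radius = 1.5, tau = 0.1, dt = 0.02,
                          sigma_noise = 0.05,
                          readout = c("currents", "rates"), seed = 1L) {
  readout <- match.arg(readout)
  if (frac_excitatory <= 0 || frac_excitatory >= 1)
    stop_param("build_network: frac_excitatory must lie in (0, 1)")
  if (any(tau <= 0) || dt <= 0 || sigma_noise < 0)
    stop_param("build_network: tau, dt must be > 0 and sigma_noise >= 0")
  with_seed(substream_seed(seed, "rnn_init"), {
    n_exc <- round(n * frac_excitatory)
    sgn <- c(rep(1, n_exc), rep(-1, n - n_exc))
    J <- abs(matrix(stats::rnorm(n * n, sd = 1 / sqrt(n)), n, n))
    # balance: inhibitory columns carry the excitatory mass
    J <- sweep(J, 2L, ifelse(sgn > 0, 1, frac_excitatory /
                                          (1 - frac_excitatory)), `*`)
    J <- sweep(J, 2L, sgn, `*`)
    diag(J) <- 0
    rad <- max(Mod(eigen(J, only.values = TRUE)$values))
    J <- J * spectral_radius / rad
    I <- matrix(stats::rnorm(n * n_in, sd = 1), n, n_in)
    w <- stats::rnorm(n, sd = 1 / sqrt(n))
    structure(list(J = J, I = I, w = w, sign = sgn,
                   tau = rep(tau, length.out = n), dt = dt,
                   sigma_noise = sigma_noise, n = n, n_in = n_in,
                   phi = "rect_tanh", readout = readout),
              class = "rnn_params")
  })
}

# project J onto the Dale cone: wrong-signed entries -> 0, diagonal -> 0
dale_project <- function(J, sgn) {
  Jp <- sweep(J, 2L, sgn, `*`)   # now "correct" entries are positive
  Jp[Jp < 0] <- 0
  J <- sweep(Jp, 2L, sgn, `*`)
  diag(J) <- 0
  J
}

#' Check the Dale constraint
#' @param params an `rnn_params`.
#' @return TRUE when every unit's outgoing (column) weights share its sign.
#' @export
dale_satisfied <- function(params) {
  all(sweep(params$J, 2L, params$sign, `*`) >= 0)
}

#' Build a batch of task trials
#'
#' Timeline per trial: baseline, four sample stimuli (0.2 s pulses at the
#' SOA), delay, the same four stimuli as probe (same order on match trials,
#' a different random order otherwise), then a decision period during
#' which the target is +1 (match) / -1 (non-match) and the loss mask is 1.
#'
#' @param n_trials number of trials.
#' @param soa stimulus onset asynchrony (s, default 0.4).
#' @param delay delay duration (s, default 2.5).
#' @param p_match match probability (ignored in evaluation mode).
#' @param dt time step (s).
#' @param seed integer seed.
#' @param evaluation if TRUE, draw `n_trials` unique stimulus sequences
#'   with exactly half assigned match (224 mirrors the experiment).
#' @param stim_duration stimulus pulse length (s, default 0.2).
#' @param baseline_dur,decision_dur pre-stimulus and decision durations (s).
#' @return list of class `task_batch`: `u` (T x n_in x B), `target` (+/-1
#'   per trial), `mask` (T), `times` (T), event times, `seq` and `probe`
#'   (B x 4 stimulus ids 1-8), `is_match`, `dt`.
#' @export
make_task_batch <- function(n_trials, soa = 0.4, delay = 2.5, p_match = 0.5,
                            dt = 0.02, seed = 1L, evaluation = FALSE,
                            stim_duration = 0.2, baseline_dur = 0.5,
                            decision_dur = 0.5) {
  if (soa < stim_duration)
    stop_param("make_task_batch: soa shorter than stimulus duration")
  n_in <- 8L
  stim_on <- baseline_dur + (0:3) * soa
  probe_start <- baseline_dur + 4 * soa + delay
  probe_on <- probe_start + (0:3) * soa
  decision_on <- probe_start + 4 * soa
  t_end <- decision_on + decision_dur
  T_ <- round(t_end / dt)
  times <- (seq_len(T_) - 1L) * dt
  with_seed(substream_seed(seed, "task"), {
    if (evaluation) {
      seqs <- matrix(0L, n_trials, 4L)
      seen <- character(0)
      i <- 1L
      while (i <= n_trials) {
        s <- sample(8L, 4L)
        key <- paste(s, collapse = ",")
        if (!(key %in% seen)) {
          seqs[i, ] <- s; seen <- c(seen, key); i <- i + 1L
        }
      }
      is_match <- sample(rep(c(TRUE, FALSE), length.out = n_trials))
    } else {
      seqs <- t(replicate(n_trials, sample(8L, 4L)))
      is_match <- stats::runif(n_trials) < p_match
    }
    probes <- seqs
    for (i in which(!is_match)) {
      repeat {
        p <- sample(4L)
        if (any(p != 1:4)) break
      }
      probes[i, ] <- seqs[i, p]
    }
    u <- array(0, c(T_, n_in, n_trials))
    for (k in 1:4) {
      win_s <- times >= stim_on[k] & times < stim_on[k] + stim_duration
      win_p <- times >= probe_on[k] & times < probe_on[k] + stim_duration
      for (i in seq_len(n_trials)) {
        u[win_s, seqs[i, k], i] <- 1
        u[win_p, probes[i, k], i] <- 1
      }
    }
    mask <- as.numeric(times >= decision_on & times < decision_on +
                         decision_dur)
    structure(list(u = u, target = ifelse(is_match, 1, -1), mask = mask,
                   times = times, stim_on = stim_on, probe_on = probe_on,
                   delay_on = stim_on[4] + stim_duration,
                   delay_off = probe_start, decision_on = decision_on,
                   seq = seqs, probe = probes, is_match = is_match,
                   soa = soa, dt = dt, T = T_),
              class = "task_batch")
  })
}

#' Simulate the network on a batch
#'
#' Exact discrete Euler update as written above; `noise = FALSE` gives the
#' deterministic trajectory.
#'
#' @param params an `rnn_params`.
#' @param batch a `task_batch` (its dt must equal `params$dt`).
#' @param noise_seed seed for the noise draws.
#' @param noise include intrinsic noise (default TRUE).
#' @param keep_rates store the full rate tensor (default TRUE).
#' @return list of class `rnn_trajectory`: `y` (T x B readout), `lfp`
#'   (T x B), `rates` (T x N x B, if kept), `x_final`, `batch_T`.
#' @export
simulate_rnn <- function(params, batch, noise_seed = 1L, noise = TRUE,
                         keep_rates = TRUE) {
  stopifnot(inherits(params, "rnn_params"), inherits(batch, "task_batch"))
  if (abs(batch$dt - params$dt) > 1e-12)
    stop_param("simulate_rnn: batch dt does not match params dt")
  N <- params$n; T_ <- batch$T; B <- dim(batch$u)[3]
  alpha <- params$dt / params$tau
  noise_sd <- sqrt(2 * alpha * params$sigma_noise^2)
  cJ <- colSums(abs(params$J))
  x <- matrix(0, N, B)
  y <- matrix(0, T_, B)
  lfp <- matrix(0, T_, B)
  rates <- if (keep_rates) array(0, c(T_, N, B)) else NULL
  from_currents <- identical(params$readout, "currents")
  with_seed(substream_seed(noise_seed, "sim_noise"), {
    for (n_ in seq_len(T_)) {
      r <- phi_rect_tanh(x)
      if (any(!is.finite(r)))
        stop("simulate_rnn: non-finite state at step ", n_)
      y[n_, ] <- crossprod(if (from_currents) x else r, params$w)
      lfp[n_, ] <- crossprod(r, cJ)
      if (keep_rates) rates[n_, , ] <- r
      drive <- params$J %*% r + params$I %*% batch$u[n_, , ]
      x <- (1 - alpha) * x + alpha * drive
      if (noise && params$sigma_noise > 0)
        x <- x + noise_sd * matrix(stats::rnorm(N * B), N, B)
    }
  })
  structure(list(y = y, lfp = lfp, rates = rates, x_final = x,
                 batch_T = T_),
            class = "rnn_trajectory")
}

#' LFP proxy from rates
#'
#' LFP^n = sum_i sum_j |J_ij| phi(x_j^n): nonnegative for nonnegative
#' rates and linear in |J|.
#'
#' @param rates matrix (T x N) or array (T x N x B) of rates.
#' @param J recurrent weight matrix.
#' @return vector (T) or matrix (T x B).
#' @export
lfp_proxy <- function(rates, J) {
  cJ <- colSums(abs(J))
  if (length(dim(rates)) == 3L) {
    apply(rates, 3L, function(R) R %*% cJ)
  } else {
    as.numeric(rates %*% cJ)
  }
}

#' Oscillation regularizer
#'
#' Normalizes the LFP to zero mean and (sqrt(2) x population s.d.) unit
#' scale, then returns minus the modulus of its discrete Fourier component
#' at `f_osc`:
#'   reg_osc = -| (1/T) sum_n LFPbar^n exp(-i 2 pi f_osc n dt) |.
#' A pure sinusoid at `f_osc` spanning an integer number of cycles gives
#' exactly -0.5; white noise gives values near 0. The value is invariant
#' to LFP amplitude scaling by construction.
#'
#' @param lfp numeric vector (one trial's LFP).
#' @param f_osc target frequency (Hz).
#' @param dt sample step (s).
#' @return scalar in `[-0.5 - eps, 0]`.
#' @export
reg_osc <- function(lfp, f_osc, dt) {
  T_ <- length(lfp)
  if (T_ * dt < 1 / f_osc)
    stop_param("reg_osc: LFP shorter than one cycle of f_osc")
  s <- sqrt(mean((lfp - mean(lfp))^2))
  if (s <= 0) stop_param("reg_osc: constant LFP, normalization degenerate")
  lbar <- (lfp - mean(lfp)) / (sqrt(2) * s)
  n_ <- seq_len(T_)
  -Mod(mean(lbar * exp(-1i * 2 * pi * f_osc * n_ * dt)))
}

#' Loss of a simulated batch
#'
#' Masked mean-squared error on the decision period (normalized by the
#' mask mass), plus `lambda_fr` times the L2 rate penalty
#' (1/(NT)) sum phi(x)^2 and `lambda_osc` times the mean per-trial
#' [reg_osc()].
#'
#' @param traj an `rnn_trajectory` with rates kept.
#' @param batch the `task_batch` it was simulated on.
#' @param lambda_fr,lambda_osc regularizer weights.
#' @param f_osc oscillation target frequency (Hz).
#' @return list with `total`, `mse`, `reg_fr`, `reg_osc`.
#' @export
rnn_loss <- function(traj, batch, lambda_fr = 0, lambda_osc = 0,
                     f_osc = 2.75) {
  m <- batch$mask
  M <- sum(m)
  if (M == 0) stop_param("rnn_loss: all-zero decision mask")
  err <- sweep(traj$y, 2L, batch$target)    # T x B
  mse <- mean(colSums(m * err^2) / M)
  rfr <- if (is.null(traj$rates)) NA_real_ else mean(traj$rates^2)
  rosc <- if (lambda_osc != 0 || !is.null(traj$lfp))
    mean(apply(traj$lfp, 2L, reg_osc, f_osc = f_osc, dt = batch$dt))
  else NA_real_
  total <- mse + lambda_fr * rfr +
    (if (is.na(rosc)) 0 else lambda_osc * rosc)
  list(total = total, mse = mse, reg_fr = rfr, reg_osc = rosc)
}

#' Decision accuracy of a trajectory
#'
#' The decision rule is the sign of the time-averaged readout over the
#' decision (masked) period.
#' @param traj an `rnn_trajectory`.
#' @param batch the `task_batch`.
#' @return fraction of trials whose decision sign matches the target.
#' @export
decision_accuracy <- function(traj, batch) {
  m <- batch$mask
  dec <- sign(colSums(m * traj$y) / sum(m))
  mean(dec == batch$target)
}

# forward + backward pass for one batch; returns loss components and
# gradients wrt J, I, w. Noise draws are treated as constants.
rnn_backprop <- function(params, batch, lambda_fr, lambda_osc, f_osc,
                         noise_seed) {
  N <- params$n; T_ <- batch$T; B <- dim(batch$u)[3]
  alpha <- params$dt / params$tau
  noise_sd <- sqrt(2 * alpha * params$sigma_noise^2)
  cJ <- colSums(abs(params$J))
  xs <- vector("list", T_)
  x <- matrix(0, N, B)
  y <- matrix(0, T_, B)
  lfp <- matrix(0, T_, B)
  from_currents <- identical(params$readout, "currents")
  with_seed(substream_seed(noise_seed, "train_noise"), {
    for (n_ in seq_len(T_)) {
      xs[[n_]] <- x
      r <- phi_rect_tanh(x)
      y[n_, ] <- crossprod(if (from_currents) x else r, params$w)
      lfp[n_, ] <- crossprod(r, cJ)
      x <- (1 - alpha) * x + alpha * (params$J %*% r +
                                        params$I %*% batch$u[n_, , ])
      if (params$sigma_noise > 0)
        x <- x + noise_sd * matrix(stats::rnorm(N * B), N, B)
    }
  })
  m <- batch$mask; M <- sum(m)
  err <- sweep(y, 2L, batch$target)
  mse <- mean(colSums(m * err^2) / M)
  # reg_osc per trial + gradient wrt LFP samples
  mu <- colMeans(lfp)
  sdp <- sqrt(colMeans(sweep(lfp, 2L, mu)^2))
  lbar <- sweep(sweep(lfp, 2L, mu), 2L, sqrt(2) * sdp, `/`)   # T x B
  ex <- exp(-1i * 2 * pi * f_osc * seq_len(T_) * batch$dt)
  Fc <- colMeans(lbar * ex)                                    # B complex
  rosc_tr <- -Mod(Fc)
  rosc <- mean(rosc_tr)
  # g = d(-|F|)/d lbar ; h = d reg / d LFP
  dlbar <- -Re(sweep(matrix(ex, T_, B), 2L, Conj(Fc) / pmax(Mod(Fc), 1e-12),
                     `*`)) / T_
  gbar <- colMeans(dlbar)
  proj <- colSums(dlbar * lbar)
  h <- sweep(sweep(dlbar, 2L, gbar), 2L, sqrt(2) * sdp, `/`) -
    sweep(lbar, 2L, sqrt(2) * proj / (T_ * sdp), `*`)
  # rate penalty needs sum of r^2: recompute per step in the backward loop
  dJ <- matrix(0, N, N); dI <- matrix(0, N, params$n_in)
  dw <- numeric(N); q <- numeric(N)
  delta_next <- matrix(0, N, B)
  sum_r2 <- 0
  coef_fr <- 2 * lambda_fr / (N * T_ * B)
  for (n_ in rev(seq_len(T_))) {
    xn <- xs[[n_]]
    r <- phi_rect_tanh(xn)
    sum_r2 <- sum_r2 + sum(r^2)
    dy <- (2 / (M * B)) * (m[n_] * err[n_, ])                  # B
    e <- coef_fr * r +
      (lambda_osc / B) * outer(cJ, h[n_, ]) +
      crossprod(params$J, alpha * delta_next)
    if (!from_currents) e <- e + outer(params$w, dy)
    adel <- alpha * delta_next
    dJ <- dJ + tcrossprod(adel, r)
    un <- batch$u[n_, , ]
    if (is.matrix(un)) {
      if (any(un != 0)) dI <- dI + tcrossprod(adel, un)
    }
    dw <- dw + (if (from_currents) xn else r) %*% dy
    q <- q + r %*% h[n_, ]
    delta_next <- phi_rect_tanh_deriv(xn) * e + (1 - alpha) * delta_next
    if (from_currents) delta_next <- delta_next + outer(params$w, dy)
  }
  # LFP-regularizer path through |J|: c_j = sum_i |J_ij|
  dJ <- dJ + sign(params$J) *
    matrix((lambda_osc / B) * q, N, N, byrow = TRUE)
  rfr <- sum_r2 / (N * T_ * B)
  list(loss = list(total = mse + lambda_fr * rfr + lambda_osc * rosc,
                   mse = mse, reg_fr = rfr, reg_osc = rosc),
       grads = list(J = dJ, I = dI, w = as.numeric(dw)),
       accuracy = mean(sign(colSums(m * y) / M) == batch$target))
}

#' Default training configuration
#'
#' Training uses a fixed set of `train_trials` trials iterated in
#' minibatch epochs (fresh noise every pass), which generalizes where a
#' stream of never-repeated batches stalls at the zero-output saddle, and
#' a delay curriculum: the comparison rule is learned at a short delay
#' first, then the delay is stretched through `delay_schedule` up to the
#' target `delay`, each stage advancing at `stage_acc` validation
#' accuracy.
#'
#' @param ... overrides.
#' @return named list of training hyperparameters.
#' @export
default_train_config <- function(...) {
  cfg <- list(lambda_fr = 0.02, lambda_osc = 3, f_osc = 2.75,
              soa = 0.4, delay = 2.5, stim_duration = 0.2,
              baseline_dur = 0.2, decision_dur = 0.4,
              lr = 5e-3, lr_decay = 0.7, lr_decay_every = 60L,
              beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
              clip = 2, batch_size = 128L, train_trials = 1536L,
              delay_schedule = c(0.1, 0.4, 0.8, 1.5),
              stage_acc = 0.85, stage_max_epochs = 60L,
              target_acc = 0.95,
              max_epochs = 400L, val_every = 2L, val_trials = 192L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop_param("default_train_config: unknown fields: ",
               paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

# view of a subset of trials of a task batch
sub_batch <- function(b, idx) {
  nb <- b
  nb$u <- b$u[, , idx, drop = FALSE]
  nb$target <- b$target[idx]
  nb$seq <- b$seq[idx, , drop = FALSE]
  nb$probe <- b$probe[idx, , drop = FALSE]
  nb$is_match <- b$is_match[idx]
  nb
}

#' Train the network to criterion
#'
#' Adam on (J, I, w) with global-norm gradient clipping on the BPTT
#' gradients; after every step J is projected back onto the Dale cone
#' (wrong-signed entries zeroed, zero diagonal). Trials come from a fixed
#' training set iterated in shuffled minibatch epochs with fresh intrinsic
#' noise; the delay follows the curriculum in
#' `config$delay_schedule` (final entries at the target `config$delay`),
#' each stage advancing at `stage_acc` validation accuracy. Training
#' stops when validation accuracy at the target delay reaches
#' `target_acc` (accuracy = sign of the time-averaged readout over the
#' decision period), or at the global epoch budget.
#'
#' @param params an `rnn_params` from [build_network()].
#' @param config list from [default_train_config()].
#' @param seed integer seed driving trial sets and noise.
#' @param verbose print progress at each validation (default FALSE).
#' @return list with `params` (trained), `history` (data.frame of stage,
#'   epoch, loss components, validation accuracy), `converged`, `epochs`.
#' @export
train_rnn <- function(params, config = default_train_config(), seed = 1L,
                      verbose = FALSE) {
  delays <- unique(c(config$delay_schedule[config$delay_schedule <
                                             config$delay], config$delay))
  mstate <- list(J = 0 * params$J, I = 0 * params$I, w = 0 * params$w)
  vstate <- mstate
  hist <- list()
  converged <- FALSE
  step <- 0L
  total_epochs <- 0L
  mk <- function(n, d, tag)
    make_task_batch(n, soa = config$soa, delay = d, dt = params$dt,
                    seed = substream_seed(seed, tag),
                    stim_duration = config$stim_duration,
                    baseline_dur = config$baseline_dur,
                    decision_dur = config$decision_dur)
  for (si in seq_along(delays)) {
    d <- delays[si]
    final <- si == length(delays)
    goal <- if (final) config$target_acc else config$stage_acc
    train_set <- mk(config$train_trials, d, paste0("train", si))
    val_batch <- mk(config$val_trials, d, paste0("val", si))
    ep <- 0L
    repeat {
      if (total_epochs >= config$max_epochs) break
      if (!final && ep >= config$stage_max_epochs) break
      ep <- ep + 1L; total_epochs <- total_epochs + 1L
      ord <- with_seed(substream_seed(seed, paste0("ord", si, "_", ep)),
                       sample(config$train_trials))
      last_bp <- NULL
      for (k in seq(1L, config$train_trials, by = config$batch_size)) {
        idx <- ord[k:min(k + config$batch_size - 1L, config$train_trials)]
        batch <- sub_batch(train_set, idx)
        step <- step + 1L
        bp <- rnn_backprop(params, batch, config$lambda_fr,
                           config$lambda_osc, config$f_osc,
                           noise_seed = substream_seed(seed,
                                                       paste0("n", step)))
        last_bp <- bp
        g <- bp$grads
        gn <- sqrt(sum(g$J^2) + sum(g$I^2) + sum(g$w^2))
        if (!is.finite(gn))
          stop("train_rnn: non-finite gradient at step ", step)
        if (gn > config$clip)
          g <- lapply(g, function(x) x * config$clip / gn)
        lr_now <- config$lr *
          config$lr_decay^(total_epochs %/% config$lr_decay_every)
        for (nm in c("J", "I", "w")) {
          mstate[[nm]] <- config$beta1 * mstate[[nm]] +
            (1 - config$beta1) * g[[nm]]
          vstate[[nm]] <- config$beta2 * vstate[[nm]] +
            (1 - config$beta2) * g[[nm]]^2
          mhat <- mstate[[nm]] / (1 - config$beta1^step)
          vhat <- vstate[[nm]] / (1 - config$beta2^step)
          params[[nm]] <- params[[nm]] - lr_now * mhat /
            (sqrt(vhat) + config$eps)
        }
        params$J <- dale_project(params$J, params$sign)
      }
      if (ep %% config$val_every == 0L || ep == 1L) {
        vt <- simulate_rnn(params, val_batch, keep_rates = FALSE,
                           noise_seed = substream_seed(seed,
                                                       paste0("v", step)))
        vacc <- decision_accuracy(vt, val_batch)
        hist[[length(hist) + 1L]] <-
          data.frame(stage = si, delay = d, epoch = total_epochs,
                     loss = last_bp$loss$total, mse = last_bp$loss$mse,
                     reg_fr = last_bp$loss$reg_fr,
                     reg_osc = last_bp$loss$reg_osc, val_acc = vacc)
        if (verbose)
          message(sprintf(
            "stage %d (delay %.1f) epoch %d loss %.4f osc %.3f val %.3f",
            si, d, total_epochs, last_bp$loss$total,
            last_bp$loss$reg_osc, vacc))
        if (vacc >= goal) {
          if (final) converged <- TRUE
          break
        }
      }
    }
    if (total_epochs >= config$max_epochs && !converged && final) break
    if (converged) break
  }
  list(params = params, history = do.call(rbind, hist),
       converged = converged, epochs = total_epochs)
}

#' Sample spikes from a rate series
#'
#' Inhomogeneous Poisson: per time bin the count is Poisson with mean
#' `gain * rate * dt`, spike times uniform within the bin.
#'
#' @param rates nonnegative rate series (arbitrary units).
#' @param gain scaling to spikes/s per rate unit.
#' @param dt bin width (s).
#' @param seed RNG seed.
#' @param t0 time of the first bin (s).
#' @return sorted spike times (s).
#' @export
sample_spikes_from_rates <- function(rates, gain = 10, dt = 0.02, seed = 1L,
                                     t0 = 0) {
  if (any(rates < 0)) stop_param("sample_spikes_from_rates: negative rates")
  with_seed(substream_seed(seed, "rate_spikes"), {
    counts <- stats::rpois(length(rates), gain * rates * dt)
    idx <- rep(seq_along(rates), counts)
    sort(t0 + (idx - 1L) * dt + stats::runif(length(idx), 0, dt))
  })
}

#' Reference oscillation with a fixed phase at an anchor time
#'
#' A sinusoid at the LFP peak frequency whose phase is 0 exactly at
#' `anchor_time` (the onset of the last sample stimulus in the model
#' analysis).
#'
#' @param f_peak frequency (Hz, > 0).
#' @param anchor_time time at which the phase is 0 (s).
#' @return list of class `reference_oscillation` with `f`, `anchor` and
#'   `phase_at(t)`.
#' @export
model_reference_oscillation <- function(f_peak, anchor_time) {
  if (f_peak <= 0) stop_param("model_reference_oscillation: f_peak must be > 0")
  force(f_peak); force(anchor_time)
  structure(list(f = f_peak, anchor = anchor_time,
                 phase_at = function(t)
                   wrap_angle(2 * pi * f_peak * (t - anchor_time))),
            class = "reference_oscillation")
}

#' Identify stimulus-responsive, stimulus-selective model units
#'
#' A unit is responsive when its stimulus-period rate exceeds its
#' baseline-period rate across trials (paired Wilcoxon signed-rank,
#' p < 0.001); its preferred stimulus is the one with the largest mean
#' evoked rate.
#'
#' @param traj an `rnn_trajectory` with rates.
#' @param batch the `task_batch`.
#' @param p_threshold responsiveness threshold (default 0.001).
#' @return data.frame with `unit`, `p`, `preferred` (stimulus id 1-8) for
#'   responsive units.
#' @export
selective_units <- function(traj, batch, p_threshold = 0.001) {
  times <- batch$times
  base_idx <- which(times < batch$stim_on[1])
  stim_idx <- which(times >= batch$stim_on[1] & times < batch$delay_on)
  N <- dim(traj$rates)[2]
  out <- lapply(seq_len(N), function(i) {
    rb <- colMeans(traj$rates[base_idx, i, ])     # per trial baseline
    rs <- colMeans(traj$rates[stim_idx, i, ])     # per trial stimulus
    if (all(rs == rb)) return(NULL)
    p <- suppressWarnings(stats::wilcox.test(rs, rb, paired = TRUE,
                                             alternative = "greater")$p.value)
    if (!is.finite(p) || p >= p_threshold) return(NULL)
    # mean evoked rate per stimulus identity (over its presentation window)
    ev <- vapply(1:8, function(s) {
      tot <- 0; cnt <- 0
      for (k in 1:4) {
        tr <- which(batch$seq[, k] == s)
        if (!length(tr)) next
        win <- times >= batch$stim_on[k] &
          times < batch$stim_on[k] + batch$soa
        tot <- tot + sum(traj$rates[win, i, tr]); cnt <- cnt + sum(win) *
          length(tr)
      }
      if (cnt == 0) -Inf else tot / cnt
    }, numeric(1))
    data.frame(unit = i, p = p, preferred = which.max(ev))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) data.frame(unit = integer(), p = numeric(),
                               preferred = integer()) else out
}

#' Phase samples of model units for the circular analyses
#'
#' For each selective unit and each trial containing its preferred
#' stimulus, delay-period rates are normalized per unit, samples above the
#' unit's `threshold` quantile are kept, and their reference-oscillation
#' phases are averaged circularly with rate weights, giving one mean phase
#' per trial labelled by the preferred stimulus' sequence position. The
#' result feeds [vex_permutation_test()] and [phase_order()] unchanged.
#'
#' @param traj an `rnn_trajectory` with rates.
#' @param batch the `task_batch`.
#' @param reference a `reference_oscillation`.
#' @param units data.frame from [selective_units()].
#' @param threshold rate quantile kept (default 0.5, the median).
#' @return list of [phase_sample_set()] (one per unit; empty samples are
#'   flagged with `empty = TRUE` attributes and dropped from the list,
#'   with names preserved).
#' @export
model_phase_analysis <- function(traj, batch, reference, units,
                                 threshold = 0.5) {
  if (nrow(units) == 0L) {
    out <- list(); attr(out, "empty") <- TRUE
    return(out)
  }
  times <- batch$times
  del <- which(times >= batch$delay_on & times < batch$delay_off)
  ph_t <- reference$phase_at(times[del])
  out <- list()
  for (j in seq_len(nrow(units))) {
    i <- units$unit[j]; pref <- units$preferred[j]
    R <- traj$rates[del, i, , drop = TRUE]          # delay samples x trials
    rng <- range(R)
    if (diff(rng) <= 0) next
    Rn <- (R - rng[1]) / diff(rng)
    thr <- stats::quantile(Rn, threshold)
    phases <- numeric(0); conds <- integer(0)
    for (b in seq_len(ncol(Rn))) {
      pos <- match(pref, batch$seq[b, ])
      if (is.na(pos)) next
      keep <- Rn[, b] > thr
      if (!any(keep)) next
      cm <- circular_mean(ph_t[keep], w = Rn[keep, b])
      if (cm$undefined) next
      phases <- c(phases, cm$mean); conds <- c(conds, pos)
    }
    if (length(phases) == 0L) next
    out[[as.character(i)]] <- phase_sample_set(phases, conds, unit_id = i,
                                               frequency = reference$f)
  }
  if (length(out) == 0L) attr(out, "empty") <- TRUE
  out
}
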