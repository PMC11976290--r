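# Circular variance explained (V_ex): the fraction of circular variance in
# per-trial mean phases accounted for by condition (sequence position)
# labels, with a trial-label permutation null. Definitions:
#   V_j^w = 1 - | (1/N_j) sum_{k in j} e^{i theta_k} |   (within condition j)
#   V^w   = (1/N) sum_j N_j V_j^w                         (pooled within)
#   V^a   = 1 - | (1/N) sum_k e^{i theta_k} |             (across conditions)
#   V_ex  = 1 - V^w / V^a

#' Construct a phase sample set
#'
#' One row per trial: the trial's mean phase of firing during the analysis
#' window and its condition (sequence position) label. Trials without spikes
#' are simply absent.
#'
#' @param phase per-trial mean phases (radians).
#' @param condition integer condition labels (e.g. positions 1..4).
#' @param weight optional per-trial weights (spike counts); default 1.
#' @param unit_id,frequency,correct optional metadata carried along.
#' @return data.frame of class `phase_sample_set`.
#' @export
phase_sample_set <- function(phase, condition, weight = NULL,
                             unit_id = NA, frequency = NA, correct = NULL) {
  if (length(phase) != length(condition))
    stop_param("phase_sample_set: length mismatch")
  if (any(!is.finite(phase))) stop_param("phase_sample_set: non-finite phase")
  d <- data.frame(phase = wrap_angle(phase),
                  condition = as.integer(condition),
                  weight = if (is.null(weight)) 1 else weight)
  if (!is.null(correct)) d$correct <- correct
  attr(d, "unit_id") <- unit_id
  attr(d, "frequency") <- frequency
  class(d) <- c("phase_sample_set", "data.frame")
  d
}

#' Circular variance explained by condition labels (point estimate)
#'
#' @param samples a [phase_sample_set()] (or data.frame with `phase` and
#'   `condition` columns).
#' @return list with `V_within` (named per condition), `Vw`, `Va`, `Vex`,
#'   `n_per_condition`, `n`.
#' @export
vex <- function(samples) {
  th <- samples$phase
  g <- samples$condition
  tab <- table(g)
  if (length(tab) < 2L || any(tab < 2L))
    stop_param("vex: need >= 2 conditions with >= 2 trials each")
  N <- length(th)
  z <- exp(1i * th)
  Sj <- vapply(split(z, g), sum, complex(1))
  Nj <- as.numeric(tab)
  Vj <- 1 - Mod(Sj) / Nj
  Vw <- sum(Nj * Vj) / N
  Va <- 1 - Mod(sum(z)) / N
  if (Va <= .Machine$double.eps * N)
    stop_param("vex: V^a = 0 (all phases identical), V_ex undefined")
  list(V_within = stats::setNames(Vj, names(tab)), Vw = Vw, Va = Va,
       Vex = 1 - Vw / Va,
       n_per_condition = stats::setNames(Nj, names(tab)), n = N)
}

# multiset permutations (used only when exhaustive enumeration is feasible)
multiset_perms <- function(labels) {
  labels <- sort(labels)
  res <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0L) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(rest)) {
      i <- match(v, rest)
      rec(c(prefix, v), rest[-i])
    }
  }
  rec(integer(0), labels)
  do.call(rbind, res)
}

#' Permutation test for V_ex
#'
#' Shuffles condition labels across trials `n_perm` times; the p-value uses
#' the add-one convention p = (1 + #\{null >= observed\}) / (1 + n_perm).
#' When the number of distinct relabelings is below `n_perm` and
#' enumeration is feasible, the exact permutation distribution is used
#' instead (with a warning).
#'
#' @param samples a [phase_sample_set()].
#' @param n_perm number of label permutations (default 1999).
#' @param seed integer seed for the shuffles.
#' @param keep_null return the null distribution (default TRUE).
#' @return list with the [vex()] fields plus `p`, `null` and `n_perm`.
#' @export
vex_permutation_test <- function(samples, n_perm = 1999L, seed = 1L,
                                 keep_null = TRUE) {
  obs <- vex(samples)
  th <- samples$phase
  g <- as.integer(factor(samples$condition))
  N <- length(th)
  z <- exp(1i * th)
  n_distinct <- exp(lgamma(N + 1) - sum(lgamma(table(g) + 1)))
  exact <- FALSE
  if (n_distinct < n_perm && N <= 10) {
    warning("vex_permutation_test: fewer distinct relabelings than n_perm; ",
            "enumerating exhaustively")
    labmat <- multiset_perms(g)
    exact <- TRUE
  }
  if (exact) {
    G <- t(sapply(sort(unique(g)), function(j) as.numeric(g == j))) # K x N
    Nj <- as.numeric(table(g))
    null <- apply(labmat, 1L, function(lab) {
      Sj <- vapply(split(z, lab), sum, complex(1))
      Vw <- sum(Nj * (1 - Mod(Sj) / Nj)) / N
      1 - Vw / obs$Va
    })
    n_used <- length(null)
  } else {
    idx <- with_seed(seed, {
      matrix(unlist(lapply(seq_len(n_perm), function(i) sample.int(N))),
             nrow = N)
    })
    Zp <- matrix(z[idx], nrow = N)          # N x P permuted phases
    G <- matrix(0, max(g), N)
    G[cbind(g, seq_len(N))] <- 1            # K x N condition indicator
    S <- G %*% Zp                           # K x P complex condition sums
    Vw_null <- 1 - colSums(Mod(S)) / N
    null <- 1 - Vw_null / obs$Va
    n_used <- n_perm
  }
  p <- (1 + sum(null >= obs$Vex)) / (1 + n_used)
  c(obs, list(p = p, null = if (keep_null) null else NULL,
              n_perm = n_used, exact = exact))
}

#' Aggregate per-frequency V_ex significance into a unit-level decision
#'
#' A unit counts as significant when its observed V_ex exceeds the 95th
#' percentile of its permutation null (p < alpha) for at least
#' `min_frequencies` frequencies of the analysis grid.
#'
#' @param p_values per-frequency permutation p-values for one unit.
#' @param alpha significance level (default 0.05).
#' @param min_frequencies required number of significant frequencies
#'   (default 2).
#' @return logical.
#' @export
unit_significant <- function(p_values, alpha = 0.05, min_frequencies = 2L) {
  sum(p_values < alpha, na.rm = TRUE) >= min_frequencies
}

#' Hedges' g effect size
#'
#' Bias-corrected standardized mean difference between two samples
#' (correction factor J = 1 - 3 / (4 df - 1), df = n_a + n_b - 2).
#'
#' @param a,b numeric samples with n >= 2 each.
#' @return scalar g (positive when mean(a) > mean(b)).
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop_param("hedges_g: need n >= 2 per sample")
  df <- na + nb - 2
  s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (s2 <= 0) stop_param("hedges_g: zero pooled variance")
  (mean(a) - mean(b)) / sqrt(s2) * (1 - 3 / (4 * df - 1))
}

#' Bootstrap confidence interval for a proportion of significant units
#'
#' Resamples units with replacement and returns the percentile CI of the
#' proportion.
#'
#' @param significant logical vector, one entry per unit.
#' @param n_boot bootstrap replicates (default 1999).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list with `proportion`, `ci` (length 2), `n_units`, `degenerate`
#'   (TRUE when only one unit is available).
#' @export
bootstrap_proportion <- function(significant, n_boot = 1999L, seed = 1L,
                                 conf = 0.95) {
  n <- length(significant)
  if (n == 0L) stop_param("bootstrap_proportion: empty input")
  prop <- mean(significant)
  boots <- with_seed(seed, {
    m <- matrix(sample(significant, n * n_boot, replace = TRUE), nrow = n)
    colMeans(m)
  })
  a <- (1 - conf) / 2
  list(proportion = prop,
       ci = unname(stats::quantile(boots, c(a, 1 - a))),
       n_units = n, degenerate = n == 1L)
}

#' Simes multiple-testing correction
#'
#' Stepwise Simes-adjusted p-values (identical to Benjamini-Hochberg
#' adjusted values, via [stats::p.adjust()]) together with the global Simes
#' p-value min_i (m * p_(i) / i).
#'
#' @param p p-values in (0, 1].
#' @param alpha rejection threshold for the returned decisions.
#' @return list with `adjusted`, `reject`, `global_p`.
#' @export
simes_correct <- function(p, alpha = 0.05) {
  if (any(p <= 0 | p > 1 | !is.finite(p)))
    stop_param("simes_correct: p-values must lie in (0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  m <- length(p)
  global_p <- min(m * sort(p) / seq_len(m))
  list(adjusted = adj, reject = adj < alpha, global_p = min(global_p, 1))
}

#' Rate-matched spike subsampling
#'
#' Control for spike-count differences between two conditions: the larger
#' spike set is randomly subsampled to the size of the smaller so phase
#' statistics are compared at matched counts. Call repeatedly (varying
#' `seed`) and average for a stable control.
#'
#' @param spikes_a,spikes_b vectors (spike times or phases).
#' @param seed RNG seed.
#' @return list with `a`, `b` (equal length) and `n`.
#' @export
rate_matched_subsample <- function(spikes_a, spikes_b, seed = 1L) {
  if (length(spikes_a) == 0L || length(spikes_b) == 0L)
    stop_param("rate_matched_subsample: empty spike set")
  n <- min(length(spikes_a), length(spikes_b))
  with_seed(seed, {
    a <- if (length(spikes_a) > n) sort(sample(spikes_a, n)) else spikes_a
    b <- if (length(spikes_b) > n) sort(sample(spikes_b, n)) else spikes_b
    list(a = a, b = b, n = n)
  })
}
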