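# Phase-order analysis: anchoring per-position preferred phases, extracting
# the circular order of positions, rotation-equivalence classes (1,2,3,4 ==
# 4,1,2,3 == ...), chance probabilities by enumeration, and the phase-reset
# model that predicts the order from stimulus timing (SOA) and oscillation
# frequency.

#' Anchor per-position phases to their circular mean
#'
#' Subtracts the circular mean across positions from each position's phase,
#' so phases are expressed relative to 0 and comparable across units.
#'
#' @param phases one phase per position (radians).
#' @return list with `anchored` (radians in (-pi, pi]), `mean_phase`,
#'   `undefined` (TRUE when the resultant across positions vanishes and
#'   anchoring is not defined).
#' @export
anchor_phases <- function(phases) {
  if (any(!is.finite(phases))) stop_param("anchor_phases: non-finite phases")
  cm <- circular_mean(phases)
  if (cm$undefined)
    return(list(anchored = rep(NA_real_, length(phases)),
                mean_phase = NA_real_, undefined = TRUE))
  list(anchored = circ_diff(phases, cm$mean),
       mean_phase = cm$mean, undefined = FALSE)
}

# rotation-invariant canonical label: rotate the order so it starts at
# position 1, e.g. (3,4,1,2) -> "1-2-3-4"
canonical_class <- function(order) {
  k <- match(1L, order)
  paste(order[c(seq(k, length(order)), seq_len(k - 1L))], collapse = "-")
}

#' Extract the circular order of positions from their phases
#'
#' Phases are sorted counter-clockwise (ascending) and the position indices
#' are read off in that order. Orders are compared under rotation
#' equivalence; the category is `"forward"` when the class matches
#' (1,2,...,n), `"reverse"` when it matches (n,...,2,1), else `"other"`.
#' Exact phase ties are broken toward the lower position index and flagged.
#'
#' @param phases one phase per position (radians); anchored or raw (the
#'   order is rotation invariant either way).
#' @return list of class `phase_order` with `order` (permutation of
#'   positions), `canonical` (class label string), `category`, `tie`.
#' @export
phase_order <- function(phases) {
  n <- length(phases)
  if (n < 3L) stop_param("phase_order: need >= 3 positions")
  if (any(!is.finite(phases))) stop_param("phase_order: non-finite phases")
  th <- wrap_angle(phases)
  ord <- order(th, seq_len(n))        # ties -> lower position index first
  tie <- anyDuplicated(th) > 0L
  cls <- canonical_class(ord)
  fwd <- canonical_class(seq_len(n))
  rev_ <- canonical_class(rev(seq_len(n)))
  category <- if (cls == fwd) "forward" else if (cls == rev_) "reverse"
              else "other"
  structure(list(order = ord, canonical = cls, category = category,
                 tie = tie), class = "phase_order")
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

#' Chance probabilities of phase-order categories
#'
#' Computed by exhaustive enumeration of all permutations of `seq_len`
#' positions under rotation equivalence (a uniformly random phase quadruple
#' induces a uniformly random permutation). Two partitions are reported:
#' the mutually exclusive one (forward / reverse / other summing to 1) and
#' complements (`not_forward`, `not_reverse`).
#'
#' @param seq_len sequence length (>= 3; 4 in the task).
#' @return list with `forward`, `reverse`, `other`, `not_forward`,
#'   `not_reverse`, `n_classes`.
#' @export
chance_probabilities <- function(seq_len = 4L) {
  if (seq_len < 3L) stop_param("chance_probabilities: seq_len must be >= 3")
  pm <- perms(as.integer(seq_len))
  cls <- apply(pm, 1L, canonical_class)
  fwd <- canonical_class(seq_len(seq_len))
  rev_ <- canonical_class(rev(seq_len(seq_len)))
  p_f <- mean(cls == fwd)
  p_r <- mean(cls == rev_)
  list(forward = p_f, reverse = p_r, other = 1 - p_f - p_r,
       not_forward = 1 - p_f, not_reverse = 1 - p_r,
       n_classes = length(unique(cls)))
}

#' Phase-reset model: predicted phases and order from SOA and frequency
#'
#' If a stimulus resets a unit's firing phase to a fixed value at its own
#' onset while the reference oscillation runs on, the phase (relative to the
#' reference) of the unit preferring the stimulus at position k is
#' phi0 + 2*pi*f_osc*(k-1)*soa. The order of positions along the circle then
#' depends only on the fractional cycle advance f_osc*soa mod 1 (and phi0).
#'
#' @param f_osc reference oscillation frequency (Hz), > 0.
#' @param soa stimulus onset asynchrony (s), > 0.
#' @param phi0 phase at the first stimulus onset (radians, default 0).
#' @param n_positions sequence length (default 4).
#' @return list of class `reset_prediction` with `phases`, `order`,
#'   `canonical`, `category`, `degenerate` (TRUE when f_osc*soa is integral
#'   and all predicted phases coincide), `cycle_advance`.
#' @export
predict_reset_phases <- function(f_osc, soa, phi0 = 0, n_positions = 4L) {
  if (f_osc <= 0 || soa <= 0)
    stop_param("predict_reset_phases: f_osc and soa must be > 0")
  k <- seq_len(n_positions) - 1L
  phases <- wrap_angle(phi0 + 2 * pi * f_osc * soa * k)
  adv <- (f_osc * soa) %% 1
  degenerate <- isTRUE(all.equal(adv, 0)) || isTRUE(all.equal(adv, 1))
  po <- phase_order(phases)
  structure(list(phases = phases, order = po$order, canonical = po$canonical,
                 category = po$category, degenerate = degenerate,
                 cycle_advance = adv, f_osc = f_osc, soa = soa, phi0 = phi0),
            class = "reset_prediction")
}

#' Match rate between observed and predicted phase orders
#'
#' Proportion of units whose observed canonical order class equals the
#' reset-model prediction, with a permutation null built by shuffling the
#' unit-to-(frequency, SOA) assignment, i.e. shuffling predictions across
#' units.
#'
#' @param observed character vector of canonical class labels (or list of
#'   `phase_order` objects).
#' @param predicted same length, predicted canonical classes (or list of
#'   `reset_prediction` objects).
#' @param n_shuffles permutation count for the null (default 999).
#' @param seed RNG seed.
#' @return list with `proportion`, `p`, `null`, `n`.
#' @export
order_match_rate <- function(observed, predicted, n_shuffles = 999L,
                             seed = 1L) {
  lab <- function(x) if (is.list(x)) vapply(x, `[[`, "", "canonical") else x
  obs <- lab(observed); prd <- lab(predicted)
  if (length(obs) != length(prd)) stop_param("order_match_rate: length mismatch")
  n <- length(obs)
  prop <- mean(obs == prd)
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) mean(obs == prd[sample.int(n)]), numeric(1))
  })
  p <- (1 + sum(null >= prop)) / (1 + n_shuffles)
  list(proportion = prop, p = p, null = null, n = n)
}
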