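# Circular-statistics core. These primitives underpin the circular variance
# explained machinery, so they are implemented here rather than pulled from a
# general-purpose package: circular mean / resultant, Rayleigh uniformity
# test, von Mises maximum-likelihood fit and the Best-Fisher sampler.

#' Circular mean and resultant length
#'
#' @param phases numeric vector of angles in radians.
#' @param w optional nonnegative weights (e.g. spike counts).
#' @return list with `mean` (angle in `[0, 2*pi)`, `NA` when the resultant
#'   length is numerically zero and the mean direction is undefined, flagged
#'   via `undefined = TRUE`), `R` (resultant length in `[0, 1]`) and `n`.
#' @export
circular_mean <- function(phases, w = NULL) {
  if (length(phases) == 0L) stop_param("circular_mean: empty sample")
  if (any(!is.finite(phases))) stop_param("circular_mean: non-finite phases")
  if (is.null(w)) w <- rep(1, length(phases))
  if (length(w) != length(phases) || any(w < 0))
    stop_param("circular_mean: bad weights")
  z <- sum(w * exp(1i * phases)) / sum(w)
  R <- Mod(z)
  undefined <- R < 1e-12
  list(mean = if (undefined) NA_real_ else wrap_angle(Arg(z)),
       R = R, n = length(phases), undefined = undefined)
}

#' Rayleigh test of circular uniformity
#'
#' Test statistic Z = n * R^2 with the standard series approximation for the
#' p-value; for very small samples (n < 5) the null is simulated instead.
#'
#' @param phases angles in radians.
#' @param n_sim Monte-Carlo draws for the small-sample fallback.
#' @return list with `Z`, `p`, `R`, `n`.
#' @export
rayleigh_test <- function(phases, n_sim = 10000L) {
  n <- length(phases)
  if (n == 0L) stop_param("rayleigh_test: empty sample")
  cm <- circular_mean(phases)
  Z <- n * cm$R^2
  if (n >= 5L) {
    # Zar (1999) approximation, as used by the common circular toolboxes
    p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                      (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
    p <- min(max(p, .Machine$double.xmin), 1)
  } else {
    warning("rayleigh_test: n < 5, p-value by Monte-Carlo simulation")
    zs <- vapply(seq_len(n_sim), function(i) {
      th <- stats::runif(n, 0, 2 * pi)
      n * circular_mean(th)$R^2
    }, numeric(1))
    p <- (1 + sum(zs >= Z)) / (1 + n_sim)
  }
  list(Z = Z, p = p, R = cm$R, n = n)
}

# Fisher's three-regime approximation to the inverse of A(kappa) = I1/I0
a1inv <- function(R) {
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

#' Maximum-likelihood von Mises fit
#'
#' Estimates the preferred direction mu (circular mean) and concentration
#' kappa by inverting the resultant length, A(kappa) = R. Optionally the fit
#' can be run on binned phases (phase histogram), mirroring fits to spike
#' distributions across phase bins.
#'
#' @param phases angles in radians.
#' @param w optional weights.
#' @param bins if not `NULL`, phases are first binned into this many equal
#'   bins and the fit uses bin centers weighted by counts.
#' @param kappa_max cap applied when R is numerically 1 (point mass).
#' @return list with `mu`, `kappa`, `R`, `n`, `capped`.
#' @export
fit_von_mises <- function(phases, w = NULL, bins = NULL, kappa_max = 1e3) {
  if (length(phases) < 2L) stop_param("fit_von_mises: need >= 2 phases")
  if (!is.null(bins)) {
    br <- seq(0, 2 * pi, length.out = bins + 1L)
    idx <- findInterval(wrap_angle(phases), br, rightmost.closed = TRUE)
    cnt <- tabulate(idx, nbins = bins)
    ctr <- (br[-1] + br[-(bins + 1L)]) / 2
    keep <- cnt > 0
    phases <- ctr[keep]; w <- cnt[keep]
  }
  cm <- circular_mean(phases, w)
  capped <- FALSE
  if (cm$R >= 1 - 1e-12) {
    kappa <- kappa_max; capped <- TRUE
  } else {
    kappa <- max(0, a1inv(cm$R))
    if (kappa > kappa_max) { kappa <- kappa_max; capped <- TRUE }
  }
  list(mu = cm$mean, kappa = kappa, R = cm$R, n = cm$n, capped = capped)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; reduces to uniform angles at kappa = 0.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return angles in `[0, 2*pi)`. Uses the current RNG stream.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop_param("rvonmises: kappa must be >= 0")
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}
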