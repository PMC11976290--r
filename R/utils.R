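#' @keywords internal
"_PACKAGE"

# All randomness in the package flows from one user seed through named
# substreams so each component (trials, lfp, spikes, ...) is independently
# reproducible. Substream seeds are derived by hashing the name into the
# 32-bit integer range.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code never disturbs the
#' caller's RNG state.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Wrap angles into [0, 2*pi)
#' @param x angles in radians.
#' @return angles in `[0, 2*pi)`.
#' @export
wrap_angle <- function(x) x %% (2 * pi)

# signed circular difference a - b in (-pi, pi]
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_param <- function(...) stop(..., call. = FALSE)
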