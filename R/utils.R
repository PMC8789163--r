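#' @keywords internal
"_PACKAGE"

## Smooth primitives shared across the package. Every switching construct in
## the mechanics (contact on/off, concentric/eccentric heat, activation vs
## deactivation) goes through these so that all model functions are C-infinity
## and safe for derivative-based optimization.

#' Smooth approximation of the Heaviside step
#'
#' `(tanh(b * x) + 1) / 2`: approaches 0 for `x << 0` and 1 for `x >> 0`.
#'
#' @param x numeric vector.
#' @param b sharpness (1/units of `x`); larger is closer to a hard switch.
#' @return numeric vector in (0, 1).
#' @keywords internal
smooth_step <- function(x, b) 0.5 * tanh(b * x) + 0.5

#' Smooth approximation of `max(x, 0)`
#'
#' `0.5 * (x + sqrt(x^2 + eps^2))`; equals `max(x, 0)` up to O(eps).
#'
#' @param x numeric vector.
#' @param eps regularization scale (units of `x`).
#' @return numeric vector `>= 0`... strictly positive for finite input.
#' @keywords internal
smooth_pos <- function(x, eps) 0.5 * (x + sqrt(x * x + eps * eps))

#' Stop with a classed configuration error
#' @noRd
config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("predgait_config_error", "error")))
}

#' Near-equality helper for structural comparisons
#' @noRd
num_eq <- function(a, b, tol = 0) {
  if (tol == 0) identical(a, b) else isTRUE(all(abs(a - b) <= tol))
}

## Small deterministic RNG scope: run expr with a local seed without
## clobbering the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Periodic cubic-spline resampling on a 0-1 cycle fraction axis
#'
#' @param x cycle fractions of the samples in `[0, 1)` (need not include 1).
#' @param y sample values; `y[1]` is also the value at cycle fraction 1.
#' @param xout cycle fractions to evaluate at (any real; wrapped mod 1).
#' @return numeric vector of resampled values.
#' @keywords internal
periodic_resample <- function(x, y, xout) {
  f <- stats::splinefun(c(x, x[1] + 1), c(y, y[1]), method = "periodic")
  f(xout %% 1)
}
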