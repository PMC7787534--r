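#' Discretized depth axis
#'
#' The observer model evaluates all likelihoods and posteriors on a regular
#' grid over perceived depth. The model axis is in centimetres: the stimulus
#' interface works in millimetres (hand movement 24 mm, visual heights up to
#' +/-20 mm) but the model's spread parameters (sigma_h, sigma_v) are of order
#' 0.1--2, which is only consistent with the stimulus scale if the axis is in
#' cm. The default grid spans -5 to 5 cm (i.e. -50 to 50 mm) in 0.01 cm steps.
#'
#' Grid values are built as integer multiples of `step` whenever `lo` and `hi`
#' are themselves multiples of `step`, so that 0 is represented exactly on
#' symmetric grids (the sign of depth carries the protrude/concave meaning,
#' so the zero sample matters).
#'
#' @param lo,hi grid limits in cm (`lo < hi`; the grid must straddle zero)
#' @param step positive grid spacing in cm
#' @return an object of class `depth_grid` with fields `lo`, `hi`, `step`,
#'   `values`
#' @examples
#' g <- depth_grid()
#' range(g$values)
#' any(g$values == 0)
#' @export
depth_grid <- function(lo = -5, hi = 5, step = 0.01) {
  stopifnot(is.numeric(lo), length(lo) == 1L, is.finite(lo),
            is.numeric(hi), length(hi) == 1L, is.finite(hi),
            is.numeric(step), length(step) == 1L, is.finite(step))
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (lo >= hi) stop("`lo` must be smaller than `hi`", call. = FALSE)
  i0 <- round(lo / step)
  i1 <- round(hi / step)
  if (abs(i0 * step - lo) < 1e-9 && abs(i1 * step - hi) < 1e-9) {
    values <- (i0:i1) * step
  } else {
    values <- seq(lo, hi, by = step)
  }
  if (!any(values > 0) || !any(values < 0))
    stop("depth grid must straddle zero", call. = FALSE)
  structure(list(lo = lo, hi = hi, step = step, values = values),
            class = "depth_grid")
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> [%g, %g] cm, step %g (%d samples)\n",
              x$lo, x$hi, x$step, length(x$values)))
  invisible(x)
}

#' Normalized density over a depth grid
#'
#' Wraps a vector of nonnegative weights over a [depth_grid()] and normalizes
#' it so the Riemann integral (`sum(w) * step`) is exactly 1. Likelihoods,
#' priors and posteriors are all represented this way.
#'
#' @param grid a [depth_grid()]
#' @param w nonnegative finite weights, one per grid sample; need not be
#'   normalized
#' @return an object of class `depth_density` with fields `grid` and `w`
#' @export
depth_density <- function(grid, w) {
  if (!inherits(grid, "depth_grid"))
    stop("`grid` must be a depth_grid", call. = FALSE)
  w <- as.numeric(w)
  if (length(w) != length(grid$values))
    stop("`w` must have one weight per grid sample", call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and nonnegative", call. = FALSE)
  tot <- sum(w) * grid$step
  if (tot <= 0)
    stop("density has zero total mass", call. = FALSE)
  structure(list(grid = grid, w = w / tot), class = "depth_density")
}

#' @export
print.depth_density <- function(x, ...) {
  cat(sprintf("<depth_density> on [%g, %g] cm; mean %.4f cm, P(S>0) = %.4f\n",
              x$grid$lo, x$grid$hi, density_mean(x), prob_positive(x)))
  invisible(x)
}

#' Riemann integral of a depth density
#'
#' Equals 1 (to numerical precision) for any density built by
#' [depth_density()]; exposed for invariant checking.
#'
#' @param d a `depth_density`
#' @return the Riemann integral over the grid
#' @export
density_integral <- function(d) {
  stopifnot(inherits(d, "depth_density"))
  sum(d$w) * d$grid$step
}

#' Mean of a depth density
#'
#' @param d a `depth_density`
#' @return the first moment, in cm
#' @export
density_mean <- function(d) {
  stopifnot(inherits(d, "depth_density"))
  sum(d$grid$values * d$w) * d$grid$step
}

#' Probability that perceived depth is positive
#'
#' Integrates a posterior (or any depth density) over depths greater than
#' zero. Positive depth corresponds to the "protrude" response in the
#' disparity task and the "convex" response in the shading task. Mass sitting
#' exactly on the zero sample is split evenly between the two responses, so a
#' symmetric density yields exactly 0.5.
#'
#' @param d a `depth_density`
#' @return a probability in `[0, 1]`
#' @export
prob_positive <- function(d) {
  stopifnot(inherits(d, "depth_density"))
  s <- d$grid$values
  p <- (sum(d$w[s > 0]) + 0.5 * sum(d$w[s == 0])) * d$grid$step
  min(max(p, 0), 1)
}

#' Posterior over depth from a visual and a haptic likelihood
#'
#' Pointwise product of the two likelihood densities, renormalized to unit
#' area. With a flat world prior over the grid this is the full Bayesian
#' posterior P(S | I_v, I_h); the shading priors enter through the visual
#' mixture weights, not through P(S).
#'
#' @param visual,haptic `depth_density` objects on the same grid
#' @return the posterior as a `depth_density`
#' @export
posterior <- function(visual, haptic) {
  stopifnot(inherits(visual, "depth_density"), inherits(haptic, "depth_density"))
  if (!isTRUE(all.equal(visual$grid$values, haptic$grid$values)))
    stop("visual and haptic densities must share a grid", call. = FALSE)
  w <- visual$w * haptic$w
  if (all(w == 0))
    stop("posterior is identically zero (disjoint supports or underflow)",
         call. = FALSE)
  depth_density(visual$grid, w)
}
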