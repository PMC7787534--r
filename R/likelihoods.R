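#' Haptic likelihood over depth
#'
#' Evaluates the mixture haptic likelihood on a depth grid:
#' a unit-peak Gaussian centred on the signed hand displacement plus a
#' constant tail of height `omega`, then normalized to unit area. Because the
#' density is renormalized over the grid, `omega` is a peak-relative height,
#' not a probability; `omega = 0` gives a (truncated) Gaussian and large
#' `omega` approaches the flat, haptics-ignored limit.
#'
#' @param grid a [depth_grid()]
#' @param params a [haptic_params()]
#' @return a `depth_density`
#' @examples
#' g <- depth_grid()
#' d <- haptic_likelihood(g, haptic_params(24, sigma_h = 0.5, omega = 0.05))
#' density_integral(d)
#' @export
haptic_likelihood <- function(grid, params) {
  stopifnot(inherits(grid, "depth_grid"), inherits(params, "haptic_params"))
  s <- grid$values
  w <- exp(-(s - params$mean_cm)^2 / (2 * params$sigma_h^2)) + params$omega
  depth_density(grid, w)
}

# unnormalized haptic weights; sigma_h = 0 degenerates to a delta at the
# nearest grid sample (used only by the constrained no-tail search)
.haptic_weights <- function(s, mean_cm, sigma_h, omega) {
  if (sigma_h == 0) {
    w <- as.numeric(abs(s - mean_cm) == min(abs(s - mean_cm)))
  } else {
    w <- exp(-(s - mean_cm)^2 / (2 * sigma_h^2))
  }
  w + omega
}

#' Disparity-defined visual likelihood over depth
#'
#' A single Gaussian centred on the displayed visual 3-D height, normalized
#' over the grid. Binocular disparity is treated as a metric, unimodal cue.
#'
#' @param grid a [depth_grid()]
#' @param params a [disparity_params()]
#' @return a `depth_density`
#' @export
visual_likelihood_disparity <- function(grid, params) {
  stopifnot(inherits(grid, "depth_grid"), inherits(params, "disparity_params"))
  s <- grid$values
  w <- exp(-(s - params$mean_cm)^2 / (2 * params$sigma_v^2))
  depth_density(grid, w)
}

#' Shape-from-shading prior weights
#'
#' Computes the weights applied to the convex and concave interpretations of
#' a shaded image with canonical light direction `theta_deg` (the direction
#' under the convex reading, 0 = from above, 180 = from below).
#'
#' The light-direction component pi_L is a pair of complementary cumulative
#' Gaussians in the light angle (expressed in radians), crossing at 0.5 for
#' side lighting (90 deg): overhead light favours the convex reading,
#' light from below favours the concave one. The convexity component pi_C is
#' a constant multiplicative preference for convex surfaces. The returned
#' weights are the products pi_C * pi_L for each interpretation.
#'
#' @param theta_deg canonical light direction(s) in degrees, in `[0, 180]`
#' @param params a [shading_params()]
#' @return a list with components `w_convex`, `w_concave` (the combined
#'   weights) and `pi_l_convex`, `pi_l_concave` (the light components alone),
#'   each vectorized over `theta_deg`
#' @examples
#' p <- shading_params(sigma_v = 1.3, pi_c_convex = 1.2, pi_c_concave = 0.8)
#' light_prior(90, p)$pi_l_convex  # 0.5 at side lighting
#' @export
light_prior <- function(theta_deg, params) {
  stopifnot(inherits(params, "shading_params"), is.numeric(theta_deg),
            all(is.finite(theta_deg)))
  if (any(theta_deg < 0 | theta_deg > 180))
    stop("`theta_deg` must lie in [0, 180]", call. = FALSE)
  z <- (theta_deg - 90) * pi / 180 / params$pi_l_spread
  pl_convex <- stats::pnorm(-z)
  pl_concave <- stats::pnorm(z)
  list(w_convex = params$pi_c_convex * pl_convex,
       w_concave = params$pi_c_concave * pl_concave,
       pi_l_convex = pl_convex,
       pi_l_concave = pl_concave)
}

#' Shading-defined visual likelihood over depth
#'
#' The depth-ambiguous shading likelihood: Gaussian modes at plus and minus
#' the deformation distance (the convex and concave readings of the image),
#' weighted by the shape-from-shading priors for the given canonical light
#' direction, summed and normalized.
#'
#' @param grid a [depth_grid()]
#' @param theta_deg canonical light direction in degrees, in `[0, 180]`
#' @param params a [shading_params()]
#' @return a `depth_density`
#' @export
visual_likelihood_shading <- function(grid, theta_deg, params) {
  stopifnot(inherits(grid, "depth_grid"), inherits(params, "shading_params"),
            is.numeric(theta_deg), length(theta_deg) == 1L)
  pr <- light_prior(theta_deg, params)
  s <- grid$values
  m <- params$mode_cm
  w <- pr$w_convex * exp(-(s - m)^2 / (2 * params$sigma_v^2)) +
       pr$w_concave * exp(-(s + m)^2 / (2 * params$sigma_v^2))
  depth_density(grid, w)
}
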