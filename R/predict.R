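#' Predicted response probabilities for the disparity task
#'
#' For each visual 3-D height, forms the posterior over depth from the
#' disparity visual likelihood and the mixture haptic likelihood for the
#' given movement direction, and returns the posterior mass on positive
#' depth, i.e. the model's probability of a "protrude" response.
#'
#' @param params a [model_params_exp1()]
#' @param heights_mm visual 3-D heights in mm (within the grid range)
#' @param movement `"push_away"` or `"pull_toward"`
#' @param grid a [depth_grid()]
#' @return a numeric vector of probabilities, one per height
#' @examples
#' active <- model_params_exp1(sigma_h = 0.5, omega = 0.05, sigma_v = 0.9)
#' predict_exp1(active, c(-10, 0, 10), "pull_toward")
#' @export
predict_exp1 <- function(params, heights_mm, movement, grid = depth_grid()) {
  stopifnot(inherits(params, "model_params_exp1"), is.numeric(heights_mm),
            all(is.finite(heights_mm)))
  movement <- .check_movement(movement, allow_visual_only = FALSE)
  if (any(heights_mm / 10 < grid$lo | heights_mm / 10 > grid$hi))
    stop("heights outside the depth grid range", call. = FALSE)
  hp <- haptic_params(.hand_sign(movement) * params$hand_distance_mm,
                      params$sigma_h, params$omega)
  h_lik <- haptic_likelihood(grid, hp)
  vapply(heights_mm, function(h) {
    v_lik <- visual_likelihood_disparity(grid, disparity_params(h, params$sigma_v))
    prob_positive(posterior(v_lik, h_lik))
  }, numeric(1))
}

#' Predicted response probabilities for the shading task
#'
#' For each canonical light direction, forms the prior-weighted bimodal
#' shading likelihood, combines it with the haptic likelihood (omitted in the
#' visual-only condition), and returns the posterior mass on positive depth,
#' i.e. the model's probability of a "convex" response.
#'
#' @param params a [model_params_exp2()]
#' @param thetas_deg canonical light directions in degrees, in `[0, 180]`
#'   (the experiment uses multiples of 30)
#' @param movement `"push_away"`, `"pull_toward"` or `"visual_only"`
#' @param grid a [depth_grid()]
#' @return a numeric vector of probabilities, one per light direction
#' @examples
#' m <- model_params_exp2(sigma_h = 0.3, omega = 0.425, sigma_v = 1.3,
#'                        pi_c_convex = 1.2, pi_c_concave = 0.8)
#' predict_exp2(m, seq(0, 180, 30), "pull_toward")
#' @export
predict_exp2 <- function(params, thetas_deg, movement, grid = depth_grid()) {
  stopifnot(inherits(params, "model_params_exp2"), is.numeric(thetas_deg))
  movement <- .check_movement(movement)
  h_lik <- NULL
  if (movement != "visual_only") {
    hp <- haptic_params(.hand_sign(movement) * params$hand_distance_mm,
                        params$sigma_h, params$omega)
    h_lik <- haptic_likelihood(grid, hp)
  }
  vapply(thetas_deg, function(th) {
    v_lik <- visual_likelihood_shading(grid, th, params$shading)
    d <- if (is.null(h_lik)) v_lik else posterior(v_lik, h_lik)
    prob_positive(d)
  }, numeric(1))
}
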