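#' Movement conditions
#'
#' The two hand-movement directions and the visual-only reference condition.
#' "pull_toward" deforms the surface toward the observer (positive depth,
#' convex); "push_away" deforms it away (negative depth, concave).
#' @keywords internal
.movements <- c("push_away", "pull_toward", "visual_only")

.check_movement <- function(movement, allow_visual_only = TRUE) {
  allowed <- if (allow_visual_only) .movements else .movements[1:2]
  movement <- match.arg(movement, allowed)
  movement
}

# signed hand displacement for a movement, in the model's cm axis
.hand_sign <- function(movement) {
  switch(movement, pull_toward = 1, push_away = -1,
         stop("no hand displacement in the visual-only condition", call. = FALSE))
}

#' Haptic likelihood parameters
#'
#' The haptic likelihood P(I_h | S) is a mixture of a Gaussian centred on the
#' signed hand displacement (the common-cause component C1) and a uniform
#' "tail" across the whole depth range (the independent-causes component C2).
#' The tail makes the haptic evidence ignorable whenever it is far from the
#' visual evidence, which is the causal-inference mechanism of the model.
#'
#' @param hand_distance_mm signed hand displacement in mm (positive =
#'   pull-toward / convex; both experiments use |d| = 24 mm)
#' @param sigma_h positive spread of the common-cause Gaussian, in cm; smaller
#'   for active movement (efference copy sharpens proprioception)
#' @param omega nonnegative height of the uniform tail relative to the unit
#'   peak of the Gaussian component, before area normalization
#' @return an object of class `haptic_params`
#' @export
haptic_params <- function(hand_distance_mm, sigma_h, omega) {
  stopifnot(is.numeric(hand_distance_mm), length(hand_distance_mm) == 1L,
            is.finite(hand_distance_mm),
            is.numeric(sigma_h), length(sigma_h) == 1L, is.finite(sigma_h),
            is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (sigma_h < 0) stop("`sigma_h` must be positive", call. = FALSE)
  if (sigma_h == 0) stop("`sigma_h` must be positive", call. = FALSE)
  if (omega < 0) stop("`omega` must be nonnegative", call. = FALSE)
  structure(list(hand_distance_mm = hand_distance_mm,
                 mean_cm = hand_distance_mm / 10,
                 sigma_h = sigma_h, omega = omega),
            class = "haptic_params")
}

#' Disparity-defined visual likelihood parameters
#'
#' In the first experiment the visual 3-D height is defined by binocular
#' disparity, a metric cue, so P(I_v | S) is a single Gaussian centred on the
#' displayed height.
#'
#' @param height_mm signed visual 3-D height in mm (positive = protruding)
#' @param sigma_v positive spread, in cm
#' @return an object of class `disparity_params`
#' @export
disparity_params <- function(height_mm, sigma_v) {
  stopifnot(is.numeric(height_mm), length(height_mm) == 1L, is.finite(height_mm),
            is.numeric(sigma_v), length(sigma_v) == 1L, is.finite(sigma_v))
  if (sigma_v <= 0) stop("`sigma_v` must be positive", call. = FALSE)
  structure(list(height_mm = height_mm, mean_cm = height_mm / 10,
                 sigma_v = sigma_v),
            class = "disparity_params")
}

#' Shading-defined visual likelihood parameters
#'
#' A shaded Lambertian bump under collimated light is depth-ambiguous: the
#' same image arises from a convex surface lit from direction theta and a
#' concave surface lit from the opposite direction. P(I_v | S) is therefore a
#' two-mode mixture, Gaussians at +/- the deformation distance (24 mm),
#' weighted by shape-from-shading priors: a light-direction weight pi_L
#' (light-from-above) and a constant convexity weight pi_C.
#'
#' @param sigma_v shared positive spread of both modes, in cm
#' @param pi_c_convex,pi_c_concave positive convexity-prior weights applied to
#'   the convex (+) and concave (-) modes; only their ratio matters after
#'   normalization
#' @param pi_l_spread positive spread of the cumulative-Gaussian
#'   light-direction prior, in radians of light angle
#' @param mode_distance_mm positive distance of the two modes from zero, in mm
#' @return an object of class `shading_params`
#' @export
shading_params <- function(sigma_v, pi_c_convex = 1, pi_c_concave = 1,
                           pi_l_spread = 0.7, mode_distance_mm = 24) {
  vals <- c(sigma_v = sigma_v, pi_c_convex = pi_c_convex,
            pi_c_concave = pi_c_concave, pi_l_spread = pi_l_spread,
            mode_distance_mm = mode_distance_mm)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0))
    stop("all shading parameters must be positive", call. = FALSE)
  structure(list(sigma_v = sigma_v, pi_c_convex = pi_c_convex,
                 pi_c_concave = pi_c_concave, pi_l_spread = pi_l_spread,
                 mode_distance_mm = mode_distance_mm,
                 mode_cm = mode_distance_mm / 10),
            class = "shading_params")
}

#' Full model parameter set for the disparity experiment
#'
#' Bundles the haptic parameters and the disparity visual spread used by
#' [predict_exp1()] and the first simulation's fitting stage.
#'
#' @param sigma_h haptic Gaussian spread, cm
#' @param omega uniform-tail height (peak-relative)
#' @param sigma_v visual Gaussian spread, cm
#' @param hand_distance_mm unsigned hand displacement, mm (sign is supplied by
#'   the movement direction at prediction time)
#' @return an object of class `model_params_exp1`
#' @export
model_params_exp1 <- function(sigma_h, omega, sigma_v, hand_distance_mm = 24) {
  stopifnot(is.numeric(hand_distance_mm), hand_distance_mm > 0)
  # constructor side-effect: validates ranges
  haptic_params(hand_distance_mm, sigma_h, omega)
  if (!is.numeric(sigma_v) || length(sigma_v) != 1L || sigma_v <= 0)
    stop("`sigma_v` must be positive", call. = FALSE)
  structure(list(sigma_h = sigma_h, omega = omega, sigma_v = sigma_v,
                 hand_distance_mm = hand_distance_mm),
            class = "model_params_exp1")
}

#' Full model parameter set for the shading experiment
#'
#' @inheritParams model_params_exp1
#' @inheritParams shading_params
#' @return an object of class `model_params_exp2`
#' @export
model_params_exp2 <- function(sigma_h, omega, sigma_v,
                              pi_c_convex = 1, pi_c_concave = 1,
                              pi_l_spread = 0.7, hand_distance_mm = 24) {
  haptic_params(hand_distance_mm, sigma_h, omega)
  sh <- shading_params(sigma_v, pi_c_convex, pi_c_concave, pi_l_spread,
                       mode_distance_mm = hand_distance_mm)
  structure(list(sigma_h = sigma_h, omega = omega, sigma_v = sigma_v,
                 pi_c_convex = pi_c_convex, pi_c_concave = pi_c_concave,
                 pi_l_spread = pi_l_spread, hand_distance_mm = hand_distance_mm,
                 shading = sh),
            class = "model_params_exp2")
}
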