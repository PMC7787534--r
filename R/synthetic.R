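#' Synthetic observer specification
#'
#' Describes a population of simulated observers sharing a generating model,
#' optionally with Gaussian inter-participant jitter on parameters (clipped
#' to valid ranges; default none, matching the homogeneous model). One root
#' seed drives everything; participant `i` uses the derived child seed
#' `(seed + 104729 * i) mod (2^31 - 1)` so tables are reproducible and
#' per-participant streams are independent of participant count.
#'
#' @param params a [model_params_exp1()] or [model_params_exp2()]
#' @param n_participants number of simulated participants (defaults: 8 for
#'   the disparity design, 13 for the shading design)
#' @param n_reps trials per condition cell (design default 8)
#' @param jitter optional named numeric vector of per-parameter SDs (names
#'   among the parameter fields, e.g. `c(sigma_h = 0.1)`)
#' @param seed integer root seed
#' @return an object of class `observer_spec`
#' @export
observer_spec <- function(params, n_participants = NULL, n_reps = 8,
                          jitter = NULL, seed = 1) {
  if (!inherits(params, c("model_params_exp1", "model_params_exp2")))
    stop("`params` must be a model parameter set", call. = FALSE)
  if (is.null(n_participants))
    n_participants <- if (inherits(params, "model_params_exp1")) 8L else 13L
  n_participants <- as.integer(n_participants)
  n_reps <- as.integer(n_reps)
  if (is.na(n_participants) || n_participants < 1L)
    stop("`n_participants` must be >= 1", call. = FALSE)
  if (is.na(n_reps) || n_reps < 1L)
    stop("`n_reps` must be >= 1", call. = FALSE)
  if (!is.null(jitter)) {
    if (is.null(names(jitter)) || any(!nzchar(names(jitter))) ||
        !is.numeric(jitter) || any(jitter < 0))
      stop("`jitter` must be a named nonnegative numeric vector", call. = FALSE)
    bad <- setdiff(names(jitter), names(unclass(params)))
    if (length(bad))
      stop("unknown jitter parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(list(params = params, n_participants = n_participants,
                 n_reps = n_reps, jitter = jitter, seed = seed),
            class = "observer_spec")
}

.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
}

# jitter a parameter set, clipping to validity; RNG state is the caller's
.jitter_params <- function(params, jitter) {
  if (is.null(jitter)) return(params)
  lows <- c(sigma_h = 1e-3, omega = 0, sigma_v = 1e-3, pi_c_convex = 1e-3,
            pi_c_concave = 1e-3, pi_l_spread = 1e-3, hand_distance_mm = 1e-3)
  p <- unclass(params)
  for (nm in names(jitter)) {
    val <- p[[nm]] + stats::rnorm(1, 0, jitter[[nm]])
    lo <- if (nm %in% names(lows)) lows[[nm]] else -Inf
    p[[nm]] <- max(val, lo)
  }
  if (inherits(params, "model_params_exp1")) {
    model_params_exp1(p$sigma_h, p$omega, p$sigma_v, p$hand_distance_mm)
  } else {
    model_params_exp2(p$sigma_h, p$omega, p$sigma_v, p$pi_c_convex,
                      p$pi_c_concave, p$pi_l_spread, p$hand_distance_mm)
  }
}

#' Simulate the disparity experiment
#'
#' Binomial responses for every movement direction x visual height cell,
#' drawn from the generating model's [predict_exp1()] probabilities (the
#' generator calls the prediction path; it does not reimplement it). The
#' default design is 2 movement directions x 10 heights (+/-1.2, 3.6, 6, 10,
#' 20 mm) x 8 repetitions x 8 participants.
#'
#' @param spec an [observer_spec()] built on [model_params_exp1()]
#' @param heights_mm visual heights in mm
#' @param grid a [depth_grid()]
#' @return a `response_table`
#' @examples
#' spec <- observer_spec(model_params_exp1(0.5, 0.05, 0.9), seed = 42)
#' tab <- simulate_exp1(spec)
#' nrow(tab)  # 8 participants x 2 movements x 10 heights
#' @export
simulate_exp1 <- function(spec,
                          heights_mm = c(-20, -10, -6, -3.6, -1.2,
                                         1.2, 3.6, 6, 10, 20),
                          grid = depth_grid()) {
  stopifnot(inherits(spec, "observer_spec"),
            inherits(spec$params, "model_params_exp1"))
  movements <- c("push_away", "pull_toward")
  rows <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    set.seed(.child_seed(spec$seed, i))
    pars <- .jitter_params(spec$params, spec$jitter)
    part <- lapply(movements, function(mv) {
      p <- predict_exp1(pars, heights_mm, mv, grid)
      data.frame(participant_id = sprintf("sim%02d", i), condition = mv,
                 level = heights_mm, n_trials = spec$n_reps,
                 n_positive = stats::rbinom(length(p), spec$n_reps, p),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, part)
  }
  out <- do.call(rbind, rows)
  response_table(out$participant_id, out$condition, out$level,
                 out$n_trials, out$n_positive)
}

#' Simulate the shading experiment (raw light directions)
#'
#' Binomial "convex" responses for every raw light direction x movement cell
#' plus a visual-only condition, drawn from the generating model's
#' [predict_exp2()] probabilities at the canonical direction each raw cell
#' folds to (so folding the simulated table reproduces the generating
#' canonical probabilities up to binomial noise). Default design: 13
#' participants, raw directions 0..330 in 30-degree steps, 8 repetitions.
#'
#' The paper's push-away asymmetry can be emulated by passing
#' `push_params` with a different tail (e.g. omega = 0.8); by default the
#' same parameters generate both movement directions.
#'
#' @param spec an [observer_spec()] built on [model_params_exp2()]
#' @param light_dirs_deg raw light directions in degrees
#' @param include_visual_only include the visual-only condition
#' @param push_params optional alternative [model_params_exp2()] for the
#'   push-away condition
#' @param grid a [depth_grid()]
#' @return a `response_table` in raw (unfolded) form
#' @export
simulate_exp2 <- function(spec, light_dirs_deg = seq(0, 330, by = 30),
                          include_visual_only = TRUE, push_params = NULL,
                          grid = depth_grid()) {
  stopifnot(inherits(spec, "observer_spec"),
            inherits(spec$params, "model_params_exp2"))
  if (!is.null(push_params))
    stopifnot(inherits(push_params, "model_params_exp2"))
  movements <- c("push_away", "pull_toward")
  if (include_visual_only) movements <- c(movements, "visual_only")
  rows <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    set.seed(.child_seed(spec$seed, i))
    pars <- .jitter_params(spec$params, spec$jitter)
    pars_push <- if (is.null(push_params)) pars
                 else .jitter_params(push_params, spec$jitter)
    part <- lapply(movements, function(mv) {
      thetas <- canonicalize(light_dirs_deg, mv)
      uth <- sort(unique(thetas))
      use <- if (mv == "push_away") pars_push else pars
      p_canon <- predict_exp2(use, uth, mv, grid)
      p <- p_canon[match(thetas, uth)]
      data.frame(participant_id = sprintf("sim%02d", i), condition = mv,
                 level = light_dirs_deg, n_trials = spec$n_reps,
                 n_positive = stats::rbinom(length(p), spec$n_reps, p),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, part)
  }
  out <- do.call(rbind, rows)
  response_table(out$participant_id, out$condition, out$level,
                 out$n_trials, out$n_positive)
}

#' Synthetic reference table: psychometric group statistics
#'
#' SYNTHETIC stand-in for a deposited per-participant response table, for
#' end-to-end verification of the psychometric pipeline. Eight simulated
#' participants are given deterministic PSE and JND values whose group mean
#' and sample SD equal planted targets (defaults: push-away PSE 1.6 mm, SD
#' 0.97; pull-toward PSE 1.1 mm, SD 1.5; JND -4, SD 2.12 and -5.1, SD 3.47),
#' and each cell stores the exact model response probability discretized at
#' `n_trials` trials. These are not recorded observations: a correct
#' pipeline recovers the planted group statistics; nothing about real
#' observers is established.
#'
#' @param n_trials trials per cell; large (default 8000) so that count
#'   discretization is negligible against the planted values
#' @param heights_mm stimulus levels in mm
#' @return a `response_table` with both movement conditions
#' @export
synthetic_reference_psychometric <- function(n_trials = 8000,
                                             heights_mm = c(-20, -10, -6, -3.6,
                                                            -1.2, 1.2, 3.6, 6,
                                                            10, 20)) {
  n <- 8L
  z <- as.numeric(scale(seq_len(n)))  # mean 0, sample SD 1
  q75 <- stats::qnorm(0.75)
  plant <- list(
    push_away = list(mu = 1.6 + 0.97 * z, sigma = (4 + 2.12 * z) / q75),
    pull_toward = list(mu = 1.1 + 1.5 * z, sigma = (5.1 + 3.47 * z) / q75))
  rows <- lapply(names(plant), function(mv) {
    pl <- plant[[mv]]
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- stats::pnorm((heights_mm - pl$mu[i]) / pl$sigma[i])
      data.frame(participant_id = sprintf("synth%02d", i), condition = mv,
                 level = heights_mm, n_trials = n_trials,
                 n_positive = as.integer(round(p * n_trials)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  response_table(out$participant_id, out$condition, out$level,
                 out$n_trials, out$n_positive)
}

#' Synthetic reference tables: disparity-task model probabilities
#'
#' SYNTHETIC noise-free stand-ins for deposited disparity-task observations:
#' every participant's cell holds the generating model's exact predicted
#' probability (discretized at `n_trials` trials). The active table is
#' generated at sigma_h = 0.5 and the passive one at sigma_h = 1.0, both
#' with omega = 0.05 and sigma_v = 0.9 — a planted ground truth the fitting
#' stages should recover exactly. Not recorded observations.
#'
#' @param condition `"active"` or `"passive"`
#' @param n_participants number of identical synthetic participants
#' @param n_trials trials per cell (large; discretization only)
#' @param params generating [model_params_exp1()]; default plants the values
#'   above
#' @param heights_mm stimulus levels in mm
#' @param grid a [depth_grid()]
#' @return a `response_table` with both movement conditions
#' @export
synthetic_reference_exp1 <- function(condition = c("active", "passive"),
                                     n_participants = 8, n_trials = 8000,
                                     params = NULL,
                                     heights_mm = c(-20, -10, -6, -3.6, -1.2,
                                                    1.2, 3.6, 6, 10, 20),
                                     grid = depth_grid()) {
  condition <- match.arg(condition)
  if (is.null(params)) {
    sh <- if (condition == "active") 0.5 else 1.0
    params <- model_params_exp1(sh, 0.05, 0.9)
  }
  rows <- lapply(c("push_away", "pull_toward"), function(mv) {
    p <- predict_exp1(params, heights_mm, mv, grid)
    do.call(rbind, lapply(seq_len(n_participants), function(i)
      data.frame(participant_id = sprintf("synth%02d", i), condition = mv,
                 level = heights_mm, n_trials = n_trials,
                 n_positive = as.integer(round(p * n_trials)),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  response_table(out$participant_id, out$condition, out$level,
                 out$n_trials, out$n_positive)
}

#' Synthetic reference table: shading-task model probabilities
#'
#' SYNTHETIC noise-free stand-in for deposited shading-task observations, in
#' canonical (folded) form. Cells hold the generating model's exact
#' predicted probabilities, discretized at `n_trials` trials, for 13
#' synthetic participants at the seven canonical light directions. Planted
#' ground truth: visual parameters pi_C = 1.2/0.8, sigma_v = 1.3, light
#' prior spread 0.7; pull-toward haptics sigma_h = 0.3, omega = 0.425;
#' push-away haptics sigma_h = 0.3, omega = 0.8. Not recorded observations.
#'
#' @param n_participants number of identical synthetic participants
#' @param n_trials trials per cell (large; discretization only)
#' @param grid a [depth_grid()]
#' @return a canonical `response_table` with pull-toward, push-away and
#'   visual-only conditions
#' @export
synthetic_reference_exp2 <- function(n_participants = 13, n_trials = 8000,
                                     grid = depth_grid()) {
  thetas <- seq(0, 180, by = 30)
  pull <- model_params_exp2(0.3, 0.425, 1.3, 1.2, 0.8, 0.7)
  push <- model_params_exp2(0.3, 0.8, 1.3, 1.2, 0.8, 0.7)
  probs <- list(pull_toward = predict_exp2(pull, thetas, "pull_toward", grid),
                push_away = predict_exp2(push, thetas, "push_away", grid),
                visual_only = predict_exp2(pull, thetas, "visual_only", grid))
  rows <- lapply(names(probs), function(mv) {
    p <- probs[[mv]]
    do.call(rbind, lapply(seq_len(n_participants), function(i)
      data.frame(participant_id = sprintf("synth%02d", i), condition = mv,
                 level = thetas, n_trials = n_trials,
                 n_positive = as.integer(round(p * n_trials)),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  response_table(out$participant_id, out$condition, out$level,
                 out$n_trials, out$n_positive)
}
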