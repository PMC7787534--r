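test_that("every density integrates to one on its grid", {
  g <- depth_grid()
  set.seed(5)
  for (i in 1:10) {
    hp <- haptic_params(sample(c(-24, 24), 1), runif(1, 0.1, 2),
                        runif(1, 0, 0.9))
    expect_equal(density_integral(haptic_likelihood(g, hp)), 1,
                 tolerance = 1e-9)
    vp <- disparity_params(runif(1, -20, 20), runif(1, 0.1, 1.5))
    expect_equal(density_integral(visual_likelihood_disparity(g, vp)), 1,
                 tolerance = 1e-9)
    sp <- shading_params(runif(1, 0.5, 2), runif(1, 0.5, 1.5),
                         runif(1, 0.5, 1.5), runif(1, 0.3, 1.2))
    expect_equal(density_integral(
      visual_likelihood_shading(g, runif(1, 0, 180), sp)), 1,
      tolerance = 1e-9)
  }
})

test_that("haptic likelihood: Gaussian core, flat tail, invalid params error", {
  g <- depth_grid()
  pure <- haptic_likelihood(g, haptic_params(24, 0.5, 0))
  # omega = 0: a (truncated) Gaussian, peaked at the hand position
  expect_equal(g$values[which.max(pure$w)], 2.4, tolerance = g$step)
  tailed <- haptic_likelihood(g, haptic_params(24, 0.5, 0.05))
  far <- abs(g$values - 2.4) > 6 * 0.5
  # exp(-18) ~ 1.5e-8 of the unit peak remains at 6 sigma; beyond that the
  # density is tail-dominated and flat to ~3e-7 relative
  expect_lt(diff(range(tailed$w[far])) / mean(tailed$w[far]), 1e-5)
  expect_error(haptic_params(24, -1, 0.1), "sigma_h")
  expect_error(haptic_params(24, 0.5, -0.1), "omega")
})

test_that("haptic density ratio matches a fine-grid first-principles oracle", {
  g <- depth_grid()
  d <- haptic_likelihood(g, haptic_params(24, 1.0, 0.05))
  at <- function(x) d$w[which(g$values == x)]
  orc <- fine_grid_haptic(c(0, 2.4), 2.4, 1.0, 0.05)
  expect_equal(at(0) / at(2.4), orc[1] / orc[2], tolerance = 1e-6)
})

test_that("disparity likelihood is centred on the visual height", {
  g <- depth_grid()
  sym <- visual_likelihood_disparity(g, disparity_params(0, 0.9))
  expect_equal(prob_positive(sym), 0.5, tolerance = 1e-12)
  hi <- visual_likelihood_disparity(g, disparity_params(20, 0.2))
  expect_gt(prob_positive(hi), 0.999)
  # half-grid-step agreement holds while grid truncation is negligible
  # (|mean| <= 10 mm keeps the +/-5 cm edges > 4 sigma away at sigma_v = 0.9)
  for (h in c(-10, -6, 1.2, 10)) {
    d <- visual_likelihood_disparity(g, disparity_params(h, 0.9))
    expect_equal(density_mean(d), h / 10, tolerance = g$step / 2)
  }
  # at the extreme height the truncation bias is visible but small
  d20 <- visual_likelihood_disparity(g, disparity_params(-20, 1.1))
  expect_equal(density_mean(d20), -2, tolerance = 0.02)
  expect_error(disparity_params(0, 0), "sigma_v")
})

test_that("light prior: crossover at 90, light-from-above, mirror symmetry", {
  p <- shading_params(1.3, pi_c_convex = 1.2, pi_c_concave = 0.8,
                      pi_l_spread = 0.7)
  mid <- light_prior(90, p)
  expect_equal(mid$pi_l_convex, 0.5)
  expect_equal(mid$pi_l_concave, 0.5)
  expect_equal(mid$w_convex / mid$w_concave, 1.2 / 0.8)
  top <- light_prior(0, p)
  expect_gt(top$pi_l_convex, top$pi_l_concave)
  th <- seq(0, 180, by = 30)
  expect_equal(light_prior(th, p)$pi_l_convex,
               light_prior(180 - th, p)$pi_l_concave, tolerance = 1e-12)
  expect_error(light_prior(200, p), "0, 180")
})

test_that("shading likelihood splits mass by the prior weights", {
  g <- depth_grid()
  even <- shading_params(1.3, 1, 1, 0.7)
  expect_equal(prob_positive(visual_likelihood_shading(g, 90, even)), 0.5,
               tolerance = 1e-12)
  biased <- shading_params(1.3, 1.2, 0.8, 0.7)
  expect_gt(prob_positive(visual_likelihood_shading(g, 0, biased)), 0.5)
  # mixture mass split equals w_convex / (w_convex + w_concave) once the
  # modes are well separated (at sigma_v = 0.5 the cross-mode leakage past
  # zero is Phi(-4.8) ~ 8e-7; at sigma_v = 1.3 it is ~3e-2 by design)
  narrow <- shading_params(0.5, 1.2, 0.8, 0.7)
  for (th in c(30, 90, 150)) {
    pr <- light_prior(th, narrow)
    d <- visual_likelihood_shading(g, th, narrow)
    expect_lt(abs(prob_positive(d) -
                    pr$w_convex / (pr$w_convex + pr$w_concave)), 2e-6)
  }
})

test_that("posterior: visual-only limit, Gaussian product, disambiguation", {
  g <- depth_grid()
  vis <- visual_likelihood_disparity(g, disparity_params(6, 0.9))
  flat <- haptic_likelihood(g, haptic_params(24, 0.5, 1e9))
  post <- posterior(vis, flat)
  expect_lt(max(abs(post$w - vis$w)), 1e-9)

  hap <- haptic_likelihood(g, haptic_params(24, 0.5, 0))
  fused <- posterior(vis, hap)
  mu_closed <- (0.9^2 * 2.4 + 0.5^2 * 0.6) / (0.9^2 + 0.5^2)
  expect_equal(density_mean(fused), mu_closed, tolerance = g$step / 2)

  bimodal <- visual_likelihood_shading(g, 90, shading_params(1.3, 1, 1, 0.7))
  sharp <- haptic_likelihood(g, haptic_params(24, 0.3, 0.05))
  expect_gt(prob_positive(posterior(bimodal, sharp)), 0.8)
  sharper <- haptic_likelihood(g, haptic_params(24, 0.3, 0.005))
  expect_gt(prob_positive(posterior(bimodal, sharper)), 0.95)

  near0 <- visual_likelihood_disparity(g, disparity_params(-20, 0.05))
  spike <- haptic_likelihood(g, haptic_params(24, 0.05, 0))
  expect_error(posterior(near0, spike), "zero")
  g2 <- depth_grid(step = 0.02)
  expect_error(posterior(vis, haptic_likelihood(g2, haptic_params(24, 1, 0))),
               "grid")
})

test_that("prob_positive: symmetric, one-sided, grid-refinement stable", {
  g <- depth_grid()
  expect_equal(prob_positive(depth_density(g, rev(seq_along(g$values)) +
                                             seq_along(g$values))), 0.5)
  one_side <- as.numeric(g$values > 1)
  expect_equal(prob_positive(depth_density(g, one_side)), 1.0)
  set.seed(9)
  for (i in 1:5) {
    h <- runif(1, -15, 15); sv <- runif(1, 0.3, 1.5)
    sh <- runif(1, 0.2, 2); om <- runif(1, 0.01, 0.9)
    p_coarse <- predict_exp1(model_params_exp1(sh, om, sv), h, "pull_toward",
                             depth_grid(step = 0.01))
    p_fine <- predict_exp1(model_params_exp1(sh, om, sv), h, "pull_toward",
                           depth_grid(step = 0.001))
    expect_lt(abs(p_coarse - p_fine), 1e-4)
  }
})

test_that("predict_exp1 approaches the haptic-free curve as omega grows", {
  h <- default_heights
  loose <- model_params_exp1(0.5, 1e3, 0.9)
  target <- pnorm(h / 9)  # Phi(height / sigma_v), heights in mm, sigma_v 0.9 cm
  for (mv in c("push_away", "pull_toward"))
    expect_lt(max(abs(predict_exp1(loose, h, mv) - target)), 1e-3)
})

test_that("movement effect: smaller for active than passive parameters", {
  h <- default_heights
  gap <- function(p) {
    push <- predict_exp1(p, h, "push_away")
    pull <- predict_exp1(p, h, "pull_toward")
    max(abs(push - pull))
  }
  expect_lt(gap(active_params()), gap(passive_params()))
  # the tail monotonically shrinks the movement effect
  expect_lt(gap(model_params_exp1(0.5, 0.4, 0.9)),
            gap(model_params_exp1(0.5, 0.05, 0.9)))
  # passive bias: the push-away curve needs a larger height to reach 0.5
  pas_push <- predict_exp1(passive_params(), h, "push_away")
  pas_pull <- predict_exp1(passive_params(), h, "pull_toward")
  cross <- function(p) approx(p, h, xout = 0.5)$y
  expect_gt(cross(pas_push), 0)
  expect_lt(cross(pas_pull), 0)
})

test_that("predict_exp2: ordering, convexity prior, mid-range effect", {
  th <- canonical_thetas
  vis <- predict_exp2(pull_params(), th, "visual_only")
  expect_gt(vis[th == 90], 0.5)  # convexity prior alone at side lighting

  # pull >= visual-only >= push pointwise over a parameter sweep
  set.seed(31)
  for (i in 1:5) {
    m <- model_params_exp2(runif(1, 0.2, 1.5), runif(1, 0.05, 0.9),
                           runif(1, 0.8, 1.8), runif(1, 0.8, 1.4),
                           runif(1, 0.6, 1.2), runif(1, 0.4, 1.0))
    p_pull <- predict_exp2(m, th, "pull_toward")
    p_vis <- predict_exp2(m, th, "visual_only")
    p_push <- predict_exp2(m, th, "push_away")
    expect_true(all(p_pull >= p_vis - 1e-12))
    expect_true(all(p_vis >= p_push - 1e-12))
  }

  # fitted parameters: movement effect concentrated at mid-range directions
  d <- predict_exp2(pull_params(), th, "pull_toward") -
    predict_exp2(push_params(), th, "push_away")
  expect_lt(d[th == 0], d[th == 90])
  expect_lt(d[th == 180], d[th == 90])
})

test_that("mirror symmetry when the convexity prior is symmetric", {
  th <- canonical_thetas
  m <- model_params_exp2(0.3, 0.425, 1.3, 1, 1, 0.7)
  pull <- predict_exp2(m, th, "pull_toward")
  push <- predict_exp2(m, rev(th), "push_away")  # push at 180 - theta
  expect_equal(pull, 1 - push, tolerance = 1e-9)
})
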