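test_that("loss_mse: exact fit, hand computation, reference oracle", {
  obs <- response_table(c("a", "a"), "pull_toward", c(-10, 10), 8, c(0, 8))
  pred_exact <- data.frame(condition = "pull_toward", level = c(-10, 10),
                           p = c(0, 1))
  expect_equal(loss_mse(pred_exact, obs), 0)
  pred_half <- data.frame(condition = "pull_toward", level = c(-10, 10),
                          p = c(0.5, 0.5))
  expect_equal(loss_mse(pred_half, obs), 0.25)

  set.seed(101)
  cells <- expand.grid(participant_id = sprintf("p%d", 1:5),
                       condition = c("push_away", "pull_toward"),
                       level = default_heights, stringsAsFactors = FALSE)
  obs2 <- response_table(cells$participant_id, cells$condition, cells$level,
                         8, rbinom(nrow(cells), 8, 0.5))
  pred2 <- expand.grid(condition = c("push_away", "pull_toward"),
                       level = default_heights, stringsAsFactors = FALSE)
  pred2$p <- runif(nrow(pred2))
  expect_equal(loss_mse(pred2, obs2), loss_mse_reference(pred2, obs2),
               tolerance = 1e-12)
  expect_equal(loss_mse(pred2, obs2, aggregate = "mean"),
               loss_mse_reference(pred2, obs2) / 5, tolerance = 1e-12)
  expect_error(loss_mse(pred2[-1, ], obs2), "missing prediction")
})

test_that("fit_sim1 recovers a planted grid point from noise-free tables", {
  act <- synthetic_reference_exp1("active", n_participants = 2)
  pas <- synthetic_reference_exp1("passive", n_participants = 2)
  fit <- fit_sim1(act, pas)
  expect_equal(fit$sigma_v, 0.9)
  expect_equal(fit$omega, 0.05)
  expect_equal(fit$sigma_h_active, 0.5)
  expect_equal(fit$sigma_h_passive, 1.0)
  expect_lt(fit$loss_total, 1e-6)
})

test_that("fit_sim1 equals a brute-force nested-loop oracle on coarse grids", {
  grids <- list(sigma_h = grid_spec(0.3, 1.1, 0.2),
                omega = grid_spec(0.025, 0.125, 0.05),
                sigma_v = grid_spec(0.7, 1.1, 0.2))
  spec_a <- observer_spec(active_params(), n_participants = 2, n_reps = 16,
                          seed = 7)
  spec_p <- observer_spec(passive_params(), n_participants = 2, n_reps = 16,
                          seed = 107)
  act <- simulate_exp1(spec_a)
  pas <- simulate_exp1(spec_p)
  fit <- fit_sim1(act, pas, grids = grids)

  # oracle: exhaustive nested loops through the public prediction path
  best <- list(obj = Inf)
  for (sv in grid_values(grids$sigma_v)) for (om in grid_values(grids$omega)) {
    prof <- lapply(list(act = act, pas = pas), function(tab) {
      losses <- vapply(grid_values(grids$sigma_h), function(sh) {
        mp <- model_params_exp1(sh, om, sv)
        pred <- do.call(rbind, lapply(c("push_away", "pull_toward"),
          function(mv) data.frame(condition = mv, level = default_heights,
                                  p = predict_exp1(mp, default_heights, mv))))
        loss_mse(pred, tab)
      }, numeric(1))
      j <- which.min(losses)
      list(sh = grid_values(grids$sigma_h)[j], loss = losses[j])
    })
    obj <- prof$act$loss + prof$pas$loss
    if (obj < best$obj)
      best <- list(obj = obj, sv = sv, om = om,
                   sh_a = prof$act$sh, sh_p = prof$pas$sh)
  }
  expect_equal(fit$sigma_v, best$sv)
  expect_equal(fit$omega, best$om)
  expect_equal(fit$sigma_h_active, best$sh_a)
  expect_equal(fit$sigma_h_passive, best$sh_p)
  expect_equal(fit$loss_total, best$obj, tolerance = 1e-10)

  # profiling consistency: reported loss equals loss_mse recomputed from the
  # reported parameters through the public path
  mp_a <- model_params_exp1(fit$sigma_h_active, fit$omega, fit$sigma_v)
  pred_a <- do.call(rbind, lapply(c("push_away", "pull_toward"), function(mv)
    data.frame(condition = mv, level = default_heights,
               p = predict_exp1(mp_a, default_heights, mv))))
  expect_equal(fit$loss_active, loss_mse(pred_a, act), tolerance = 1e-10)

  # determinism: a repeated run is identical
  fit2 <- fit_sim1(act, pas, grids = grids)
  expect_identical(fit[c("sigma_v", "omega", "sigma_h_active",
                         "sigma_h_passive", "loss_total")],
                   fit2[c("sigma_v", "omega", "sigma_h_active",
                          "sigma_h_passive", "loss_total")])
})

test_that("fit_visual_only: symmetry forces no convexity bias; oracle identity", {
  # symmetric synthetic data: p(theta) + p(180 - theta) = 1
  th <- canonical_thetas
  p_sym <- predict_exp2(model_params_exp2(0.3, 0.425, 1.3, 1, 1, 0.7),
                        th, "visual_only")
  tab_sym <- response_table(rep(c("a", "b"), each = 7), "visual_only",
                            rep(th, 2), 4000,
                            rep(as.integer(round(p_sym * 4000)), 2))
  grids <- sim2_grids()
  fit_sym <- fit_visual_only(tab_sym, grids = grids)
  expect_equal(fit_sym$pi_c_convex, fit_sym$pi_c_concave)

  # coarse-grid oracle identity through the public prediction path
  coarse <- grids
  coarse$pi_c <- grid_spec(1.0, 1.4, 0.1)
  coarse$sigma_v <- grid_spec(1.1, 1.5, 0.2)
  coarse$pi_l_spread <- grid_spec(0.5, 0.9, 0.2)
  tab <- synthetic_reference_exp2(n_participants = 2, n_trials = 64)
  vo <- tab[tab$condition == "visual_only", ]
  fit <- fit_visual_only(tab, grids = coarse)
  best <- list(loss = Inf)
  for (pc in grid_values(coarse$pi_c))
    for (sv in grid_values(coarse$sigma_v))
      for (sp in grid_values(coarse$pi_l_spread)) {
        m <- model_params_exp2(0.3, 0.425, sv, pc, 2 - pc, sp)
        pred <- data.frame(condition = "visual_only", level = th,
                           p = predict_exp2(m, th, "visual_only"))
        l <- loss_mse(pred, validate_response_table(vo))
        if (l < best$loss) best <- list(loss = l, pc = pc, sv = sv, sp = sp)
      }
  expect_equal(fit$pi_c_convex, best$pc)
  expect_equal(fit$sigma_v, best$sv)
  expect_equal(fit$pi_l_spread, best$sp)
  expect_equal(fit$loss, best$loss, tolerance = 1e-10)
})

test_that("fit_sim2 recovers planted haptics; no-tail search hits the boundary", {
  tab <- synthetic_reference_exp2(n_participants = 3)
  vf <- fit_visual_only(tab)
  fit <- fit_sim2(tab, vf)
  expect_equal(fit$sigma_h, 0.3)
  expect_equal(fit$omega, 0.425)
  expect_identical(fit$k_params, 2L)

  fit0 <- fit_sim2(tab, vf, no_tail = TRUE)
  expect_identical(fit0$omega, 0)
  expect_equal(fit0$sigma_h, 2.0)  # boundary of the constrained grid
  expect_identical(fit0$k_params, 1L)
  expect_gt(fit0$loss, fit$loss)

  # push-away fits with its own (larger) tail
  fit_push <- fit_sim2(tab, vf, movement = "push_away")
  expect_equal(fit_push$omega, 0.8)
  expect_error(fit_sim2(tab, list(pi_c_convex = 1.2)), "lacks field")
})

test_that("compare_models prefers lower AIC and validates its inputs", {
  tab <- synthetic_reference_exp2(n_participants = 2)
  vf <- fit_visual_only(tab)
  with_tail <- fit_sim2(tab, vf)
  without <- fit_sim2(tab, vf, no_tail = TRUE)
  cmp <- compare_models(with_tail, without)
  expect_identical(cmp$preferred, "with_tail")
  expect_lt(cmp$loss_with_tail, cmp$loss_without_tail)

  # identical losses, fewer parameters -> simpler model preferred
  tie_a <- with_tail; tie_b <- with_tail
  tie_b$k_params <- 1L
  tie_b$aic <- tie_a$aic
  expect_identical(compare_models(tie_a, tie_b)$preferred, "without_tail")

  # AIC ordering is invariant to scaling both SSEs by a constant
  scale_fit <- function(f, c) {
    f$sse <- f$sse * c
    f$aic <- f$n_points * log(f$sse / f$n_points) + 2 * f$k_params
    f
  }
  for (c in c(0.1, 3, 40)) {
    cmp_s <- compare_models(scale_fit(with_tail, c), scale_fit(without, c))
    expect_identical(cmp_s$preferred, cmp$preferred)
  }

  other <- fit_sim2(synthetic_reference_exp2(n_participants = 4), vf)
  expect_error(compare_models(with_tail, other), "identical data")
})

test_that("grid_spec values are deterministic and validated", {
  expect_equal(grid_values(grid_spec(0, 0.9, 0.025)), seq(0, 0.9, 0.025))
  expect_length(grid_values(grid_spec(0.1, 2, 0.1)), 20L)
  expect_equal(grid_values(grid_spec(0.5, 0.5, 0.1)), 0.5)
  expect_error(grid_spec(1, 0, 0.1), "exceed")
  expect_error(grid_spec(0, 1, 0), "positive")
})
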