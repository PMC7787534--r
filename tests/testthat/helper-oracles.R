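# Independent oracles and small fixture builders used across test files.

# Brute-force grid-search MLE oracle for the cumulative-Gaussian fit:
# exhaustive over mu in [-20, 20] and sigma in (0, 20], both step 0.05.
grid_oracle_psychometric <- function(levels, k, n,
                                     mu_grid = seq(-20, 20, by = 0.05),
                                     sigma_grid = seq(0.05, 20, by = 0.05)) {
  best <- c(mu = NA_real_, sigma = NA_real_, ll = -Inf)
  for (sg in sigma_grid) {
    P <- stats::pnorm(outer(levels, mu_grid, "-") / sg)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    ll <- colSums(k * log(P) + (n - k) * log1p(-P))
    j <- which.max(ll)
    if (ll[j] > best["ll"]) best <- c(mu = mu_grid[j], sigma = sg, ll = ll[j])
  }
  best
}

# random binomial psychometric table in the disparity-task regime
random_psy_table <- function(mu, sigma, n_reps = 8,
                             levels = c(-20, -10, -6, -3.6, -1.2,
                                        1.2, 3.6, 6, 10, 20)) {
  p <- stats::pnorm((levels - mu) / sigma)
  list(levels = levels, k = stats::rbinom(length(levels), n_reps, p),
       n = rep(n_reps, length(levels)))
}

# independent double-loop reference for the MSE loss (sum aggregation)
loss_mse_reference <- function(predicted, observed) {
  total <- 0
  for (id in unique(observed$participant_id)) {
    rows <- observed[observed$participant_id == id, ]
    errs <- numeric(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      hit <- predicted$condition == rows$condition[r] &
        predicted$level == rows$level[r]
      errs[r] <- (rows$n_positive[r] / rows$n_trials[r] -
                    predicted$p[hit])^2
    }
    total <- total + mean(errs)
  }
  total
}

# density of the mixture haptic likelihood on an arbitrary step, computed
# from first principles (independent of the package's density plumbing)
fine_grid_haptic <- function(s_query, mean_cm, sigma_h, omega, step = 1e-4,
                             lo = -5, hi = 5) {
  s <- seq(lo, hi, by = step)
  w <- exp(-(s - mean_cm)^2 / (2 * sigma_h^2)) + omega
  w <- w / (sum(w) * step)
  w[vapply(s_query, function(q) which.min(abs(s - q)), integer(1))]
}

default_heights <- c(-20, -10, -6, -3.6, -1.2, 1.2, 3.6, 6, 10, 20)
canonical_thetas <- seq(0, 180, by = 30)

active_params <- function() model_params_exp1(0.5, 0.05, 0.9)
passive_params <- function() model_params_exp1(1.0, 0.05, 0.9)
pull_params <- function() model_params_exp2(0.3, 0.425, 1.3, 1.2, 0.8, 0.7)
push_params <- function() model_params_exp2(0.3, 0.8, 1.3, 1.2, 0.8, 0.7)
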