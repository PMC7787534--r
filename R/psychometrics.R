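#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of a two-parameter cumulative Gaussian
#' `p(x) = pnorm((x - mu) / sigma)` to binomial response counts, maximizing
#' `sum(k * log(p) + (n - k) * log(1 - p))`. No lapse or guess rate is
#' fitted: the function is the plain two-parameter form so that `mu` is the
#' point of subjective equality (PSE) directly.
#'
#' The optimizer is Nelder-Mead over `(mu, log sigma)` with a BFGS polish,
#' restarted from several starting points (level median with a range-based
#' spread, and a probit-GLM start when available) to avoid local maxima.
#'
#' @param levels stimulus levels (mm)
#' @param n_positive counts of positive responses per level
#' @param n_trials trial counts per level
#' @return an object of class `psychometric_fit` with fields `mu` (the PSE,
#'   mm), `sigma` (mm), `loglik`, `n_points`
#' @examples
#' x <- c(-20, -10, -6, -3.6, -1.2, 1.2, 3.6, 6, 10, 20)
#' p <- pnorm(x / 6)
#' fit <- fit_psychometric(x, round(p * 1000), rep(1000, 10))
#' c(fit$mu, fit$sigma)
#' @export
fit_psychometric <- function(levels, n_positive, n_trials) {
  x <- as.numeric(levels)
  k <- as.numeric(n_positive)
  n <- as.numeric(n_trials)
  if (length(x) != length(k) || length(x) != length(n))
    stop("`levels`, `n_positive`, `n_trials` must have equal length",
         call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(k)) || any(!is.finite(n)))
    stop("inputs must be finite", call. = FALSE)
  if (any(k < 0) || any(k > n))
    stop("0 <= n_positive <= n_trials violated", call. = FALSE)
  keep <- n > 0
  x <- x[keep]; k <- k[keep]; n <- n[keep]
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct levels", call. = FALSE)
  if (sum(k) == 0 || sum(k) == sum(n))
    stop("degenerate data: all responses identical", call. = FALSE)
  p_hat <- k / n
  interior <- any(p_hat > 0 & p_hat < 1)
  if (!interior && !(any(p_hat == 0) && any(p_hat == 1)))
    stop("degenerate data: no interior probability and no 0/1 bracket",
         call. = FALSE)

  nll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    p <- stats::pnorm((x - mu) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }

  rng <- diff(range(x))
  starts <- list(c(stats::median(x), log(rng / 4)),
                 c(sum(x * n) / sum(n), log(rng / 8)),
                 c(0, log(rng / 2)))
  glm_start <- tryCatch({
    g <- suppressWarnings(stats::glm(cbind(k, n - k) ~ x,
                                     family = stats::binomial("probit")))
    b <- stats::coef(g)
    if (all(is.finite(b)) && b[2] > 0) c(-b[1] / b[2], log(1 / b[2])) else NULL
  }, error = function(e) NULL)
  if (!is.null(glm_start)) starts <- c(list(glm_start), starts)

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(stats::optim(st, nll, method = "Nelder-Mead",
                                 control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    opt2 <- tryCatch(stats::optim(opt$par, nll, method = "BFGS",
                                  control = list(maxit = 500, reltol = 1e-12)),
                     error = function(e) opt)
    cand <- if (!is.null(opt2) && opt2$value <= opt$value) opt2 else opt
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best))
    stop("psychometric fit failed to converge from all starts", call. = FALSE)
  structure(list(mu = unname(best$par[1]), sigma = unname(exp(best$par[2])),
                 loglik = -best$value, n_points = length(x)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE = %.3f mm, sigma = %.3f mm, JND = %.3f mm, logLik = %.3f (%d levels)\n",
              x$mu, x$sigma, jnd(x), x$loglik, x$n_points))
  invisible(x)
}

#' Just-noticeable difference of a psychometric fit
#'
#' Defined from the levels at which the fitted function reaches 0.5 and
#' 0.75: `x(p = 0.5) - x(p = 0.75) = -sigma * qnorm(0.75)`. Under this sign
#' convention the JND of an increasing psychometric function is negative
#' (matching how the quantity is reported for these tasks); its magnitude is
#' `0.6745 * sigma`.
#'
#' @param fit a `psychometric_fit`
#' @return the JND in mm (negative for any valid fit)
#' @examples
#' jnd(structure(list(sigma = 1), class = "psychometric_fit"))  # -0.6745
#' @export
jnd <- function(fit) {
  if (!inherits(fit, "psychometric_fit"))
    stop("`fit` must be a psychometric_fit", call. = FALSE)
  if (!is.numeric(fit$sigma) || fit$sigma <= 0)
    stop("invalid fit: sigma must be positive", call. = FALSE)
  -fit$sigma * stats::qnorm(0.75)
}

#' Per-participant psychometric fits for one condition
#'
#' Convenience wrapper: fits [fit_psychometric()] to every participant's rows
#' for a given condition of a [response_table()].
#'
#' @param tab a `response_table`
#' @param condition condition to fit
#' @return a data.frame with one row per participant: `participant_id`,
#'   `pse`, `sigma`, `jnd`, `loglik`, `n_points`
#' @export
fit_psychometric_table <- function(tab, condition) {
  stopifnot(inherits(tab, "response_table"))
  condition <- .check_movement(condition)
  sub <- tab[tab$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no rows for condition ", condition, call. = FALSE)
  ids <- unique(sub$participant_id)
  rows <- lapply(ids, function(id) {
    d <- sub[sub$participant_id == id, ]
    f <- fit_psychometric(d$level, d$n_positive, d$n_trials)
    data.frame(participant_id = id, pse = f$mu, sigma = f$sigma,
               jnd = jnd(f), loglik = f$loglik, n_points = f$n_points,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group summary of a per-participant quantity
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' standard error across participants. With a single participant the SD and
#' SE are `NA` (the n - 1 convention has no spread estimate at n = 1).
#'
#' @param values named numeric vector (names = participant ids) or a
#'   data.frame with columns `participant_id` and `value`
#' @return an object of class `group_summary` with `per_participant`,
#'   `mean`, `sd`, `se`, `n`
#' @examples
#' summarize_group(c(a = 1, b = 3))
#' @export
summarize_group <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("participant_id", "value") %in% names(values)))
    per <- data.frame(participant_id = as.character(values$participant_id),
                      value = as.numeric(values$value),
                      stringsAsFactors = FALSE)
  } else {
    v <- as.numeric(values)
    ids <- names(values)
    if (is.null(ids)) ids <- as.character(seq_along(v))
    per <- data.frame(participant_id = ids, value = v,
                      stringsAsFactors = FALSE)
  }
  if (nrow(per) == 0L) stop("empty value list", call. = FALSE)
  if (any(!is.finite(per$value))) stop("non-finite values", call. = FALSE)
  n <- nrow(per)
  s <- if (n > 1L) stats::sd(per$value) else NA_real_
  structure(list(per_participant = per,
                 mean = mean(per$value),
                 sd = s,
                 se = if (n > 1L) s / sqrt(n) else NA_real_,
                 n = n),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> n = %d, mean = %.4f, sd = %.4f, se = %.4f\n",
              x$n, x$mean, x$sd, x$se))
  invisible(x)
}
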