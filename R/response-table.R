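#' Response tables
#'
#' The empirical object every fitting routine consumes: one row per
#' (participant, condition, stimulus level) cell with the number of trials
#' and the number of "positive" responses ("protrude" in the disparity task,
#' "convex" in the shading task). `level` is the visual 3-D height in mm for
#' the disparity task and a light direction in degrees for the shading task.
#'
#' @param participant_id character vector of participant identifiers
#' @param condition one of `"push_away"`, `"pull_toward"`, `"visual_only"`
#'   per row
#' @param level numeric stimulus level per row
#' @param n_trials nonnegative integer trial counts
#' @param n_positive nonnegative integer counts of positive responses,
#'   `0 <= n_positive <= n_trials`
#' @return a validated `data.frame` of class `response_table`
#' @examples
#' response_table("p1", "pull_toward", c(-10, 0, 10), 8, c(1, 4, 7))
#' @export
response_table <- function(participant_id, condition, level, n_trials,
                           n_positive) {
  df <- data.frame(participant_id = as.character(participant_id),
                   condition = as.character(condition),
                   level = as.numeric(level),
                   n_trials = as.integer(n_trials),
                   n_positive = as.integer(n_positive),
                   stringsAsFactors = FALSE)
  validate_response_table(df)
}

#' Validate a response table
#'
#' Checks the schema and the count/uniqueness invariants and attaches the
#' `response_table` class. Called by every reader and constructor.
#'
#' @param df a data.frame with columns `participant_id`, `condition`,
#'   `level`, `n_trials`, `n_positive`
#' @return `df`, classed as `response_table`
#' @export
validate_response_table <- function(df) {
  need <- c("participant_id", "condition", "level", "n_trials", "n_positive")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_cond <- !df$condition %in% .movements
  if (any(bad_cond))
    stop("invalid condition at row(s) ", paste(which(bad_cond), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$level)))
    stop("non-finite levels", call. = FALSE)
  if (any(is.na(df$n_trials)) || any(df$n_trials < 0))
    stop("n_trials must be nonnegative integers", call. = FALSE)
  bad_k <- is.na(df$n_positive) | df$n_positive < 0 | df$n_positive > df$n_trials
  if (any(bad_k))
    stop("0 <= n_positive <= n_trials violated at row(s) ",
         paste(which(bad_k), collapse = ", "), call. = FALSE)
  key <- paste(df$participant_id, df$condition, df$level, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant_id, condition, level) at row(s) ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  class(df) <- c("response_table", "data.frame")
  df
}

#' Observed response probabilities
#'
#' @param tab a `response_table`
#' @return `tab` with an added `p_hat = n_positive / n_trials` column
#'   (plain data.frame)
#' @export
observed_probabilities <- function(tab) {
  stopifnot(inherits(tab, "response_table"))
  out <- as.data.frame(tab)
  out$p_hat <- ifelse(out$n_trials > 0, out$n_positive / out$n_trials, NA_real_)
  out
}
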