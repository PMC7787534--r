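#' Read a response table from CSV
#'
#' Canonical schema: header `participant_id,condition,level,n_trials,
#' n_positive` (UTF-8, "." decimal). A probability column `p` may replace
#' the two count columns, in which case counts are reconstructed from
#' `n_reps` trials per cell (warning if a probability is not a multiple of
#' `1/n_reps`; it is rounded to the nearest count). Counts are canonical
#' storage because the binomial likelihood needs them.
#'
#' @param path CSV file path
#' @param schema expected level semantics: `"exp1"` (visual heights, mm),
#'   `"exp2_raw"` (raw light directions 0..330), `"exp2_canonical"`
#'   (canonical directions 0..180); used for validation only
#' @param n_reps trials per cell assumed when converting probabilities
#' @return a `response_table`
#' @export
read_response_table <- function(path, schema = c("exp1", "exp2_raw",
                                                 "exp2_canonical"),
                                n_reps = 8) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_base <- c("participant_id", "condition", "level")
  missing_cols <- setdiff(need_base, names(df))
  if (length(missing_cols))
    stop("header lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(c("n_trials", "n_positive") %in% names(df))) {
    if (!"p" %in% names(df))
      stop("need either n_trials/n_positive or a probability column `p`",
           call. = FALSE)
    if (any(!is.finite(df$p) | df$p < 0 | df$p > 1))
      stop("probabilities outside [0, 1]", call. = FALSE)
    k <- df$p * n_reps
    off <- abs(k - round(k)) > 1e-6
    if (any(off))
      warning(sum(off), " probability value(s) are not multiples of 1/",
              n_reps, "; rounded to the nearest count", call. = FALSE)
    df$n_trials <- as.integer(n_reps)
    df$n_positive <- as.integer(round(k))
    df$p <- NULL
  }
  tab <- tryCatch(validate_response_table(df), error = function(e)
    stop("invalid table in ", path, ": ", conditionMessage(e), call. = FALSE))
  lv <- tab$level
  ok <- switch(schema,
               exp1 = TRUE,
               exp2_raw = all(lv >= 0 & lv < 360),
               exp2_canonical = all(lv >= 0 & lv <= 180))
  if (!isTRUE(ok))
    stop("levels violate schema ", schema, " at row(s) ",
         paste(which(!switch(schema,
                             exp2_raw = lv >= 0 & lv < 360,
                             exp2_canonical = lv >= 0 & lv <= 180)),
               collapse = ", "), call. = FALSE)
  tab
}

#' Write a response table to CSV
#'
#' @param tab a `response_table`
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_response_table <- function(tab, path) {
  stopifnot(inherits(tab, "response_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide probability spreadsheet layout
#'
#' Converter for the wide per-participant layout in which each stimulus
#' level is a column of response probabilities: header
#' `participant_id,condition,<level1>,<level2>,...` with level names
#' parseable as numbers (an optional leading "X" from spreadsheet exports is
#' stripped). Probabilities are converted to counts with `n_reps` trials per
#' cell. The long-format CSV of [read_response_table()] is canonical; this
#' reader only ingests.
#'
#' @param path CSV file path in wide layout
#' @param n_reps trials per cell
#' @return a `response_table`
#' @export
read_wide_probability_table <- function(path, n_reps = 8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("participant_id", "condition") %in% names(df)))
    stop("wide layout needs participant_id and condition columns",
         call. = FALSE)
  level_cols <- setdiff(names(df), c("participant_id", "condition"))
  levels <- suppressWarnings(as.numeric(sub("^X", "", level_cols)))
  if (any(is.na(levels)))
    stop("column name(s) not parseable as levels: ",
         paste(level_cols[is.na(levels)], collapse = ", "), call. = FALSE)
  long <- do.call(rbind, lapply(seq_along(level_cols), function(j) {
    data.frame(participant_id = df$participant_id, condition = df$condition,
               level = levels[j], p = as.numeric(df[[level_cols[j]]]),
               stringsAsFactors = FALSE)
  }))
  if (any(!is.finite(long$p) | long$p < 0 | long$p > 1))
    stop("probabilities outside [0, 1]", call. = FALSE)
  k <- long$p * n_reps
  off <- abs(k - round(k)) > 1e-6
  if (any(off))
    warning(sum(off), " probability value(s) are not multiples of 1/",
            n_reps, "; rounded to the nearest count", call. = FALSE)
  response_table(long$participant_id, long$condition, long$level,
                 rep(n_reps, nrow(long)), as.integer(round(k)))
}

.config_keys <- c("units", "grid_lo", "grid_hi", "grid_step",
                  "sigma_h", "omega", "sigma_v",
                  "pi_c_convex", "pi_c_concave", "pi_l_spread",
                  "hand_distance_mm", "seed", "n_participants", "n_reps",
                  "aggregate", "verbosity")

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; blank lines are
#' ignored. Unknown keys are rejected so typos cannot silently fall back to
#' defaults. Numeric-looking values are converted.
#'
#' @param path configuration file path
#' @return a named list of configuration values
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed config line: ", lines[i], call. = FALSE)
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    if (!key %in% .config_keys)
      stop("unknown config key: ", key, call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
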