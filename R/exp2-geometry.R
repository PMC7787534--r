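#' Canonicalize a shading-trial light direction
#'
#' A shaded image is depth-ambiguous: the convex surface lit from direction
#' `x` and the concave surface lit from `x + 180` produce the same image.
#' Trials are therefore aligned to the light direction of the convex
#' interpretation: pull-toward (convex-deforming) trials keep their raw
#' direction, push-away (concave-deforming) trials are rotated by 180
#' degrees. Mirror-image sides are then folded together
#' (`fold(x) = min(x, 360 - x)`), since left/right of the vertical is not
#' analysed separately. The result lies in `[0, 180]`; with 30-degree raw
#' steps this yields the seven canonical directions 0, 30, ..., 180.
#'
#' Visual-only trials carry no deformation direction and are aligned with
#' the convex (identity) rule.
#'
#' @param light_dir_deg raw light direction(s), degrees (multiples of 30
#'   expected)
#' @param movement `"push_away"`, `"pull_toward"` or `"visual_only"`
#'   (recycled against `light_dir_deg`)
#' @param strict error on directions that are not multiples of 30
#'   (`TRUE`, default) or warn and fold anyway (`FALSE`)
#' @return canonical light direction(s) in degrees, in `[0, 180]`
#' @examples
#' canonicalize(270, "push_away")   # 90
#' canonicalize(c(120, 240), "push_away")  # both 60
#' canonicalize(90, "pull_toward")  # 90
#' @export
canonicalize <- function(light_dir_deg, movement, strict = TRUE) {
  x <- as.numeric(light_dir_deg)
  if (any(!is.finite(x))) stop("non-finite light direction", call. = FALSE)
  movement <- as.character(movement)
  if (!all(movement %in% .movements))
    stop("invalid movement", call. = FALSE)
  off <- x %% 30 != 0
  if (any(off)) {
    if (strict)
      stop("light direction not a multiple of 30 degrees: ",
           paste(unique(x[off]), collapse = ", "), call. = FALSE)
    warning("light direction not a multiple of 30 degrees; folding anyway")
  }
  x <- ((x %% 360) + 360) %% 360
  shift <- ifelse(rep_len(movement, length(x)) == "push_away", 180, 0)
  x <- (x + shift) %% 360
  pmin(x, 360 - x)
}

#' Fold a raw shading response table onto canonical light directions
#'
#' Maps every (raw light direction, movement) cell through [canonicalize()]
#' and sums trial and positive-response counts over cells sharing a
#' canonical direction, per participant and condition. Counts are conserved;
#' `n_positive` counts "convex" reports throughout.
#'
#' @param raw a `response_table` whose `level` column holds raw light
#'   directions in degrees
#' @param strict passed to [canonicalize()]
#' @return a `response_table` keyed by canonical direction (level in
#'   `[0, 180]`), sorted by participant, condition, level
#' @export
fold_responses <- function(raw, strict = TRUE) {
  stopifnot(inherits(raw, "response_table"))
  theta <- canonicalize(raw$level, raw$condition, strict = strict)
  agg <- stats::aggregate(cbind(n_trials, n_positive) ~ participant_id +
                            condition + theta,
                          data = cbind(as.data.frame(raw), theta = theta),
                          FUN = sum)
  agg <- agg[order(agg$participant_id, agg$condition, agg$theta), ]
  rownames(agg) <- NULL
  response_table(agg$participant_id, agg$condition, agg$theta,
                 agg$n_trials, agg$n_positive)
}
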