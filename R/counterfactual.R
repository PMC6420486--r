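#' State-specific death-rate slope per 1 point of net gain
#'
#' Inverts a fitted state's total death-rate coefficient (fixed slope
#' plus the state's predicted random slope, in points of net gain per
#' 1/100,000 of death-rate change) into the table presentation: the
#' death-rate difference, per 100,000, associated with one percentage
#' point of net Republican gain.
#'
#' @param fit a \code{model_fit} from \code{\link{fit_primary}}.
#' @param state_id state identifier present in the fit.
#' @return slope in death-rate units (per 100,000) per 1 point of net
#'   gain.
#' @export
state_slope <- function(fit, state_id) {
  i <- match(state_id, fit$state_slopes$state_id)
  if (anyNA(i)) abort_input("state not present in fit: ",
                            paste(state_id[is.na(i)], collapse = ", "))
  total <- fit$state_slopes$slope[i]
  if (any(abs(total) < 1e-6))
    abort_input("state total death-rate slope is near zero; ",
                "its reciprocal is unstable")
  1 / total
}

#' Death-rate reduction that would offset a victory margin
#'
#' Association-based, not causal: given a state's death-rate slope per 1
#' point of net gain and the winner's victory margin in points, the
#' product is the hypothetical reduction in the age-adjusted death rate
#' (per 100,000) associated with erasing the margin.
#'
#' @param slope_per_1pct death-rate units (per 100,000) per 1 point of
#'   net gain; must be positive.
#' @param victory_margin victory margin in percentage points (>= 0).
#' @param state_id optional state labels carried through.
#' @return data.frame of class \code{counterfactual_result}:
#'   \code{state_id}, \code{slope_per_1pct}, \code{victory_margin},
#'   \code{required_reduction} (full precision) and
#'   \code{required_reduction_reported} (nearest integer per 100,000,
#'   half-up). All rows are labeled association-based, not causal.
#' @examples
#' required_reduction(80, 0.22)  # 17.6 -> reported 18 per 100,000
#' @export
required_reduction <- function(slope_per_1pct, victory_margin,
                               state_id = NULL) {
  if (any(slope_per_1pct <= 0))
    abort_input("non-positive slope: counterfactual direction undefined")
  if (any(victory_margin < 0))
    abort_input("victory margin must be >= 0")
  red <- slope_per_1pct * victory_margin
  out <- data.frame(
    state_id = if (is.null(state_id)) NA_character_ else state_id,
    slope_per_1pct = slope_per_1pct,
    victory_margin = victory_margin,
    required_reduction = red,
    required_reduction_reported = round_half_up(red, 0),
    interpretation = "association-based, not causal",
    stringsAsFactors = FALSE
  )
  class(out) <- c("counterfactual_result", "data.frame")
  out
}

#' Swing-state counterfactual table from a fitted model
#'
#' Combines \code{\link{state_slope}} and \code{\link{required_reduction}}
#' for a set of states and their victory margins.
#'
#' @param fit a \code{model_fit}.
#' @param margins data.frame with \code{state_id} and
#'   \code{victory_margin} (points).
#' @return a \code{counterfactual_result} data.frame, one row per state.
#' @export
electoral_counterfactual <- function(fit, margins) {
  if (!all(c("state_id", "victory_margin") %in% names(margins)))
    abort_input("margins needs columns state_id, victory_margin")
  sl <- state_slope(fit, margins$state_id)
  required_reduction(sl, margins$victory_margin, margins$state_id)
}
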