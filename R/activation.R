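#' Steady-state logistic activation functions
#'
#' The stage-to-stage couplings of the model are sigmoid (logistic) functions
#' of the upstream signal, parameterized by a trigger (the input value at the
#' response midpoint, or onset for the gated form) and a dimensionless slope.
#'
#' The plain form is \deqn{\sigma(x) = 1 / (1 + e^{-s (x - x_0)})} for an
#' increasing response (mirror the sign of the exponent for a decreasing one),
#' so the output is 0.5 at the trigger \eqn{x_0}.
#'
#' The gated form enforces an exact zero response at and below the trigger:
#' writing \eqn{d} for the signed distance from the trigger (positive in the
#' activating direction), \deqn{g(d) = \tanh(s d)_{+}} which is the logistic
#' curve rescaled from its upper half-range \eqn{[1/2, 1)} onto \eqn{[0, 1)};
#' it is 0 at the trigger and saturates at 1. It is used for the Activity
#' stage so that individuals whose exposure never exceeds the trigger mount no
#' inflammatory response at all.
#'
#' @param x numeric input signal (same units as `trigger`). Must be finite.
#' @param trigger input value at the response midpoint (plain form) or onset
#'   (gated form).
#' @param slope positive dimensionless steepness.
#' @param direction `"increasing"` (response grows with `x`) or
#'   `"decreasing"`.
#' @param gated logical; use the thresholded, rescaled form.
#' @return numeric vector of responses in `[0, 1]`.
#' @examples
#' logistic_activation(0.8, trigger = 0.8, slope = 2)          # midpoint: 0.5
#' logistic_activation(0.45, 0.8, 2, direction = "decreasing") # 1/(1+exp(-0.7))
#' logistic_activation(0.2, 0.3, 2, gated = TRUE)              # below trigger: 0
#' @export
logistic_activation <- function(x, trigger, slope,
                                direction = c("increasing", "decreasing"),
                                gated = FALSE) {
  direction <- match.arg(direction)
  if (any(!is.finite(x))) {
    stop("logistic_activation(): `x` must be finite", call. = FALSE)
  }
  if (any(!is.finite(slope)) || any(slope <= 0)) {
    stop("logistic_activation(): `slope` must be positive and finite",
         call. = FALSE)
  }
  d <- if (direction == "increasing") x - trigger else trigger - x
  if (gated) {
    ifelse(d <= 0, 0, tanh(slope * d))
  } else {
    stats::plogis(slope * d)
  }
}
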