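#' Activation-dependent force-length scaling factor
#'
#' Gaussian normalized force-length relationship whose apparent optimal
#' length shifts with activation:
#' `f_FL = exp(-((l_bar - l0(a)) / width)^2)` with
#' `l0(a) = shift_gain * (1 - a) + 1`. At full activation the optimum sits
#' at `l_bar = 1`; at rest it shifts up to 15% longer, so partially active
#' muscle produces relatively more force at long lengths.
#'
#' @param l_bar Normalized MU length(s), > 0.
#' @param a Active state(s) in `[0, 1]` (recycled against `l_bar`).
#' @param width Gaussian width (dimensionless).
#' @param shift_gain Optimal-length shift at zero activation.
#' @return Force-length factor(s) in `(0, 1]`.
#' @examples
#' fl_factor(1, 1)      # 1: optimum under full activation
#' fl_factor(1.15, 0)   # 1: the resting optimum sits 15% longer
#' fl_factor(1.16, 1)   # 0.881 at the working length of the TA model
#' @export
fl_factor <- function(l_bar, a, width = 0.45, shift_gain = 0.15) {
  if (any(l_bar <= 0)) abort("`l_bar` must be > 0.")
  if (any(a < 0 | a > 1)) abort("`a` must lie in [0, 1].")
  l0 <- shift_gain * (1 - a) + 1
  exp(-((l_bar - l0) / width)^2)
}
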