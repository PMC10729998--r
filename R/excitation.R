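#' Excitation-dynamics parameters
#'
#' Parameters of the motoneuron action-potential (AP) waveform and of the
#' second-order fibre-AP response. Defaults were tuned on mammalian data at
#' body temperature: half-sine MN APs of amplitude `Ve = 90` mV and full
#' period `Tap = 1.4` ms, and an overdamped fibre membrane with
#' characteristic roots of about -2929 and -17071 s^-1.
#'
#' @param Ve MN AP amplitude in volts.
#' @param Tap MN AP full period in seconds (the wave occupies `Tap/2`).
#' @param a1 Drive gain of the fibre-AP equation, s^-2.
#' @param a2 Stiffness term, s^-2.
#' @param a3 Damping term, s^-1. The defaults satisfy `a3^2 >= 4*a2`
#'   (overdamped response; no ringing after a single AP).
#' @return An object of class `excitation_params`.
#' @export
excitation_params <- function(Ve = 0.090, Tap = 1.4e-3,
                              a1 = 9e7, a2 = 5e7, a3 = 2e4) {
  stopifnot(Ve > 0, Tap > 0, a1 > 0, a2 > 0, a3 > 0)
  if (a3^2 < 4 * a2) {
    warn("a3^2 < 4*a2: the fibre-AP response is underdamped.")
  }
  structure(list(Ve = Ve, Tap = Tap, a1 = a1, a2 = a2, a3 = a3),
            class = "excitation_params")
}

# Fastest characteristic rate of the fibre-AP equation (rad/s).
fibre_ap_max_root <- function(params) {
  d <- params$a3^2 - 4 * params$a2
  if (d >= 0) (params$a3 + sqrt(d)) / 2 else params$a3 / 2
}

check_dt_solver <- function(dt_solver, max_root, what) {
  lim <- 0.1 / max_root
  if (dt_solver > lim) {
    abort(sprintf(paste0(
      "dt_solver = %.2e s is too coarse for the %s dynamics: the fastest ",
      "mode decays at %.0f s^-1, so the step must not exceed 0.1/%.0f = ",
      "%.2e s. Reduce `dt_solver`."), dt_solver, what, max_root, max_root, lim))
  }
  invisible(dt_solver)
}

#' Motoneuron action-potential train
#'
#' Transforms discharge times into the motoneuron membrane potential
#' `e(t)`: each discharge at `t_i` launches a half-sine wave
#' `Ve * sin(2*pi/Tap * (t - t_i))` supported on `[t_i, t_i + Tap/2]`; the
#' membrane is at rest elsewhere. Discharges closer than `Tap/2` produce
#' overlapping waves, which are summed with a warning (the physiological
#' regime never reaches such rates).
#'
#' @param spike_times Numeric vector of discharge times (s) for one MU.
#' @param params An [excitation_params()].
#' @param fs Output sampling rate in Hz.
#' @param duration Trace duration in seconds.
#' @return Tibble with columns `time` (s) and `e` (V).
#' @examples
#' e <- mn_ap_train(0.01, duration = 0.02, fs = 20480)
#' max(e$e) # ~0.09 V at the sine peak
#' @export
mn_ap_train <- function(spike_times, params = excitation_params(),
                        fs = 2048, duration) {
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) > 1 &&
      any(diff(spike_times) < params$Tap / 2)) {
    warn("Discharges closer than Tap/2: overlapping AP waves are summed.")
  }
  tt <- seq(0, duration, by = 1 / fs)
  tibble::tibble(time = tt,
                 e = mn_ap_eval_cpp(tt, spike_times, params$Ve, params$Tap))
}

#' Fibre action-potential train
#'
#' Solves the driven second-order fibre membrane equation
#' `u'' = a1*e(t) - a2*u - a3*u'` from rest, with fixed-step RK4 and linear
#' interpolation of the sampled input. For the default coefficients the
#' response to a single MN AP is overdamped with time-to-peak of about
#' 0.6 ms.
#'
#' @param e Tibble `(time, e)` from [mn_ap_train()] (uniform time grid).
#' @param params An [excitation_params()].
#' @param dt_solver Integration step in seconds. Must resolve the fastest
#'   characteristic rate (`dt_solver <= 0.1/max_root`, about 5.9e-6 s for
#'   the defaults); coarser steps are refused.
#' @return Tibble with columns `time` (s) and `u` (V) on the input grid.
#' @export
fibre_ap_ode <- function(e, params = excitation_params(), dt_solver = 5e-6) {
  tr <- check_trace(e, value_col = "e", arg = "e")
  check_dt_solver(dt_solver, fibre_ap_max_root(params), "fibre AP")
  u <- ode2_driven_cpp(tr$time, tr$value,
                       params$a1, params$a2, params$a3, dt_solver)
  tibble::tibble(time = tr$time, u = u)
}
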