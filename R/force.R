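#' Normalized force of one motor unit
#'
#' Scales the active state by the MU's normalized maximum force and the
#' activation-dependent force-length factor:
#' `f_mu_bar(t) = f0_bar * a(t) * f_FL(l_bar, a(t))`.
#'
#' @param a_trace Tibble `(time, a)` (e.g. an `ne_trajectory`).
#' @param f0_bar The MU's normalized maximum isometric force.
#' @param l_bar Normalized MU length.
#' @return Tibble with columns `time` and `f` (normalized force).
#' @export
mu_force <- function(a_trace, f0_bar, l_bar = 1.16) {
  if (f0_bar <= 0) abort("`f0_bar` must be > 0.")
  tr <- check_trace(a_trace, value_col = "a", arg = "a_trace")
  tibble::tibble(time = tr$time,
                 f = f0_bar * tr$value * fl_factor(l_bar, tr$value))
}

#' Twitch-dispersion filter
#'
#' The fibres of one MU receive the motoneuron command with small random
#' delays, so the MU force is the average of many slightly shifted copies
#' of the fibre twitch - a low-pass filter. The deterministic default
#' implements the many-fibre limit of this average: convolution with a
#' centred uniform (boxcar) kernel of width `window_s`, which preserves
#' the force-time integral exactly. `mode = "montecarlo"` instead draws
#' `ir` explicit fibre delays uniformly in `[-window_s/2, window_s/2]`
#' (seeded), reproducing the finite-fibre average.
#'
#' @param f_trace Tibble `(time, f)` of one MU's normalized force.
#' @param window_s Dispersion window in seconds (0 = identity).
#' @param mode `"boxcar"` (deterministic limit) or `"montecarlo"`.
#' @param ir Fibre count for the Monte-Carlo mode.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return Tibble with columns `time` and `f` (dispersed force).
#' @export
dispersion_filter <- function(f_trace, window_s = 0.004,
                              mode = c("boxcar", "montecarlo"),
                              ir = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (window_s < 0) abort("`window_s` must be >= 0.")
  tr <- check_trace(f_trace, value_col = "f", arg = "f_trace")
  n <- nrow(tr)
  if (n < 2 || window_s == 0) return(tibble::tibble(time = tr$time, f = tr$value))
  dt <- tr$time[2] - tr$time[1]
  if (window_s >= (tr$time[n] - tr$time[1])) {
    abort("Dispersion window exceeds the trace length.")
  }
  half <- floor(window_s / dt / 2)
  if (mode == "boxcar") {
    k <- rep(1, 2 * half + 1)
    k <- k / sum(k)
    if (length(k) == 1) return(tibble::tibble(time = tr$time, f = tr$value))
    # edge-replication padding: constant traces pass through unchanged and
    # the integral of a compactly supported trace is preserved exactly
    x <- c(rep(tr$value[1], half), tr$value, rep(tr$value[n], half))
    y <- stats::filter(x, k, method = "convolution", sides = 2)
    f <- as.numeric(y[(half + 1):(half + n)])
  } else {
    if (is.null(ir)) abort("Monte-Carlo mode needs the fibre count `ir`.")
    shifts <- with_local_seed(seed,
      round(stats::runif(ir, -window_s / 2, window_s / 2) / dt))
    f <- rep(0, n)
    for (s in shifts) {
      idx <- seq_len(n) - s
      v <- ifelse(idx >= 1 & idx <= n, tr$value[pmin(pmax(idx, 1), n)], 0)
      f <- f + v
    }
    f <- f / ir
  }
  tibble::tibble(time = tr$time, f = f)
}

#' Zero low-rate MUs recruited during the plateau
#'
#' MUs that first appear during the constant-torque plateau and discharge
#' below `min_rate_hz` on average over the plateau carry too little
#' information to contribute a meaningful force estimate; their predicted
#' force is set to zero over the whole trace. MUs recruited during the
#' ramps are untouched regardless of rate.
#'
#' @param spikes A [spike_train_set()], same MU ordering as `forces`.
#' @param forces Long tibble `(time, mu, f)` of per-MU forces.
#' @param plateau Numeric `c(start, end)` of the plateau in seconds.
#' @param min_rate_hz Rate threshold in Hz (0 = identity).
#' @return `forces` with the affected MUs zeroed; the zeroed MU indices
#'   are recorded in the `zeroed` attribute.
#' @export
plateau_rate_rule <- function(spikes, forces, plateau, min_rate_hz = 7) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (length(plateau) != 2 || plateau[2] <= plateau[1]) {
    abort("`plateau` must be a non-empty interval c(start, end).")
  }
  dur <- plateau[2] - plateau[1]
  zeroed <- integer(0)
  if (min_rate_hz > 0) {
    for (k in seq_len(spikes$n_mu)) {
      tt <- spikes$times[[k]]
      if (!length(tt)) next
      recruited_in_plateau <- min(tt) >= plateau[1] && min(tt) <= plateau[2]
      if (!recruited_in_plateau) next
      rate <- sum(tt >= plateau[1] & tt <= plateau[2]) / dur
      if (rate < min_rate_hz) zeroed <- c(zeroed, k)
    }
  }
  out <- dplyr::mutate(forces,
                       f = ifelse(.data$mu %in% zeroed, 0, .data$f))
  attr(out, "zeroed") <- zeroed
  out
}

#' Simulate whole-muscle force from a set of spike trains
#'
#' Runs the excitation-activation chain for every MU, converts active
#' states to normalized MU forces with the force-length factor, applies
#' the twitch-dispersion filter and (optionally) the plateau low-rate
#' rule, and sums across MUs:
#' `F_M(t) = F0M * sum_k F_mu_bar_k(t)`.
#'
#' @param spikes A [spike_train_set()].
#' @param f0_bar Normalized maximum force per MU (own `f0_bar` for a full
#'   pool, or representative values from [representative_forces()]);
#'   recycled if length 1.
#' @param mu_type `"slow"`/`"fast"` per MU (recycled).
#' @param l_bar Normalized MU length shared by the pool (1.16 for the TA
#'   working posture).
#' @param F0M Muscle maximum isometric force (N).
#' @param dispersion_window Twitch-dispersion window in seconds.
#' @param plateau Optional plateau interval `c(start, end)` activating the
#'   low-rate rule.
#' @param min_rate_hz Rate threshold of the plateau rule.
#' @param fs Output sampling rate (Hz); defaults to the spike set's.
#' @param dt_solver Internal RK4 step (s).
#' @return A `muscle_sim` object: list with `mu_forces` (long tibble
#'   `time, mu, f_raw, f`), `muscle` (tibble `time, F_M_bar, F_M`) and the
#'   simulation settings.
#' @examples
#' \donttest{
#' sp <- spike_train_set(list(seq(0.1, 2, by = 1/12)), duration = 3)
#' sim <- simulate_muscle(sp, f0_bar = 0.01, mu_type = "slow", F0M = 1046)
#' glance(sim)
#' }
#' @export
simulate_muscle <- function(spikes, f0_bar, mu_type = "slow", l_bar = 1.16,
                            F0M = 1, dispersion_window = 0.004,
                            plateau = NULL, min_rate_hz = 7,
                            fs = NULL, dt_solver = 5e-6) {
  stopifnot(inherits(spikes, "spike_train_set"))
  n <- spikes$n_mu
  if (n < 1) abort("Empty spike set: no MUs to simulate.")
  f0_bar <- rep_len(f0_bar, n)
  mu_type <- rep_len(mu_type, n)
  fs <- fs %||% spikes$fs
  mu_forces <- purrr::map_dfr(seq_len(n), function(k) {
    tr <- simulate_ne(spikes$times[[k]], mu_type[k], l_bar,
                      duration = spikes$duration, fs = fs,
                      dt_solver = dt_solver)
    fr <- mu_force(tr, f0_bar[k], l_bar)
    fd <- dispersion_filter(fr, dispersion_window)
    tibble::tibble(time = fr$time, mu = k, f_raw = fr$f, f = fd$f)
  })
  zeroed <- integer(0)
  if (!is.null(plateau)) {
    mu_forces <- plateau_rate_rule(spikes, mu_forces, plateau, min_rate_hz)
    zeroed <- attr(mu_forces, "zeroed")
  }
  muscle <- mu_forces |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(F_M_bar = sum(.data$f), .groups = "drop") |>
    dplyr::mutate(F_M = F0M * .data$F_M_bar)
  structure(
    list(mu_forces = mu_forces, muscle = muscle,
         settings = list(n_mu = n, f0_bar = f0_bar, mu_type = mu_type,
                         l_bar = l_bar, F0M = F0M,
                         dispersion_window = dispersion_window,
                         plateau = plateau, min_rate_hz = min_rate_hz,
                         fs = fs, dt_solver = dt_solver,
                         zeroed = zeroed)),
    class = "muscle_sim")
}

#' @export
print.muscle_sim <- function(x, ...) {
  cat(sprintf(
    "<muscle_sim> %d MUs, %.1f s at %g Hz; peak force %.1f N (F0M = %g N)\n",
    x$settings$n_mu, max(x$muscle$time), x$settings$fs,
    max(x$muscle$F_M), x$settings$F0M))
  if (length(x$settings$zeroed)) {
    cat("  plateau low-rate rule zeroed MU(s):",
        paste(x$settings$zeroed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a whole-muscle simulation
#'
#' `tidy()` returns the whole-muscle force trace; `glance()` a one-row
#' summary with the peak and mean forces and the simulation settings.
#'
#' @param x A `muscle_sim` from [simulate_muscle()].
#' @param ... Unused.
#' @method tidy muscle_sim
#' @export
tidy.muscle_sim <- function(x, ...) x$muscle

#' @rdname tidy.muscle_sim
#' @method glance muscle_sim
#' @export
glance.muscle_sim <- function(x, ...) {
  tibble::tibble(n_mu = x$settings$n_mu,
                 duration = max(x$muscle$time),
                 peak_F_M = max(x$muscle$F_M),
                 mean_F_M = mean(x$muscle$F_M),
                 F0M = x$settings$F0M,
                 l_bar = x$settings$l_bar,
                 n_zeroed = length(x$settings$zeroed))
}
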