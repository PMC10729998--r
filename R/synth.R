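#' Synthetic trapezoidal isometric task
#'
#' Describes a trapezoidal isometric contraction - linear ramp up at
#' `ramp_rate` %MVC/s, constant plateau, linear ramp down - together with
#' an onion-skin rate-coding model for the MU pool: every MU starts
#' discharging when the common input exceeds its recruitment threshold,
#' its instantaneous rate grows with the excess drive, and its saturation
#' rate decreases with its threshold (earlier-recruited MUs fire faster).
#' Discharge times are drawn by integrating the instantaneous rate to a
#' unit threshold with lognormal inter-spike jitter, so a fixed seed gives
#' bit-reproducible spike trains.
#'
#' @param mvc_peak Plateau level in %MVC, in (0, 100].
#' @param ramp_rate Ramp rate in %MVC/s.
#' @param plateau_s Plateau duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param lead_s Quiet lead-in (and tail) before the ramp, seconds.
#' @param rate_model List with `min_rate` (Hz at recruitment), `peak_rate`
#'   (Hz, saturation of the lowest-threshold MU), `onion_slope` (Hz lost
#'   per %MVC of recruitment threshold) and `gain` (Hz per %MVC of excess
#'   drive).
#' @param isi_jitter_cv Coefficient of variation of the inter-spike
#'   intervals.
#' @param seed Integer seed for the discharge-time generator.
#' @return An object of class `synthetic_task`.
#' @export
synthetic_task <- function(mvc_peak = 30, ramp_rate = 5, plateau_s = 20,
                           fs = 2048, lead_s = 1,
                           rate_model = list(min_rate = 8, peak_rate = 35,
                                             onion_slope = 0.3, gain = 3),
                           isi_jitter_cv = 0.15, seed = 1) {
  if (mvc_peak <= 0 || mvc_peak > 100) abort("`mvc_peak` must be in (0, 100].")
  if (fs <= 0) abort("`fs` must be > 0.")
  ramp_s <- mvc_peak / ramp_rate
  duration <- 2 * lead_s + 2 * ramp_s + plateau_s
  structure(
    list(mvc_peak = mvc_peak, ramp_rate = ramp_rate, plateau_s = plateau_s,
         ramp_s = ramp_s, lead_s = lead_s, fs = fs, duration = duration,
         rate_model = rate_model, isi_jitter_cv = isi_jitter_cv,
         seed = as.integer(seed)),
    class = "synthetic_task")
}

#' @export
print.synthetic_task <- function(x, ...) {
  cat(sprintf(
    "<synthetic_task> trapezoid to %g%% MVC (%g%%/s ramps, %g s plateau), %g s at %g Hz, seed %d\n",
    x$mvc_peak, x$ramp_rate, x$plateau_s, x$duration, x$fs, x$seed))
  invisible(x)
}

#' @rdname synthetic_task
#' @param task A `synthetic_task`.
#' @return `common_input()`: tibble `(time, target)` with the target
#'   contraction level in %MVC; `task_plateau()`: the plateau interval
#'   `c(start, end)` in seconds.
#' @export
common_input <- function(task) {
  tt <- seq(0, task$duration, by = 1 / task$fs)
  up0 <- task$lead_s
  pl0 <- up0 + task$ramp_s
  pl1 <- pl0 + task$plateau_s
  dn1 <- pl1 + task$ramp_s
  target <- ifelse(tt < up0, 0,
            ifelse(tt < pl0, (tt - up0) * task$ramp_rate,
            ifelse(tt < pl1, task$mvc_peak,
            ifelse(tt < dn1, task$mvc_peak - (tt - pl1) * task$ramp_rate, 0))))
  tibble::tibble(time = tt, target = target)
}

#' @rdname synthetic_task
#' @export
task_plateau <- function(task) {
  c(task$lead_s + task$ramp_s, task$lead_s + task$ramp_s + task$plateau_s)
}

# Instantaneous discharge rate of MU with threshold th under drive ci.
onion_rate <- function(ci, th, rm) {
  peak <- max(rm$min_rate, rm$peak_rate - rm$onion_slope * th)
  ifelse(ci >= th, pmin(rm$min_rate + rm$gain * (ci - th), peak), 0)
}

#' Generate synthetic spike trains for a pool subset
#'
#' Draws discharge times for each MU of `pool` (or a subset) under the
#' task's common input: a MU discharges only while the target exceeds its
#' recruitment threshold, at the onion-skin instantaneous rate, with
#' lognormal inter-spike jitter. Lower-threshold MUs are always recruited
#' no later than higher-threshold ones.
#'
#' @param pool A [mu_pool()] tibble.
#' @param task A [synthetic_task()].
#' @param indices Optional pool indices (rows of `pool`) to simulate;
#'   defaults to all.
#' @return A [spike_train_set()] with one train per selected MU, the
#'   selected pool indices in attribute `pool_indices` and the common
#'   input trace in attribute `target`.
#' @examples
#' pool <- mu_pool(mu_pool_spec())
#' sp <- generate_spikes(pool, synthetic_task(mvc_peak = 10, plateau_s = 2),
#'                       indices = c(1, 50, 100))
#' vapply(sp$times, length, integer(1))
#' @export
generate_spikes <- function(pool, task, indices = NULL) {
  stopifnot(inherits(task, "synthetic_task"))
  indices <- indices %||% pool$mu
  sub <- pool[match(indices, pool$mu), ]
  if (any(is.na(sub$mu))) abort("`indices` must be rows of `pool`.")
  rm_ <- task$rate_model
  if (rm_$peak_rate > task$fs / 2) {
    abort("Rate model exceeds fs/2: increase `fs` or lower `peak_rate`.")
  }
  ci <- common_input(task)
  dt <- 1 / task$fs
  sdlog <- sqrt(log(1 + task$isi_jitter_cv^2))
  times <- with_local_seed(task$seed, {
    lapply(seq_len(nrow(sub)), function(k) {
      rate <- onion_rate(ci$target, sub$T_th[k], rm_)
      phase <- 0
      thresh <- 1
      out <- numeric(0)
      for (i in seq_along(rate)) {
        if (rate[i] <= 0) { phase <- 0; next }
        phase <- phase + rate[i] * dt
        if (phase >= thresh) {
          out <- c(out, ci$time[i])
          phase <- 0
          thresh <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }
      }
      out
    })
  })
  sts <- spike_train_set(times, fs = task$fs, duration = task$duration)
  attr(sts, "pool_indices") <- sub$mu
  attr(sts, "target") <- ci
  sts
}

#' End-to-end synthetic self-test of the pipeline
#'
#' Generates a trapezoidal task with a reduced MU sample spread over the
#' recruited pool, simulates the whole-muscle force, estimates the
#' effective neural drive from the same spike trains, and validates the
#' drive against the simulated force (both normalized to their plateau
#' mean). In this isometric regime the smoothed drive and the force should
#' agree closely (r^2 >= 0.9) and increase together on the ramps.
#'
#' @param seed Integer seed.
#' @param n_mu Number of simulated MUs sampled from the recruited pool.
#' @param mvc_peak Plateau level in %MVC.
#' @param plateau_s Plateau duration (s).
#' @param spec A [mu_pool_spec()].
#' @param F0M Muscle maximum isometric force (N).
#' @param l_bar Normalized MU length.
#' @param dt_solver Internal RK4 step (s).
#' @return List with `report` (a `validation_report`), `r2`, the ramp
#'   correlation `ramp_rho`, `passed`, and the underlying `sim`, `drive`
#'   and `force` objects.
#' @export
end_to_end_selftest <- function(seed = 42, n_mu = 50, mvc_peak = 30,
                                plateau_s = 26, spec = mu_pool_spec(),
                                F0M = 1046, l_bar = 1.16,
                                dt_solver = 5e-6) {
  if (n_mu < 1) abort("Zero-MU pool: nothing to self-test.")
  pool <- mu_pool(spec, F0M = F0M)
  n_active <- recruited_count(spec, mvc_peak)
  n_mu <- min(n_mu, n_active)
  rep_f <- representative_forces(spec, n_active = n_active,
                                 n_identified = n_mu, method = "blind",
                                 F0M = F0M)
  task <- synthetic_task(mvc_peak = mvc_peak, plateau_s = plateau_s,
                         seed = seed)
  spikes <- generate_spikes(pool, task, indices = rep_f$N_i)
  plateau <- task_plateau(task)
  sim <- simulate_muscle(spikes, f0_bar = rep_f$f0_rep_bar,
                         mu_type = pool$type[rep_f$N_i], l_bar = l_bar,
                         F0M = F0M, plateau = plateau,
                         dt_solver = dt_solver)
  drive <- neural_drive(spikes, plateau = plateau)
  fsel <- sim$muscle$time >= plateau[1] & sim$muscle$time <= plateau[2]
  force <- tibble::tibble(time = sim$muscle$time,
                          value = sim$muscle$F_M / mean(sim$muscle$F_M[fsel]))
  report <- trace_metrics(tibble::tibble(time = drive$time,
                                         value = drive$drive),
                          force, segments = "auto")
  ramp_sel <- force$time >= task$lead_s &
    force$time <= task$lead_s + task$ramp_s
  ramp_rho <- stats::cor(drive$drive[ramp_sel], force$value[ramp_sel],
                         method = "spearman")
  list(report = report, r2 = report$r2, ramp_rho = ramp_rho,
       passed = is.finite(report$r2) && report$r2 >= 0.9 && ramp_rho > 0,
       sim = sim, drive = drive, force = force, task = task)
}
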