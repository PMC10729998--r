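#' Effective neural drive to the muscle
#'
#' The low-frequency content of the cumulative spike train of the pool is
#' the component of the neural command that is transduced into force in
#' isometric conditions. The binary spike trains are summed per sample,
#' low-pass filtered (2nd-order Butterworth, default 4 Hz cutoff, applied
#' forward-backward so onsets are not delayed), and normalized to the
#' trace's mean over the contraction plateau - mirroring the normalization
#' of the reference force. Without a plateau interval the trace is
#' normalized to its maximum, with a warning.
#'
#' @param spikes A [spike_train_set()] with at least one discharge.
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @param order Butterworth order.
#' @param plateau Optional `c(start, end)` plateau interval (s) for the
#'   normalization.
#' @return Tibble with columns `time` (s) and `drive` (normalized).
#' @export
neural_drive <- function(spikes, cutoff_hz = 4, order = 2, plateau = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (sum(vapply(spikes$times, length, integer(1))) == 0) {
    abort("Empty spike set: cannot estimate a neural drive.")
  }
  cst <- colSums(spike_matrix(spikes))
  bf <- signal::butter(order, cutoff_hz / (spikes$fs / 2), type = "low")
  d <- as.numeric(signal::filtfilt(bf, cst))
  tt <- (seq_along(d) - 1) / spikes$fs
  if (is.null(plateau)) {
    warn("No plateau interval supplied: normalizing the drive to its maximum.")
    ref <- max(d)
  } else {
    ref <- mean(d[tt >= plateau[1] & tt <= plateau[2]])
  }
  tibble::tibble(time = tt, drive = d / ref)
}

trace_onset <- function(time, value, threshold_frac) {
  if (max(value) <= 0) return(NA_real_)
  th <- threshold_frac * max(value)
  i <- which(value >= th)[1]
  if (is.na(i)) return(NA_real_)
  time[i]
}

#' Onset error between predicted and reference traces
#'
#' The onset of a trace is its first crossing of `threshold_frac` (default
#' 2%) of its own maximum. `delta1` is the predicted onset minus the
#' reference onset (positive = late prediction); `delta1F` is the
#' reference value already developed at the predicted onset time.
#'
#' @param pred,ref Data frames `(time, value)` on a shared time base.
#' @param threshold_frac Onset threshold as a fraction of the trace max.
#' @return List with `delta1` (s) and `delta1F` (reference units).
#' @export
onset_error <- function(pred, ref, threshold_frac = 0.02) {
  p <- check_trace(pred, arg = "pred")
  r <- check_trace(ref, arg = "ref")
  t_p <- trace_onset(p$time, p$value, threshold_frac)
  t_r <- trace_onset(r$time, r$value, threshold_frac)
  if (is.na(t_p) || is.na(t_r)) {
    abort("A trace never crosses the onset threshold: onset error undefined.")
  }
  d1F <- approx(r$time, r$value, xout = t_p, rule = 2)$y
  list(delta1 = t_p - t_r, delta1F = d1F)
}

segment_nrmse <- function(p, r, sel, normalizer, plateau_mean) {
  if (!any(sel)) return(NA_real_)
  rmse <- sqrt(mean((p[sel] - r[sel])^2))
  den <- switch(normalizer,
                range = diff(range(r[sel])),
                max = max(r[sel]),
                plateau = plateau_mean)
  100 * rmse / den
}

#' Validation metrics for a predicted-vs-reference trace pair
#'
#' Computes the whole set of metrics used to validate a predicted force
#' (or neural drive) against a reference trace: onset error `delta1` and
#' the reference force `delta1F` developed at the predicted onset, the
#' maximum absolute error `ME`, the normalized RMS error (in %, over the
#' whole trace and optionally over the ascending ramp, plateau and
#' descending ramp), and the coefficient of determination `r2`.
#'
#' The nRMSE normalizer is configurable: the reference range over the
#' analysed interval (default), its maximum, or the plateau mean.
#'
#' @param pred,ref Data frames `(time, value)` sharing a time base (equal
#'   lengths).
#' @param segments Optional list with elements `r1`, `plateau`, `r2`, each
#'   `c(start, end)` in seconds, or `"auto"` to detect them from the
#'   reference trapezoid (see [detect_segments()]).
#' @param normalizer `"range"`, `"max"` or `"plateau"`.
#' @param threshold_frac Onset threshold for [onset_error()].
#' @return A `validation_report` object. `tidy()` gives a long
#'   metric/value tibble; `glance()` a one-row tibble.
#' @examples
#' tr <- tibble::tibble(time = seq(0, 10, 0.01),
#'                      value = pmin(time, 10 - time, 3) / 3)
#' glance(trace_metrics(tr, tr))
#' @export
trace_metrics <- function(pred, ref, segments = NULL,
                          normalizer = c("range", "max", "plateau"),
                          threshold_frac = 0.02) {
  normalizer <- match.arg(normalizer)
  p <- check_trace(pred, arg = "pred")
  r <- check_trace(ref, arg = "ref")
  if (nrow(p) != nrow(r)) abort("`pred` and `ref` must have equal lengths.")
  if (identical(segments, "auto")) segments <- detect_segments(r)
  plateau_mean <- if (!is.null(segments$plateau)) {
    sel <- r$time >= segments$plateau[1] & r$time <= segments$plateau[2]
    mean(r$value[sel])
  } else max(r$value)
  if (normalizer == "plateau" && is.null(segments$plateau)) {
    warn("No plateau segment for the plateau normalizer: using max(ref).")
  }
  me <- max(abs(p$value - r$value))
  ss_tot <- sum((r$value - mean(r$value))^2)
  r2 <- if (ss_tot == 0) {
    warn("Constant reference trace: r^2 undefined (NaN).")
    NaN
  } else 1 - sum((p$value - r$value)^2) / ss_tot
  all_sel <- rep(TRUE, nrow(r))
  nrmse <- segment_nrmse(p$value, r$value, all_sel, normalizer, plateau_mean)
  seg_nrmse <- c(r1 = NA_real_, plateau = NA_real_, r2 = NA_real_)
  for (sname in c("r1", "plateau", "r2")) {
    if (!is.null(segments[[sname]])) {
      sel <- r$time >= segments[[sname]][1] & r$time <= segments[[sname]][2]
      seg_nrmse[sname] <- segment_nrmse(p$value, r$value, sel,
                                        normalizer, plateau_mean)
    }
  }
  ons <- onset_error(p, r, threshold_frac)
  structure(
    list(delta1 = ons$delta1, delta1F = ons$delta1F, ME = me,
         nRMSE = nrmse, nRMSE_r1 = unname(seg_nrmse["r1"]),
         nRMSE_p = unname(seg_nrmse["plateau"]),
         nRMSE_r2 = unname(seg_nrmse["r2"]), r2 = r2,
         normalizer = normalizer, segments = segments,
         pred = p, ref = r),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  delta1 = %.3f s, delta1F = %.3g, ME = %.3g\n",
              x$delta1, x$delta1F, x$ME))
  cat(sprintf("  nRMSE = %.2f%% (%s-normalized), r2 = %.3f\n",
              x$nRMSE, x$normalizer, x$r2))
  if (!is.na(x$nRMSE_r1) || !is.na(x$nRMSE_p) || !is.na(x$nRMSE_r2)) {
    cat(sprintf("  segments: r1 %.2f%%, plateau %.2f%%, r2 %.2f%%\n",
                x$nRMSE_r1, x$nRMSE_p, x$nRMSE_r2))
  }
  invisible(x)
}

#' @rdname trace_metrics
#' @param x A `validation_report`.
#' @param ... Unused.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  tibble::tibble(
    metric = c("delta1", "delta1F", "ME", "nRMSE", "nRMSE_r1", "nRMSE_p",
               "nRMSE_r2", "r2"),
    value = c(x$delta1, x$delta1F, x$ME, x$nRMSE, x$nRMSE_r1, x$nRMSE_p,
              x$nRMSE_r2, x$r2))
}

#' @rdname trace_metrics
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(delta1 = x$delta1, delta1F = x$delta1F, ME = x$ME,
                 nRMSE = x$nRMSE, nRMSE_r1 = x$nRMSE_r1,
                 nRMSE_p = x$nRMSE_p, nRMSE_r2 = x$nRMSE_r2, r2 = x$r2)
}

#' Detect the trapezoid segments of a reference trace
#'
#' The plateau is the longest contiguous run of samples within 95-105% of
#' the plateau level (estimated as the mean of the top 5% of the trace);
#' the ascending ramp runs from the 2%-of-max onset to the plateau start,
#' the descending ramp from the plateau end to the last 2% crossing.
#'
#' @param ref Data frame `(time, value)`.
#' @param tol Relative band around the plateau level.
#' @return List with `r1`, `plateau`, `r2`, each `c(start, end)` in s.
#' @export
detect_segments <- function(ref, tol = 0.05) {
  r <- check_trace(ref, arg = "ref")
  lev <- mean(r$value[r$value >= stats::quantile(r$value, 0.95)])
  inband <- r$value >= (1 - tol) * lev & r$value <= (1 + tol) * lev
  runs <- rle(inband)
  if (!any(runs$values)) abort("No plateau found in the reference trace.")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which.max(ifelse(runs$values, runs$lengths, 0))
  p1 <- r$time[starts[k]]; p2 <- r$time[ends[k]]
  th <- 0.02 * max(r$value)
  on <- r$time[which(r$value >= th)[1]]
  off <- r$time[rev(which(r$value >= th))[1]]
  list(r1 = c(on, p1), plateau = c(p1, p2), r2 = c(p2, off))
}
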