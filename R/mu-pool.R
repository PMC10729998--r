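#' Motor-unit pool specification
#'
#' Defines the size and the distribution coefficients of a muscle-specific
#' motor-unit (MU) pool. The defaults describe a typical adult human tibialis
#' anterior (TA): `N = 400` MUs innervating `n_fibres = 200000` muscle
#' fibres, with linear-exponential distributions of recruitment threshold,
#' normalized twitch force and normalized maximum (tetanic) force across the
#' threshold-ranked pool, and 72% slow-type fibres.
#'
#' Each distribution has the form
#' `scale * (linear * (j/N) + base^((j/N)^exponent))` where `j` is the MU
#' index in ascending recruitment-threshold order. The second term is an
#' exponential with base `base` raised to the power `(j/N)^exponent`; this
#' parse is the one that reproduces the published fold ranges (16.3-fold
#' twitch, 11-fold tetanic) and recruitment counts of the TA pool.
#'
#' @param N Number of MUs in the pool.
#' @param n_fibres Total number of muscle fibres in the muscle.
#' @param threshold_coeffs,twitch_coeffs,force_coeffs Named numeric vectors
#'   with elements `scale`, `linear`, `base`, `exponent`.
#' @param slow_fibre_fraction Fraction of `n_fibres` that are slow-type,
#'   in (0, 1).
#'
#' @return An object of class `mu_pool_spec`.
#' @examples
#' spec <- mu_pool_spec()
#' threshold_distribution(spec, 400) # 89.06 %MVC
#' @export
mu_pool_spec <- function(N = 400,
                         n_fibres = 200000,
                         threshold_coeffs = c(scale = 0.50, linear = 58.12,
                                              base = 120, exponent = 1.83),
                         twitch_coeffs = c(scale = 6.07, linear = 4.52,
                                           base = 11.96, exponent = 4.66),
                         force_coeffs = c(scale = 7.86e-4, linear = 3.00,
                                          base = 8.20, exponent = 5.29),
                         slow_fibre_fraction = 0.72) {
  stopifnot(N >= 1, n_fibres >= N)
  for (cf in list(threshold_coeffs, twitch_coeffs, force_coeffs)) {
    if (!all(c("scale", "linear", "base", "exponent") %in% names(cf))) {
      abort("Distribution coefficients need names scale, linear, base, exponent.")
    }
    if (any(cf <= 0)) abort("All distribution coefficients must be > 0.")
  }
  if (slow_fibre_fraction <= 0 || slow_fibre_fraction >= 1) {
    abort("`slow_fibre_fraction` must lie in (0, 1).")
  }
  structure(
    list(N = as.integer(N), n_fibres = n_fibres,
         threshold_coeffs = threshold_coeffs,
         twitch_coeffs = twitch_coeffs,
         force_coeffs = force_coeffs,
         slow_fibre_fraction = slow_fibre_fraction),
    class = "mu_pool_spec")
}

#' @export
print.mu_pool_spec <- function(x, ...) {
  cat("<mu_pool_spec>", x$N, "MUs,", format(x$n_fibres, big.mark = ","),
      "fibres,", sprintf("%.0f%% slow fibres\n", 100 * x$slow_fibre_fraction))
  invisible(x)
}

# Linear-exponential distribution evaluated at (possibly fractional) index x.
linexp_eval <- function(coeffs, x, N) {
  r <- x / N
  coeffs[["scale"]] * (coeffs[["linear"]] * r +
                         coeffs[["base"]]^(r^coeffs[["exponent"]]))
}

check_index <- function(j, N) {
  if (any(j < 1 | j > N)) {
    abort(sprintf("MU index out of range [1, %d].", N))
  }
  j
}

#' MU property distributions across the threshold-ranked pool
#'
#' `threshold_distribution()` returns recruitment thresholds in %MVC,
#' `twitch_distribution()` normalized twitch forces (printed scale) and
#' `max_force_distribution()` normalized and absolute maximum isometric
#' forces. All three are strictly increasing in the MU index, so ranking by
#' any of them is equivalent (size-ordered recruitment).
#'
#' @param spec A [mu_pool_spec()].
#' @param j MU indices in `[1, N]`; defaults to the whole pool.
#'
#' @return For `threshold_distribution()` and `twitch_distribution()`, a
#'   numeric vector along `j`. For `max_force_distribution()`, a tibble with
#'   columns `mu`, `f0_bar` (dimensionless, summing to about 1 over the full
#'   pool) and `f0_N` (Newtons, `f0_bar * F0M`).
#' @examples
#' spec <- mu_pool_spec()
#' # 16.3-fold range of twitch force across the TA pool
#' twitch_distribution(spec, 400) / twitch_distribution(spec, 1)
#' @export
threshold_distribution <- function(spec, j = seq_len(spec$N)) {
  check_index(j, spec$N)
  linexp_eval(spec$threshold_coeffs, j, spec$N)
}

#' @rdname threshold_distribution
#' @export
twitch_distribution <- function(spec, j = seq_len(spec$N)) {
  check_index(j, spec$N)
  linexp_eval(spec$twitch_coeffs, j, spec$N)
}

#' @rdname threshold_distribution
#' @param F0M Muscle maximum isometric force in Newtons.
#' @export
max_force_distribution <- function(spec, F0M = 1, j = seq_len(spec$N)) {
  if (F0M <= 0) abort("`F0M` must be > 0.")
  check_index(j, spec$N)
  f0_bar <- linexp_eval(spec$force_coeffs, j, spec$N)
  tibble::tibble(mu = as.integer(j), f0_bar = f0_bar, f0_N = f0_bar * F0M)
}

#' Innervation ratios of the MU pool
#'
#' Distributes the muscle's `n_fibres` fibres across MUs in proportion to
#' the normalized twitch-force distribution, so that the innervation ratios
#' sum exactly to `n_fibres` before rounding.
#'
#' @inheritParams threshold_distribution
#' @return Numeric vector of (real-valued) fibre counts per MU.
#' @seealso [round_innervation_ratios()] for total-preserving integer export.
#' @export
innervation_ratios <- function(spec) {
  ftw <- twitch_distribution(spec)
  ftw / sum(ftw) * spec$n_fibres
}

#' Round innervation ratios to integers, preserving the total
#'
#' Largest-remainder rounding: floors every value, then distributes the
#' remaining fibres to the largest fractional parts.
#'
#' @param ir Real-valued innervation ratios.
#' @param n_fibres Target total; defaults to `round(sum(ir))`.
#' @return Integer vector with `sum(out) == n_fibres`.
#' @export
round_innervation_ratios <- function(ir, n_fibres = round(sum(ir))) {
  fl <- floor(ir)
  rem <- n_fibres - sum(fl)
  if (rem > 0) {
    idx <- order(ir - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Partition the pool into slow- and fast-type MUs
#'
#' MUs `1..m` are labelled slow, the rest fast, where `m` is the smallest
#' index whose cumulative innervation ratio reaches
#' `slow_fibre_fraction * n_fibres`. With the TA defaults the boundary falls
#' at MU 359: the 359 smallest MUs gather 72% of the fibres.
#'
#' @param ir Innervation ratios (real-valued), one per MU.
#' @param slow_fibre_fraction Fraction of fibres that are slow-type.
#' @return Character vector `"slow"`/`"fast"` along the pool.
#' @export
assign_fibre_types <- function(ir, slow_fibre_fraction = 0.72) {
  m <- which(cumsum(ir) >= slow_fibre_fraction * sum(ir))[1]
  m <- max(m, 1L)  # the cumulative prefix always includes at least one MU
  c(rep("slow", m), rep("fast", length(ir) - m))
}

#' Build the full motor-unit pool table
#'
#' Assembles the per-MU recruitment thresholds, normalized twitch and
#' tetanic forces, innervation ratios and slow/fast labels into one tibble,
#' one row per MU in ascending recruitment-threshold order.
#'
#' @inheritParams threshold_distribution
#' @param F0M Muscle maximum isometric force in Newtons used to scale
#'   `f0_bar` to `f0_N`; `NA` leaves `f0_N` unset.
#' @return A tibble of class `mu_pool` with columns `mu`, `T_th` (%MVC),
#'   `f_tw_bar`, `f0_bar`, `f0_N`, `IR`, `type`, and the spec stored as an
#'   attribute.
#' @examples
#' pool <- mu_pool(mu_pool_spec(), F0M = 1046)
#' sum(pool$f0_bar)       # ~1: the normalized tetanic forces tile the muscle
#' table(pool$type)       # 359 slow / 41 fast
#' @export
mu_pool <- function(spec = mu_pool_spec(), F0M = NA_real_) {
  ir <- innervation_ratios(spec)
  f0 <- max_force_distribution(spec, F0M = if (is.na(F0M)) 1 else F0M)
  out <- tibble::tibble(
    mu = seq_len(spec$N),
    T_th = threshold_distribution(spec),
    f_tw_bar = twitch_distribution(spec),
    f0_bar = f0$f0_bar,
    f0_N = if (is.na(F0M)) NA_real_ else f0$f0_N,
    IR = ir,
    type = assign_fibre_types(ir, spec$slow_fibre_fraction))
  attr(out, "spec") <- spec
  attr(out, "F0M") <- F0M
  class(out) <- c("mu_pool", class(out))
  out
}

#' Number of MUs recruited at a contraction level
#'
#' @param spec A [mu_pool_spec()].
#' @param level Contraction level in %MVC.
#' @param inclusive Count thresholds equal to `level` as recruited
#'   (default); `FALSE` uses a strict comparison.
#' @return Integer count of MUs with threshold at or below `level`.
#' @export
recruited_count <- function(spec, level, inclusive = TRUE) {
  th <- threshold_distribution(spec)
  if (inclusive) sum(th <= level) else sum(th < level)
}

#' Measure recruitment thresholds from spike trains and a torque trace
#'
#' The recruitment threshold of each MU is the mean torque over a window
#' (default 10 ms) centred on the MU's first discharge. MUs without any
#' discharge are dropped with a warning; windows extending beyond the trace
#' are truncated with a warning.
#'
#' @param spikes A [spike_train_set()].
#' @param torque Data frame with columns `time` (s) and a torque value
#'   column (Nm, or %MVC if the trace is normalized).
#' @param window_ms Window width in milliseconds.
#' @return Tibble with columns `mu` (index in `spikes`), `t_first` (s) and
#'   `threshold`, ranked by ascending threshold.
#' @export
measure_recruitment_thresholds <- function(spikes, torque, window_ms = 10) {
  stopifnot(inherits(spikes, "spike_train_set"))
  tr <- check_trace(torque, arg = "torque")
  half <- window_ms / 2000
  n_spk <- vapply(spikes$times, length, integer(1))
  if (any(n_spk == 0)) {
    warn(sprintf("%d MU(s) without discharges excluded from threshold measurement.",
                 sum(n_spk == 0)))
  }
  keep <- which(n_spk > 0)
  res <- purrr::map_dfr(keep, function(k) {
    t1 <- min(spikes$times[[k]])
    lo <- t1 - half
    hi <- t1 + half
    if (lo < min(tr$time) || hi > max(tr$time)) {
      warn(sprintf("Threshold window for MU %d truncated to the torque trace.", k))
      lo <- max(lo, min(tr$time)); hi <- min(hi, max(tr$time))
    }
    sel <- tr$time >= lo & tr$time <= hi
    tibble::tibble(mu = k, t_first = t1, threshold = mean(tr$value[sel]))
  })
  dplyr::arrange(res, .data$threshold)
}

#' Map measured recruitment thresholds into the generic pool
#'
#' Solves `T_th(x) = threshold` for the continuous extension of the
#' threshold distribution over `x in [1, N]` by bisection and rounds the
#' root to the nearest integer MU index (ties round half up). Thresholds
#' above the pool maximum are clamped to `N` with a warning.
#'
#' @param thresholds Measured thresholds in the same units as the pool
#'   distribution (%MVC). Must be positive.
#' @param spec A [mu_pool_spec()].
#' @param tol Bisection tolerance on the continuous index.
#' @return Integer pool indices, one per measured threshold. Duplicates
#'   after rounding are kept, with a warning.
#' @examples
#' spec <- mu_pool_spec()
#' map_to_pool(threshold_distribution(spec, c(50, 400)), spec)
#' @export
map_to_pool <- function(thresholds, spec, tol = 1e-6) {
  if (any(thresholds <= 0)) abort("Thresholds must be positive.")
  th_max <- threshold_distribution(spec, spec$N)
  th_min <- threshold_distribution(spec, 1)
  out <- vapply(thresholds, function(th) {
    if (th > th_max) {
      warn(sprintf("Threshold %.2f above the pool maximum %.2f; clamped to N.",
                   th, th_max))
      return(as.numeric(spec$N))
    }
    if (th <= th_min) return(1)
    lo <- 1; hi <- spec$N
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (linexp_eval(spec$threshold_coeffs, mid, spec$N) < th) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  idx <- as.integer(floor(out + 0.5))  # ties round half up
  if (anyDuplicated(idx)) {
    warn("Duplicate pool indices after rounding; duplicates kept.")
  }
  idx
}

#' Representative maximum forces for a sample of identified MUs
#'
#' Experimental decomposition identifies only `N_r` of the `N_a` MUs
#' recruited in a task. Each identified MU is assigned the summed maximum
#' force of a window of neighbouring pool MUs so the sample represents the
#' whole recruited pool. With `method = "blind"` the identified MUs are
#' assumed evenly spread (`N_i = i * floor(N_a/N_r)`); with
#' `method = "mapped"` the caller supplies pool indices from
#' [map_to_pool()]. Interior window bounds follow the floor-midpoint rule
#' `[floor((N_{i-1}+N_i)/2)+1, floor((N_i+N_{i+1})/2)]`; the first window
#' starts at MU 1 and the last ends at `N_a`, so the windows tile the
#' recruited range exactly and the representative forces conserve the total
#' recruited force.
#'
#' @param spec A [mu_pool_spec()].
#' @param n_active Number of recruited MUs `N_a` (e.g.
#'   `recruited_count(spec, 30)`).
#' @param indices Sorted pool indices of the identified MUs (mapped method).
#' @param n_identified Number of identified MUs (blind method).
#' @param method `"mapped"` or `"blind"`.
#' @param F0M Muscle maximum isometric force (N) scaling the output.
#' @return Tibble with one row per identified MU: `i`, `N_i`, `lo`, `hi`,
#'   `n_represented`, `f0_rep_bar`, `f0_rep_N`.
#' @examples
#' spec <- mu_pool_spec()
#' # the middle MU of mapped indices (90, 120, 180) represents 45 MUs
#' representative_forces(spec, n_active = 300, indices = c(90, 120, 180),
#'                       F0M = 1046)
#' @export
representative_forces <- function(spec, n_active,
                                  indices = NULL, n_identified = NULL,
                                  method = c("mapped", "blind"), F0M = 1) {
  method <- match.arg(method)
  if (method == "blind") {
    if (is.null(n_identified)) abort("Blind method needs `n_identified`.")
    if (n_identified > n_active) abort("More identified MUs than recruited MUs.")
    indices <- seq_len(n_identified) * (n_active %/% n_identified)
  } else {
    if (is.null(indices)) abort("Mapped method needs `indices`.")
    if (is.unsorted(indices, strictly = TRUE)) {
      abort("`indices` must be strictly increasing (sorted, no duplicates).")
    }
    if (length(indices) > n_active) abort("More identified MUs than recruited MUs.")
  }
  if (any(indices < 1 | indices > spec$N)) abort("Pool indices out of [1, N].")
  nr <- length(indices)
  lo <- c(1L, floor((head(indices, -1) + indices[-1]) / 2) + 1L)
  hi <- c(floor((indices[-nr] + indices[-1]) / 2), as.integer(n_active))
  f0 <- max_force_distribution(spec, F0M = if (is.na(F0M)) 1 else F0M)
  rep_bar <- vapply(seq_len(nr),
                    function(i) sum(f0$f0_bar[lo[i]:hi[i]]), numeric(1))
  tibble::tibble(i = seq_len(nr), N_i = as.integer(indices),
                 lo = as.integer(lo), hi = as.integer(hi),
                 n_represented = as.integer(hi - lo + 1L),
                 f0_rep_bar = rep_bar, f0_rep_N = rep_bar * F0M)
}
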