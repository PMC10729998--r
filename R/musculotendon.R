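#' Subject-specific musculotendon parameter scaling
#'
#' Scales a generic model's optimal fibre length and tendon slack length to
#' a subject by preserving their ratios to the full musculotendon length.
#'
#' @param lMT Subject musculotendon length (any consistent length unit).
#' @param lMT_generic Generic-model musculotendon length.
#' @param l0_generic,lsT_generic Generic optimal fibre length and tendon
#'   slack length.
#' @return Named list with `l0M` and `lsT` in the unit of `lMT`.
#' @export
scale_lengths <- function(lMT, lMT_generic, l0_generic, lsT_generic) {
  if (any(c(lMT, lMT_generic, l0_generic, lsT_generic) <= 0)) {
    abort("All lengths must be > 0.")
  }
  r <- lMT / lMT_generic
  list(l0M = r * l0_generic, lsT = r * lsT_generic)
}

#' Maximum isometric force from muscle volume
#'
#' `F0M = (V / l0M) * sigma`: the physiological cross-sectional area
#' (volume over optimal fibre length) times the specific tetanic tension.
#'
#' @param V Muscle volume in cm^3.
#' @param l0M Optimal fibre length in cm.
#' @param sigma Specific tetanic tension in N/cm^2 (default 60).
#' @return Maximum isometric force in Newtons.
#' @examples
#' max_isometric_force(V = 118.9, l0M = 6.82) # TA: ~1046 N
#' @export
max_isometric_force <- function(V, l0M, sigma = 60) {
  if (any(c(V, l0M, sigma) <= 0)) abort("V, l0M and sigma must be > 0.")
  V / l0M * sigma
}

#' Normalized muscle length under the rigid-tendon assumption
#'
#' With the tendon fixed at its slack length, the fibre length is
#' `lMT - lsT` and the normalized length is `(lMT - lsT) / l0M`.
#'
#' @param lMT Musculotendon length.
#' @param lsT Tendon slack length (same unit).
#' @param l0M Optimal fibre length (same unit).
#' @return Dimensionless normalized length.
#' @examples
#' normalized_length(319, 240, 68.2) # TA at 30 deg plantarflexion: 1.16
#' @export
normalized_length <- function(lMT, lsT, l0M) {
  if (any(lMT <= lsT)) abort("`lMT` must exceed `lsT` (muscle length > 0).")
  (lMT - lsT) / l0M
}

#' Experimental muscle force from joint torque
#'
#' Converts a recorded joint torque trace into the force developed by one
#' muscle: `F(t) = (T(t) - deltaT(T(t))) / L`, where `deltaT` accounts for
#' the torque taken by co-contracting agonist and antagonist muscles. The
#' co-contraction correction is subject-specific and must be supplied; the
#' default `deltaT = NULL` applies no correction (as if the muscle alone
#' produced the torque) and warns.
#'
#' @param torque Data frame with columns `time` (s) and torque (Nm).
#' @param L Muscle moment arm in metres.
#' @param deltaT Either `NULL`, a function of torque returning the
#'   co-contraction torque, or numeric polynomial coefficients
#'   `c(a0, a1, ...)` evaluated as `a0 + a1*T + a2*T^2 + ...`.
#' @param fit_range Optional numeric range of torques over which `deltaT`
#'   was fitted; evaluation outside it warns about extrapolation.
#' @return Tibble with columns `time` and `force` (N).
#' @export
experimental_force <- function(torque, L, deltaT = NULL, fit_range = NULL) {
  if (L <= 0) abort("Moment arm `L` must be > 0.")
  tr <- check_trace(torque, arg = "torque")
  if (is.null(deltaT)) {
    warn(paste("No co-contraction correction supplied (deltaT = NULL):",
               "attributing the whole joint torque to this muscle."))
    dT <- rep(0, nrow(tr))
  } else if (is.function(deltaT)) {
    dT <- deltaT(tr$value)
  } else if (is.numeric(deltaT)) {
    dT <- rowSums(outer(tr$value, seq_along(deltaT) - 1, `^`) *
                    rep(deltaT, each = nrow(tr)))
  } else {
    abort("`deltaT` must be NULL, a function, or polynomial coefficients.")
  }
  if (!is.null(fit_range) &&
      any(tr$value < min(fit_range) | tr$value > max(fit_range))) {
    warn("Torque values outside the deltaT fit range: extrapolating.")
  }
  tibble::tibble(time = tr$time, force = (tr$value - dT) / L)
}

#' Subject-specific ankle muscle parameters
#'
#' Musculotendon parameters of the six main ankle muscles of one adult
#' subject with the ankle at 30 degrees plantarflexion: moment arm `L` (mm),
#' maximum isometric force `F0M` (N), musculotendon length `lMT` (mm),
#' optimal fibre length `l0M` (mm), tendon slack length `lsT` (mm) and the
#' rigid-tendon normalized muscle length `l_bar`. The tibialis anterior row
#' (`TA`) parameterises the default whole-muscle simulations
#' (`F0M = 1046` N, `l_bar = 1.16`).
#'
#' @return Tibble with one row per muscle.
#' @examples
#' p <- ankle_muscle_params()
#' with(p[p$muscle == "TA", ], normalized_length(lMT, lsT, l0M))
#' @export
ankle_muscle_params <- function() {
  tibble::tribble(
    ~muscle, ~L,   ~F0M, ~lMT, ~l0M, ~lsT, ~l_bar,
    "TA",    25.5, 1046, 319,  68.2, 240,  1.16,
    "EDL",   26.1,  403, 525,  80.5, 462,  0.78,
    "EHL",   25.9,  176, 487,  87.6, 382,  1.20,
    "SOL",   51.1, 3822, 373,  54.1, 340,  0.60,
    "GM",    51.8, 2232, 447,  52.6, 411,  0.68,
    "GL",    52.2, 1058, 448,  62.4, 398,  0.80)
}
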