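# Shared fixtures: everything is generated in code at test time.

ta_spec <- mu_pool_spec()  # default tibialis anterior pool

# A coarse trapezoidal torque trace (time in s, value in the trace's unit).
trapezoid_trace <- function(peak = 30, ramp_s = 6, plateau_s = 10,
                            lead_s = 1, fs = 200) {
  dur <- 2 * lead_s + 2 * ramp_s + plateau_s
  tt <- seq(0, dur, by = 1 / fs)
  v <- pmax(0, pmin((tt - lead_s) / ramp_s, 1,
                    (dur - lead_s - tt) / ramp_s)) * peak
  tibble::tibble(time = tt, value = v)
}

# Independent analytic solution of the driven fibre-AP equation for a
# single half-sine AP starting at t = 0: u(t) = a1 * (h * e)(t) with the
# two-exponential impulse response h. Quadrature, not RK4, so it is an
# independent oracle for the solver path.
fibre_ap_analytic <- function(t, exc = excitation_params()) {
  r1 <- (-exc$a3 + sqrt(exc$a3^2 - 4 * exc$a2)) / 2
  r2 <- (-exc$a3 - sqrt(exc$a3^2 - 4 * exc$a2)) / 2
  h <- function(tau) (exp(r1 * tau) - exp(r2 * tau)) / (r1 - r2)
  e0 <- function(s) ifelse(s >= 0 & s <= exc$Tap / 2,
                           exc$Ve * sin(2 * pi / exc$Tap * s), 0)
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    exc$a1 * stats::integrate(function(s) h(ti - s) * e0(s), 0, ti,
                              rel.tol = 1e-10, subdivisions = 2000L)$value
  }, numeric(1))
}
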