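test_that("length scalings follow the piecewise-linear branches", {
  expect_equal(f1_scaling(c(0.6, 1.0)), c(0.8, 0.8))
  expect_equal(f1_scaling(1.15), 0.8 + 1.33 * 0.15)  # 0.9995, ~continuous
  expect_equal(f1_scaling(1.30), 1.0)
  expect_equal(f1_scaling(1.5), 1.0 - 0.6 * 0.2)
  expect_equal(f2_scaling(c(1.0, 1.15)), c(1, 1))
  expect_equal(f2_scaling(1.16), 0.996)
  # continuity at the breakpoints within 1e-3
  for (bp in c(1.0, 1.15, 1.30)) {
    expect_lt(abs(f1_scaling(bp - 1e-9) - f1_scaling(bp + 1e-9)), 1e-3)
    expect_lt(abs(f2_scaling(bp - 1e-9) - f2_scaling(bp + 1e-9)), 1e-3)
  }
  # injectable hooks
  sc <- length_scalings(1.2, f3 = function(l) l^2)
  expect_equal(sc$f3, 1.44)
  expect_equal(sc$f4, 1)
})

test_that("calcium stage is linear and time invariant in the fibre potential", {
  e <- mn_ap_train(0.005, fs = 20480, duration = 0.1)
  u <- fibre_ap_ode(e)
  c1t <- calcium_ode(u, activation_params("fast"))
  expect_true(all(calcium_ode(dplyr::mutate(u, u = 0),
                              activation_params("fast"))$c == 0))
  c2t <- calcium_ode(dplyr::mutate(u, u = 2 * u), activation_params("fast"))
  expect_equal(c2t$c, 2 * c1t$c, tolerance = 1e-12)
  # superposition of shifted inputs
  shift <- round(0.03 * 20480)
  u_two <- u
  u_two$u <- u$u + c(rep(0, shift), u$u[seq_len(nrow(u) - shift)])
  c_two <- calcium_ode(u_two, activation_params("fast"))
  c_shifted <- c(rep(0, shift), c1t$c[seq_len(nrow(u) - shift)])
  expect_equal(c_two$c, c1t$c + c_shifted, tolerance = 1e-6 * max(c1t$c))
})

test_that("calcium-troponin binding saturates below total troponin", {
  act <- activation_params("slow")
  tt <- seq(0, 0.5, by = 1 / 2048)
  # constant calcium: equilibrium P* = P0 * k c^2 / (k c^2 + c2)
  cval <- 2e-6
  ctr <- tibble::tibble(time = tt, c = cval)
  P <- catn_ode(ctr, act)
  Pstar <- act$P0 * act$c1 * cval^2 / (act$c1 * cval^2 + act$c2)
  expect_equal(P$P[length(tt)], Pstar, tolerance = 1e-3)
  expect_true(all(P$P <= act$P0 + 1e-15))
  expect_true(all(P$P >= 0))
  # zero calcium keeps P at zero
  expect_true(all(catn_ode(tibble::tibble(time = tt, c = 0), act)$P == 0))
  # f4 rescales the saturation bound
  sc <- length_scalings(1, f4 = 0.5)
  P2 <- catn_ode(tibble::tibble(time = tt, c = 1e-4), act, scalings = sc)
  expect_true(all(P2$P <= 0.5 * act$P0 + 1e-15))
  expect_equal(max(P2$P), 0.5 * act$P0, tolerance = 1e-3)
})

test_that("active state relaxes with time constant d2 and tracks d1*P", {
  act <- activation_params("slow")
  tt <- seq(0, 0.2, by = 1 / 4096)
  # P = 0, a0 = 0.5: pure exponential decay exp(-t/d2)
  a <- active_state_ode(tibble::tibble(time = tt, P = 0), act, a0 = 0.5)
  expect_equal(a$a, 0.5 * exp(-tt / 0.024), tolerance = 1e-6)
  # constant P below saturation: equilibrium d1*P
  Pc <- 4e-6
  a2 <- active_state_ode(tibble::tibble(time = seq(0, 1, 1 / 4096), P = Pc), act)
  expect_equal(a2$a[length(a2$a)], min(act$d1 * Pc, 1), tolerance = 1e-4)
  # large P: clamped at 1, clamp recorded
  a3 <- active_state_ode(tibble::tibble(time = tt, P = 5e-5), act)
  expect_true(all(a3$a <= 1 & a3$a >= 0))
  expect_gt(attr(a3, "n_clamped"), 0)
})

test_that("the chained simulation reproduces the stage-by-stage path", {
  sp <- c(0.01, 0.05)
  tr <- simulate_ne(sp, "slow", duration = 0.4, fs = 8192, dt_solver = 2e-6)
  act <- activation_params("slow")
  e <- mn_ap_train(sp, fs = 8192, duration = 0.4)
  u <- fibre_ap_ode(e, dt_solver = 2e-6)
  cc <- calcium_ode(u, act, dt_solver = 2e-6)
  P <- catn_ode(cc, act, dt_solver = 2e-6)
  a <- active_state_ode(P, act, dt_solver = 2e-6)
  # per-stage path interpolates its sampled input, so allow a small bound
  expect_equal(tr$u, u$u, tolerance = 5e-3)
  expect_equal(max(tr$a), max(a$a), tolerance = 5e-2)
  # empty input leaves every state at rest
  tr0 <- simulate_ne(numeric(0), "slow", duration = 0.2)
  expect_true(all(as.matrix(tr0[, c("e", "u", "c", "P", "a")]) == 0))
})

test_that("activation invariants hold along a stimulation train", {
  sp <- seq(0.01, 1.5, by = 1 / 30)
  tr <- simulate_ne(sp, "slow", duration = 1.6)
  act <- activation_params("slow")
  expect_true(all(tr$a >= 0 & tr$a <= 1))
  expect_true(all(tr$P >= -1e-18 & tr$P <= act$P0 + 1e-18))
  expect_true(all(tr$c > -1e-12))
})

test_that("activation twitches fuse and the frequency curve is monotone", {
  afc <- suppressWarnings(
    activation_frequency_curve("slow", freqs = c(3, 8, 15, 30, 50),
                               duration = 2.5))
  expect_true(all(diff(afc$a_ss) >= -1e-9))       # non-decreasing with rate
  expect_true(all(diff(afc$ripple) <= 0))         # progressive fusion
  expect_lt(afc$ripple[length(afc$ripple)], afc$ripple[1])
  expect_equal(afc$a_ss[afc$freq == 50], 1.0, tolerance = 1e-6)
})
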