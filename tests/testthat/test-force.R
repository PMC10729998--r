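test_that("MU force scales activation by maximum force and force-length", {
  tt <- seq(0, 1, by = 1 / 2048)
  a1 <- tibble::tibble(time = tt, a = 1)
  expect_equal(mu_force(a1, f0_bar = 0.01, l_bar = 1)$f, rep(0.01, length(tt)))
  expect_equal(mu_force(a1, f0_bar = 0.01, l_bar = 1.16)$f[1],
               0.01 * exp(-(0.16 / 0.45)^2))  # 0.00881
  a0 <- tibble::tibble(time = tt, a = 0)
  expect_true(all(mu_force(a0, 0.01)$f == 0))
  expect_error(mu_force(a1, f0_bar = 0), "> 0")
})

test_that("dispersion filter is a DC- and integral-preserving boxcar", {
  tt <- seq(0, 1, by = 1 / 2048)
  # zero window: identity
  x <- tibble::tibble(time = tt, f = sin(2 * pi * tt))
  expect_equal(dispersion_filter(x, 0)$f, x$f)
  # constant input unchanged
  cst <- tibble::tibble(time = tt, f = 0.5)
  expect_equal(dispersion_filter(cst, 0.004)$f, rep(0.5, length(tt)),
               tolerance = 1e-12)
  # unit impulse -> rectangular pulse of ~4 ms, area preserved to 1e-9
  imp <- tibble::tibble(time = tt, f = c(rep(0, 1024), 1, rep(0, length(tt) - 1025)))
  y <- dispersion_filter(imp, 0.004)
  expect_equal(sum(y$f), sum(imp$f), tolerance = 1e-9)
  expect_identical(sum(y$f > 0), 9L)  # 2*floor(0.004*2048/2) + 1 samples
  expect_equal(max(y$f), 1 / 9, tolerance = 1e-12)
  # integral preservation on an arbitrary compactly supported trace
  z <- tibble::tibble(time = tt, f = pmax(0, sin(8 * pi * tt)) * (tt > 0.2 & tt < 0.8))
  expect_equal(sum(dispersion_filter(z, 0.01)$f), sum(z$f), tolerance = 1e-9)
  expect_error(dispersion_filter(x, 2), "exceeds")
})

test_that("Monte-Carlo dispersion converges to the boxcar and is seeded", {
  tt <- seq(0, 0.5, by = 1 / 2048)
  x <- tibble::tibble(time = tt, f = exp(-((tt - 0.25) / 0.01)^2))
  m1 <- dispersion_filter(x, 0.004, mode = "montecarlo", ir = 5000, seed = 7)
  m2 <- dispersion_filter(x, 0.004, mode = "montecarlo", ir = 5000, seed = 7)
  expect_identical(m1$f, m2$f)  # reproducible under a fixed seed
  b <- dispersion_filter(x, 0.004)
  expect_equal(m1$f, b$f, tolerance = 0.05)  # many-fibre limit
})

test_that("plateau rule zeroes only low-rate MUs recruited in the plateau", {
  # MU 1: recruited during the ramp (t=1), slow rate -> untouched
  # MU 2: recruited mid-plateau at 5 Hz -> zeroed
  # MU 3: recruited mid-plateau above the rate threshold -> untouched
  sts <- spike_train_set(list(seq(1, 20, by = 0.3),
                              seq(8, 14, by = 0.2)[seq(1, 30, by = 4)],
                              seq(8, 14, by = 0.08)),
                         duration = 20)
  tt <- seq(0, 20, by = 0.1)
  forces <- purrr::map_dfr(1:3, function(k)
    tibble::tibble(time = tt, mu = k, f = 1))
  out <- plateau_rate_rule(sts, forces, plateau = c(6, 16), min_rate_hz = 7)
  expect_identical(attr(out, "zeroed"), 2L)
  expect_true(all(out$f[out$mu == 2] == 0))
  expect_true(all(out$f[out$mu != 2] == 1))
  # threshold 0 is the identity
  out0 <- plateau_rate_rule(sts, forces, plateau = c(6, 16), min_rate_hz = 0)
  expect_identical(length(attr(out0, "zeroed")), 0L)
  expect_error(plateau_rate_rule(sts, forces, plateau = c(6, 6)), "interval")
})

test_that("whole-muscle force is the exact sum of per-MU forces", {
  sp <- spike_train_set(list(seq(0.2, 1.5, by = 1 / 10),
                             seq(0.4, 1.5, by = 1 / 14)),
                        duration = 2)
  sim <- simulate_muscle(sp, f0_bar = c(0.01, 0.02), mu_type = "slow",
                         l_bar = 1, F0M = 1000)
  total <- sim$mu_forces |>
    dplyr::group_by(time) |>
    dplyr::summarise(f = sum(f))
  expect_equal(sim$muscle$F_M_bar, total$f, tolerance = 1e-12)
  expect_equal(sim$muscle$F_M, 1000 * sim$muscle$F_M_bar)
  expect_true(all(sim$muscle$F_M >= 0))
  # additivity: subsets simulated separately sum to the full simulation
  s1 <- simulate_muscle(spike_train_set(sp$times[1], duration = 2),
                        f0_bar = 0.01, mu_type = "slow", l_bar = 1, F0M = 1000)
  s2 <- simulate_muscle(spike_train_set(sp$times[2], duration = 2),
                        f0_bar = 0.02, mu_type = "slow", l_bar = 1, F0M = 1000)
  expect_equal(sim$muscle$F_M, s1$muscle$F_M + s2$muscle$F_M,
               tolerance = 1e-9)
  # no spikes anywhere -> zero force
  s0 <- simulate_muscle(spike_train_set(list(numeric(0)), duration = 0.5),
                        f0_bar = 0.01)
  expect_true(all(s0$muscle$F_M == 0))
})

test_that("adding discharges never decreases the peak MU force", {
  base <- seq(0.2, 1.2, by = 1 / 8)
  peak_for <- function(times) {
    sim <- simulate_muscle(spike_train_set(list(times), duration = 1.8),
                           f0_bar = 0.01, mu_type = "slow", l_bar = 1)
    max(sim$muscle$F_M_bar)
  }
  p0 <- peak_for(base)
  for (extra in c(0.25, 0.7, 1.3)) {
    expect_gte(peak_for(sort(c(base, extra))), p0 - 1e-12)
  }
})

test_that("tidiers summarise a muscle simulation", {
  sp <- spike_train_set(list(seq(0.2, 0.8, by = 0.1)), duration = 1)
  sim <- simulate_muscle(sp, f0_bar = 0.01)
  expect_identical(tidy(sim), sim$muscle)
  g <- glance(sim)
  expect_identical(nrow(g), 1L)
  expect_equal(g$peak_F_M, max(sim$muscle$F_M))
})
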