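test_that("threshold distribution matches its closed form and end point", {
  expect_equal(threshold_distribution(ta_spec, 400), 0.50 * (58.12 + 120))
  # spot values against a direct evaluation of the linear-exponential form
  j <- c(1, 57, 200, 399)
  expect_equal(threshold_distribution(ta_spec, j),
               0.50 * (58.12 * j / 400 + 120^((j / 400)^1.83)))
  expect_error(threshold_distribution(ta_spec, 0), "out of range")
  expect_error(threshold_distribution(ta_spec, 401), "out of range")
})

test_that("all four pool distributions are strictly increasing in MU index", {
  pool <- mu_pool(ta_spec)
  for (col in c("T_th", "f_tw_bar", "f0_bar", "IR")) {
    expect_true(all(diff(pool[[col]]) > 0), label = paste(col, "increasing"))
  }
})

test_that("twitch distribution has the documented fold range and endpoints", {
  f1 <- twitch_distribution(ta_spec, 1)
  f400 <- twitch_distribution(ta_spec, 400)
  expect_equal(f400, 6.07 * (4.52 + 11.96), tolerance = 1e-12)
  expect_equal(f400 / f1, 16.3, tolerance = 0.005)
  # (j/N) -> 0 forces the exponential term to 1: f(1) ~ 6.07 * (0.0113 + 1)
  expect_equal(f1, 6.14, tolerance = 1e-3)
})

test_that("normalized tetanic forces sum to ~1 and span an 11-fold range", {
  f0 <- max_force_distribution(ta_spec)
  expect_gt(sum(f0$f0_bar), 0.97)
  expect_lt(sum(f0$f0_bar), 1.03)
  expect_equal(f0$f0_bar[400] / f0$f0_bar[1], 11, tolerance = 0.02)
  expect_error(max_force_distribution(ta_spec, F0M = -1), "F0M")
})

test_that("innervation ratios split fibres proportionally to twitch force", {
  ir <- innervation_ratios(ta_spec)
  expect_equal(sum(ir), 200000)
  # tiny proportional-split case: twitches (1, 3) over 4 fibres -> IR (1, 3)
  tiny <- mu_pool_spec(N = 2, n_fibres = 4)
  ftw <- twitch_distribution(tiny)
  expect_equal(ftw / sum(ftw) * 4, innervation_ratios(tiny))
  # integer export preserves the total exactly
  iri <- round_innervation_ratios(ir)
  expect_identical(sum(iri), 200000L)
  expect_true(all(abs(iri - ir) < 1))
})

test_that("slow/fast partition follows the cumulative innervation boundary", {
  ir <- innervation_ratios(ta_spec)
  ty <- assign_fibre_types(ir, 0.72)
  m <- sum(ty == "slow")
  expect_identical(m, which(cumsum(ir) >= 0.72 * 200000)[1])
  expect_true(all(ty[seq_len(m)] == "slow"))
  expect_true(all(ty[-seq_len(m)] == "fast"))
  expect_true(all(assign_fibre_types(ir, 1 - 1e-12) == "slow"))
  expect_identical(sum(assign_fibre_types(ir, 1e-12) == "slow"), 1L)
})

test_that("recruitment thresholds are measured as windowed torque means", {
  # two MUs discharging on a unit-slope ramp at t = 1 and t = 2 s
  ramp <- tibble::tibble(time = seq(0, 5, by = 1e-3), value = seq(0, 5, by = 1e-3))
  sts <- spike_train_set(list(c(2, 2.5, 3), c(1, 1.4, 1.8)), duration = 5)
  th <- measure_recruitment_thresholds(sts, ramp)
  # symmetric window mean, up to half-sample discretization
  expect_equal(th$threshold, c(1, 2), tolerance = 1e-3)
  expect_identical(th$mu, c(2L, 1L))                     # ranked ascending
  # constant torque: every MU reads the constant
  flat <- tibble::tibble(time = seq(0, 5, by = 1e-3), value = 7)
  expect_equal(measure_recruitment_thresholds(sts, flat)$threshold, c(7, 7))
  # MU without discharges is excluded with a warning
  sts2 <- spike_train_set(list(c(2, 3), numeric(0)), duration = 5)
  expect_warning(th2 <- measure_recruitment_thresholds(sts2, ramp),
                 "without discharges")
  expect_identical(nrow(th2), 1L)
  # window beyond the trace start is truncated with a warning
  sts3 <- spike_train_set(list(c(0.002, 0.4)), duration = 5)
  expect_warning(measure_recruitment_thresholds(sts3, ramp), "truncated")
})

test_that("map_to_pool inverts the threshold distribution on integer indices", {
  j <- c(1, 3, 50, 123, 399, 400)
  th <- threshold_distribution(ta_spec, j)
  expect_identical(map_to_pool(th, ta_spec), as.integer(j))
  # sorted inputs give sorted indices
  th_r <- sort(c(2.3, 4.1, 8.8, 15.2, 22.9, 31.7, 44.4, 58.6, 71.3, 84.9))
  expect_false(is.unsorted(map_to_pool(th_r, ta_spec)))
  expect_error(map_to_pool(-1, ta_spec), "positive")
  expect_warning(out <- map_to_pool(95, ta_spec), "clamped")
  expect_identical(out, 400L)
})

test_that("representative-force windows tile the recruited pool", {
  # printed worked example: middle MU of (90, 120, 180) covers [106, 150]
  rf <- representative_forces(ta_spec, n_active = 300,
                              indices = c(90, 120, 180), F0M = 1046)
  expect_identical(rf$lo[2], 106L)
  expect_identical(rf$hi[2], 150L)
  expect_identical(rf$n_represented[2], 45L)
  # blind method, 30 of 300: the 10th MU sits at index 100, window [96, 105]
  rb <- representative_forces(ta_spec, n_active = 300, n_identified = 30,
                              method = "blind")
  expect_identical(rb$N_i[10], 100L)
  expect_identical(c(rb$lo[10], rb$hi[10]), c(96L, 105L))
  expect_identical(rb$n_represented[10], 10L)
  # windows partition [1, N_a]: contiguous, disjoint, covering
  for (rfx in list(rf, rb)) {
    expect_identical(rfx$lo[1], 1L)
    expect_identical(rfx$hi[nrow(rfx)], 300L)
    expect_identical(rfx$lo[-1], rfx$hi[-nrow(rfx)] + 1L)
    expect_identical(sum(rfx$n_represented), 300L)
    # force conservation across the partition
    f0 <- max_force_distribution(ta_spec)
    expect_equal(sum(rfx$f0_rep_bar), sum(f0$f0_bar[1:300]), tolerance = 1e-12)
  }
  # identity mapping: every MU represents itself
  ri <- representative_forces(ta_spec, n_active = 5, indices = 1:5)
  expect_identical(ri$n_represented, rep(1L, 5))
  expect_equal(ri$f0_rep_bar, max_force_distribution(ta_spec)$f0_bar[1:5])
  expect_error(representative_forces(ta_spec, n_active = 10,
                                     indices = c(5, 3)), "increasing")
  expect_error(representative_forces(ta_spec, n_active = 5,
                                     n_identified = 10, method = "blind"),
               "More identified")
})

test_that("pool tables round-trip through TSV and JSON", {
  pool <- mu_pool(ta_spec, F0M = 1046)
  tsv <- tempfile(fileext = ".tsv")
  write_mu_pool(pool, tsv)
  back <- read_mu_pool(tsv)
  expect_equal(back$T_th, pool$T_th, tolerance = 1e-9)
  expect_identical(sum(back$IR), 200000L)
  js <- tempfile(fileext = ".json")
  write_mu_pool(pool, js)
  backj <- read_mu_pool(js)
  expect_equal(backj$f0_bar, pool$f0_bar, tolerance = 1e-12)
})
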