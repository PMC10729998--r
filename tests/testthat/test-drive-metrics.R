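test_that("neural drive self-normalizes over the plateau", {
  sts <- spike_train_set(list(seq(1, 19, by = 0.1)), fs = 512, duration = 20)
  d <- neural_drive(sts, plateau = c(5, 15))
  sel <- d$time >= 5 & d$time <= 15
  expect_equal(mean(d$drive[sel]), 1, tolerance = 1e-9)
  # near-zero before the first discharge (zero-phase filtering leaks a little)
  expect_lt(max(abs(d$drive[d$time < 0.5])), 0.05)
  expect_error(neural_drive(spike_train_set(list(numeric(0)), duration = 1)),
               "Empty spike set")
  expect_warning(neural_drive(sts), "maximum")
})

test_that("neural drive is invariant to MU ordering and spike splitting", {
  t1 <- seq(1, 19, by = 0.13)
  t2 <- seq(1.05, 19, by = 0.21)
  a <- neural_drive(spike_train_set(list(t1, t2), fs = 512, duration = 20),
                    plateau = c(5, 15))
  b <- neural_drive(spike_train_set(list(t2, t1), fs = 512, duration = 20),
                    plateau = c(5, 15))
  expect_equal(a$drive, b$drive)
  # splitting one MU's discharges across two rows changes nothing
  odd <- t1[c(TRUE, FALSE)]; even <- t1[c(FALSE, TRUE)]
  c_ <- neural_drive(spike_train_set(list(odd, even, t2), fs = 512,
                                     duration = 20), plateau = c(5, 15))
  expect_equal(a$drive, c_$drive)
  # duplicating every MU rescales the raw sum but not the normalized drive
  d_ <- neural_drive(spike_train_set(list(t1, t2, t1, t2), fs = 512,
                                     duration = 20), plateau = c(5, 15))
  expect_equal(a$drive, d_$drive, tolerance = 1e-12)
})

test_that("onset error measures threshold-crossing delays", {
  tt <- seq(0, 10, by = 0.01)
  ramp <- tibble::tibble(time = tt, value = pmin(tt, 10 - tt, 3) / 3 * 100)
  same <- onset_error(ramp, ramp)
  expect_equal(same$delta1, 0)
  expect_equal(same$delta1F, 0.02 * 100, tolerance = 1)
  # pure delay of 0.5 s
  delayed <- tibble::tibble(time = tt,
                            value = approx(tt + 0.5, ramp$value, tt,
                                           yleft = 0, rule = 2)$y)
  expect_equal(onset_error(delayed, ramp)$delta1, 0.5, tolerance = 0.02)
  # antisymmetry of the onset delay
  expect_equal(onset_error(ramp, delayed)$delta1,
               -onset_error(delayed, ramp)$delta1)
  expect_error(onset_error(tibble::tibble(time = tt, value = 0), ramp),
               "never crosses|undefined")
})

test_that("trace metrics satisfy their identities", {
  tt <- seq(0, 10, by = 0.01)
  ref <- tibble::tibble(time = tt, value = pmin(tt / 3, 1, (10 - tt) / 3) * 10)
  self <- trace_metrics(ref, ref)
  expect_equal(self$nRMSE, 0)
  expect_equal(self$r2, 1)
  expect_equal(self$ME, 0)
  # constant offset of 1 on a range-10 reference: ME = 1, nRMSE = 10%
  off <- dplyr::mutate(ref, value = value + 1)
  m <- trace_metrics(off, ref)
  expect_equal(m$ME, 1)
  expect_equal(m$nRMSE, 10)
  # predicting the mean gives r2 = 0
  flat <- dplyr::mutate(ref, value = mean(ref$value))
  expect_equal(suppressWarnings(trace_metrics(flat, ref)$r2), 0,
               tolerance = 1e-12)
  # constant reference: r2 undefined with a warning
  cref <- dplyr::mutate(ref, value = 5)
  expect_warning(mc <- trace_metrics(dplyr::mutate(cref, value = 5 + 0.1 * sin(tt)),
                                     cref), "undefined")
  expect_true(is.nan(mc$r2))
  # ME is symmetric in the two traces
  expect_equal(trace_metrics(off, ref)$ME, trace_metrics(ref, off)$ME)
})

test_that("segment detection and segment-wise nRMSE work on a trapezoid", {
  tt <- seq(0, 20, by = 0.01)
  ref <- tibble::tibble(time = tt, value = pmin((tt - 1) / 5, 1, (19 - tt) / 5))
  ref$value <- pmax(ref$value, 0) * 100
  seg <- detect_segments(ref)
  expect_equal(seg$plateau[1], 6, tolerance = 0.3)
  expect_equal(seg$plateau[2], 14, tolerance = 0.3)
  expect_equal(seg$r1[1], 1, tolerance = 0.3)
  expect_equal(seg$r2[2], 19, tolerance = 0.3)
  pred <- dplyr::mutate(ref, value = value * 1.05)
  m <- trace_metrics(pred, ref, segments = "auto")
  expect_false(any(is.na(c(m$nRMSE_r1, m$nRMSE_p, m$nRMSE_r2))))
  # plateau errors dominate for a multiplicative bias
  expect_gt(m$nRMSE_p, m$nRMSE_r1)
})

test_that("validation reports tidy into tables", {
  tt <- seq(0, 10, by = 0.01)
  ref <- tibble::tibble(time = tt, value = pmin(tt, 10 - tt, 3) / 3)
  m <- trace_metrics(dplyr::mutate(ref, value = value * 1.02), ref)
  td <- tidy(m)
  expect_identical(td$metric[td$metric == "r2"], "r2")
  expect_identical(nrow(glance(m)), 1L)
  expect_equal(glance(m)$r2, m$r2)
})
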