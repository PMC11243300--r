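test_that("waveform calibration honours mean, peak and trough targets", {
  w <- build_waveform()
  tt <- seq(0, w$period, length.out = 20001)
  q <- sacflow:::cycle_flow(w, tt)
  expect_lt(abs(mean(q[-length(q)]) - 4) / 4, 1e-3)
  expect_lt(abs(reynolds_number(max(q)) - 520), 1)
  expect_lt(abs(reynolds_number(min(q)) - 220), 1)
  expect_true(w$single_peak)
  # systolic peak at 15% of the cycle
  expect_lt(abs(tt[which.max(q)] / w$period - 0.15), 0.01)
})

test_that("constant flow at the mean maps to tube Reynolds 318.3", {
  expect_equal(reynolds_number(4), 4 * 1000 * 4e-6 / (0.004 * pi * 0.004),
               tolerance = 1e-12)
  expect_equal(reynolds_number(4), 318.3099, tolerance = 1e-4)
})

test_that("ramp is linear, continuous, and the waveform is periodic after it", {
  w <- build_waveform()
  expect_equal(evaluate_flowrate(w, 0), 0)
  expect_equal(evaluate_flowrate(w, 0.1),
               0.5 * sacflow:::cycle_flow(w, 0.1), tolerance = 1e-12)
  expect_equal(evaluate_flowrate(w, 0.2 - 1e-10),
               evaluate_flowrate(w, 0.2 + 1e-10), tolerance = 1e-6)
  expect_equal(evaluate_flowrate(w, 0.9), evaluate_flowrate(w, 1.7))
  ts <- seq(1, 1.8, length.out = 20001)
  expect_lt(abs(mean(evaluate_flowrate(w, ts)[-1]) - 4) / 4, 1e-3)
})

test_that("infeasible calibration targets raise a calibration error", {
  expect_error(build_waveform(peak_flow_mlps = 3.9),
               class = "sacflow_calibration_error")
  expect_error(build_waveform(min_flow_mlps = -1),
               class = "sacflow_calibration_error")
})

test_that("waveform CSV export is a two-column 1 ms sampling", {
  w <- build_waveform()
  f <- tempfile(fileext = ".csv")
  df <- write_waveform_csv(w, f, t_end = 0.5)
  on.exit(unlink(f))
  got <- read.csv(f)
  expect_identical(names(got), c("t", "Q"))
  expect_equal(diff(got$t)[1], 1e-3)
  expect_equal(got$Q, df$Q)
})

test_that("the standard Womersley number for the study vessel is about 2.8", {
  expect_equal(womersley_number(), 2.8025, tolerance = 1e-3)
})
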