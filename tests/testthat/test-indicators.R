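test_that("constant shear gives OSI 0 and TAWSS equal to its magnitude", {
  tt <- seq(1, 1.8, length.out = 51)
  tau <- lapply(tt, function(t) cbind(rep(1.7, 5), rep(-0.6, 5)))
  r <- compute_tawss_osi(list(times = tt, tau = tau))
  expect_equal(r$osi, rep(0, 5), tolerance = 1e-12)
  expect_equal(r$tawss, rep(sqrt(1.7^2 + 0.6^2), 5), tolerance = 1e-12)
})

test_that("zero-mean sinusoidal shear gives OSI 0.5 and TAWSS 2A/pi", {
  A <- 2.3
  tt <- seq(1, 1.8, length.out = 4001)
  tau <- lapply(tt, function(t)
    cbind(A * sin(2 * pi * (t - 1) / 0.8), 0))
  r <- compute_tawss_osi(list(times = tt, tau = tau))
  expect_equal(r$osi[1], 0.5, tolerance = 1e-6)
  expect_equal(r$tawss[1], 2 * A / pi, tolerance = 1e-4)
})

test_that("OSI stays within [0, 0.5] for arbitrary series and is 0 at zero shear", {
  set.seed(2)
  tt <- seq(1, 1.8, length.out = 41)
  tau <- lapply(tt, function(t) cbind(rnorm(20), rnorm(20)))
  tau <- lapply(tau, function(m) { m[7, ] <- 0; m })
  r <- compute_tawss_osi(list(times = tt, tau = tau))
  expect_true(all(r$osi >= 0 & r$osi <= 0.5))
  # the all-zero node uses the limit convention
  tau0 <- lapply(tt, function(t) cbind(c(0, 1), c(0, 0)))
  r0 <- compute_tawss_osi(list(times = tt, tau = tau0))
  expect_equal(r0$osi[1], 0)
})

test_that("doubling the sample density changes OSI by less than 1e-3", {
  set.seed(4)
  f <- function(t) cbind(sin(2 * pi * t / 0.8) + 0.3, cos(4 * pi * t / 0.8))
  t1 <- seq(1, 1.8, length.out = 101)
  t2 <- seq(1, 1.8, length.out = 201)
  r1 <- compute_tawss_osi(list(times = t1, tau = lapply(t1, f)))
  r2 <- compute_tawss_osi(list(times = t2, tau = lapply(t2, f)))
  expect_lt(max(abs(r1$osi - r2$osi)), 1e-3)
})

test_that("sac_reduce computes weighted means over masks", {
  expect_equal(sac_reduce(c(0, 4), c(1, 3), c(TRUE, TRUE))$mean, 3)
  expect_equal(sac_reduce(rep(2.5, 7), runif(7) + 0.1, rep(TRUE, 7))$mean, 2.5)
  expect_error(sac_reduce(1:3, 1:3, rep(FALSE, 3)), class = "sacflow_mask_error")
})

test_that("relative change: percentages, zero case, and undefined flags", {
  expect_equal(unclass(relative_change(c(A = 10), c(A = 12)))[["A"]], 20)
  expect_equal(unclass(relative_change(c(A = 7), c(A = 7)))[["A"]], 0)
  expect_equal(unclass(relative_change(c(A = 0.05), c(A = 0.387)))[["A"]],
               674, tolerance = 1e-12)
  r <- relative_change(c(A = 0, B = 1), c(A = 2, B = 2))
  expect_true(is.na(unclass(r)[["A"]]))
  expect_identical(attr(r, "undefined"), "A")
})

test_that("sac mask shrinks monotonically with the cut height", {
  case <- make_case_2d(m_neck = 8, n_phi = 16, n_side = 8)
  m79 <- sac_mask(case, 7.9); m80 <- sac_mask(case, 8.0); m81 <- sac_mask(case, 8.1)
  expect_true(all(m81$wall_sac <= m80$wall_sac))
  expect_true(all(m80$wall_sac <= m79$wall_sac))
  expect_true(length(m81$sac_tris) <= length(m80$sac_tris))
  expect_true(length(m80$sac_tris) <= length(m79$sac_tris))
  expect_gt(sum(m81$wall_sac), 0)
})
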