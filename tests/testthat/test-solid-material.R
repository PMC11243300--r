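test_that("strain energy closed forms: identity, dilation, simple shear", {
  props <- solid_properties()
  expect_equal(props$mu_s, 258620.6897, tolerance = 1e-9)
  expect_equal(props$kappa, 2.5e6, tolerance = 1e-12)
  expect_equal(strain_energy(diag(3)), 0)
  lam <- 1.1
  expect_equal(strain_energy(diag(3) * lam),
               0.25 * props$kappa * (lam^6 - 1) - 1.5 * props$kappa * log(lam),
               tolerance = 1e-12)
  g <- 0.3
  Fs <- diag(3); Fs[1, 2] <- g
  expect_equal(strain_energy(Fs), 0.5 * props$mu_s * g^2, tolerance = 1e-12)
})

test_that("stress split: dilation gives zero deviator and p = kappa(J-1/J)/2", {
  props <- solid_properties()
  s0 <- cauchy_stress(diag(3))
  expect_equal(max(abs(s0$sigma)), 0)
  lam <- 1.05
  s <- cauchy_stress(diag(3) * lam)
  expect_equal(max(abs(s$dev)), 0)
  expect_equal(s$p_s, 0.5 * props$kappa * (lam^3 - lam^-3), tolerance = 1e-12)
})

test_that("deviator is trace free and p_s has the sign of J - 1", {
  set.seed(7)
  for (k in 1:20) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    if (det(F) <= 0.5) next
    s <- cauchy_stress(F)
    expect_lt(abs(sum(diag(s$dev))) / max(abs(s$dev), 1), 1e-12)
    expect_equal(sign(s$p_s), sign(det(F) - 1))
  }
})

test_that("stress is the consistent derivative of the energy (100 random F)", {
  set.seed(11)
  worst <- 0
  tried <- 0
  while (tried < 100) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    J <- det(F)
    if (J < 0.8 || J > 1.2) next
    tried <- tried + 1
    P <- piola_stress(F)
    eps <- 1e-6
    Pfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + eps
      Fm <- F; Fm[i, j] <- Fm[i, j] - eps
      Pfd[i, j] <- (strain_energy(Fp) - strain_energy(Fm)) / (2 * eps)
    }
    worst <- max(worst, max(abs(P - Pfd)) / max(abs(P)))
  }
  expect_lt(worst, 1e-6)
})

test_that("energy is objective under superposed rotations", {
  set.seed(3)
  for (k in 1:10) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    Q <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_lt(abs(strain_energy(Q %*% F) - strain_energy(F)) /
                max(strain_energy(F), 1), 1e-12)
  }
})

test_that("inverted deformation states are rejected", {
  F <- diag(3); F[1, 1] <- -1
  expect_error(strain_energy(F), class = "sacflow_inversion_error")
  expect_error(cauchy_stress(F), class = "sacflow_inversion_error")
})

test_that("regional stiffness follows the y > 8 mm sac plane rule", {
  m <- mesh_rectangle(2, 4, 2, 8)          # y in [0,4]
  m$nodes[, 2] <- m$nodes[, 2] + 6         # shift to y in [6,10]
  f <- assign_regions(m, plane_height_mm = 8)
  cy <- colMeans(matrix(m$nodes[as.vector(t(m$tri)), 2], nrow = 3))
  expect_true(all(f[cy > 8] == 1))
  expect_true(all(f[cy <= 8] == 10))
  # shifting the plane reclassifies only the centroids in between
  f2 <- assign_regions(m, plane_height_mm = 8.1)
  changed <- which(f != f2)
  expect_true(all(cy[changed] > 8 & cy[changed] <= 8.1))
})
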