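test_that("Aitken recovers divergent scalar fixed points in few iterations", {
  # x <- a x + b with a = -2: plain iteration diverges, omega = 1 diverges
  a <- -2; b <- 3
  x_star <- b / (1 - a)
  x <- 0; omega <- 0.5; r_prev <- NULL
  for (k in 1:10) {
    g <- a * x + b
    r <- g - x
    if (abs(r) < 1e-13) break
    if (!is.null(r_prev)) omega <- aitken_update(r_prev, r, omega, c(-10, 10))
    r_prev <- r
    x <- x + omega * r
  }
  expect_lte(k, 3)
  expect_lt(abs(x - x_star), 1e-10)
})

test_that("Aitken never needs more iterations than constant relaxation (2-dof maps)", {
  set.seed(3)
  run_map <- function(A, b, use_aitken) {
    x <- c(0, 0); omega <- 0.5; r_prev <- NULL
    for (k in 1:200) {
      r <- A %*% x + b - x
      if (sqrt(sum(r^2)) < 1e-12) return(k)
      if (use_aitken && !is.null(r_prev))
        omega <- aitken_update(r_prev, r, omega, c(0.05, 1))
      r_prev <- r
      x <- x + omega * as.vector(r)
    }
    200
  }
  for (s in 1:10) {
    # symmetric maps with real eigenvalues in (-2.5, 0.8): the relaxed
    # iteration converges for constant omega = 0.5, slowly at the stiff end
    Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
    A <- Q %*% diag(runif(2, -2.5, 0.8)) %*% t(Q)
    b <- rnorm(2)
    expect_lte(run_map(A, b, TRUE), run_map(A, b, FALSE),
               label = sprintf("seed case %d", s))
  }
})

test_that("aitken_update handles the converged-residual edge case", {
  r <- c(1e-3, -2e-3)
  expect_equal(aitken_update(r, r, 0.37), 0.37)   # zero denominator
  expect_equal(aitken_update(c(1, 0), c(0, 0), 0.5, c(0.05, 1)), 0.5)
})

test_that("convergence norm follows the node-count scaling algebra", {
  expect_equal(convergence_norm(matrix(1, 4, 2), matrix(1, 4, 2), 10), 0)
  n <- 25
  d <- matrix(1e-5, n, 1)
  expect_equal(convergence_norm(d, 0, n), 1e-5 * sqrt(n) / n, tolerance = 1e-15)
  spike <- matrix(0, n, 1); spike[3] <- n * 1e-5
  expect_equal(convergence_norm(spike, 0, n), 1e-5, tolerance = 1e-15)
})

test_that("harmonic mesh motion: zero, rigid translation, radial closed form", {
  m <- mesh_rectangle(6, 4, 12, 8)
  walls <- sacflow:::bnd_nodes(m, c("wall"))
  allb <- sort(unique(c(m$bnd$n1, m$bnd$n2)))
  # zero boundary motion
  expect_equal(max(abs(move_mesh(m, allb, matrix(0, length(allb), 2)))), 0)
  # uniform translation of the whole boundary
  full <- move_mesh(m, allb, matrix(c(0.1, -0.2), length(allb), 2, byrow = TRUE))
  expect_lt(max(abs(sweep(full, 2, c(0.1, -0.2)))), 1e-10)
  # annulus: radial inflation of the outer circle decays as log(r) (unit
  # diffusivity; stiffening disabled to match the closed form)
  th <- seq(0, 2 * pi, length.out = 49)   # closed: the seam merges below
  rr <- seq(1, 2, length.out = 9)
  g <- sacflow:::grid_to_tri(outer(cos(th), rr), outer(sin(th), rr))
  ann <- sacflow:::merge_blocks(list(g))
  ann <- sacflow:::tag_boundary(ann, list(dummy = function(p) rep(FALSE, nrow(p))))
  nn <- ann$nodes
  rad <- sqrt(rowSums(nn^2))
  outer_idx <- which(abs(rad - 2) < 1e-9)
  ext <- mesh_motion_operator(ann, outer_idx, stiffen = FALSE)
  disp <- ext(0.02 * nn[outer_idx, ] / rad[outer_idx])
  ur <- rowSums(disp * nn / rad)
  mid <- which(abs(rad - 1.5) < 0.01)
  # component-wise harmonic extension of a radial boundary field:
  # u_r(r) = c (r - 1/r)/(R - 1/R) with R = 2
  u_exact <- 0.02 * (1.5 - 1 / 1.5) / (2 - 1 / 2)
  expect_lt(max(abs(ur[mid] - u_exact)), 0.01 * 0.02 + 2e-4)
})

test_that("rigid mode performs exactly one fluid solve per step with zero wall motion", {
  case <- make_case_2d(m_neck = 8, n_phi = 12, n_side = 6, n_bl = 2)
  wf <- build_waveform()
  cfg <- protocol_config(mode = "rigid", dt = 0.01, n_cycles = 1,
                         window = c(0.9, 1.0))
  fs <- run_protocol(case, cfg, wf)
  expect_true(all(diff(fs$hist$sac_area) == 0))
  expect_equal(fs$mode, "rigid")
})

test_that("the flexible-channel coupling converges with monotone residuals and exact kinematic continuity", {
  case <- make_flexible_channel_2d(props_s = solid_properties(E = 1.2e7),
                                   outlet = outlet_model(P0_kpa = 0,
                                                         Rd_kpa_s_per_ml = 1.31))
  ctx <- sacflow:::fsi_context(case)
  wf <- build_waveform()
  fst <- sacflow:::fluid_state(case$fluid)
  sst <- sacflow:::solid_state_init(ctx$solid)
  coords <- case$fluid$nodes
  st <- NULL
  for (s in 1:4) {
    st <- coupling_step(ctx, fst, sst, coords, 0.35 + s * 0.002, 0.002, wf,
                        coupling_config(max_subiters = 100))
    fst <- st$fstate; sst <- st$sstate; coords <- st$coords
  }
  expect_gt(st$iters, 2)
  r <- st$residuals
  expect_true(all(diff(r[-1]) < 0))   # strictly decreasing after iteration 2
  n_s <- ctx$solid$n
  ud_s <- cbind(sst$ud[ctx$iface_s], sst$ud[n_s + ctx$iface_s])
  vf <- fst$v[ctx$iface_f, ]
  expect_lt(max(abs(vf - ud_s)), 1e-6)
})
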