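test_that("steady Poiseuille: profile, wall shear and mass balance", {
  pc <- poiseuille_case(ny = 10, nx = 24)
  expect_true(pc$state$converged)
  expect_lt(pc$err, 0.01)
  wt <- wall_traction(pc$state, pc$mesh, pc$walls, "wall")
  mid <- which(abs(pc$mesh$nodes[pc$walls, 1] - 6) < 0.01 &
                 pc$mesh$nodes[pc$walls, 2] < 1)
  # on the bottom wall the fluid-side tangential traction opposes the flow
  expect_lt(abs(abs(wt$traction[mid[1], 1]) - poiseuille_wss()) /
              poiseuille_wss(), 0.02)
  expect_lt(wt$traction[mid[1], 1], 0)
  q_in <- -sacflow:::boundary_flux(pc$mesh, pc$state$v, "inlet")
  q_out <- sacflow:::boundary_flux(pc$mesh, pc$state$v, "outlet")
  expect_lt(abs(q_in - q_out) / q_in, 1e-3)
})

test_that("a fluid at rest with zero forcing stays at rest", {
  m <- mesh_rectangle(8, 4, 8, 6)
  allb <- sort(unique(c(m$bnd$n1, m$bnd$n2)))
  bc <- list(dirichlet = list(idx = allb, v = matrix(0, length(allb), 2)),
             f = c(0, 0), pin_pressure = 1L)
  st <- advance_fluid(m, sacflow:::fluid_state(m), 0.002, bc)
  expect_lt(max(abs(st$v)), 1e-12)
})

test_that("uniform flow is transported exactly on a moving mesh (GCL)", {
  m <- mesh_rectangle(8, 4, 8, 6)
  n <- nrow(m$nodes)
  allb <- sort(unique(c(m$bnd$n1, m$bnd$n2)))
  st <- sacflow:::fluid_state(m)
  st$v <- matrix(c(0.3, 0), n, 2, byrow = TRUE)
  vm <- matrix(c(0.1, 0.05), n, 2, byrow = TRUE)
  bc <- list(dirichlet = list(idx = allb,
                              v = matrix(c(0.3, 0), length(allb), 2, byrow = TRUE)),
             f = c(0, 0), pin_pressure = 1L)
  s1 <- advance_fluid(m, st, 0.002, bc, v_mesh = vm)
  expect_lt(max(abs(s1$v[, 1] - 0.3)), 1e-8)
  expect_lt(max(abs(s1$v[, 2])), 1e-8)
})

test_that("hydrostatic state returns the pure pressure traction -P n", {
  m <- mesh_rectangle(8, 4, 8, 6)
  walls <- sacflow:::bnd_nodes(m, "wall")
  inlet <- sacflow:::bnd_nodes(m, "inlet")
  fixed <- sort(unique(c(walls, inlet)))      # outlet stays a traction side
  bc <- list(dirichlet = list(idx = fixed, v = matrix(0, length(fixed), 2)),
             outlet = list(tag = "outlet", P = 250), f = c(0, 0))
  st <- steady_fluid(m, bc)
  expect_lt(max(abs(st$v)), 1e-8)
  expect_lt(max(abs(st$p - 250)), 1e-5)
  wt <- wall_traction(st, m, walls, "wall")
  nrm <- sacflow:::wall_normals(m, walls, "wall")
  # sigma.n = -P n at every interior wall node (corners excluded), and the
  # force on the wall pushes outward (along +n) under positive pressure
  interior <- which(m$nodes[walls, 1] > 0.6 & m$nodes[walls, 1] < 7.4)
  expect_lt(max(abs(wt$traction[interior, ] + 250 * nrm[interior, ])), 1e-5)
  expect_true(all(rowSums(wt$force[interior, ] * nrm[interior, ]) > 0))
})

test_that("parabolic inlet data reproduces the 2D and 3D peak factors", {
  w <- build_waveform()
  inlet <- list(coords = cbind(0, seq(0, 4, by = 0.5)),
                direction = c(1, 0), diameter_mm = 4)
  # at t = 1.0 the cycle value applies
  q <- evaluate_flowrate(w, 1.0)
  v2 <- apply_inlet(w, 1.0, inlet)
  expect_equal(max(v2[, 1]), 1.5 * mean_velocity_from_flow(q), tolerance = 1e-12)
  v3 <- apply_inlet(w, 1.0, inlet, peak_factor = 2)
  expect_equal(max(v3[, 1]), 2 * mean_velocity_from_flow(q), tolerance = 1e-12)
  expect_equal(mean_velocity_from_flow(4), 0.31831, tolerance = 1e-4)
  # ramp start: zero profile
  expect_equal(max(abs(apply_inlet(w, 0, inlet))), 0)
})

test_that("resistive outlet model maps flow to pressure as printed", {
  om <- outlet_model()
  expect_equal(outlet_traction(om, 4), 1540, tolerance = 1e-9)
  expect_equal(outlet_traction(om, 0), -3700, tolerance = 1e-9)
  dq <- flow_for_reynolds(520) - flow_for_reynolds(220)
  dp <- om$Rd * dq
  expect_equal(dp, 4937.6, tolerance = 0.1)
  expect_equal(dp / 133.322, 37.0, tolerance = 0.05)   # mmHg
})

test_that("tube Reynolds stays within the physiological band over the cycle", {
  w <- build_waveform()
  tt <- seq(1, 1.8, length.out = 2001)
  re <- reynolds_number(evaluate_flowrate(w, tt))
  expect_gte(min(re), 215)
  expect_lte(max(re), 525)
})
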