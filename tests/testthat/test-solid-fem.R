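test_that("zero load gives zero displacement", {
  m <- mesh_rectangle(4, 2, 8, 4)
  model <- solid_model(m, fixed = which(abs(m$nodes[, 1]) < 1e-9))
  sol <- static_solid(model)
  expect_equal(max(abs(sol$u)), 0)
  st <- advance_solid(model, sacflow:::solid_state_init(model), 0.001)
  expect_lt(max(abs(st$u)), 1e-12)
})

test_that("small-load Lame cylinder matches the plane-strain closed form", {
  lm <- lame_model()
  sol <- static_solid(lm$model, edge_pressure = list(edges = lm$inner_edges,
                                                     p = 100))
  n <- lm$model$n
  ur <- sqrt(sol$u[1:n]^2 + sol$u[n + 1:n]^2)
  props <- lm$model$props
  for (rq in c(2, 2.5, 3)) {
    sel <- abs(lm$rad - rq) < 1e-6
    expect_lt(abs(mean(ur[sel]) /
                    lame_u_exact(rq * 1e-3, 2e-3, 3e-3, 100,
                                 props$mu_s, props$nu) - 1), 0.03)
  }
})

test_that("free vibration frequency matches an independent eigen oracle", {
  lx <- 8; ly <- 2
  m <- mesh_rectangle(lx, ly, 24, 6)
  nn <- m$nodes; n <- nrow(nn)
  props <- solid_properties(E = 0.75e6, nu = 0.3)
  clamp <- which(abs(nn[, 1]) < 1e-9)
  f_oracle <- linear_eigen_f1(m, props$E, props$nu, props$rho_s0, clamp)
  model <- solid_model(m, props, fixed = clamp)
  tip <- which(abs(nn[, 1] - lx) < 1e-9 & abs(nn[, 2] - ly / 2) < 1e-9)
  f0 <- numeric(2 * n); f0[n + tip] <- 1e-4
  sol0 <- static_solid(model, f_ext = f0)
  st <- sacflow:::solid_state_init(model)
  st$u <- sol0$u; st$p <- sol0$p
  dt <- 2e-5
  tipy <- numeric(400)
  for (s in 1:400) {
    st <- advance_solid(model, st, dt)
    tipy[s] <- st$u[n + tip]
  }
  sgn <- sign(tipy)
  cross <- which(diff(sgn) != 0 & sgn[-1] != 0)
  f_num <- 1 / (2 * mean(diff(cross)) * dt)
  expect_lt(abs(f_num / f_oracle - 1), 0.05)
})

test_that("trapezoidal Newmark keeps the energy drift below 1% per cycle", {
  lx <- 8; ly <- 2
  m <- mesh_rectangle(lx, ly, 24, 6)
  nn <- m$nodes; n <- nrow(nn)
  props <- solid_properties(E = 0.75e6, nu = 0.3)
  model <- solid_model(m, props, fixed = which(abs(nn[, 1]) < 1e-9),
                       stab_alpha = 0.01, finite_vol = TRUE)
  tip <- which(abs(nn[, 1] - lx) < 1e-9 & abs(nn[, 2] - ly / 2) < 1e-9)
  f0 <- numeric(2 * n); f0[n + tip] <- 1e-4
  sol0 <- static_solid(model, f_ext = f0)
  st <- sacflow:::solid_state_init(model)
  st$u <- sol0$u; st$p <- sol0$p
  dt <- 2e-5; nsteps <- 400
  tipy <- numeric(nsteps)
  E0 <- solid_energy(model, st)$total
  for (s in 1:nsteps) {
    st <- advance_solid(model, st, dt, tol = 1e-10)
    tipy[s] <- st$u[n + tip]
  }
  E1 <- solid_energy(model, st)$total
  cross <- which(diff(sign(tipy)) != 0 & sign(tipy)[-1] != 0)
  per <- 2 * mean(diff(cross)) * dt
  drift_per_cycle <- abs((E1 - E0) / E0) / (nsteps * dt / per)
  expect_lt(drift_per_cycle, 0.01)
})

test_that("the finite-strain volumetric option satisfies p = U'(J) pointwise", {
  m <- mesh_rectangle(2, 2, 4, 4)
  props <- solid_properties()
  model <- solid_model(m, props, fixed = which(abs(m$nodes[, 1]) < 1e-9),
                       finite_vol = TRUE, stab_alpha = 0.01)
  n <- model$n
  f <- numeric(2 * n)
  edge <- which(abs(m$nodes[, 1] - 2) < 1e-9)
  f[edge] <- 1e-3
  sol <- static_solid(model, f_ext = f)
  # integral identity: area-weighted mean of p equals that of U'(J)
  # (pointwise equality is blurred by the equal-order stabilization)
  A <- abs(sacflow:::tri_areas(m))
  pc <- uj <- numeric(nrow(m$tri))
  for (e in seq_len(nrow(m$tri))) {
    nd <- m$tri[e, ]
    X <- m$nodes[nd, ] * 1e-3
    ue <- cbind(sol$u[nd], sol$u[n + nd])
    Dm <- cbind(X[2, ] - X[1, ], X[3, ] - X[1, ])
    Du <- cbind(ue[2, ] - ue[1, ], ue[3, ] - ue[1, ])
    F2 <- diag(2) + Du %*% solve(Dm)
    pc[e] <- mean(sol$p[nd])
    uj[e] <- 0.5 * props$kappa * (det(F2) - 1 / det(F2))
  }
  pbar <- sum(A * pc) / sum(A); ubar <- sum(A * uj) / sum(A)
  expect_lt(abs(pbar - ubar) / max(abs(pbar), 1), 0.05)
})
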