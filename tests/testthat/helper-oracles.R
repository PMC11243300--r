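# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no stored data.

# --- plane Poiseuille runner -------------------------------------------------
# channel lx x 4 mm, inlet parabola at the 4 mL/s-equivalent mean velocity,
# no-slip walls, traction-free outlet. Returns solution and L2 velocity error
# against the analytic parabola.
poiseuille_case <- function(ny, nx = 3 * ny, lx = 12, picard_tol = 1e-9) {
  vbar <- mean_velocity_from_flow(4)
  m <- mesh_rectangle(lx, 4, nx, ny)
  inlet <- sacflow:::bnd_nodes(m, "inlet")
  walls <- sacflow:::bnd_nodes(m, "wall")
  y <- m$nodes[, 2] * 1e-3
  h <- 4e-3
  uex <- function(y) 6 * vbar * (y / h) * (1 - y / h)
  dir_idx <- c(inlet, walls)
  dir_v <- rbind(cbind(uex(y[inlet]), 0), matrix(0, length(walls), 2))
  dup <- duplicated(dir_idx, fromLast = TRUE)
  bc <- list(dirichlet = list(idx = dir_idx[!dup], v = dir_v[!dup, , drop = FALSE]),
             outlet = list(tag = "outlet", P = 0), f = c(0, 0))
  st <- steady_fluid(m, bc, picard_tol = picard_tol, picard_max = 60)
  err <- sqrt(mean((st$v[, 1] - uex(y))^2 + st$v[, 2]^2)) /
    sqrt(mean(uex(y)^2))
  list(mesh = m, state = st, err = err, walls = walls, vbar = vbar,
       uex = uex, y = y)
}

# exact wall shear of the plane Poiseuille profile (Pa)
poiseuille_wss <- function() 6 * 0.004 * mean_velocity_from_flow(4) / 4e-3

# --- oscillatory channel (start-from-rest modal series) ----------------------
# du/dt = nu d2u/dy2 + G cos(om t), u(0) = u(H) = 0, u(y,0) = 0
womersley_exact <- function(y, t, H = 4e-3, nu = 4e-6, om = 2 * pi / 0.8,
                            G = 1, K = 80) {
  u <- 0
  for (k in seq(1, K, by = 2)) {
    lam <- nu * (k * pi / H)^2
    ck <- 4 * G / (k * pi)
    u <- u + ck * sin(k * pi * y / H) *
      (lam * cos(om * t) + om * sin(om * t) - lam * exp(-lam * t)) /
      (lam^2 + om^2)
  }
  u
}

# --- Lame thick-wall cylinder (plane strain, internal pressure) --------------
lame_u_exact <- function(r_m, a_m, b_m, p, mu, nu) {
  p * a_m^2 / (2 * mu * (b_m^2 - a_m^2)) * ((1 - 2 * nu) * r_m + b_m^2 / r_m)
}

# quarter-annulus Lame model with symmetry rollers and pressurized inner edge
lame_model <- function(a = 2, b = 3, nth = 24, nr = 12,
                       props = solid_properties()) {
  th <- seq(0, pi / 2, length.out = nth + 1)
  rr <- seq(a, b, length.out = nr + 1)
  X <- outer(cos(th), rr); Y <- outer(sin(th), rr)
  g <- sacflow:::grid_to_tri(X, Y)
  m <- sacflow:::mesh2d(g$nodes, g$tri)
  nn <- m$nodes
  model <- solid_model(m, props,
                       fixed_x = which(abs(nn[, 1]) < 1e-9),
                       fixed_y = which(abs(nn[, 2]) < 1e-9))
  e <- sacflow:::boundary_edges(m)
  rad <- sqrt(rowSums(nn^2))
  inner_e <- e[rad[e[, 1]] < a + 1e-9 & rad[e[, 2]] < a + 1e-9, , drop = FALSE]
  d <- nn[inner_e[, 2], ] - nn[inner_e[, 1], ]
  nrm <- cbind(-d[, 2], d[, 1])
  mid <- (nn[inner_e[, 1], ] + nn[inner_e[, 2], ]) / 2
  flip <- rowSums(nrm * mid) < 0
  inner_e[flip, ] <- inner_e[flip, c(2, 1)]
  list(model = model, inner_edges = inner_e, rad = rad, nodes = nn)
}

# --- independent small-strain plane-strain eigen oracle ----------------------
# P1 displacement FEM assembled here (not via the package's solid path)
linear_eigen_f1 <- function(mesh, E, nu, rho, clamped) {
  nn <- mesh$nodes; n <- nrow(nn)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- matrix(c(lam + 2 * mu, lam, 0, lam, lam + 2 * mu, 0, 0, 0, mu), 3, 3)
  K <- matrix(0, 2 * n, 2 * n); M <- matrix(0, 2 * n, 2 * n)
  for (e in seq_len(nrow(mesh$tri))) {
    nd <- mesh$tri[e, ]; P <- nn[nd, ] * 1e-3
    det <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
      (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])
    A <- det / 2
    gx <- c(P[2, 2] - P[3, 2], P[3, 2] - P[1, 2], P[1, 2] - P[2, 2]) / det
    gy <- c(P[3, 1] - P[2, 1], P[1, 1] - P[3, 1], P[2, 1] - P[1, 1]) / det
    B <- matrix(0, 3, 6)
    for (j in 1:3) {
      B[1, 2 * j - 1] <- gx[j]; B[2, 2 * j] <- gy[j]
      B[3, 2 * j - 1] <- gy[j]; B[3, 2 * j] <- gx[j]
    }
    dof <- as.vector(rbind(nd, n + nd))
    K[dof, dof] <- K[dof, dof] + A * t(B) %*% D %*% B
    Me <- matrix(0, 6, 6)
    for (i in 1:3) for (j in 1:3)
      Me[c(2 * i - 1, 2 * i), c(2 * j - 1, 2 * j)] <-
        diag(2) * rho * A / 12 * (1 + (i == j))
    M[dof, dof] <- M[dof, dof] + Me
  }
  free <- setdiff(seq_len(2 * n), c(clamped, n + clamped))
  ev <- eigen(solve(M[free, free], K[free, free]), only.values = TRUE)$values
  sqrt(min(Re(ev[abs(Im(ev)) < 1e-6 * max(abs(ev))]))) / (2 * pi)
}

# --- brute-force signed-rank null (all 2^n sign assignments) -----------------
signed_rank_exact_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(grid) %*% r
  p_ge <- mean(W_all >= W_obs - 1e-12)
  p_le <- mean(W_all <= W_obs + 1e-12)
  min(1, 2 * min(p_ge, p_le))
}

# small labelled hemisphere for geometry checks; target diameter chosen so
# the volume-matching rescale is the identity (D_eq of a hemisphere of
# radius r is (4)^(1/3) r)
hemisphere_bulge <- function(r = 1.2, segments = 64, rings = 32, seed = 1) {
  generate_bulge(bulge_spec(seed = seed, target_diameter = 4^(1 / 3) * r,
                            height_ratio = 0.5, tilt = 0, lobulation_amp = 0,
                            neck_radius = r),
                 segments = segments, rings = rings)
}

# independent point-in-bulge test by upward ray parity against the dome
# triangles (the neck cap lies in z = 0, below every z > 0 sample)
raycast_inside <- function(b, pts) {
  cnt <- integer(nrow(pts))
  V <- b$vertices; Tr <- b$tri
  for (f in seq_len(nrow(Tr))) {
    p1 <- V[Tr[f, 1], ]; p2 <- V[Tr[f, 2], ]; p3 <- V[Tr[f, 3], ]
    xmin <- min(p1[1], p2[1], p3[1]); xmax <- max(p1[1], p2[1], p3[1])
    ymin <- min(p1[2], p2[2], p3[2]); ymax <- max(p1[2], p2[2], p3[2])
    cand <- which(pts[, 1] >= xmin & pts[, 1] <= xmax &
                    pts[, 2] >= ymin & pts[, 2] <= ymax)
    if (!length(cand)) next
    d <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(d) < 1e-14) next
    wx <- pts[cand, 1] - p1[1]; wy <- pts[cand, 2] - p1[2]
    l2 <- (wx * (p3[2] - p1[2]) - wy * (p3[1] - p1[1])) / d
    l3 <- (wy * (p2[1] - p1[1]) - wx * (p2[2] - p1[2])) / d
    ok <- l2 >= 0 & l3 >= 0 & (l2 + l3) <= 1
    if (!any(ok)) next
    zt <- p1[3] + l2[ok] * (p2[3] - p1[3]) + l3[ok] * (p3[3] - p1[3])
    hit <- cand[ok][zt > pts[cand[ok], 3]]
    cnt[hit] <- cnt[hit] + 1L
  }
  cnt %% 2L == 1L
}

# UV-sphere fixture shared by the remeshing and extrusion tests
make_uv_sphere <- function(r = 5, nseg = 32, nring = 16) {
  th <- seq(0, pi, length.out = nring + 1)
  ph <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  verts <- rbind(c(0, 0, r))
  rings <- list()
  for (i in 2:nring) {
    ring <- cbind(r * sin(th[i]) * cos(ph), r * sin(th[i]) * sin(ph),
                  r * cos(th[i]))
    rings[[i - 1]] <- nrow(verts) + seq_len(nseg)
    verts <- rbind(verts, ring)
  }
  verts <- rbind(verts, c(0, 0, -r))
  south <- nrow(verts)
  tri <- NULL
  top <- rings[[1]]
  jp <- c(2:nseg, 1)
  tri <- rbind(tri, cbind(rep(1, nseg), top, top[jp]))
  for (i in 1:(length(rings) - 1)) {
    a <- rings[[i]]; b <- rings[[i + 1]]
    tri <- rbind(tri, cbind(a, b, b[jp]), cbind(a, b[jp], a[jp]))
  }
  bot <- rings[[length(rings)]]
  tri <- rbind(tri, cbind(bot, rep(south, nseg), bot[jp]))
  m <- surface_mesh(verts, tri)
  if (surf_volume(m) < 0) m$tri <- m$tri[, c(1, 3, 2)]
  m
}


# nearly uniform sphere (subdivided icosahedron projected to radius r) --
# the right fixture for "already uniform mesh" remeshing premises
make_icosphere <- function(r = 5, subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  Tr <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
              c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
              c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
              c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e <- rbind(Tr[, 1:2], Tr[, 2:3], Tr[, c(3, 1)])
    ek <- key(e[, 1], e[, 2])
    uk <- unique(ek)
    mid_of <- setNames(nrow(V) + seq_along(uk), uk)
    V <- rbind(V, (V[e[!duplicated(ek), 1], ] + V[e[!duplicated(ek), 2], ]) / 2)
    m12 <- mid_of[key(Tr[, 1], Tr[, 2])]
    m23 <- mid_of[key(Tr[, 2], Tr[, 3])]
    m31 <- mid_of[key(Tr[, 3], Tr[, 1])]
    Tr <- rbind(cbind(Tr[, 1], m12, m31), cbind(Tr[, 2], m23, m12),
                cbind(Tr[, 3], m31, m23), cbind(m12, m23, m31))
  }
  V <- V * r / sqrt(rowSums(V^2))
  m <- surface_mesh(V, Tr)
  if (surf_volume(m) < 0) m$tri <- m$tri[, c(1, 3, 2)]
  m
}
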