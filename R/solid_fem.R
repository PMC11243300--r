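# Mixed displacement-pressure solid dynamics (plane strain) -----------------
#
# P1-P1 triangles, total-Lagrangian assembly of the Neo-Hookean/Simo-Taylor
# material, volumetric constraint div(u) - p/kappa = 0 as the default
# (finite-strain variant p = U'(J) behind `finite_vol`), small pressure
# Laplacian stabilization, Newmark-beta time integration (beta = 1/4,
# gamma = 1/2), Newton iterations with a finite-difference consistent tangent.

#' Build a solid model from a mesh
#'
#' @param mesh `mesh2d`, coordinates in mm (reference configuration)
#' @param props [solid_properties()]
#' @param factors per-element stiffness factors (from [assign_regions()]);
#'   default all 1
#' @param fixed node indices with both displacement components clamped
#' @param fixed_x,fixed_y node indices with a single clamped component
#'   (symmetry planes)
#' @param stab_alpha pressure-stabilization coefficient (alpha h^2/mu)
#' @param finite_vol use the finite-strain volumetric constraint p = U'(J)
#' @param foundation per-element elastic-foundation coefficient (N/m^4).
#'   In the plane cut of a vessel the out-of-plane hoop ring is lost; a
#'   Winkler foundation k = E_eff/R^2 (R the out-of-plane curvature radius)
#'   restores the membrane pressure response of the 3D wall. Zero disables.
#' @return object of class `solid_model`
#' @export
solid_model <- function(mesh, props = solid_properties(), factors = NULL,
                        fixed = integer(), fixed_x = integer(),
                        fixed_y = integer(), stab_alpha = 0.05,
                        finite_vol = FALSE, foundation = NULL) {
  n <- nrow(mesh$nodes)
  if (is.null(factors)) factors <- rep(1, nrow(mesh$tri))
  stopifnot(length(factors) == nrow(mesh$tri))
  if (is.null(foundation)) foundation <- rep(0, nrow(mesh$tri))
  stopifnot(length(foundation) == nrow(mesh$tri))
  m <- structure(list(mesh = mesh, props = props, factors = factors,
                      fixed = sort(unique(fixed)),
                      fixed_x = sort(unique(fixed_x)),
                      fixed_y = sort(unique(fixed_y)),
                      stab_alpha = stab_alpha, finite_vol = finite_vol,
                      foundation = foundation,
                      n = n), class = "solid_model")
  m$M <- solid_mass(m)
  m$Kf <- if (any(foundation > 0)) foundation_matrix(m)
  m
}

# consistent foundation matrix (mass-matrix pattern weighted by k_e)
foundation_matrix <- function(model) {
  m <- model$mesh; n <- model$n
  A <- abs(tri_areas(m)) * MM^2
  ke <- model$foundation
  i0 <- m$tri[, 1]; i1 <- m$tri[, 2]; i2 <- m$tri[, 3]
  ii <- c(i0, i0, i0, i1, i1, i1, i2, i2, i2)
  jj <- c(i0, i1, i2, i0, i1, i2, i0, i1, i2)
  ml <- ke * A / 12
  xx <- c(2 * ml, ml, ml, ml, 2 * ml, ml, ml, ml, 2 * ml)
  Mb <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::bdiag(Mb, Mb)
}

#' @export
print.solid_model <- function(x, ...) {
  cat(sprintf(
    "solid model: %d nodes, %d elements, %d clamped; E = %g MPa (x%g stiff region)\n",
    x$n, nrow(x$mesh$tri), length(x$fixed), x$props$E / 1e6,
    x$props$artery_factor))
  invisible(x)
}

solid_state_init <- function(model, t = 0) {
  n <- model$n
  list(u = numeric(2 * n), ud = numeric(2 * n), udd = numeric(2 * n),
       p = numeric(n), t = t)
}

# consistent mass matrix (2N x 2N), reference density, SI
solid_mass <- function(model) {
  m <- model$mesh; n <- model$n
  A <- abs(tri_areas(m)) * MM^2
  rho <- model$props$rho_s0
  i0 <- m$tri[, 1]; i1 <- m$tri[, 2]; i2 <- m$tri[, 3]
  ii <- c(i0, i0, i0, i1, i1, i1, i2, i2, i2)
  jj <- c(i0, i1, i2, i0, i1, i2, i0, i1, i2)
  ml <- rho * A / 12
  xx <- c(2 * ml, ml, ml, ml, 2 * ml, ml, ml, ml, 2 * ml)
  Mb <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::bdiag(Mb, Mb)
}

solid_residual_tangent <- function(model, u, p, want_tangent = TRUE) {
  mu_e <- model$props$mu_s * model$factors
  ka_e <- model$props$kappa * model$factors
  solid_assemble_cpp(model$mesh$nodes * MM, model$mesh$tri, u, p,
                     mu_e, ka_e, model$stab_alpha,
                     as.integer(model$finite_vol), as.integer(want_tangent))
}

# Newton solve of: inertia_fun(u) + f_int(u,p) - f_ext = 0 (momentum rows)
#                  volumetric rows = 0
# inertia_fun returns list(res = 2N vector, coef = a0 scalar for tangent)
solid_newton <- function(model, u, p, f_ext, inertia = NULL,
                         tol = 1e-8, abstol = NULL, max_it = 30) {
  n <- model$n
  fixed_rows <- c(model$fixed, n + model$fixed,
                  model$fixed_x, n + model$fixed_y)
  dirflag <- logical(3 * n); dirflag[fixed_rows] <- TRUE
  keep <- as.numeric(!dirflag)
  # block scaling: the raw volumetric rows are O(A/kappa) while the momentum
  # rows are O(mu); scale pressure rows by kappa and pressure columns by mu
  # (unknown q = p/mu) so the LU factorization sees balanced blocks
  row_s <- model$props$kappa
  col_s <- model$props$mu_s
  prows <- (2 * n + 1):(3 * n)
  # force scale for the relative residual
  fscale <- max(sqrt(sum(f_ext^2)), model$props$mu_s * 1e-6)
  if (is.null(abstol)) abstol <- tol * fscale
  conv <- FALSE
  for (it in seq_len(max_it)) {
    asm <- solid_residual_tangent(model, u, p, TRUE)
    R <- asm$R
    R[seq_len(2 * n)] <- R[seq_len(2 * n)] - f_ext
    if (!is.null(model$Kf))
      R[seq_len(2 * n)] <- R[seq_len(2 * n)] + as.vector(model$Kf %*% u)
    if (!is.null(inertia)) {
      ia <- inertia(u)
      R[seq_len(2 * n)] <- R[seq_len(2 * n)] + ia$res
    }
    Rf <- R * keep
    rn <- sqrt(sum(Rf[seq_len(2 * n)]^2)) + row_s * sqrt(sum(Rf[prows]^2))
    if (rn < abstol || rn < tol * fscale) { conv <- TRUE; break }
    ii <- asm$i + 1L; jj <- asm$j + 1L; xx <- asm$x
    p_row <- ii > 2 * n; p_col <- jj > 2 * n
    xx[p_row] <- xx[p_row] * row_s
    xx[p_col] <- xx[p_col] * col_s
    xx[dirflag[ii]] <- 0
    extra <- NULL
    if (!is.null(inertia) && ia$coef > 0) extra <- ia$coef * model$M
    if (!is.null(model$Kf))
      extra <- if (is.null(extra)) model$Kf else extra + model$Kf
    if (!is.null(extra)) {
      Ms <- methods::as(extra, "TsparseMatrix")
      mi <- Ms@i + 1L; mj <- Ms@j + 1L; mx <- Ms@x
      sel <- !dirflag[mi]
      ii <- c(ii, mi[sel]); jj <- c(jj, mj[sel]); xx <- c(xx, mx[sel])
    }
    K <- Matrix::sparseMatrix(i = c(ii, fixed_rows), j = c(jj, fixed_rows),
                              x = c(xx, rep(1, length(fixed_rows))),
                              dims = c(3 * n, 3 * n))
    rhs <- -Rf
    rhs[prows] <- rhs[prows] * row_s
    rhs[fixed_rows] <- 0
    dz <- tryCatch(as.vector(Matrix::solve(K, rhs, sparse = FALSE)),
                   error = function(e) abort_sf(
                     paste("solid Newton linear solve failed:", conditionMessage(e)),
                     "sacflow_solver_error"))
    du <- dz[seq_len(2 * n)]; dp <- col_s * dz[prows]
    # backtracking line search guards against element inversion and
    # divergence on large load steps
    step <- 1
    for (ls in 1:20) {
      ok <- TRUE
      rn_new <- tryCatch({
        asm2 <- solid_residual_tangent(model, u + step * du, p + step * dp,
                                       FALSE)
        R2 <- asm2$R
        R2[seq_len(2 * n)] <- R2[seq_len(2 * n)] - f_ext
        if (!is.null(model$Kf))
          R2[seq_len(2 * n)] <- R2[seq_len(2 * n)] +
            as.vector(model$Kf %*% (u + step * du))
        if (!is.null(inertia))
          R2[seq_len(2 * n)] <- R2[seq_len(2 * n)] + inertia(u + step * du)$res
        R2 <- R2 * keep
        sqrt(sum(R2[seq_len(2 * n)]^2)) + row_s * sqrt(sum(R2[prows]^2))
      }, error = function(e) { ok <<- FALSE; Inf })
      if (ok && is.finite(rn_new) && rn_new < rn * (1 - 0.1 * step)) break
      step <- step / 2
    }
    u <- u + step * du
    p <- p + step * dp
  }
  if (!conv) abort_sf("solid Newton did not converge", "sacflow_solver_error")
  list(u = u, p = p, iters = it)
}

#' Static solid solve
#'
#' @param model [solid_model()]
#' @param f_ext nodal force vector (length 2N, N per unit depth) or NULL
#' @param edge_pressure optional list(edges = 2-column node index matrix,
#'   p = pressure Pa) applied as a dead load along the reference edge normals
#'   (outward of the loaded surface defined by edge direction: normal is the
#'   left-hand normal of each directed edge)
#' @param u0,p0 optional initial guesses
#' @param tol Newton relative tolerance
#' @return list(u, p, iters); u in m (length 2N), p in Pa
#' @export
static_solid <- function(model, f_ext = NULL, edge_pressure = NULL,
                         u0 = NULL, p0 = NULL, tol = 1e-8) {
  n <- model$n
  if (is.null(f_ext)) f_ext <- numeric(2 * n)
  if (!is.null(edge_pressure))
    f_ext <- f_ext + edge_pressure_forces(model$mesh, edge_pressure$edges,
                                          edge_pressure$p, n)
  u <- u0 %||% numeric(2 * n); p <- p0 %||% numeric(n)
  solid_newton(model, u, p, f_ext, inertia = NULL, tol = tol)
}

# dead-load nodal forces from pressure p on directed reference edges;
# force per edge = p * L * n_in, n_in the left normal (-dy, dx)/L ... the
# caller orients edges so that the normal points INTO the solid surface being
# pushed (i.e. along the load direction).
edge_pressure_forces <- function(mesh, edges, p, n) {
  f <- numeric(2 * n)
  dx <- (mesh$nodes[edges[, 2], 1] - mesh$nodes[edges[, 1], 1]) * MM
  dy <- (mesh$nodes[edges[, 2], 2] - mesh$nodes[edges[, 1], 2]) * MM
  fx <- p * (-dy) / 2; fy <- p * dx / 2
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    f[a] <- f[a] + fx[k]; f[b] <- f[b] + fx[k]
    f[n + a] <- f[n + a] + fy[k]; f[n + b] <- f[n + b] + fy[k]
  }
  f
}

#' One Newmark step of the solid dynamics
#'
#' @param model [solid_model()]
#' @param state list(u, ud, udd, p, t) from [solid_state_init()] or a
#'   previous step
#' @param dt time step (s)
#' @param f_ext external nodal force vector (2N)
#' @param beta,gamma Newmark parameters (trapezoidal default)
#' @param tol Newton tolerance
#' @param scheme "newmark" (default) or "be": backward-Euler kinematics
#'   (u_dot = du/dt), first-order dissipative; used by the FSI coupling so
#'   the wall, mesh and solid velocities coincide exactly at the interface
#' @return updated state
#' @export
advance_solid <- function(model, state, dt, f_ext = NULL,
                          beta = 0.25, gamma = 0.5, tol = 1e-8,
                          scheme = c("newmark", "be")) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0)
  n <- model$n
  if (is.null(f_ext)) f_ext <- numeric(2 * n)
  un <- state$u; vdn <- state$ud; an <- state$udd
  if (scheme == "be") {
    a0 <- 1 / dt^2
    inertia <- function(u) {
      acc <- (u - un - dt * vdn) / dt^2
      list(res = as.vector(model$M %*% acc), coef = a0)
    }
    sol <- solid_newton(model, un, state$p, f_ext, inertia = inertia, tol = tol)
    vel <- (sol$u - un) / dt
    acc <- (vel - vdn) / dt
  } else {
    a0 <- 1 / (beta * dt^2); a1 <- 1 / (beta * dt); a2 <- 1 / (2 * beta) - 1
    inertia <- function(u) {
      acc <- a0 * (u - un) - a1 * vdn - a2 * an
      list(res = as.vector(model$M %*% acc), coef = a0)
    }
    sol <- solid_newton(model, un, state$p, f_ext, inertia = inertia, tol = tol)
    acc <- a0 * (sol$u - un) - a1 * vdn - a2 * an
    vel <- vdn + dt * ((1 - gamma) * an + gamma * acc)
  }
  list(u = sol$u, ud = vel, udd = acc, p = sol$p, t = state$t + dt,
       iters = sol$iters)
}

#' Total mechanical energy of a solid state
#' @param model solid model
#' @param state solid state
#' @return list(elastic, kinetic, total) in J per unit depth
#' @export
solid_energy <- function(model, state) {
  m <- model$mesh; n <- model$n
  X <- m$nodes * MM
  el <- 0
  for (e in seq_len(nrow(m$tri))) {
    nd <- m$tri[e, ]
    Xe <- X[nd, ]
    ue <- cbind(state$u[nd], state$u[n + nd])
    d1 <- Xe[2, ] - Xe[1, ]; d2 <- Xe[3, ] - Xe[1, ]
    A0 <- 0.5 * abs(d1[1] * d2[2] - d1[2] * d2[1])
    Dm <- cbind(d1, d2)
    Du <- cbind(ue[2, ] - ue[1, ], ue[3, ] - ue[1, ])
    F2 <- diag(2) + Du %*% solve(Dm)
    props_e <- model$props
    props_e$mu_s <- props_e$mu_s * model$factors[e]
    props_e$kappa <- props_e$kappa * model$factors[e]
    el <- el + A0 * strain_energy(F2, props_e)
  }
  ke <- 0.5 * sum(state$ud * as.vector(model$M %*% state$ud))
  if (!is.null(model$Kf))
    el <- el + 0.5 * sum(state$u * as.vector(model$Kf %*% state$u))
  list(elastic = el, kinetic = ke, total = el + ke)
}
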