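# Transient incompressible ALE Navier-Stokes, equal-order stabilized --------
#
# Mixed velocity-pressure P1-P1 triangles with residual-based SUPG/PSPG and
# grad-div stabilization; implicit Euler in time; Picard iterations on the
# advection field; convective velocity is (v - v_mesh) in the ALE frame.
# The assembled system is scaled by 1/rho (kinematic pressure p/rho); the
# state stores physical pressure (Pa).

#' Resistive outlet model
#'
#' Linear hydraulic model P(t) = P0 + Rd * Q_out modelling the downstream
#' vasculature. Defaults P0 = -3.7 kPa, Rd = 1.31 kPa s/mL.
#'
#' @param P0_kpa reference pressure (kPa)
#' @param Rd_kpa_s_per_ml distal resistance (kPa s/mL)
#' @return object of class `outlet_model`
#' @export
outlet_model <- function(P0_kpa = -3.7, Rd_kpa_s_per_ml = 1.31) {
  stopifnot(Rd_kpa_s_per_ml > 0)
  structure(list(P0 = P0_kpa * 1e3, Rd = Rd_kpa_s_per_ml * 1e3),
            class = "outlet_model")
}

#' Outlet pressure from the resistive model
#' @param model [outlet_model()]
#' @param q_out_mlps outlet flow rate (mL/s)
#' @return pressure P (Pa); the applied boundary traction is -P n
#' @export
outlet_traction <- function(model, q_out_mlps) {
  model$P0 + model$Rd * q_out_mlps
}

#' Parabolic inlet Dirichlet data
#'
#' 2D: parabola with peak 1.5x the mean velocity; 3D mapping (peak 2x mean)
#' is available via `peak_factor`. The 2D slice conserves the 3D mean velocity
#' (Q / (pi D^2/4)), not the volumetric rate.
#'
#' @param waveform [build_waveform()]
#' @param t time (s)
#' @param inlet list with `coords` (n x 2, mm), `direction` (unit 2-vector,
#'   into the domain), `diameter_mm` reference vessel diameter
#' @param peak_factor profile peak over mean (1.5 parabola in 2D, 2 in 3D)
#' @return n x 2 matrix of velocities (m/s)
#' @export
apply_inlet <- function(waveform, t, inlet, peak_factor = 1.5) {
  q <- evaluate_flowrate(waveform, t)                      # mL/s
  vbar <- mean_velocity_from_flow(q, inlet$diameter_mm)    # m/s
  co <- inlet$coords
  # signed distance across the inlet from its midpoint
  mid <- colMeans(co)
  rel <- sweep(co, 2, mid)
  s <- sqrt(rowSums(rel^2)) * sign(rel %*% perp(inlet$direction))
  a <- max(abs(s))
  prof <- peak_factor * vbar * (1 - (s / a)^2)
  outer(as.vector(prof), inlet$direction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
perp <- function(v) c(-v[2], v[1])

#' Mean (bulk) velocity for a flow rate in a circular vessel
#' @param q_mlps flow rate (mL/s)
#' @param diameter_mm vessel diameter (mm)
#' @return mean velocity (m/s)
#' @export
mean_velocity_from_flow <- function(q_mlps, diameter_mm = 4) {
  (q_mlps * 1e-6) / (pi * (diameter_mm * MM / 2)^2)
}

fluid_state <- function(mesh, t = 0) {
  n <- nrow(mesh$nodes)
  structure(list(v = matrix(0, n, 2), p = rep(0, n), t = t), class = "fluid_state")
}

# flow across tagged boundary edges, outward positive (m^2/s in 2D);
# outward normal times edge length is (dy, -dx) for directed edges
boundary_flux <- function(mesh, v, tags) {
  sel <- mesh$bnd$tag %in% tags
  a <- mesh$bnd$n1[sel]; b <- mesh$bnd$n2[sel]
  dx <- (mesh$nodes[b, 1] - mesh$nodes[a, 1]) * MM
  dy <- (mesh$nodes[b, 2] - mesh$nodes[a, 2]) * MM
  vx <- 0.5 * (v[a, 1] + v[b, 1]); vy <- 0.5 * (v[a, 2] + v[b, 2])
  sum(vx * dy - vy * dx)
}

# nodal boundary measure (m) for nodes on tagged edges
nodal_boundary_length <- function(mesh, tags) {
  sel <- mesh$bnd$tag %in% tags
  a <- mesh$bnd$n1[sel]; b <- mesh$bnd$n2[sel]
  len <- sqrt(rowSums((mesh$nodes[b, , drop = FALSE] -
                       mesh$nodes[a, , drop = FALSE])^2)) * MM
  l <- numeric(nrow(mesh$nodes))
  for (k in seq_along(a)) {
    l[a[k]] <- l[a[k]] + len[k] / 2
    l[b[k]] <- l[b[k]] + len[k] / 2
  }
  l
}

#' One implicit fluid step (or steady solve)
#'
#' @param mesh `mesh2d` in its current (ALE) configuration, coordinates in mm
#' @param state previous `fluid_state` (values at the old time level)
#' @param dt time step (s); `Inf` requests a steady solve
#' @param bc list: `dirichlet` = list(idx, v [n x 2 m/s]); `outlet` = list
#'   (tag, model or P fixed Pa); `f` body force (m/s^2, per unit mass)
#' @param props [fluid_properties()]
#' @param v_mesh ALE mesh velocity, N x 2 (m/s) or 0
#' @param picard_tol,picard_max nonlinear iteration controls
#' @param q3d_map function mapping the 2D outlet mean velocity to an
#'   equivalent 3D flow rate (mL/s) for the resistive model; default uses the
#'   mean-velocity equivalence on a 4 mm vessel
#' @param stab_scales multipliers on the SUPG, PSPG and grad-div terms
#'   (diagnostic knobs; the defaults are the method)
#' @return new `fluid_state` (pressure in Pa), with the raw assembled system
#'   kept for consistent wall-traction evaluation
#' @export
advance_fluid <- function(mesh, state, dt, bc, props = fluid_properties(),
                          v_mesh = 0, picard_tol = 1e-6, picard_max = 25,
                          q3d_map = NULL, stab_scales = c(1, 1, 1)) {
  stopifnot(dt > 0)
  n <- nrow(mesh$nodes)
  nodes_m <- mesh$nodes * MM
  inv_dt <- if (is.finite(dt)) 1 / dt else 0
  if (!is.matrix(v_mesh)) v_mesh <- matrix(v_mesh, n, 2)
  vn <- state$v
  v <- vn; pt <- state$p / props$rho_f
  # seed Dirichlet values so the first advection field sees them
  if (!is.null(bc$dirichlet)) v[bc$dirichlet$idx, ] <- bc$dirichlet$v
  f <- bc$f %||% c(0, 0)
  if (is.null(q3d_map))
    q3d_map <- function(vbar) vbar * pi * (2 * MM)^2 * 1e6  # mL/s at D = 4 mm

  dir_idx <- bc$dirichlet$idx
  dir_rows <- c(dir_idx, n + dir_idx)
  dir_vals <- c(bc$dirichlet$v[, 1], bc$dirichlet$v[, 2])
  if (!is.null(bc$pin_pressure)) {
    # fix the pressure level (needed for all-Dirichlet velocity problems)
    dir_rows <- c(dir_rows, 2 * n + bc$pin_pressure)
    dir_vals <- c(dir_vals, rep(0, length(bc$pin_pressure)))
  }
  dirflag <- logical(3 * n); dirflag[dir_rows] <- TRUE

  # outlet boundary operator: w_out^T v = outward flux (m^2/s); traction
  # contribution -(P/rho) w_out.  With the linear resistive model the Rd part
  # is made implicit as a rank-one term (Rd k / rho) w_out w_out^T, which is
  # unconditionally stable (the explicit update diverges for stiff Rd).
  w_out <- NULL
  if (!is.null(bc$outlet)) {
    sel <- mesh$bnd$tag %in% bc$outlet$tag
    oa <- mesh$bnd$n1[sel]; ob <- mesh$bnd$n2[sel]
    odx <- (nodes_m[ob, 1] - nodes_m[oa, 1])
    ody <- (nodes_m[ob, 2] - nodes_m[oa, 2])
    wvec <- numeric(2 * n)
    for (k in seq_along(oa)) {
      wvec[oa[k]] <- wvec[oa[k]] + ody[k] / 2
      wvec[ob[k]] <- wvec[ob[k]] + ody[k] / 2
      wvec[n + oa[k]] <- wvec[n + oa[k]] - odx[k] / 2
      wvec[n + ob[k]] <- wvec[n + ob[k]] - odx[k] / 2
    }
    out_nodes <- which(wvec != 0)
    w_out <- list(idx = out_nodes, w = wvec[out_nodes],
                  width = sum(sqrt(odx^2 + ody^2)))
    if (!is.null(bc$outlet$model)) {
      # dP/dQ2d in kinematic units: q3d_map(1) is mL/s per unit mean
      # velocity, so mL/s per unit 2D flux is q3d_map(1)/width
      k3d <- q3d_map(1) / w_out$width
      scl <- bc$outlet$scale %||% 1     # start-up envelope
      w_out$gain <- scl * bc$outlet$model$Rd * k3d / props$rho_f
      w_out$p0_kin <- scl * bc$outlet$model$P0 / props$rho_f
    }
  }

  conv <- FALSE; iters <- 0
  for (it in seq_len(picard_max)) {
    a_adv <- v - v_mesh
    a_ref <- max(sqrt(rowSums(a_adv^2)))
    asm <- fluid_assemble_cpp(nodes_m, mesh$tri, vn[, 1], vn[, 2],
                              a_adv[, 1], a_adv[, 2], v[, 1], v[, 2],
                              inv_dt, props$nu,
                              f[1], f[2], 1L, stab_scales[1], stab_scales[2],
                              stab_scales[3], a_ref)
    ii <- asm$i + 1L; jj <- asm$j + 1L; xx <- asm$x
    b0 <- asm$rhs
    # outlet traction -P n (kinematic)
    if (!is.null(w_out)) {
      if (!is.null(bc$outlet$model)) {
        b0[w_out$idx] <- b0[w_out$idx] - w_out$p0_kin * w_out$w
        # implicit resistance: A[idx, idx] += gain * w w^T
        nw <- length(w_out$idx)
        ii <- c(ii, rep(w_out$idx, each = nw))
        jj <- c(jj, rep(w_out$idx, times = nw))
        xx <- c(xx, as.vector(outer(w_out$w, w_out$w)) * w_out$gain)
      } else {
        b0[w_out$idx] <- b0[w_out$idx] - (bc$outlet$P / props$rho_f) * w_out$w
      }
    }
    xx_raw <- xx
    # Dirichlet rows zapped in triplet space; unit diagonal appended
    xx[dirflag[ii]] <- 0
    A <- Matrix::sparseMatrix(i = c(ii, dir_rows), j = c(jj, dir_rows),
                              x = c(xx, rep(1, length(dir_rows))),
                              dims = c(3 * n, 3 * n))
    b <- b0; b[dir_rows] <- dir_vals
    z <- as.vector(Matrix::solve(A, b, sparse = FALSE))
    v_new <- cbind(z[1:n], z[(n + 1):(2 * n)])
    dv <- max(abs(v_new - v)); scale_v <- max(abs(v_new), 1e-12)
    v <- v_new; pt <- z[(2 * n + 1):(3 * n)]
    iters <- it
    if (dv / scale_v < picard_tol) { conv <- TRUE; break }
  }
  # raw (unconstrained) system, outlet terms included, for consistent
  # reaction/traction evaluation
  A0 <- Matrix::sparseMatrix(i = ii, j = jj, x = xx_raw, dims = c(3 * n, 3 * n))
  structure(list(
    v = v, p = pt * props$rho_f,
    t = state$t + if (is.finite(dt)) dt else 0,
    converged = conv, picard_iters = iters,
    sys = list(A0 = A0, b0 = b0, z = z, rho = props$rho_f)),
    class = "fluid_state")
}

#' Steady fluid solve (drops the time-derivative terms)
#' @inheritParams advance_fluid
#' @export
steady_fluid <- function(mesh, bc, props = fluid_properties(),
                         picard_tol = 1e-6, picard_max = 50, state = NULL) {
  if (is.null(state)) state <- fluid_state(mesh)
  advance_fluid(mesh, state, Inf, bc, props,
                picard_tol = picard_tol, picard_max = picard_max)
}

#' Variationally consistent wall traction
#'
#' Evaluates sigma_f . n on the requested wall nodes from the converged
#' residual of the unconstrained system (boundary-flux / reaction method),
#' with n the outward fluid normal.
#'
#' @param state converged [advance_fluid()] state (keeps the raw system)
#' @param mesh the mesh the state was computed on
#' @param wall_idx node indices of the wall
#' @param wall_tags boundary tags used for the nodal length weights
#' @return list: `traction` (W x 2, Pa; sigma_f.n per node), `force` (W x 2,
#'   N per unit depth; nodal force exerted by the fluid on the wall),
#'   `lengths` nodal measures (m)
#' @export
wall_traction <- function(state, mesh, wall_idx,
                          wall_tags = c("fsi", "wall")) {
  stopifnot(!is.null(state$sys))
  n <- nrow(mesh$nodes)
  r <- as.vector(state$sys$A0 %*% state$sys$z - state$sys$b0)
  rho <- state$sys$rho
  # integrating the interior weak form by parts leaves the boundary term
  # +int w.(sigma.n) on the constrained rows, so rho*r is the nodal boundary
  # traction integral on the fluid side; the wall feels the opposite force
  traction_int <- rho * cbind(r[wall_idx], r[n + wall_idx])
  l <- nodal_boundary_length(mesh, wall_tags)[wall_idx]
  traction <- traction_int / l          # sigma_f . n_f
  force <- -traction_int                # nodal force exerted on the wall
  list(traction = traction, force = force, lengths = l)
}
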