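# Strong partitioned Dirichlet-Neumann coupling with Aitken relaxation ------
#
# Fixed-point unknown: the interface displacement. Per sub-iteration the
# fluid mesh is moved by harmonic extension of the relaxed interface
# displacement, the fluid is advanced with the interface velocity as wall
# Dirichlet data, consistent wall tractions load the solid, and the solid
# returns a new interface displacement. Convergence is declared on the
# node-scaled L2 norm of the displacement change (tolerance 1e-5 mm).

#' Coupling configuration
#' @param tol scaled interface-displacement tolerance (mm), default 1e-5
#' @param max_subiters maximum sub-iterations per time step
#' @param omega_init initial relaxation factor
#' @param omega_bounds clip range for the Aitken factor
#' @param aitken use Aitken acceleration (FALSE = constant omega_init)
#' @param min_subiters minimum sub-iterations per step: accepting the
#'   predictor without at least one corrector pass degenerates to loose
#'   coupling, which the added-mass effect destabilizes
#' @return `coupling_config` list
#' @export
coupling_config <- function(tol = 1e-5, max_subiters = 50, omega_init = 0.5,
                            omega_bounds = c(0.05, 1), aitken = TRUE,
                            min_subiters = 2) {
  stopifnot(tol > 0, omega_init >= omega_bounds[1],
            omega_init <= omega_bounds[2], min_subiters >= 1)
  structure(list(tol = tol, max_subiters = max_subiters,
                 omega_init = omega_init, omega_bounds = omega_bounds,
                 aitken = aitken, min_subiters = min_subiters),
            class = "coupling_config")
}

#' Aitken delta-squared relaxation update
#'
#' omega_{k+1} = -omega_k <r_k, r_{k+1} - r_k> / ||r_{k+1} - r_k||^2,
#' clipped to `bounds`; a vanishing denominator keeps the previous factor.
#'
#' @param r_k,r_k1 successive interface residual vectors
#' @param omega_k current relaxation factor
#' @param bounds clip range
#' @return next relaxation factor
#' @export
aitken_update <- function(r_k, r_k1, omega_k, bounds = c(0.05, 1)) {
  d <- r_k1 - r_k
  den <- sum(d * d)
  if (den <= .Machine$double.eps * max(sum(r_k^2), 1e-300)) return(omega_k)
  om <- -omega_k * sum(r_k * d) / den
  min(max(om, bounds[1]), bounds[2])
}

#' Node-scaled interface convergence norm
#'
#' Plain L2 norm of the change divided by the number of solid nodes
#' (||d_new - d_old||_2 / N), in the units of the inputs.
#'
#' @param d_new,d_old interface displacement fields (same layout)
#' @param n_nodes solid-mesh node count (default: rows of `d_new`)
#' @return scalar norm
#' @export
convergence_norm <- function(d_new, d_old, n_nodes = NROW(d_new)) {
  sqrt(sum((d_new - d_old)^2)) / n_nodes
}

#' Harmonic (diffusion) mesh-motion operator
#'
#' Prefactors the P1 Laplace operator on the reference fluid mesh with
#' Dirichlet data on every boundary node: the interface follows the wall, all
#' other boundary nodes (inlet/outlet planes) stay fixed.
#'
#' @param mesh reference fluid `mesh2d`
#' @param moving_idx boundary nodes receiving prescribed displacement
#' @param stiffen weight elements by inverse area so thin boundary-layer
#'   cells translate almost rigidly with the wall
#' @return function(disp W x 2) -> N x 2 displacement extension (same units)
#' @export
mesh_motion_operator <- function(mesh, moving_idx, stiffen = TRUE) {
  n <- nrow(mesh$nodes)
  K <- laplace_stiffness(mesh, stiffen = stiffen)
  bidx <- sort(unique(c(mesh$bnd$n1, mesh$bnd$n2)))
  int_idx <- setdiff(seq_len(n), bidx)
  KII <- K[int_idx, int_idx]
  KIB <- K[int_idx, bidx, drop = FALSE]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(KII))
  force(moving_idx)
  function(disp) {
    full <- matrix(0, n, 2)
    full[moving_idx, ] <- disp
    if (length(int_idx)) {
      rhs <- -KIB %*% full[bidx, , drop = FALSE]
      full[int_idx, ] <- as.matrix(Matrix::solve(fac, rhs))
    }
    full
  }
}

# P1 Laplace stiffness, vectorized assembly; `stiffen` weights each element
# by 1/area so small (boundary-layer) cells move nearly rigidly with the wall
laplace_stiffness <- function(mesh, stiffen = FALSE) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  A <- det / 2
  gx <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  gy <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  wgt <- if (stiffen) mean(A) / A else rep(1, length(A))
  ii <- jj <- xx <- vector("list", 9)
  k <- 1
  for (a in 1:3) for (b in 1:3) {
    ii[[k]] <- mesh$tri[, a]; jj[[k]] <- mesh$tri[, b]
    xx[[k]] <- wgt * A * (gx[, a] * gx[, b] + gy[, a] * gy[, b])
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

#' Harmonic extension of a boundary displacement (one-shot convenience)
#'
#' @param mesh reference fluid `mesh2d`
#' @param moving_idx nodes with prescribed displacement
#' @param disp W x 2 displacement of those nodes
#' @return N x 2 displacement field
#' @export
move_mesh <- function(mesh, moving_idx, disp) {
  mesh_motion_operator(mesh, moving_idx)(disp)
}

# FSI simulation context: prebuilt operators and matched interface maps
fsi_context <- function(case) {
  sm <- solid_model(case$solid, case$props_s, case$solid_factors,
                    fixed = case$solid_fixed,
                    foundation = case$solid_foundation)
  ext <- mesh_motion_operator(case$fluid, case$interface$fluid)
  list(case = case, solid = sm, extend = ext,
       iface_f = case$interface$fluid, iface_s = case$interface$solid)
}

# interface displacement (m, W x 2) from a solid state
iface_disp <- function(ctx, sstate) {
  n <- ctx$solid$n
  cbind(sstate$u[ctx$iface_s], sstate$u[n + ctx$iface_s])
}

#' One strongly coupled FSI time step
#'
#' @param ctx context from `fsi_context()` (internal; built by
#'   [run_protocol()])
#' @param fstate,sstate fluid and solid states at the old time level
#' @param coords_old fluid node coordinates (mm) at the old time level
#' @param t_new new time (s)
#' @param dt step (s)
#' @param waveform inflow waveform
#' @param cfg [coupling_config()]
#' @param scheme solid time scheme: "be" (default; backward-Euler kinematics
#'   make the wall, mesh and solid velocities identical at the interface) or
#'   "newmark"
#' @param gamma,beta Newmark parameters used when `scheme = "newmark"`
#' @return list(fstate, sstate, coords (mm), iters, residuals (mm), omega)
#' @export
coupling_step <- function(ctx, fstate, sstate, coords_old, t_new, dt,
                          waveform, cfg = coupling_config(),
                          scheme = c("be", "newmark"),
                          gamma = 0.5, beta = 0.25) {
  scheme <- match.arg(scheme)
  out_scale <- min(t_new / waveform$ramp, 1)
  case <- ctx$case
  n_s <- ctx$solid$n
  W <- length(ctx$iface_f)
  d_n <- iface_disp(ctx, sstate)                       # m
  ud_n <- cbind(sstate$ud[ctx$iface_s], sstate$ud[n_s + ctx$iface_s])
  d_k <- d_n + dt * ud_n                               # predictor
  omega <- cfg$omega_init
  r_prev <- NULL
  res_hist <- c()
  ref <- case$fluid$nodes

  for (k in seq_len(cfg$max_subiters)) {
    full_disp <- ctx$extend(d_k)                       # m
    coords <- ref + full_disp / MM
    mesh_cur <- case$fluid; mesh_cur$nodes <- coords
    if (min(tri_areas(mesh_cur)) <= 0)
      abort_sf(sprintf(
        "fluid mesh inverted at t = %.4f s (max interface disp %.3g mm)",
        t_new, max(abs(d_k)) / MM), "sacflow_mesh_error")
    v_mesh_full <- (coords - coords_old) * MM / dt
    # interface velocity consistent with the solid time scheme; with the
    # backward-Euler scheme it equals the mesh velocity exactly (no spurious
    # flux through the moving wall)
    ud_k <- if (scheme == "be") (d_k - d_n) / dt else
      (gamma / (beta * dt)) * (d_k - d_n) -
        (gamma / beta - 1) * ud_n -
        dt * (gamma / (2 * beta) - 1) *
          cbind(sstate$udd[ctx$iface_s], sstate$udd[n_s + ctx$iface_s])
    vin <- apply_inlet(waveform, t_new, case$inlet)
    dir_idx <- c(case$inlet$idx, ctx$iface_f)
    dir_v <- rbind(vin, ud_k)
    # inlet corners belong to both sets; wall value wins (no-slip consistency)
    dup <- duplicated(dir_idx, fromLast = TRUE)
    bc <- list(dirichlet = list(idx = dir_idx[!dup],
                                v = dir_v[!dup, , drop = FALSE]),
               outlet = list(tag = case$outlet_tag,
                             model = case$outlet_model %||% outlet_model(),
                             scale = out_scale),
               f = c(0, 0))
    fs <- advance_fluid(mesh_cur, fstate, dt, bc, case$props_f,
                        v_mesh = v_mesh_full)
    wt <- wall_traction(fs, mesh_cur, ctx$iface_f)
    f_ext <- numeric(2 * n_s)
    f_ext[ctx$iface_s] <- wt$force[, 1]
    f_ext[n_s + ctx$iface_s] <- wt$force[, 2]
    ss_try <- advance_solid(ctx$solid, sstate, dt, f_ext,
                            beta = beta, gamma = gamma, scheme = scheme)
    d_tilde <- cbind(ss_try$u[ctx$iface_s], ss_try$u[n_s + ctx$iface_s])
    r_k <- d_tilde - d_k                               # m
    rnorm_mm <- convergence_norm(r_k / MM, 0, n_s)
    res_hist <- c(res_hist, rnorm_mm)
    if (rnorm_mm < cfg$tol && k >= (cfg$min_subiters %||% 1)) {
      # final consistency sweep: re-solve the fluid with the converged solid
      # interface kinematics so the returned states satisfy the discrete
      # kinematic continuity exactly (wall velocity = solid velocity)
      full_disp <- ctx$extend(d_tilde)
      coords <- ref + full_disp / MM
      mesh_cur <- case$fluid; mesh_cur$nodes <- coords
      v_mesh_full <- (coords - coords_old) * MM / dt
      ud_conv <- cbind(ss_try$ud[ctx$iface_s], ss_try$ud[n_s + ctx$iface_s])
      dir_v <- rbind(vin, ud_conv)
      bc$dirichlet <- list(idx = dir_idx[!dup], v = dir_v[!dup, , drop = FALSE])
      fs <- advance_fluid(mesh_cur, fstate, dt, bc, case$props_f,
                          v_mesh = v_mesh_full)
      fs$wall <- wall_traction(fs, mesh_cur, ctx$iface_f)
      return(list(fstate = fs, sstate = ss_try, coords = coords,
                  iters = k, residuals = res_hist, omega = omega))
    }
    if (cfg$aitken && !is.null(r_prev))
      omega <- aitken_update(as.vector(r_prev), as.vector(r_k), omega,
                             cfg$omega_bounds)
    r_prev <- r_k
    d_k <- d_k + omega * r_k
  }
  abort_sf(sprintf(
    "FSI coupling failed to converge in %d sub-iterations (last residual %.3g mm)",
    cfg$max_subiters, tail(res_hist, 1)), "sacflow_coupling_error")
}
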