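# Two-cycle simulation protocol --------------------------------------------
#
# 0.2 s linear inflow ramp followed by two 0.8 s cardiac cycles; indicators
# are evaluated over the second cycle (t in [1.0, 1.8] s) to limit transient
# initialization effects. Runs in "rigid" (u = 0, fixed mesh) or "compliant"
# (full FSI) mode on the same geometry and waveform samples.

#' Protocol configuration
#' @param ramp ramp duration (s)
#' @param period cardiac period (s)
#' @param n_cycles number of simulated cycles
#' @param dt time step (s)
#' @param mode "rigid" or "compliant"
#' @param snapshot_stride store volume-field snapshots every k-th step inside
#'   the averaging window
#' @param window averaging window (s); default second cycle
#' @param solid_scheme solid kinematics in the coupled runs ("be" default;
#'   see [advance_solid()])
#' @return `protocol_config`
#' @export
protocol_config <- function(ramp = 0.2, period = 0.8, n_cycles = 2,
                            dt = 0.002, mode = c("compliant", "rigid"),
                            snapshot_stride = 5, window = NULL,
                            solid_scheme = "be") {
  mode <- match.arg(mode)
  t_end <- ramp + n_cycles * period
  if (is.null(window)) window <- c(ramp + (n_cycles - 1) * period, t_end)
  stopifnot(window[1] >= 0, window[2] <= t_end + 1e-12, dt > 0)
  structure(list(ramp = ramp, period = period, n_cycles = n_cycles, dt = dt,
                 mode = mode, snapshot_stride = snapshot_stride,
                 window = window, t_end = t_end,
                 solid_scheme = solid_scheme), class = "protocol_config")
}

# area-weighted mean speed over the sac triangles (current coords)
sac_mean_speed <- function(mesh, tris, v) {
  a <- abs(tri_areas(mesh))[tris]
  tt <- mesh$tri[tris, , drop = FALSE]
  sp <- sqrt(rowSums(v^2))
  vt <- (sp[tt[, 1]] + sp[tt[, 2]] + sp[tt[, 3]]) / 3
  sum(a * vt) / sum(a)
}

#' Run the two-cycle protocol on a 2D case
#'
#' @param case [make_case_2d()] geometry
#' @param cfg [protocol_config()]
#' @param waveform [build_waveform()]
#' @param coupling [coupling_config()] (compliant mode)
#' @param quiet suppress progress output
#' @return `field_series`: step histories (flow rates, sac area and mean
#'   speed, iteration counts), wall-traction series over the averaging
#'   window, velocity/pressure snapshots at the configured stride
#' @export
run_protocol <- function(case, cfg = protocol_config(), waveform = build_waveform(),
                         coupling = coupling_config(), quiet = TRUE) {
  stopifnot(inherits(case, "case_geometry"))
  rigid <- cfg$mode == "rigid"
  mesh0 <- case$fluid
  wall_idx <- case$wall_fluid_idx
  fstate <- fluid_state(mesh0)
  ctx <- if (!rigid) fsi_context(case)
  sstate <- if (!rigid) solid_state_init(ctx$solid)
  coords <- mesh0$nodes
  nsteps <- round(cfg$t_end / cfg$dt)
  hist <- data.frame(t = numeric(nsteps), q_in = NA_real_, q_out = NA_real_,
                     sac_area = NA_real_, sac_speed = NA_real_,
                     iters = NA_real_)
  wall_times <- c(); wall_trac <- list(); wall_force <- list()
  wall_coords <- list()
  snap_times <- c(); snaps <- list()
  zero_wall <- matrix(0, length(wall_idx), 2)

  for (s in seq_len(nsteps)) {
    t_new <- s * cfg$dt
    if (rigid) {
      vin <- apply_inlet(waveform, t_new, case$inlet)
      dir_idx <- c(case$inlet$idx, wall_idx)
      dir_v <- rbind(vin, zero_wall)
      dup <- duplicated(dir_idx, fromLast = TRUE)
      bc <- list(dirichlet = list(idx = dir_idx[!dup],
                                  v = dir_v[!dup, , drop = FALSE]),
                 outlet = list(tag = case$outlet_tag,
                               model = case$outlet_model %||% outlet_model(),
                               scale = min(t_new / cfg$ramp, 1)),
                 f = c(0, 0))
      fstate <- advance_fluid(mesh0, fstate, cfg$dt, bc, case$props_f)
      fstate$wall <- wall_traction(fstate, mesh0, wall_idx)
      iters <- fstate$picard_iters
      mesh_cur <- mesh0
    } else {
      st <- coupling_step(ctx, fstate, sstate, coords, t_new, cfg$dt,
                          waveform, coupling, scheme = cfg$solid_scheme)
      fstate <- st$fstate; sstate <- st$sstate; coords <- st$coords
      iters <- st$iters
      mesh_cur <- mesh0; mesh_cur$nodes <- coords
    }
    hist$t[s] <- t_new
    hist$q_in[s] <- -boundary_flux(mesh_cur, fstate$v, "inlet")
    hist$q_out[s] <- boundary_flux(mesh_cur, fstate$v, "outlet")
    if (length(case$sac_tris)) {
      hist$sac_area[s] <- sum(abs(tri_areas(mesh_cur))[case$sac_tris])
      hist$sac_speed[s] <- sac_mean_speed(mesh_cur, case$sac_tris, fstate$v)
    }
    hist$iters[s] <- iters
    in_win <- t_new >= cfg$window[1] - 1e-12 & t_new <= cfg$window[2] + 1e-12
    if (in_win) {
      wall_times <- c(wall_times, t_new)
      wall_trac[[length(wall_trac) + 1]] <- fstate$wall$traction
      wall_force[[length(wall_force) + 1]] <- fstate$wall$force
      wall_coords[[length(wall_coords) + 1]] <- mesh_cur$nodes[wall_idx, ,
                                                               drop = FALSE]
      if ((s %% cfg$snapshot_stride) == 0 || t_new >= cfg$t_end - 1e-12) {
        snap_times <- c(snap_times, t_new)
        snaps[[length(snaps) + 1]] <- list(v = fstate$v, p = fstate$p,
                                           coords = mesh_cur$nodes)
      }
    }
    if (!quiet && (s %% 50 == 0))
      message(sprintf("  t = %.3f s (%d/%d), iters %d", t_new, s, nsteps, iters))
  }
  structure(list(
    mode = cfg$mode, cfg = cfg, case = case,
    hist = hist,
    wall = list(times = wall_times, idx = wall_idx,
                traction = wall_trac, force = wall_force,
                coords = wall_coords,
                lengths = nodal_boundary_length(mesh0, "fsi")[wall_idx]),
    snaps = list(times = snap_times, data = snaps),
    final_fluid = fstate,
    final_solid = if (!rigid) sstate), class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("field_series (%s): %d steps to t = %g s; window [%g, %g] s\n",
              x$mode, nrow(x$hist), max(x$hist$t),
              x$cfg$window[1], x$cfg$window[2]))
  win <- x$hist$t >= x$cfg$window[1]
  cat(sprintf("  window-mean Q_in %.3f cm^2/s eq.; sac area %.3f mm^2; sac speed %.4f m/s\n",
              mean(x$hist$q_in[win]) * 1e4, mean(x$hist$sac_area[win]),
              mean(x$hist$sac_speed[win])))
  invisible(x)
}

#' Sac area pulsation over the averaging window
#' @param fs `field_series`
#' @return percent pulsation 100*(max-min)/min of the sac area
#' @export
sac_pulsation <- function(fs) {
  win <- fs$hist$t >= fs$cfg$window[1] - 1e-12
  a <- fs$hist$sac_area[win]
  100 * (max(a) - min(a)) / min(a)
}
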