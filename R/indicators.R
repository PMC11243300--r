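# Haemodynamic risk indicators ----------------------------------------------
#
# WSS is the tangential wall traction tau = t - (t.n)n, reported by Euclidean
# norm; TAWSS its time average over the window; OSI = 0.5(1 - |int tau|/int
# |tau|) in [0, 0.5] (0 at zero-shear nodes by convention). The sac battery
# (KER, VDR, HSA/LSA, ICI, SCI) follows the standard aneurysm-haemodynamics
# definitions on the sac region above the cut plane, with the parent-artery
# wall (minus a 2 mm buffer at the in/outflow planes) as reference.

#' Time-averaged WSS and oscillatory shear index per node
#'
#' @param series list with `times` (strictly increasing, spanning the
#'   averaging window) and `tau` (list of W x 2 tangential-traction matrices,
#'   Pa, one per time)
#' @return data.frame(tawss, osi) with one row per wall node
#' @export
compute_tawss_osi <- function(series) {
  tt <- series$times
  stopifnot(length(tt) >= 2, all(diff(tt) > 0))
  W <- nrow(series$tau[[1]])
  Tn <- tt[length(tt)] - tt[1]
  wts <- trapz_weights(tt)
  mag_int <- numeric(W); vec_int <- matrix(0, W, ncol(series$tau[[1]]))
  for (k in seq_along(tt)) {
    tau <- series$tau[[k]]
    mag_int <- mag_int + wts[k] * sqrt(rowSums(tau^2))
    vec_int <- vec_int + wts[k] * tau
  }
  tawss <- mag_int / Tn
  osi <- ifelse(mag_int > 0,
                0.5 * (1 - sqrt(rowSums(vec_int^2)) / mag_int), 0)
  data.frame(tawss = tawss, osi = pmin(pmax(osi, 0), 0.5))
}

trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  w[1] <- (t[2] - t[1]) / 2
  w[n] <- (t[n] - t[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  w
}

# tangential part of wall traction given outward wall normals
tangential_traction <- function(traction, normals) {
  tn <- rowSums(traction * normals)
  traction - normals * tn
}

# outward fluid normals at wall nodes (averaged adjacent-edge normals)
wall_normals <- function(mesh, idx, tags = "fsi") {
  sel <- mesh$bnd$tag %in% tags
  a <- mesh$bnd$n1[sel]; b <- mesh$bnd$n2[sel]
  dx <- mesh$nodes[b, 1] - mesh$nodes[a, 1]
  dy <- mesh$nodes[b, 2] - mesh$nodes[a, 2]
  nrm <- matrix(0, nrow(mesh$nodes), 2)
  for (k in seq_along(a)) {
    e <- c(dy[k], -dx[k])                       # outward (domain left of edge)
    nrm[a[k], ] <- nrm[a[k], ] + e
    nrm[b[k], ] <- nrm[b[k], ] + e
  }
  out <- nrm[idx, , drop = FALSE]
  out / pmax(sqrt(rowSums(out^2)), 1e-300)
}

#' Wall-shear series of a protocol run
#'
#' Projects the stored wall-traction history onto the wall tangent plane,
#' using the deformed wall geometry of each sample (a fixed reference normal
#' would leak a slice of the kPa-level pressure into the Pa-level shear on a
#' compliant wall).
#'
#' @param fs `field_series` from [run_protocol()]
#' @return list(times, tau, idx, lengths) usable by [compute_tawss_osi()]
#' @export
wall_shear_series <- function(fs) {
  mesh <- fs$case$fluid
  idx <- fs$wall$idx
  tau <- vector("list", length(fs$wall$times))
  for (k in seq_along(tau)) {
    mk <- mesh
    if (length(fs$wall$coords))
      mk$nodes[idx, ] <- fs$wall$coords[[k]]
    nrm <- wall_normals(mk, idx)
    tau[[k]] <- tangential_traction(fs$wall$traction[[k]], nrm)
  }
  list(times = fs$wall$times, tau = tau, idx = idx,
       lengths = fs$wall$lengths)
}

#' Sac mask over wall nodes and fluid elements
#'
#' @param case `case_geometry`
#' @param cut_height_mm sac cut plane (mm)
#' @param buffer_mm parent-wall exclusion buffer near the in/outflow planes
#' @return list: wall-node masks `sac`/`parent` (into `case$wall_fluid_idx`),
#'   element masks `sac_tris`/`parent_tris`
#' @export
sac_mask <- function(case, cut_height_mm = case$params$cut_height,
                     buffer_mm = 2) {
  widx <- case$wall_fluid_idx
  y <- case$fluid$nodes[widx, 2]
  sac <- y > cut_height_mm
  if (!any(sac)) abort_sf("empty sac mask", "sacflow_mask_error")
  th <- atan2(case$fluid$nodes[widx, 2], case$fluid$nodes[widx, 1])
  r <- sqrt(rowSums(case$fluid$nodes[widx, , drop = FALSE]^2))
  dth <- buffer_mm / r                           # arc-length buffer
  parent <- !sac & th > case$params$theta[1] + dth &
    th < case$params$theta[2] - dth
  cy <- colMeans(matrix(case$fluid$nodes[as.vector(t(case$fluid$tri)), 2],
                        nrow = 3))
  ctheta <- atan2(cy, colMeans(matrix(
    case$fluid$nodes[as.vector(t(case$fluid$tri)), 1], nrow = 3)))
  sac_tris <- which(cy > cut_height_mm)
  parent_tris <- which(cy <= cut_height_mm &
                         ctheta > case$params$theta[1] + buffer_mm / 6 &
                         ctheta < case$params$theta[2] - buffer_mm / 6)
  list(wall_sac = sac, wall_parent = parent,
       sac_tris = sac_tris, parent_tris = parent_tris)
}

#' Weighted reduction of nodal/element fields over a mask
#'
#' @param values numeric vector
#' @param weights non-negative weights (areas or lengths)
#' @param mask logical or index vector
#' @return list(mean, max, min) weighted mean and plain extrema over the mask
#' @export
sac_reduce <- function(values, weights, mask) {
  v <- values[mask]; w <- weights[mask]
  if (!length(v)) abort_sf("empty mask in sac_reduce", "sacflow_mask_error")
  list(mean = sum(v * w) / sum(w), max = max(v), min = min(v))
}

# per-element velocity gradient components (constant per P1 triangle), SI
elem_velocity_grad <- function(mesh, v) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE] * MM
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE] * MM
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE] * MM
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  gx <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  gy <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  vx <- matrix(v[mesh$tri, 1], ncol = 3); vy <- matrix(v[mesh$tri, 2], ncol = 3)
  list(dvxdx = rowSums(gx * vx), dvxdy = rowSums(gy * vx),
       dvydx = rowSums(gx * vy), dvydy = rowSums(gy * vy))
}

#' Full indicator battery for one protocol run
#'
#' TAWSS/OSI statistics over the sac wall, sac-average velocity, and the
#' sac-to-parent ratios: KER (kinetic energy density), VDR (viscous
#' dissipation density 2 mu eps:eps), HSA/LSA (sac wall fraction above/below
#' parent mean +/- 1 SD of TAWSS), ICI (ostium inflow concentration), SCI
#' (shear concentration on the high-WSS sac wall region).
#'
#' @param fs `field_series`
#' @param cut_height_mm sac cut plane (mm)
#' @param hi_lo_k threshold multiplier on the parent TAWSS SD
#' @return object of class `indicator_set` (named list of scalars; undefined
#'   indicators are NA with names listed in `attr(, "undefined")`)
#' @export
compute_flow_indicators <- function(fs, cut_height_mm = fs$case$params$cut_height,
                                    hi_lo_k = 1) {
  case <- fs$case
  msk <- sac_mask(case, cut_height_mm)
  ws <- wall_shear_series(fs)
  to <- compute_tawss_osi(ws)
  L <- ws$lengths
  undefined <- character()

  s_tawss <- sac_reduce(to$tawss, L, msk$wall_sac)
  s_osi <- sac_reduce(to$osi, L, msk$wall_sac)
  # parent wall TAWSS statistics (length-weighted)
  pw <- msk$wall_parent
  mu_p <- sum(to$tawss[pw] * L[pw]) / sum(L[pw])
  var_p <- sum(L[pw] * (to$tawss[pw] - mu_p)^2) / sum(L[pw])
  sd_p <- sqrt(var_p)
  hi_thr <- mu_p + hi_lo_k * sd_p
  lo_thr <- max(mu_p - hi_lo_k * sd_p, 0)
  sacL <- L[msk$wall_sac]; sacT <- to$tawss[msk$wall_sac]
  HSA <- sum(sacL[sacT > hi_thr]) / sum(sacL)
  LSA <- sum(sacL[sacT < lo_thr]) / sum(sacL)
  # SCI on the high-WSS sac region
  Fh <- sum(sacL[sacT > hi_thr] * sacT[sacT > hi_thr])
  Ftot <- sum(sacL * sacT)
  SCI <- if (HSA > 0 && Ftot > 0) (Fh / Ftot) / HSA else {
    undefined <- c(undefined, "SCI"); NA_real_
  }

  # volume ratios from snapshots
  mesh <- case$fluid
  A_el <- abs(tri_areas(mesh))
  ke_sac <- ke_par <- diss_sac <- diss_par <- 0
  mu <- case$props_f$mu
  ici_num <- ici_den <- 0; n_snap <- length(fs$snaps$data)
  chord <- ostium_edges(case)
  for (k in seq_len(n_snap)) {
    sn <- fs$snaps$data[[k]]
    mcur <- mesh; mcur$nodes <- sn$coords
    Ac <- abs(tri_areas(mcur))
    sp2 <- rowSums(sn$v^2)
    el_ke <- (sp2[mesh$tri[, 1]] + sp2[mesh$tri[, 2]] + sp2[mesh$tri[, 3]]) / 6
    g <- elem_velocity_grad(mcur, sn$v)
    diss <- 2 * mu * (g$dvxdx^2 + g$dvydy^2 + 0.5 * (g$dvxdy + g$dvydx)^2)
    ke_sac <- ke_sac + sum(Ac[msk$sac_tris] * el_ke[msk$sac_tris]) /
      sum(Ac[msk$sac_tris])
    ke_par <- ke_par + sum(Ac[msk$parent_tris] * el_ke[msk$parent_tris]) /
      sum(Ac[msk$parent_tris])
    diss_sac <- diss_sac + sum(Ac[msk$sac_tris] * diss[msk$sac_tris]) /
      sum(Ac[msk$sac_tris])
    diss_par <- diss_par + sum(Ac[msk$parent_tris] * diss[msk$parent_tris]) /
      sum(Ac[msk$parent_tris])
    # ostium inflow concentration
    fl <- ostium_fluxes(mcur, sn$v, chord)
    qp <- abs(boundary_flux(mcur, sn$v, "inlet"))
    pos <- fl$flux > 0
    if (any(pos) && qp > 0) {
      q_in_ost <- sum(fl$flux[pos]); l_in <- sum(fl$len[pos])
      ici_num <- ici_num + (q_in_ost / qp)
      ici_den <- ici_den + (l_in / sum(fl$len))
    }
  }
  KER <- (ke_sac / n_snap) / (ke_par / n_snap)
  VDR <- (diss_sac / n_snap) / (diss_par / n_snap)
  ICI <- if (ici_den > 0) (ici_num / n_snap) / (ici_den / n_snap) else {
    undefined <- c(undefined, "ICI"); NA_real_
  }
  win <- fs$hist$t >= fs$cfg$window[1] - 1e-12
  out <- list(TAWSS_mean = s_tawss$mean, TAWSS_max = s_tawss$max,
              TAWSS_min = s_tawss$min, OSI_mean = s_osi$mean,
              OSI_max = s_osi$max, v_sac = mean(fs$hist$sac_speed[win]),
              KER = KER, VDR = VDR, HSA = HSA, LSA = LSA, ICI = ICI,
              SCI = SCI)
  structure(out, class = "indicator_set", undefined = undefined)
}

# ostium (neck chord) interior edges: node pairs on the chord line
ostium_edges <- function(case) {
  yA <- case$params$chord_y; w2 <- case$params$neck_width / 2
  nn <- case$fluid$nodes
  on_chord <- which(abs(nn[, 2] - yA) < 1e-6 & abs(nn[, 1]) <= w2 + 1e-6)
  on_chord <- on_chord[order(nn[on_chord, 1])]
  cbind(on_chord[-length(on_chord)], on_chord[-1])
}

# per-edge flux through the ostium, positive into the sac (+y), SI m^2/s
ostium_fluxes <- function(mesh, v, edges) {
  a <- edges[, 1]; b <- edges[, 2]
  len <- sqrt(rowSums((mesh$nodes[b, , drop = FALSE] -
                       mesh$nodes[a, , drop = FALSE])^2)) * MM
  vy <- 0.5 * (v[a, 2] + v[b, 2])
  list(flux = vy * len, len = len)
}

#' @export
print.indicator_set <- function(x, ...) {
  cat("indicator_set:\n")
  for (nm in names(x)) cat(sprintf("  %-10s %.5g\n", nm, x[[nm]]))
  ud <- attr(x, "undefined")
  if (length(ud)) cat("  undefined:", paste(ud, collapse = ", "), "\n")
  invisible(x)
}

#' Relative change between rigid and compliant indicator sets
#'
#' Delta% = 100 (compliant - rigid)/rigid per indicator; positive means the
#' compliant value is larger. Indicators with a zero rigid value are flagged
#' undefined and excluded from cohort statistics.
#'
#' @param ind_rigid,ind_compliant `indicator_set`s or named numeric vectors
#' @param zero_tol rigid magnitudes below this floor count as zero: the
#'   relative change of an indicator at solver-noise level is meaningless
#' @return object of class `delta_report`: named percentage vector with
#'   attribute `undefined`
#' @export
relative_change <- function(ind_rigid, ind_compliant, zero_tol = 1e-10) {
  r <- unlist(ind_rigid); c_ <- unlist(ind_compliant)
  stopifnot(identical(names(r), names(c_)))
  out <- 100 * (c_ - r) / r
  und <- names(r)[abs(r) <= zero_tol | is.na(r) | is.na(c_)]
  out[names(out) %in% und] <- NA_real_
  structure(out, class = "delta_report", undefined = und)
}

#' @export
print.delta_report <- function(x, ...) {
  cat("relative changes (compliant vs rigid), %:\n")
  y <- unclass(x)
  for (nm in names(y)) cat(sprintf("  %-10s %+.2f%%\n", nm, y[[nm]]))
  invisible(x)
}
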