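# Braided flow-diverter analog ----------------------------------------------
#
# Deployment is a parametric counter-wound helix braid mapped onto the
# luminal torus surface (24 + 24 wires of 40 um at defaults).  On the outer
# wall the axial metric stretches by (R_c + a cos phi)/R_c, so the local
# braid angle and hence the porosity vary across the neck patch; the pitch
# is calibrated so the patch-mean porosity hits the target.  In 2D the
# device appears as equally spaced wire cross-sections along the neck chord,
# immersed into the fluid mesh by node removal with local refinement.

#' Braided flow-diverter parameters
#'
#' @param n_wires total wire count (even; half per winding direction)
#' @param wire_diameter_um wire thickness (um)
#' @param device_diameter_mm nominal device diameter (mm)
#' @param pitch_mm braid pitch (centerline length per full turn, mm); NULL
#'   lets [deploy_braid()] calibrate it to `target_porosity` over the patch
#' @param covered_arc_deg centerline arc kept around the neck
#' @param target_porosity neck-patch mean porosity used for calibration
#' @return `braid_spec`
#' @export
braid_spec <- function(n_wires = 48, wire_diameter_um = 40,
                       device_diameter_mm = 4, pitch_mm = NULL,
                       covered_arc_deg = 40, target_porosity = 0.69) {
  if (n_wires %% 2 != 0 || n_wires <= 0 || wire_diameter_um <= 0)
    abort_sf("braid needs an even positive wire count and positive diameter",
             "sacflow_parameter_error")
  structure(list(n_wires = n_wires, wire_d = wire_diameter_um * 1e-3,
                 device_diameter = device_diameter_mm, pitch = pitch_mm,
                 covered_arc = covered_arc_deg,
                 target_porosity = target_porosity), class = "braid_spec")
}

# local per-family metal fraction at tube angle phi (phi = 0: outer equator)
braid_family_fraction <- function(spec, Rc, a, phi, pitch) {
  dc <- 2 * pi * a / (spec$n_wires / 2)        # circumferential spacing
  m <- 2 * pi * a * Rc / (pitch * (Rc + a * cos(phi)))  # local wire slope
  (spec$wire_d / dc) * sqrt(1 + m^2)
}

#' Deploy the braid on the toroidal artery wall
#'
#' Counter-wound helices apposed to the luminal surface (wire centerlines at
#' tube radius a - d/2), truncated to the neck-covering arc. A NULL pitch is
#' calibrated so the patch-mean analytic porosity equals the spec target.
#'
#' @param artery `artery_surface` (or a list with `params` as in
#'   [make_artery()])
#' @param spec [braid_spec()]
#' @param n_samples points per wire
#' @param patch_phi_half_deg patch half-extent in tube angle used for
#'   calibration
#' @return list of wire polylines (n x 3 matrices, mm); attributes `spec`
#'   (with the realized pitch) and `artery_params`
#' @export
deploy_braid <- function(artery, spec, n_samples = 200,
                         patch_phi_half_deg = 18) {
  pr <- artery$params
  a <- pr$tube_diameter / 2 - spec$wire_d / 2
  Rc <- pr$centerline_radius
  pitch <- spec$pitch
  if (is.null(pitch)) {
    phh <- patch_phi_half_deg * pi / 180
    phig <- seq(-phh, phh, length.out = 41)
    por_of <- function(P)
      mean((1 - pmin(braid_family_fraction(spec, Rc, a, phig, P), 1))^2)
    lo <- 0.5; hi <- 200
    if (por_of(hi) < spec$target_porosity)
      abort_sf("target porosity unreachable even at very large pitch",
               "sacflow_parameter_error")
    pitch <- uniroot(function(P) por_of(P) - spec$target_porosity,
                     c(lo, hi), tol = 1e-10)$root
  }
  if (braid_family_fraction(spec, Rc, a, pi, pitch) >= 1)
    abort_sf("braid pitch too small: wires overlap", "sacflow_parameter_error")
  spec$pitch <- pitch
  th_c <- pi / 2
  half <- spec$covered_arc * pi / 180 / 2
  th <- seq(th_c - half, th_c + half, length.out = n_samples)
  s <- Rc * (th - th_c)
  nw <- spec$n_wires / 2
  wires <- vector("list", spec$n_wires)
  k <- 0
  for (dir_ in c(1, -1)) for (i in seq_len(nw)) {
    phi0 <- 2 * pi * (i - 1) / nw + (dir_ == -1) * pi / nw
    phi <- phi0 + dir_ * 2 * pi * s / pitch
    r <- Rc + a * cos(phi)
    k <- k + 1
    wires[[k]] <- cbind(r * cos(th), r * sin(th), a * sin(phi))
  }
  attr(wires, "spec") <- spec
  attr(wires, "artery_params") <- pr
  wires
}

#' Porosity of the braid over the neck patch
#'
#' Analytic route: porosity = (1 - f)^2 with the local per-family coverage
#' f(phi) = (d / dc) sqrt(1 + m(phi)^2), dc the circumferential wire
#' spacing and m the local wire slope; averaged over the patch. Sampled
#' route: dense grid in the flattened (arc length, circumference) strip
#' against the wire stripes. The report carries both and the local range.
#'
#' @param wires [deploy_braid()] result
#' @param patch list(theta_half_deg, phi_half_deg) half-extents about the
#'   apex (defaults match a ~2 mm neck on the outer wall)
#' @param n_grid sampling resolution per direction
#' @return `porosity_report`
#' @export
compute_porosity <- function(wires, patch = list(theta_half_deg = 8,
                                                 phi_half_deg = 18),
                             n_grid = 500) {
  if (length(wires) == 0)
    return(structure(list(analytic = 1, sampled = 1, range = c(1, 1),
                          pitch = NA), class = "porosity_report"))
  spec <- attr(wires, "spec"); pr <- attr(wires, "artery_params")
  if (is.null(spec) || is.null(spec$pitch))
    abort_sf("wires lack braid metadata", "sacflow_parameter_error")
  a <- pr$tube_diameter / 2 - spec$wire_d / 2
  Rc <- pr$centerline_radius
  thh <- patch$theta_half_deg * pi / 180
  phh <- patch$phi_half_deg * pi / 180
  phig <- seq(-phh, phh, length.out = 61)
  f_loc <- braid_family_fraction(spec, Rc, a, phig, spec$pitch)
  por_loc <- (1 - pmin(f_loc, 1))^2
  analytic <- mean(por_loc)

  nw <- spec$n_wires / 2
  thg <- seq(-thh, thh, length.out = n_grid)
  TH <- matrix(thg, n_grid, length(phig))
  PH <- matrix(phig, n_grid, length(phig), byrow = TRUE)
  m_loc <- 2 * pi * a * Rc / (spec$pitch * (Rc + a * cos(PH)))
  metal <- matrix(FALSE, n_grid, length(phig))
  for (dir_ in c(1, -1)) {
    off <- if (dir_ == -1) 0.5 else 0
    u <- (PH - dir_ * 2 * pi * Rc * TH / spec$pitch) / (2 * pi / nw) - off
    du_c <- abs(u - round(u)) * (2 * pi / nw) * a   # circumferential offset
    dperp <- du_c / sqrt(1 + m_loc^2)
    metal <- metal | (dperp <= spec$wire_d / 2)
  }
  sampled <- 1 - mean(metal)
  structure(list(analytic = analytic, sampled = sampled,
                 range = range(por_loc), pitch = spec$pitch),
            class = "porosity_report")
}

#' @export
print.porosity_report <- function(x, ...) {
  cat(sprintf(
    "porosity: analytic %.3f (local range %.3f-%.3f), sampled %.3f, pitch %.3g mm\n",
    x$analytic, x$range[1], x$range[2], x$sampled, x$pitch))
  invisible(x)
}

#' Linear porosity of the 2D wire row
#' @param n number of wire cross-sections
#' @param d_mm wire diameter (mm)
#' @param l_mm neck length (mm)
#' @return 1 - n d / L
#' @export
porosity_2d <- function(n, d_mm, l_mm) 1 - n * d_mm / l_mm

#' Immerse 2D wire cross-sections into a fluid mesh
#'
#' Removes the nodes inside the strut circles (and the triangles touching
#' them); the resulting hole boundaries are tagged "stent" (no-slip).
#'
#' @param mesh tagged `mesh2d`
#' @param wires data.frame(x, y, r) circle centers and radii (mm); empty or
#'   NULL returns the mesh unchanged
#' @param dilate fraction of the local spacing added to the removal radius,
#'   the strut-fitting margin: node removal alone leaves the staircase hole
#'   under-resolved, so the boundary is pushed out by a grid-cell fraction,
#'   mirroring how mesh adaptation fits cells to the wire surface
#' @return `mesh2d` with strut holes and updated tags
#' @export
immerse_2d <- function(mesh, wires, dilate = 0.65) {
  if (is.null(wires) || nrow(wires) == 0) return(mesh)
  if (nrow(wires) > 1) {
    dd <- as.matrix(stats::dist(wires[, c("x", "y")]))
    diag(dd) <- Inf
    if (min(dd) < (max(wires$r) * 2))
      abort_sf("overlapping wire cross-sections", "sacflow_parameter_error")
  }
  nn <- mesh$nodes
  remove <- logical(nrow(nn))
  for (k in seq_len(nrow(wires))) {
    d2 <- (nn[, 1] - wires$x[k])^2 + (nn[, 2] - wires$y[k])^2
    near <- d2 < (4 * wires$r[k])^2
    if (!any(near)) next
    h_loc <- local_spacing(mesh, which(near))
    remove <- remove | d2 < (wires$r[k] + dilate * h_loc)^2
  }
  keep_tri <- !(remove[mesh$tri[, 1]] | remove[mesh$tri[, 2]] |
                  remove[mesh$tri[, 3]])
  tri2 <- mesh$tri[keep_tri, , drop = FALSE]
  used <- sort(unique(as.vector(tri2)))
  map <- integer(nrow(nn)); map[used] <- seq_along(used)
  m2 <- mesh2d(nn[used, , drop = FALSE], matrix(map[tri2], ncol = 3))
  # re-tag: previous boundary edges keep their tag, new edges are stent holes
  old_mid <- (mesh$nodes[mesh$bnd$n1, , drop = FALSE] +
              mesh$nodes[mesh$bnd$n2, , drop = FALSE]) / 2
  e <- boundary_edges(m2)
  mid <- (m2$nodes[e[, 1], , drop = FALSE] + m2$nodes[e[, 2], , drop = FALSE]) / 2
  nnx <- nearest_idx(cbind(mid, 0), cbind(old_mid, 0))
  d_old <- sqrt(rowSums((mid - old_mid[nnx, , drop = FALSE])^2))
  tag <- ifelse(d_old < 1e-9, mesh$bnd$tag[nnx], "stent")
  m2$bnd <- data.frame(n1 = e[, 1], n2 = e[, 2], tag = tag,
                       stringsAsFactors = FALSE)
  attr(m2, "n_removed_nodes") <- sum(remove)
  m2
}

# median incident edge length around a node subset
local_spacing <- function(mesh, idx) {
  sel <- mesh$tri[, 1] %in% idx | mesh$tri[, 2] %in% idx |
    mesh$tri[, 3] %in% idx
  tt <- mesh$tri[sel, , drop = FALSE]
  if (!nrow(tt)) return(0)
  e <- rbind(tt[, 1:2], tt[, 2:3], tt[, c(3, 1)])
  stats::median(sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                              mesh$nodes[e[, 2], , drop = FALSE])^2)))
}

#' Hole boundary loops of a stented mesh
#' @param mesh stented `mesh2d`
#' @return list of ordered node-index loops tagged "stent"
#' @export
stent_hole_loops <- function(mesh) {
  sel <- mesh$bnd$tag == "stent"
  if (!any(sel)) return(list())
  be <- mesh$bnd[sel, ]
  nxt <- setNames(be$n2, as.character(be$n1))
  loops <- list(); used <- rep(FALSE, nrow(be))
  while (any(!used)) {
    s <- be$n1[which(!used)[1]]
    loop <- s; cur <- s
    repeat {
      used[match(cur, be$n1)] <- TRUE
      nx <- nxt[as.character(cur)]
      if (is.na(nx) || nx == s) break
      cur <- nx
      loop <- c(loop, cur)
      if (length(loop) > nrow(be) + 1) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}
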