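# 2D computational domains --------------------------------------------------
#
# The desk-scale analog of the 3D configuration is its mid-plane cut: a curved
# channel (annular sector, inner radius 4 mm, outer radius 8 mm so the outer
# wall apex sits at y = 8 mm) carrying a circular-arc sac mounted over a neck
# opening at the apex.  The sac dome is the arc of a circle through the neck
# endpoints; the fluid sac block is a structured fan, conforming to the
# channel block along the neck chord.  Wall strips (4 layers, 0.25 mm total)
# are extruded outward for the solid.

#' Boundary-layer thickness sequence
#'
#' Geometric progression t_k = first * ratio^(k-1).
#'
#' @param n_bl number of layers
#' @param first first-layer thickness (mm default 0.02 = 20 um)
#' @param ratio growth ratio (default 1.2)
#' @return vector of layer thicknesses (mm)
#' @export
bl_thicknesses <- function(n_bl, first = 0.02, ratio = 1.2) {
  stopifnot(n_bl >= 0)
  if (n_bl == 0) return(numeric())
  first * ratio^(seq_len(n_bl) - 1)
}

# 1D breakpoints across a span with BL stacks at one/both ends and a uniform
# core of size <= core_size. Returns increasing breakpoints from 0 to span.
spacing_1d <- function(span, core_size, n_bl = 0, bl_first = 0.02,
                       bl_ratio = 1.2, both_ends = TRUE) {
  t_bl <- bl_thicknesses(n_bl, bl_first, bl_ratio)
  lo <- cumsum(c(0, t_bl))
  hi <- if (both_ends) span - rev(lo) else span
  core_span <- (if (both_ends) hi[1] else span) - lo[length(lo)]
  if (core_span <= 0)
    abort_sf("boundary layers collide: span too narrow for the BL stack",
             "sacflow_mesh_error")
  n_core <- max(1, ceiling(core_span / core_size))
  core <- lo[length(lo)] + core_span * seq(0, 1, length.out = n_core + 1)
  pts <- if (both_ends) c(lo, core[-1], hi[-1]) else c(lo, core[-1])
  unique(pts)
}

#' Rectangular channel mesh
#'
#' @param lx,ly dimensions (mm)
#' @param sx,sy breakpoint vectors (mm, from [spacing_1d()]) or cell counts
#' @return tagged `mesh2d`: left "inlet", right "outlet", top/bottom "wall"
#' @export
mesh_rectangle <- function(lx, ly, sx, sy) {
  if (length(sx) == 1) sx <- seq(0, lx, length.out = sx + 1)
  if (length(sy) == 1) sy <- seq(0, ly, length.out = sy + 1)
  X <- outer(sx, rep(1, length(sy)))
  Y <- outer(rep(1, length(sx)), sy)
  g <- grid_to_tri(X, Y)
  m <- mesh2d(g$nodes, g$tri)
  tol <- 1e-9
  tag_boundary(m, list(
    inlet  = function(p) p[, 1] < tol,
    outlet = function(p) p[, 1] > lx - tol))
}

#' Desk-scale sidewall-aneurysm case (2D cut)
#'
#' @param r_inner,r_outer channel wall radii (mm); defaults 4 and 8 put the
#'   outer-wall apex at y = 8 mm with a 4 mm vessel
#' @param theta_deg angular extent (degrees), apex at 90
#' @param neck_width_mm neck chord width (mm)
#' @param sac_radius_mm dome circle radius (mm); must exceed neck_width/2
#' @param m_neck number of chord intervals (even)
#' @param n_phi sac fan rays
#' @param n_side channel cells on each side of the neck
#' @param n_bl,bl_first,bl_ratio radial boundary-layer controls (mm)
#' @param core_size radial core cell size (mm)
#' @param wall_thickness_mm,wall_layers solid shell extrusion controls
#' @param cut_height_mm sac cut plane (mm) used for region stiffness
#' @param props_f,props_s fluid/solid properties
#' @return object of class `case_geometry`
#' @export
make_case_2d <- function(r_inner = 4, r_outer = 8, theta_deg = c(40, 140),
                         neck_width_mm = 2, sac_radius_mm = 1.8,
                         m_neck = 12, n_phi = 24, n_side = 12,
                         n_bl = 3, bl_first = 0.06, bl_ratio = 1.2,
                         core_size = 0.45,
                         wall_thickness_mm = 0.25, wall_layers = 4,
                         cut_height_mm = 8,
                         props_f = fluid_properties(),
                         props_s = solid_properties(),
                         stent_refine = NULL) {
  stopifnot(r_outer > r_inner, sac_radius_mm > neck_width_mm / 2,
            m_neck %% 2 == 0)
  th0 <- theta_deg[1] * pi / 180; th1 <- theta_deg[2] * pi / 180
  w2 <- neck_width_mm / 2
  delta <- asin(w2 / r_outer)
  thB <- pi / 2 - delta; thA <- pi / 2 + delta
  yA <- r_outer * cos(delta)                      # chord height
  q <- c(0, yA)                                   # fan center (chord midpoint)
  ee <- sqrt(sac_radius_mm^2 - w2^2)
  cc <- c(0, yA + ee)                             # dome circle center

  # channel theta array: sides + neck columns at prescribed chord abscissae
  xk <- seq(w2, -w2, length.out = m_neck + 1)     # ascending theta
  th_neck <- atan2(yA, xk)
  if (is.null(stent_refine)) {
    th_lo <- seq(th0, thB, length.out = n_side + 1)
    th_hi <- seq(thA, th1, length.out = n_side + 1)
  } else {
    h_th <- mean(diff(th_neck))
    h_max <- core_size / r_outer
    g_lo <- sort(graded_breaks(0, thB - th0, h_th, stent_refine$ratio, h_max))
    th_lo <- th0 + g_lo                       # fine at thB
    g_hi <- sort(graded_breaks(0, th1 - thA, h_th, stent_refine$ratio, h_max))
    th_hi <- thA + (th1 - thA) - rev(g_hi)    # fine at thA
  }
  th <- c(th_lo, th_neck[-1], th_hi[-1])

  # outer boundary radius: circle outside the neck, chord within
  r_out_fun <- function(t) ifelse(t > thB + 1e-12 & t < thA - 1e-12,
                                  yA / sin(t), r_outer)
  span_r <- r_outer - r_inner
  s_mm <- spacing_1d(span_r, core_size, n_bl, bl_first, bl_ratio,
                     both_ends = TRUE)
  if (!is.null(stent_refine)) {
    depth <- stent_refine$depth %||% 0.06    # fine band below the chord (mm)
    fine <- span_r - rev(seq(0, depth, by = stent_refine$h))
    s_mm <- sort(unique(c(s_mm[s_mm < min(fine) - stent_refine$h / 2], fine)))
  }
  s_norm <- s_mm / span_r
  RO <- r_out_fun(th)
  Rgrid <- outer(RO - r_inner, s_norm) + r_inner  # (n_th x n_r)
  Xc <- Rgrid * cos(th); Yc <- Rgrid * sin(th)
  chan <- grid_to_tri(Xc, Yc)

  # sac fan: rays from q, phi in [0, pi]; ring fractions uniform (m_neck/2)
  n_c <- m_neck / 2
  phi <- seq(0, pi, length.out = n_phi + 1)
  rho <- ee * sin(phi) + sqrt(sac_radius_mm^2 - (ee * cos(phi))^2)
  frac <- seq(0, 1, length.out = n_c + 1)
  Xs <- q[1] + outer(rho * cos(phi), frac)
  Ys <- q[2] + outer(rho * sin(phi), frac)
  sac <- grid_to_tri(t(Xs), t(Ys))    # rows = rings so collapse column works
  fluid <- merge_blocks(list(chan, sac), tol = 1e-7)

  tol <- 1e-6
  on_line <- function(p, tt) {
    d <- p[, 1] * sin(tt) - p[, 2] * cos(tt)     # distance to ray theta = tt
    rr <- sqrt(rowSums(p^2))
    abs(d) < 1e-6 * pmax(rr, 1) & rr > r_inner - 0.5 & rr < r_outer + 0.5
  }
  fluid <- tag_boundary(fluid, list(
    inlet  = function(p) on_line(p, th1),
    outlet = function(p) on_line(p, th0)), default = "fsi")

  nn <- fluid$nodes
  rr <- sqrt(rowSums(nn^2))
  dome_dist <- sqrt((nn[, 1] - cc[1])^2 + (nn[, 2] - cc[2])^2)
  bidx <- sort(unique(c(fluid$bnd$n1, fluid$bnd$n2)))
  is_b <- logical(nrow(nn)); is_b[bidx] <- TRUE

  # ordered wall polylines (for solid extrusion); outer: artery - dome - artery
  ang <- atan2(nn[, 2], nn[, 1])
  inner_idx <- which(is_b & abs(rr - r_inner) < tol)
  inner_idx <- inner_idx[order(ang[inner_idx])]
  out_lo <- which(is_b & abs(rr - r_outer) < tol & out_tol(ang, th0, thB))
  out_lo <- out_lo[order(ang[out_lo])]
  out_hi <- which(is_b & abs(rr - r_outer) < tol & out_tol(ang, thA, th1))
  out_hi <- out_hi[order(ang[out_hi])]
  dome_idx <- which(is_b & abs(dome_dist - sac_radius_mm) < tol &
                      nn[, 2] > yA - tol)
  dang <- atan2(nn[dome_idx, 2] - cc[2], nn[dome_idx, 1] - cc[1])
  dang[dang < -pi / 2] <- dang[dang < -pi / 2] + 2 * pi   # B ~ -56deg ... A ~ 236deg
  dome_idx <- dome_idx[order(dang)]
  # corners A/B live in both the artery arcs and the dome: keep them once
  outer_line <- c(out_lo, setdiff(dome_idx, c(out_lo, out_hi)), out_hi)

  # outward normals
  n_inner <- -nn[inner_idx, ] / rr[inner_idx]
  n_outer <- normals_outer(nn[outer_line, ], cc, sac_radius_mm, r_outer, yA)

  so_i <- extrude_wall_strip(nn[inner_idx, ], n_inner, wall_thickness_mm,
                             wall_layers)
  so_o <- extrude_wall_strip(nn[outer_line, ], n_outer, wall_thickness_mm,
                             wall_layers)
  n_i_nodes <- nrow(so_i$mesh$nodes)
  solid <- merge_blocks(list(so_i$mesh, so_o$mesh), tol = 1e-7)
  # merge must not fuse the two strips
  stopifnot(nrow(solid$nodes) == n_i_nodes + nrow(so_o$mesh$nodes))
  solid_base_idx <- c(so_i$base, so_o$base + n_i_nodes)
  fluid_iface_idx <- c(inner_idx, outer_line)
  # clamp solid nodes on the inlet/outlet planes
  sang <- atan2(solid$nodes[, 2], solid$nodes[, 1])
  fixed <- which(abs(sang - th0) < 1e-9 + 1e-4 | abs(sang - th1) < 1e-9 + 1e-4)

  factors <- assign_regions(solid, cut_height_mm, props_s$artery_factor)
  # Winkler foundation restoring the out-of-plane hoop stiffness lost in the
  # plane cut: k = E_eff/R^2 with R the tube radius (artery) or the dome
  # radius (sac)
  tube_r_m <- (r_outer - r_inner) / 2 * MM
  sac_r_m <- sac_radius_mm * MM
  R_e <- ifelse(factors == 1, sac_r_m, tube_r_m)
  foundation <- factors * props_s$E / R_e^2

  inlet_nodes <- bnd_nodes(fluid, "inlet")
  dir_in <- c(sin(th1), -cos(th1))               # flow toward decreasing theta
  sac_tris <- which(colMeans(matrix(fluid$nodes[as.vector(t(fluid$tri)), 2],
                                    nrow = 3)) > yA + 1e-9)
  structure(list(
    fluid = fluid, solid = solid, solid_fixed = fixed,
    solid_factors = factors, solid_foundation = foundation,
    interface = data.frame(fluid = fluid_iface_idx, solid = solid_base_idx),
    inlet = list(idx = inlet_nodes,
                 coords = fluid$nodes[inlet_nodes, , drop = FALSE],
                 direction = dir_in, diameter_mm = r_outer - r_inner),
    outlet_tag = "outlet",
    sac_tris = sac_tris,
    dome_fluid_idx = dome_idx,
    wall_fluid_idx = fluid_iface_idx,
    params = list(r_inner = r_inner, r_outer = r_outer, theta = c(th0, th1),
                  neck_width = neck_width_mm, sac_radius = sac_radius_mm,
                  chord_y = yA, dome_center = cc, cut_height = cut_height_mm,
                  wall_thickness = wall_thickness_mm,
                  wall_layers = wall_layers),
    props_f = props_f, props_s = props_s,
    dimension = 2), class = "case_geometry")
}

out_tol <- function(ang, a, b) ang > min(a, b) - 1e-9 & ang < max(a, b) + 1e-9

# outward normal for the outer wall polyline: radial on the artery arcs,
# radial-from-dome-center on the dome, blended at the two neck corners
normals_outer <- function(pts, cc, r_sac, r_outer, yA) {
  rr <- sqrt(rowSums(pts^2))
  dome <- abs(sqrt((pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2) - r_sac) <
    1e-6 & pts[, 2] > yA - 1e-6
  art <- abs(rr - r_outer) < 1e-6
  n <- matrix(0, nrow(pts), 2)
  n[art, ] <- pts[art, , drop = FALSE] / rr[art]
  dvec <- cbind(pts[, 1] - cc[1], pts[, 2] - cc[2])
  dlen <- sqrt(rowSums(dvec^2))
  n[dome & !art, ] <- dvec[dome & !art, , drop = FALSE] / dlen[dome & !art]
  corner <- dome & art
  if (any(corner)) {
    blend <- pts[corner, , drop = FALSE] / rr[corner] +
      dvec[corner, , drop = FALSE] / dlen[corner]
    n[corner, ] <- blend / sqrt(rowSums(blend^2))
  }
  n
}

# extrude a wall polyline into a layered strip; returns mesh + base node
# indices (row l = 0 equals the input coordinates, mapping 1:1).
# Vertex offsets use miter joints (bisector direction scaled by the
# reciprocal half-turn cosine, capped) so sharp corners such as the neck
# crease keep valid, well-shaped layers; light smoothing spreads the turn.
extrude_wall_strip <- function(coords, normals, thickness, layers,
                               smooth = 2, miter_cap = 2.5) {
  n_ <- nrow(coords)
  for (s in seq_len(smooth)) {
    nb <- normals
    nb[2:(n_ - 1), ] <- (normals[1:(n_ - 2), ] + 2 * normals[2:(n_ - 1), ] +
                           normals[3:n_, ]) / 4
    normals <- nb / sqrt(rowSums(nb^2))
  }
  # segment normals (left of travel flipped to match the vertex normals)
  seg <- coords[-1, , drop = FALSE] - coords[-n_, , drop = FALSE]
  seg_n <- cbind(seg[, 2], -seg[, 1])
  seg_n <- seg_n / sqrt(rowSums(seg_n^2))
  vavg <- (normals[-n_, , drop = FALSE] + normals[-1, , drop = FALSE]) / 2
  flip <- rowSums(seg_n * vavg) < 0
  seg_n[flip, ] <- -seg_n[flip, ]
  # miter scale: distance so both adjacent segments are offset by `thickness`
  scale <- numeric(n_)
  scale[1] <- 1 / max(sum(normals[1, ] * seg_n[1, ]), 1 / miter_cap)
  scale[n_] <- 1 / max(sum(normals[n_, ] * seg_n[n_ - 1, ]), 1 / miter_cap)
  for (i in 2:(n_ - 1)) {
    d <- min(sum(normals[i, ] * seg_n[i - 1, ]), sum(normals[i, ] * seg_n[i, ]))
    scale[i] <- 1 / max(d, 1 / miter_cap)
  }
  lt <- thickness / layers
  X <- matrix(0, n_, layers + 1); Y <- matrix(0, n_, layers + 1)
  for (l in 0:layers) {
    X[, l + 1] <- coords[, 1] + l * lt * scale * normals[, 1]
    Y[, l + 1] <- coords[, 2] + l * lt * scale * normals[, 2]
  }
  g <- grid_to_tri(X, Y)
  m <- mesh2d(g$nodes, g$tri)
  list(mesh = m, base = seq_len(n_))
}

#' @export
print.case_geometry <- function(x, ...) {
  cat(sprintf(
    "case_geometry (%dD): fluid %d nodes / %d tri; solid %d nodes / %d tri\n",
    x$dimension, nrow(x$fluid$nodes), nrow(x$fluid$tri),
    nrow(x$solid$nodes), nrow(x$solid$tri)))
  cat(sprintf("  sac: radius %g mm, neck %g mm, cut plane y > %g mm\n",
              x$params$sac_radius, x$params$neck_width, x$params$cut_height))
  invisible(x)
}

# geometric grading from the `to` end: fine step h_fine at b, growing by
# `ratio` up to h_max toward a; returns ascending breakpoints [a, b]
graded_breaks <- function(a, b, h_fine, ratio = 1.3, h_max = Inf) {
  span <- b - a
  stopifnot(span > 0, h_fine > 0)
  steps <- c(); h <- h_fine; tot <- 0
  while (tot + h < span) {
    steps <- c(steps, h); tot <- tot + h
    h <- min(h * ratio, h_max)
  }
  steps <- c(steps, span - tot)
  b - c(0, cumsum(steps))
}

#' Stented variant of the 2D case
#'
#' Rebuilds the case with the neck chord resolved at the wire scale, places
#' equally spaced wire cross-sections along the chord at the target linear
#' porosity, and immerses them by node removal ([immerse_2d()]). Index sets
#' (interface, inlet, sac) are rebuilt for the holed mesh.
#'
#' @param porosity target linear porosity of the wire row
#' @param wire_d_mm wire diameter (mm; 0.04 = 40 um)
#' @param refine_mm neck-region mesh size (mm; 0.015 = 15 um)
#' @param side_ratio grading ratio away from the neck
#' @param ... geometry arguments passed to [make_case_2d()]
#' @return `case_geometry` with the stented fluid mesh; attribute `wires`
#'   holds the circle table
#' @export
make_stented_case_2d <- function(porosity = 0.70, wire_d_mm = 0.04,
                                 refine_mm = 0.015, side_ratio = 1.3, ...) {
  args <- list(...)
  args$m_neck <- NULL
  if (is.null(args$n_phi)) args$n_phi <- 48
  base <- do.call(make_case_2d, c(args, list(
    m_neck = 2 * ceiling(ceiling((args$neck_width_mm %||% 2) / refine_mm) / 2),
    stent_refine = list(h = refine_mm, ratio = side_ratio))))
  w2 <- base$params$neck_width / 2
  yA <- base$params$chord_y
  L <- base$params$neck_width
  n_w <- round((1 - porosity) * L / wire_d_mm)
  margin <- L / n_w / 2
  xc <- seq(-w2 + margin, w2 - margin, length.out = n_w)
  wires <- data.frame(x = xc, y = yA - wire_d_mm / 2, r = wire_d_mm / 2)
  holed <- immerse_2d(base$fluid, wires)
  rebuild_case_indices(base, holed, wires)
}

# rebuild a case_geometry around a modified (renumbered) fluid mesh
rebuild_case_indices <- function(case, fluid_new, wires = NULL) {
  old <- case$fluid$nodes; new <- fluid_new$nodes
  key <- function(m) paste(round(m[, 1] * 1e7), round(m[, 2] * 1e7))
  map <- match(key(old), key(new))       # old index -> new index (or NA)
  remap <- function(idx) {
    out <- map[idx]
    if (any(is.na(out)))
      abort_sf("stent immersion removed wall/inlet nodes", "sacflow_mesh_error")
    out
  }
  tri_key <- function(m) {
    cx <- colMeans(matrix(m$nodes[as.vector(t(m$tri)), 1], nrow = 3))
    cy <- colMeans(matrix(m$nodes[as.vector(t(m$tri)), 2], nrow = 3))
    paste(round(cx * 1e7), round(cy * 1e7))
  }
  old_sac_keys <- tri_key(case$fluid)[case$sac_tris]
  new_keys <- tri_key(fluid_new)
  sac_new <- which(new_keys %in% old_sac_keys)
  case$fluid <- fluid_new
  case$interface$fluid <- remap(case$interface$fluid)
  case$wall_fluid_idx <- remap(case$wall_fluid_idx)
  case$dome_fluid_idx <- remap(case$dome_fluid_idx)
  case$inlet$idx <- remap(case$inlet$idx)
  case$sac_tris <- sac_new
  attr(case, "wires") <- wires
  case
}

#' Straight channel with one flexible wall (coupling test bed)
#'
#' Rectangular channel whose top wall carries an extruded elastic strip
#' (clamped at both ends); the bottom wall, inlet and outlet behave as in
#' the curved case. Used to exercise the partitioned coupling on a geometry
#' with a known, simple response.
#'
#' @param lx,ly channel size (mm)
#' @param nx,ny fluid cells
#' @param wall_thickness_mm,wall_layers solid strip extrusion
#' @param props_f,props_s material properties (the flat wall has no membrane
#'   stiffness, so the default uses the artery-grade modulus)
#' @param outlet outlet pressure model (mild resistance by default: a flat
#'   strip in pure bending cannot carry arterial pressures)
#' @return `case_geometry`
#' @export
make_flexible_channel_2d <- function(lx = 6, ly = 4, nx = 16, ny = 8,
                                     wall_thickness_mm = 0.25,
                                     wall_layers = 4,
                                     props_f = fluid_properties(),
                                     props_s = solid_properties(E = 7.5e6),
                                     outlet = outlet_model(P0_kpa = 0,
                                       Rd_kpa_s_per_ml = 0.05)) {
  fluid <- mesh_rectangle(lx, ly, nx, ny)
  nn <- fluid$nodes
  top <- which(abs(nn[, 2] - ly) < 1e-9)
  top <- top[order(nn[top, 1])]
  bot <- which(abs(nn[, 2]) < 1e-9)
  # only the top wall is coupled; bottom stays rigid (tag kept "wall")
  bnd <- fluid$bnd
  mid_y <- (nn[bnd$n1, 2] + nn[bnd$n2, 2]) / 2
  bnd$tag[bnd$tag == "wall" & mid_y > ly - 1e-9] <- "fsi"
  fluid$bnd <- bnd
  nrm <- matrix(rep(c(0, 1), each = length(top)), ncol = 2)
  strip <- extrude_wall_strip(nn[top, , drop = FALSE], nrm,
                              wall_thickness_mm, wall_layers)
  solid <- strip$mesh
  fixed <- which(abs(solid$nodes[, 1]) < 1e-9 |
                   abs(solid$nodes[, 1] - lx) < 1e-9)
  inlet_nodes <- bnd_nodes(fluid, "inlet")
  structure(list(
    fluid = fluid, solid = solid, solid_fixed = fixed,
    solid_factors = rep(1, nrow(solid$tri)),
    interface = data.frame(fluid = top, solid = strip$base),
    inlet = list(idx = inlet_nodes,
                 coords = nn[inlet_nodes, , drop = FALSE],
                 direction = c(1, 0), diameter_mm = ly),
    outlet_tag = "outlet", outlet_model = outlet,
    sac_tris = integer(),
    dome_fluid_idx = integer(),
    wall_fluid_idx = top,
    params = list(lx = lx, ly = ly, cut_height = Inf,
                  wall_thickness = wall_thickness_mm,
                  wall_layers = wall_layers),
    props_f = props_f, props_s = props_s,
    dimension = 2), class = "case_geometry")
}
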