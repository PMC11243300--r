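# Idealized toroidal artery --------------------------------------------------
#
# Coordinates: torus in the x-y plane, y vertical; the outer-wall apex sits
# at y = R_c + D/2 (8 mm at defaults), so the sac cut plane y > 8 mm
# coincides with the artery apex.  Surface parameterization
# P(theta, phi) = ((R_c + a cos phi) cos theta, (R_c + a cos phi) sin theta,
# a sin phi) with a the tube radius; phi = 0 is the outer equator (z = 0).

#' Build the idealized toroidal artery
#'
#' 3D: watertight tube section (capped ends) with an optional neck opening
#' around the apex, returned as a labelled surface. 2D: the mid-plane cut,
#' an annular-sector channel mesh.
#'
#' @param tube_diameter_mm vessel diameter (default 4)
#' @param centerline_radius_mm torus centerline radius (default 6)
#' @param angular_extent_deg arc (degrees), apex at 90
#' @param n_theta,n_phi surface grid resolution
#' @param neck_hole cut the neck opening (3D)
#' @param hole_radius_mm neck opening radius (surface metric)
#' @param dimension 2 or 3
#' @param ... 2D meshing controls passed to [mesh_annular_channel()]
#' @return 3D: `artery_surface` (a [surface_mesh()] with `hole_ring`,
#'   `cap_area`, parameters); 2D: tagged `mesh2d`
#' @export
make_artery <- function(tube_diameter_mm = 4, centerline_radius_mm = 6,
                        angular_extent_deg = c(40, 140), n_theta = 48,
                        n_phi = 36, neck_hole = TRUE, hole_radius_mm = 1.2,
                        dimension = 3, ...) {
  a <- tube_diameter_mm / 2; Rc <- centerline_radius_mm
  if (Rc <= a)
    abort_sf("centerline radius must exceed the tube radius",
             "sacflow_geometry_error")
  if (dimension == 2)
    return(mesh_annular_channel(Rc - a, Rc + a,
                                angular_extent_deg[1], angular_extent_deg[2],
                                ...))
  th <- seq(angular_extent_deg[1], angular_extent_deg[2],
            length.out = n_theta + 1) * pi / 180
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  # phi measured from the outer equator; wrap to (-pi, pi] for hole metric
  grid_pt <- function(t_, p_) {
    r <- Rc + a * cos(p_)
    c(r * cos(t_), r * sin(t_), a * sin(p_))
  }
  nv <- (n_theta + 1) * n_phi
  verts <- matrix(0, nv, 3)
  id <- function(i, j) (i - 1) * n_phi + j      # i theta, j phi
  for (i in seq_len(n_theta + 1)) for (j in seq_len(n_phi))
    verts[id(i, j), ] <- grid_pt(th[i], ph[j])

  keep_quad <- function(i, j) {
    if (!neck_hole) return(TRUE)
    tc <- (th[i] + th[i + 1]) / 2
    jp <- if (j == n_phi) 1 else j + 1
    pc <- atan2(mean(sin(c(ph[j], ph[jp]))), mean(cos(c(ph[j], ph[jp]))))
    ds <- (Rc + a * cos(pc)) * (tc - pi / 2)
    dp <- a * pc
    ds^2 + dp^2 > hole_radius_mm^2
  }
  tri <- matrix(0L, 0, 3)
  for (i in seq_len(n_theta)) for (j in seq_len(n_phi)) {
    if (!keep_quad(i, j)) next
    jp <- if (j == n_phi) 1 else j + 1
    aq <- id(i, j); bq <- id(i + 1, j); cq <- id(i + 1, jp); dq <- id(i, jp)
    tri <- rbind(tri, c(aq, bq, cq), c(aq, cq, dq))
  }
  # end caps: fan to the tube center of each end plane
  centers <- rbind(c(Rc * cos(th[1]), Rc * sin(th[1]), 0),
                   c(Rc * cos(th[n_theta + 1]), Rc * sin(th[n_theta + 1]), 0))
  verts <- rbind(verts, centers)
  c1 <- nv + 1; c2 <- nv + 2
  for (j in seq_len(n_phi)) {
    jp <- if (j == n_phi) 1 else j + 1
    tri <- rbind(tri, c(id(1, j), id(1, jp), c1),
                 c(id(n_theta + 1, jp), id(n_theta + 1, j), c2))
  }
  # drop vertices orphaned by the hole cut
  used <- sort(unique(as.vector(tri)))
  vmap <- integer(nrow(verts)); vmap[used] <- seq_along(used)
  verts <- verts[used, , drop = FALSE]
  tri <- matrix(vmap[tri], ncol = 3)
  c1 <- vmap[c1]; c2 <- vmap[c2]
  m <- surface_mesh(verts, tri)
  if (surf_volume(m) < 0) m$tri <- m$tri[, c(1, 3, 2)]
  loops <- surf_boundary_loops(m)
  au <- surf_audit(m)
  if (!au$edge_manifold || !au$oriented)
    abort_sf("artery surface failed the manifold/orientation audit",
             "sacflow_topology_error")
  cap_area <- pi * a^2
  structure(c(m, list(
    hole_ring = if (length(loops)) loops[[1]] else integer(),
    inlet_center = c1, outlet_center = c2, cap_area = cap_area,
    params = list(tube_diameter = tube_diameter_mm, centerline_radius = Rc,
                  angular_extent = angular_extent_deg,
                  hole_radius = if (neck_hole) hole_radius_mm else NA))),
    class = c("artery_surface", "surface_mesh"))
}

#' 2D annular-sector channel mesh (the artery mid-plane cut)
#'
#' @param r1,r2 inner/outer wall radii (mm)
#' @param theta0_deg,theta1_deg angular extent
#' @param n_theta cells along the channel
#' @param n_bl,bl_first,bl_ratio,core_size radial spacing controls (mm)
#' @return tagged `mesh2d` (inlet at theta1, outlet at theta0, walls "wall")
#' @export
mesh_annular_channel <- function(r1 = 4, r2 = 8, theta0_deg = 40,
                                 theta1_deg = 140, n_theta = 40, n_bl = 0,
                                 bl_first = 0.02, bl_ratio = 1.2,
                                 core_size = 0.4) {
  th <- seq(theta0_deg, theta1_deg, length.out = n_theta + 1) * pi / 180
  rr <- r1 + spacing_1d(r2 - r1, core_size, n_bl, bl_first, bl_ratio, TRUE)
  X <- outer(cos(th), rr); Y <- outer(sin(th), rr)
  g <- grid_to_tri(X, Y)
  m <- mesh2d(g$nodes, g$tri)
  th0 <- theta0_deg * pi / 180; th1 <- theta1_deg * pi / 180
  online <- function(p, tt) abs(p[, 1] * sin(tt) - p[, 2] * cos(tt)) <
    1e-6 * pmax(sqrt(rowSums(p^2)), 1)
  tag_boundary(m, list(inlet = function(p) online(p, th1),
                       outlet = function(p) online(p, th0)),
               default = "wall")
}
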