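# Shell extrusion and boundary-layered volume meshes ------------------------

#' Extrude a surface into a layered solid shell
#'
#' Outward extrusion along (unit) vertex normals in `layers` equal steps to
#' the total `thickness`; the layer-0 node set is the input surface (the FSI
#' interface). Prisms are split into tetrahedra with a globally consistent
#' diagonal rule so neighbouring prisms conform.
#'
#' @param m oriented `surface_mesh`
#' @param thickness_mm total shell thickness (default 0.25)
#' @param layers number of layers (default 4)
#' @return `shell_mesh`: vertices ((layers+1) stacks), tets, layer thickness,
#'   `base_idx` (interface nodes), `outer_idx`
#' @export
extrude_solid <- function(m, thickness_mm = 0.25, layers = 4) {
  vn <- surf_vertex_normals(m)
  nv <- nrow(m$vertices)
  lt <- thickness_mm / layers
  verts <- do.call(rbind, lapply(0:layers, function(l)
    m$vertices + l * lt * vn))
  # each prism splits into 8 tets around its centroid; quad-face diagonals
  # run from the smaller global vertex index, so neighbouring prisms share
  # identical face triangulations (conforming stack)
  Tr <- m$tri
  nf <- nrow(Tr)
  ctr_list <- vector("list", layers)
  tets_list <- vector("list", layers)
  n_stack <- (layers + 1) * nv
  quad_tris <- function(pa, pb, qa, qb, wa, wb) {
    # diagonal from the bottom of min(wa, wb) to the top of the other
    a_min <- wa < wb
    t1 <- ifelse(a_min, pa, pb); t1b <- ifelse(a_min, pb, pa)
    t1c <- ifelse(a_min, qb, qa)
    t2c <- ifelse(a_min, qa, qb)
    rbind(cbind(t1, t1b, t1c), cbind(t1, t1c, t2c))
  }
  for (l in 0:(layers - 1)) {
    lo <- l * nv; hi <- (l + 1) * nv
    p1 <- lo + Tr[, 1]; p2 <- lo + Tr[, 2]; p3 <- lo + Tr[, 3]
    q1 <- hi + Tr[, 1]; q2 <- hi + Tr[, 2]; q3 <- hi + Tr[, 3]
    cidx <- n_stack + l * nf + seq_len(nf)
    ctr_list[[l + 1]] <- (verts[p1, ] + verts[p2, ] + verts[p3, ] +
                            verts[q1, ] + verts[q2, ] + verts[q3, ]) / 6
    faces <- rbind(cbind(p1, p3, p2), cbind(q1, q2, q3),
                   quad_tris(p1, p2, q1, q2, Tr[, 1], Tr[, 2]),
                   quad_tris(p2, p3, q2, q3, Tr[, 2], Tr[, 3]),
                   quad_tris(p3, p1, q3, q1, Tr[, 3], Tr[, 1]))
    tets_list[[l + 1]] <- cbind(faces, rep(cidx, 8))
  }
  verts <- rbind(verts, do.call(rbind, ctr_list))
  tets <- do.call(rbind, tets_list)
  storage.mode(tets) <- "integer"
  # fold-over audit: the classic 3-tet split with consistent winding must be
  # positive prism-wise; concave creases collapse it before the stack does
  bad_v <- integer()
  for (l in 0:(layers - 1)) {
    lo <- l * nv; hi <- (l + 1) * nv
    p1 <- lo + Tr[, 1]; p2 <- lo + Tr[, 2]; p3 <- lo + Tr[, 3]
    q1 <- hi + Tr[, 1]; q2 <- hi + Tr[, 2]; q3 <- hi + Tr[, 3]
    chk <- rbind(cbind(p1, p2, p3, q3), cbind(p1, p2, q3, q2),
                 cbind(p1, q2, q3, q1))
    vv <- tet_volumes(verts, chk)
    if (any(vv <= 0))
      bad_v <- c(bad_v, unique(((as.vector(chk[vv <= 0, 1:3]) - 1) %% nv) + 1))
  }
  if (length(bad_v))
    abort_sf(sprintf(
      "self-intersecting extrusion at %d vertices (high concave curvature)",
      length(unique(bad_v))), "sacflow_extrusion_error")
  # orient the stored centroid tets positively (face windings vary)
  v0 <- tet_volumes(verts, tets)
  neg <- v0 < 0
  tets[neg, c(1, 2)] <- tets[neg, c(2, 1)]
  structure(list(vertices = verts, tets = tets, base = m,
                 layers = layers, layer_thickness = lt,
                 base_idx = seq_len(nv),
                 outer_idx = layers * nv + seq_len(nv),
                 normals = vn), class = "shell_mesh")
}

tet_volumes <- function(verts, tets) {
  a <- verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 2], , drop = FALSE] - a
  c_ <- verts[tets[, 3], , drop = FALSE] - a
  d <- verts[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Total volume of a shell mesh (mm^3)
#' @param shell `shell_mesh`
#' @export
shell_volume <- function(shell) sum(tet_volumes(shell$vertices, shell$tets))

#' @export
print.shell_mesh <- function(x, ...) {
  cat(sprintf("shell_mesh: %d layers x %.4g mm = %.4g mm total, %d tets\n",
              x$layers, x$layer_thickness, x$layers * x$layer_thickness,
              nrow(x$tets)))
  invisible(x)
}

#' Boundary-layered fluid mesh
#'
#' 2D (`domain` a list with `type = "rectangle"` or `"annulus"` and its
#' dimensions): wall-normal breakpoints start with the exact geometric
#' boundary-layer stack 20*1.2^(k-1) um (defaults) on both walls and continue
#' with an isotropic core, conforming by construction. 3D (`domain` a closed
#' `surface_mesh`): inward prismatic stack with the exact thicknesses; the
#' isotropic tetrahedral core fills the remaining cavity by a centroid fan
#' and is only available when the offset cavity is star-shaped with respect
#' to its centroid (checked); otherwise the stack is returned with
#' `core = NULL` and a report entry.
#'
#' @param domain domain description (see above)
#' @param bl_ratio growth ratio (1.2)
#' @param bl_first first-layer thickness (mm; 0.02 = 20 um)
#' @param n_bl number of boundary layers
#' @param core_size isotropic core size (mm)
#' @return 2D: tagged `mesh2d` with attribute `bl` (the thicknesses); 3D:
#'   list(stack_vertices, prism layer thicknesses, core tets or NULL, report)
#' @export
generate_fluid_mesh <- function(domain, bl_ratio = 1.2, bl_first = 0.02,
                                n_bl = 4, core_size = 0.4) {
  if (inherits(domain, "surface_mesh")) {
    return(fluid_mesh_3d(domain, bl_ratio, bl_first, n_bl, core_size))
  }
  t_bl <- bl_thicknesses(n_bl, bl_first, bl_ratio)
  m <- switch(domain$type,
    rectangle = {
      sy <- spacing_1d(domain$ly, core_size, n_bl, bl_first, bl_ratio, TRUE)
      sx <- seq(0, domain$lx, length.out = max(2, ceiling(domain$lx / core_size)) + 1)
      mesh_rectangle(domain$lx, domain$ly, sx, sy)
    },
    annulus = mesh_annular_channel(domain$r1, domain$r2, domain$theta0,
                                   domain$theta1,
                                   n_theta = max(8, ceiling(
                                     (domain$theta1 - domain$theta0) * pi / 180 *
                                       (domain$r1 + domain$r2) / 2 / core_size)),
                                   n_bl = n_bl, bl_first = bl_first,
                                   bl_ratio = bl_ratio, core_size = core_size),
    abort_sf("unknown 2D domain type", "sacflow_parameter_error"))
  attr(m, "bl") <- t_bl
  m
}

fluid_mesh_3d <- function(surf, bl_ratio, bl_first, n_bl, core_size) {
  au <- surf_audit(surf)
  if (au$n_boundary_edges != 0)
    abort_sf("3D fluid meshing needs a watertight boundary",
             "sacflow_topology_error")
  vn <- surf_vertex_normals(surf)         # outward
  t_bl <- bl_thicknesses(n_bl, bl_first, bl_ratio)
  offs <- cumsum(t_bl)
  nv <- nrow(surf$vertices)
  stack <- do.call(rbind, lapply(c(0, offs), function(o)
    surf$vertices - o * vn))              # inward offsets
  inner <- surface_mesh(stack[n_bl * nv + seq_len(nv), , drop = FALSE],
                        surf$tri)
  ctr <- colMeans(inner$vertices)
  # reverse the face winding so tets toward the interior centroid are positive
  tets <- cbind(inner$tri[, c(1, 3, 2)] + n_bl * nv, nv * (n_bl + 1) + 1L)
  verts_all <- rbind(stack, ctr)
  vols <- tet_volumes(verts_all, tets)
  star <- all(vols > 0)
  list(stack_vertices = stack, layer_thicknesses = t_bl,
       inner_surface = inner,
       core = if (star) list(vertices = verts_all, tets = tets) else NULL,
       report = list(star_shaped = star, n_bl = n_bl,
                     total_bl = sum(t_bl)))
}
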