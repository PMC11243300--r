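# Triangulated surface meshes (3D, coordinates in mm) ------------------------

#' Construct a surface mesh
#' @param vertices V x 3 matrix (mm)
#' @param tri F x 3 integer matrix (1-based, consistently oriented)
#' @return object of class `surface_mesh`
#' @export
surface_mesh <- function(vertices, tri) {
  vertices <- as.matrix(vertices); storage.mode(tri) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(tri) == 3)
  structure(list(vertices = vertices, tri = tri), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  loops <- tryCatch(length(surf_boundary_loops(x)), error = function(e) NA)
  cat(sprintf("surface_mesh: %d vertices, %d faces, %s boundary loop(s)\n",
              nrow(x$vertices), nrow(x$tri),
              if (is.na(loops)) "?" else loops))
  invisible(x)
}

surf_face_normals <- function(m, normalize = TRUE) {
  p1 <- m$vertices[m$tri[, 1], , drop = FALSE]
  e1 <- m$vertices[m$tri[, 2], , drop = FALSE] - p1
  e2 <- m$vertices[m$tri[, 3], , drop = FALSE] - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n / pmax(sqrt(rowSums(n^2)), 1e-300) else n
}

surf_face_areas <- function(m) {
  0.5 * sqrt(rowSums(surf_face_normals(m, normalize = FALSE)^2))
}

#' Total surface area (mm^2)
#' @param m surface mesh
#' @export
surf_area <- function(m) sum(surf_face_areas(m))

# angle-weighted vertex normals (more accurate than area weighting for
# surface offsetting; exactly radial on symmetric sphere tessellations)
surf_vertex_normals <- function(m) {
  fn <- surf_face_normals(m)
  V <- m$vertices
  vn <- matrix(0, nrow(V), 3)
  corner_angle <- function(p, q, r) {
    u <- q - p; w <- r - p
    cosang <- rowSums(u * w) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)), 1e-300)
    acos(pmin(pmax(cosang, -1), 1))
  }
  p1 <- V[m$tri[, 1], , drop = FALSE]
  p2 <- V[m$tri[, 2], , drop = FALSE]
  p3 <- V[m$tri[, 3], , drop = FALSE]
  angs <- cbind(corner_angle(p1, p2, p3), corner_angle(p2, p3, p1),
                corner_angle(p3, p1, p2))
  for (c_ in 1:3) {
    acc <- numeric(nrow(V))
    for (k in 1:3) {
      t_ <- tapply(fn[, c_] * angs[, k], m$tri[, k], sum)
      acc[as.integer(names(t_))] <- acc[as.integer(names(t_))] + t_
    }
    vn[, c_] <- acc
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

# all undirected edges with incidence counts
surf_edges <- function(m) {
  e <- rbind(m$tri[, c(1, 2)], m$tri[, c(2, 3)], m$tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  list(edges = e, key = key, counts = table(key))
}

#' Manifold / orientation audit
#'
#' Checks that every edge is shared by at most two faces and that interior
#' edges are traversed once in each direction (consistent orientation).
#'
#' @param m surface mesh
#' @return list(edge_manifold, oriented, n_boundary_edges, euler)
#' @export
surf_audit <- function(m) {
  se <- surf_edges(m)
  edge_manifold <- all(se$counts <= 2)
  dir_key <- paste(se$edges[, 1], se$edges[, 2])
  oriented <- !any(duplicated(dir_key))
  nb <- sum(se$counts == 1)
  V <- nrow(m$vertices); E <- length(se$counts); F <- nrow(m$tri)
  list(edge_manifold = edge_manifold, oriented = oriented,
       n_boundary_edges = nb, euler = V - E + F)
}

#' Ordered boundary loops of an open surface
#' @param m surface mesh
#' @return list of integer vectors (vertex cycles)
#' @export
surf_boundary_loops <- function(m) {
  se <- surf_edges(m)
  bsel <- se$counts[se$key] == 1
  be <- se$edges[bsel, , drop = FALSE]
  if (!nrow(be)) return(list())
  nxt <- setNames(be[, 2], as.character(be[, 1]))
  if (anyDuplicated(be[, 1]))
    abort_sf("non-manifold boundary (branching loop)", "sacflow_topology_error")
  loops <- list(); used <- rep(FALSE, nrow(be))
  starts <- be[, 1]
  while (any(!used)) {
    s <- starts[which(!used)[1]]
    loop <- s; cur <- s
    repeat {
      used[match(cur, starts)] <- TRUE
      cur <- nxt[[as.character(cur)]]
      if (cur == s) break
      loop <- c(loop, cur)
      if (length(loop) > nrow(be) + 1)
        abort_sf("open boundary chain (not a loop)", "sacflow_topology_error")
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Enclosed volume of a surface (mm^3)
#'
#' Divergence theorem over the faces; open boundary loops are closed with a
#' fan to their barycenter when `cap = TRUE`.
#'
#' @param m surface mesh (outward orientation)
#' @param cap close boundary loops before integrating
#' @return volume (mm^3)
#' @export
surf_volume <- function(m, cap = TRUE) {
  tris <- m$tri; verts <- m$vertices
  if (cap) {
    loops <- surf_boundary_loops(m)
    for (lp in loops) {
      ctr <- colMeans(verts[lp, , drop = FALSE])
      verts <- rbind(verts, ctr)
      ci <- nrow(verts)
      nl <- length(lp)
      # boundary edges run with the surface; the cap must run against them
      fan <- cbind(lp[c(2:nl, 1)], lp, rep(ci, nl))
      tris <- rbind(tris, fan)
    }
  }
  p1 <- verts[tris[, 1], , drop = FALSE]
  p2 <- verts[tris[, 2], , drop = FALSE]
  p3 <- verts[tris[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p3[, 2] * p2[, 3]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p3[, 1] * p2[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p3[, 1] * p2[, 2])) / 6
}

#' Write a surface as ASCII STL (mm units)
#' @param m surface mesh
#' @param path output file
#' @export
write_stl <- function(m, path) {
  n <- surf_face_normals(m)
  con <- file(path, "w"); on.exit(close(con))
  cat("solid sacflow_mm\n", file = con)
  p1 <- m$vertices[m$tri[, 1], , drop = FALSE]
  p2 <- m$vertices[m$tri[, 2], , drop = FALSE]
  p3 <- m$vertices[m$tri[, 3], , drop = FALSE]
  writeLines(sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3], p1[, 1], p1[, 2], p1[, 3],
    p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3]), con)
  cat("endsolid sacflow_mm\n", file = con)
  invisible(path)
}

#' Read an ASCII STL file (vertices merged by coordinate)
#' @param path STL file
#' @param tol merge tolerance (mm)
#' @return surface mesh
#' @export
read_stl <- function(path, tol = 1e-7) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(s)
    as.numeric(s[2:4])))
  key <- apply(round(xyz / tol), 1, paste, collapse = " ")
  ids <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  tri <- matrix(ids, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tri)
}

#' Write a surface as Wavefront OBJ (mm units)
#' @param m surface mesh
#' @param path output file
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat("# sacflow surface, units mm\n", file = con)
  writeLines(sprintf("v %g %g %g", m$vertices[, 1], m$vertices[, 2],
                     m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", m$tri[, 1], m$tri[, 2], m$tri[, 3]), con)
  invisible(path)
}
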