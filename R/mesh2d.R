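# 2D triangular meshes ------------------------------------------------------
#
# A `mesh2d` is a list(nodes = N x 2 matrix [mm], tri = M x 3 integer matrix,
# bnd = data.frame(n1, n2, tag)).  Triangles are counter-clockwise; boundary
# edges are directed so the domain lies on their left (outward normal =
# (dy, -dx)/L).  Structured blocks are built from mapped grids and glued by
# coordinate matching.

mesh2d <- function(nodes, tri, bnd = NULL) {
  nodes <- as.matrix(nodes); storage.mode(tri) <- "integer"
  m <- structure(list(nodes = nodes, tri = tri, bnd = bnd), class = "mesh2d")
  fix_orientation(m)
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("mesh2d: %d nodes, %d triangles", nrow(x$nodes), nrow(x$tri)))
  if (!is.null(x$bnd))
    cat(sprintf(", boundary tags: %s",
                paste(names(table(x$bnd$tag)), collapse = ", ")))
  cat("\n"); invisible(x)
}

tri_areas <- function(m) {
  p1 <- m$nodes[m$tri[, 1], , drop = FALSE]
  p2 <- m$nodes[m$tri[, 2], , drop = FALSE]
  p3 <- m$nodes[m$tri[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

fix_orientation <- function(m) {
  a <- tri_areas(m)
  neg <- a < 0
  if (any(neg)) m$tri[neg, c(2, 3)] <- m$tri[neg, c(3, 2)]
  if (any(abs(tri_areas(m)) < 1e-14))
    abort_sf("degenerate (zero-area) triangle in mesh", "sacflow_topology_error")
  m
}

# directed boundary edges (domain on the left), from triangle incidence
boundary_edges <- function(m) {
  e <- rbind(m$tri[, c(1, 2)], m$tri[, c(2, 3)], m$tri[, c(3, 1)])
  key  <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  sel <- cnt[key] == 1
  e[sel, , drop = FALSE]
}

# tag boundary edges with predicate functions on edge midpoints.
# preds: named list of functions(mid_xy_matrix) -> logical; first match wins.
tag_boundary <- function(m, preds, default = "wall") {
  e <- boundary_edges(m)
  mid <- (m$nodes[e[, 1], , drop = FALSE] + m$nodes[e[, 2], , drop = FALSE]) / 2
  tag <- rep(default, nrow(e))
  for (nm in rev(names(preds))) tag[preds[[nm]](mid)] <- nm
  m$bnd <- data.frame(n1 = e[, 1], n2 = e[, 2], tag = tag,
                      stringsAsFactors = FALSE)
  m
}

bnd_nodes <- function(m, tags) {
  sel <- m$bnd$tag %in% tags
  sort(unique(c(m$bnd$n1[sel], m$bnd$n2[sel])))
}

# structured quad grid -> triangles.  X, Y: (n1 x n2) coordinate matrices.
# Quads split along their shorter diagonal.
grid_to_tri <- function(X, Y) {
  n1 <- nrow(X); n2 <- ncol(X)
  idx <- matrix(seq_len(n1 * n2), n1, n2)
  i <- rep(seq_len(n1 - 1), n2 - 1)
  j <- rep(seq_len(n2 - 1), each = n1 - 1)
  a <- idx[cbind(i, j)];     b <- idx[cbind(i + 1, j)]
  c_ <- idx[cbind(i + 1, j + 1)]; d <- idx[cbind(i, j + 1)]
  nodes <- cbind(as.vector(X), as.vector(Y))
  d1 <- rowSums((nodes[a, , drop = FALSE] - nodes[c_, , drop = FALSE])^2)
  d2 <- rowSums((nodes[b, , drop = FALSE] - nodes[d, , drop = FALSE])^2)
  use1 <- d1 <= d2
  tri <- rbind(cbind(a, b, c_)[use1, , drop = FALSE],
               cbind(a, c_, d)[use1, , drop = FALSE],
               cbind(a, b, d)[!use1, , drop = FALSE],
               cbind(b, c_, d)[!use1, , drop = FALSE])
  list(nodes = nodes, tri = tri)
}

# glue blocks: concatenate, merge coincident nodes (tol in mm), drop
# degenerate and duplicate triangles
merge_blocks <- function(blocks, tol = 1e-7) {
  nodes <- do.call(rbind, lapply(blocks, `[[`, "nodes"))
  offs <- cumsum(c(0, head(vapply(blocks, function(b) nrow(b$nodes), 0L), -1)))
  tri <- do.call(rbind, mapply(function(b, o) b$tri + o, blocks, offs,
                               SIMPLIFY = FALSE))
  key <- paste(round(nodes[, 1] / tol), round(nodes[, 2] / tol))
  first <- match(key, key)
  new_id <- match(first, sort(unique(first)))
  keep <- sort(unique(first))
  nodes2 <- nodes[keep, , drop = FALSE]
  tri2 <- matrix(new_id[tri], ncol = 3)
  # drop collapsed triangles (repeated vertex)
  ok <- tri2[, 1] != tri2[, 2] & tri2[, 2] != tri2[, 3] & tri2[, 1] != tri2[, 3]
  tri2 <- tri2[ok, , drop = FALSE]
  # drop duplicated triangles
  tk <- apply(tri2, 1, function(r) paste(sort(r), collapse = " "))
  tri2 <- tri2[!duplicated(tk), , drop = FALSE]
  mesh2d(nodes2, tri2)
}

# triangle quality: 2 r_in / r_circ (1 for equilateral)
tri_quality <- function(m) {
  p1 <- m$nodes[m$tri[, 1], , drop = FALSE]
  p2 <- m$nodes[m$tri[, 2], , drop = FALSE]
  p3 <- m$nodes[m$tri[, 3], , drop = FALSE]
  a <- sqrt(rowSums((p2 - p3)^2)); b <- sqrt(rowSums((p1 - p3)^2))
  c_ <- sqrt(rowSums((p1 - p2)^2))
  s <- (a + b + c_) / 2
  area <- abs(tri_areas(m))
  r_in <- area / s
  r_circ <- a * b * c_ / (4 * area)
  2 * r_in / r_circ
}

#' Write a 2D mesh (with optional point data) as legacy ASCII VTK
#'
#' @param m mesh2d
#' @param path output .vtk file
#' @param point_data named list of per-node vectors or 2-column matrices
#' @return invisibly, `path`
#' @export
write_vtk2d <- function(m, path, point_data = list()) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(m$nodes); ntri <- nrow(m$tri)
  cat("# vtk DataFile Version 3.0\nsacflow mesh (coordinates in mm)\nASCII\n",
      "DATASET UNSTRUCTURED_GRID\n", sep = "", file = con)
  cat(sprintf("POINTS %d double\n", n), file = con)
  writeLines(sprintf("%.9g %.9g 0", m$nodes[, 1], m$nodes[, 2]), con)
  cat(sprintf("CELLS %d %d\n", ntri, 4 * ntri), file = con)
  writeLines(sprintf("3 %d %d %d", m$tri[, 1] - 1, m$tri[, 2] - 1,
                     m$tri[, 3] - 1), con)
  cat(sprintf("CELL_TYPES %d\n", ntri), file = con)
  writeLines(rep("5", ntri), con)
  if (length(point_data)) {
    cat(sprintf("POINT_DATA %d\n", n), file = con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 2) {
        cat(sprintf("VECTORS %s double\n", nm), file = con)
        writeLines(sprintf("%.9g %.9g 0", v[, 1], v[, 2]), con)
      } else {
        cat(sprintf("SCALARS %s double 1\nLOOKUP_TABLE default\n", nm),
            file = con)
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  invisible(path)
}
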