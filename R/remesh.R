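# Isotropic surface remeshing -----------------------------------------------
#
# Split / collapse / flip / tangential-smooth passes toward a target edge
# length (the in-house replacement for metric-based external remeshers):
# edges longer than 4/3 h are split at their midpoint, edges shorter than
# 4/5 h are collapsed to their midpoint under fold-over and manifoldness
# guards, interior edges are flipped when that improves the worse of the two
# triangle qualities, and interior vertices receive tangential Laplacian
# smoothing. Boundary vertices are kept fixed.

#' Remesh a triangulated surface to a uniform target edge length
#'
#' @param m `surface_mesh`
#' @param target target edge length (mm)
#' @param passes number of split/collapse/flip/smooth passes
#' @param smooth_lambda tangential smoothing step
#' @return remeshed `surface_mesh`
#' @export
remesh_surface <- function(m, target, passes = 5, smooth_lambda = 0.5) {
  au <- surf_audit(m)
  if (!au$edge_manifold)
    abort_sf("non-manifold input to remesh_surface", "sacflow_topology_error")
  V <- m$vertices; Tr <- m$tri
  for (p in seq_len(passes)) {
    r <- remesh_split(V, Tr, 4 / 3 * target)
    V <- r$V; Tr <- r$T
    r <- remesh_collapse(V, Tr, 4 / 5 * target)
    V <- r$V; Tr <- r$T
    Tr <- remesh_flip(V, Tr)
    V <- remesh_smooth(V, Tr, smooth_lambda)
    # pull interior vertices back onto the input surface: split midpoints and
    # smoothing otherwise shrink curved regions chordally
    bv <- boundary_vertices(Tr)
    keep <- setdiff(sort(unique(as.vector(Tr))), bv)
    V[keep, ] <- project_to_surface(V[keep, , drop = FALSE], m)
  }
  used <- sort(unique(as.vector(Tr)))
  map <- integer(nrow(V)); map[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE], matrix(map[Tr], ncol = 3))
}

# closest points on a reference surface for a set of query points
project_to_surface <- function(P, ref) {
  p1 <- ref$vertices[ref$tri[, 1], , drop = FALSE]
  p2 <- ref$vertices[ref$tri[, 2], , drop = FALSE]
  p3 <- ref$vertices[ref$tri[, 3], , drop = FALSE]
  ctr <- (p1 + p2 + p3) / 3
  rad <- sqrt(pmax(rowSums((p1 - ctr)^2), rowSums((p2 - ctr)^2),
                   rowSums((p3 - ctr)^2)))
  maxrad <- max(rad)
  out <- P
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    d_ctr <- sqrt(colSums((t(ctr) - p)^2))
    cand <- which(d_ctr <= min(d_ctr) + maxrad + 1e-12)
    best <- Inf; bq <- p
    for (k in cand) {
      q <- closest_on_tri(p, p1[k, ], p2[k, ], p3[k, ])
      d2 <- sum((p - q)^2)
      if (d2 < best) { best <- d2; bq <- q }
    }
    out[i, ] <- bq
  }
  out
}

# closest point on a single triangle (same region logic as point_tri_dist)
closest_on_tri <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A; ap <- p - A
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(A)
  bp <- p - B; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(B)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(A + (d1 / (d1 - d3)) * ab)
  cp <- p - C; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(C)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(A + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(B + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (C - B))
  den <- va + vb + vc
  A + (vb / den) * ab + (vc / den) * ac
}

edge_table <- function(Tr) {
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tri_of <- rep(seq_len(nrow(Tr)), 3)
  list(e = e, key = key, tri_of = tri_of)
}

remesh_split <- function(V, Tr, lmax) {
  for (sweep_ in 1:3) {
    et <- edge_table(Tr)
    len <- sqrt(rowSums((V[et$e[, 1], , drop = FALSE] -
                         V[et$e[, 2], , drop = FALSE])^2))
    ord <- order(-len)
    long <- ord[len[ord] > lmax]
    if (!length(long)) break
    done_key <- character(); touched <- logical(nrow(Tr))
    newV <- list(); newT <- list(); drop <- logical(nrow(Tr))
    mid_id <- nrow(V)
    for (k in long) {
      ky <- et$key[k]
      if (ky %in% done_key) next
      tris <- et$tri_of[et$key == ky]
      if (any(touched[tris])) next
      a <- et$e[k, 1]; b <- et$e[k, 2]
      mid_id <- mid_id + 1
      newV[[length(newV) + 1]] <- (V[a, ] + V[b, ]) / 2
      for (tq in tris) {
        tv <- Tr[tq, ]
        # replace edge (a,b) by two triangles through the midpoint
        ia <- which(tv == a); ib <- which(tv == b)
        other <- tv[-c(ia, ib)]
        t1 <- tv; t1[ib] <- mid_id
        t2 <- tv; t2[ia] <- mid_id
        newT[[length(newT) + 1]] <- t1
        newT[[length(newT) + 1]] <- t2
        drop[tq] <- TRUE; touched[tq] <- TRUE
      }
      done_key <- c(done_key, ky)
    }
    if (!length(newT)) break
    V <- rbind(V, do.call(rbind, newV))
    Tr <- rbind(Tr[!drop, , drop = FALSE], do.call(rbind, newT))
  }
  list(V = V, T = Tr)
}

tri_normal_rows <- function(V, Tr) {
  e1 <- V[Tr[, 2], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  e2 <- V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

tri_quality_rows <- function(V, Tr) {
  a <- sqrt(rowSums((V[Tr[, 2], , drop = FALSE] - V[Tr[, 3], , drop = FALSE])^2))
  b <- sqrt(rowSums((V[Tr[, 1], , drop = FALSE] - V[Tr[, 3], , drop = FALSE])^2))
  c_ <- sqrt(rowSums((V[Tr[, 1], , drop = FALSE] - V[Tr[, 2], , drop = FALSE])^2))
  area <- 0.5 * sqrt(rowSums(tri_normal_rows(V, Tr)^2))
  s <- (a + b + c_) / 2
  q <- 2 * (area / s) / (a * b * c_ / (4 * pmax(area, 1e-300)))
  ifelse(area <= 0, 0, q)
}

boundary_vertices <- function(Tr) {
  et <- edge_table(Tr)
  cnt <- table(et$key)
  bd <- et$e[cnt[et$key] == 1, , drop = FALSE]
  unique(as.vector(bd))
}

remesh_collapse <- function(V, Tr, lmin, max_sweeps = 5) {
  for (sw in seq_len(max_sweeps)) {
    bv <- boundary_vertices(Tr)
    locked <- logical(nrow(V)); locked[bv] <- TRUE
    et <- edge_table(Tr)
    len <- sqrt(rowSums((V[et$e[, 1], , drop = FALSE] -
                         V[et$e[, 2], , drop = FALSE])^2))
    short <- order(len)
    short <- short[len[short] < lmin]
    short <- short[!duplicated(et$key[short])]
    if (!length(short)) break
    # vertex -> incident (alive) triangle rows
    inc <- split(rep(seq_len(nrow(Tr)), 3), as.vector(Tr))
    alive <- rep(TRUE, nrow(Tr))
    accepted <- 0
    for (k in short) {
      a <- et$e[k, 1]; b <- et$e[k, 2]
      if (locked[a] || locked[b]) next
      ra <- inc[[as.character(a)]]; ra <- ra[alive[ra]]
      rb <- inc[[as.character(b)]]; rb <- rb[alive[rb]]
      na_ <- setdiff(unique(as.vector(Tr[ra, ])), a)
      nb_ <- setdiff(unique(as.vector(Tr[rb, ])), b)
      # manifold guard: a and b must share exactly the two wing vertices
      if (length(intersect(na_, nb_)) != 2) next
      mid <- (V[a, ] + V[b, ]) / 2
      rows <- unique(c(ra, rb))
      Tt <- Tr[rows, , drop = FALSE]
      Tt[Tt == b] <- a
      deg <- Tt[, 1] == Tt[, 2] | Tt[, 2] == Tt[, 3] | Tt[, 1] == Tt[, 3]
      Vt <- V; Vt[a, ] <- mid
      n_old <- tri_normal_rows(V, Tr[rows[!deg], , drop = FALSE])
      n_new <- tri_normal_rows(Vt, Tt[!deg, , drop = FALSE])
      q_new <- tri_quality_rows(Vt, Tt[!deg, , drop = FALSE])
      if (any(rowSums(n_old * n_new) <= 0) || any(q_new < 0.05)) next
      V[a, ] <- mid
      Tr[rows, ] <- Tt
      alive[rows[deg]] <- FALSE
      # append the rewritten rows to a's incidence (conservative superset)
      inc[[as.character(a)]] <- unique(c(inc[[as.character(a)]], rows))
      locked[c(a, b, na_, nb_)] <- TRUE
      accepted <- accepted + 1
    }
    keep <- alive & !(Tr[, 1] == Tr[, 2] | Tr[, 2] == Tr[, 3] |
                        Tr[, 1] == Tr[, 3])
    Tr <- Tr[keep, , drop = FALSE]
    if (accepted == 0) break
  }
  list(V = V, T = Tr)
}

remesh_flip <- function(V, Tr) {
  et <- edge_table(Tr)
  cnt <- table(et$key)
  interior <- names(cnt)[cnt == 2]
  by_key <- split(seq_along(et$key), et$key)
  touched <- logical(nrow(Tr))
  for (ky in interior) {
    rows <- by_key[[ky]]
    t1 <- et$tri_of[rows[1]]; t2 <- et$tri_of[rows[2]]
    if (touched[t1] || touched[t2]) next
    shared <- as.integer(strsplit(ky, " ")[[1]])
    o1 <- setdiff(Tr[t1, ], shared); o2 <- setdiff(Tr[t2, ], shared)
    if (length(o1) != 1 || length(o2) != 1 || o1 == o2) next
    # flipping onto an existing edge would create a non-manifold pair
    if (paste(min(o1, o2), max(o1, o2)) %in% names(cnt)) next
    q_old <- min(tri_quality_rows(V, Tr[c(t1, t2), , drop = FALSE]))
    cand <- flip_tri(Tr[t1, ], Tr[t2, ], shared, o1, o2)
    if (is.null(cand)) next
    q_new <- min(tri_quality_rows(V, cand))
    n_old <- tri_normal_rows(V, Tr[c(t1, t2), , drop = FALSE])
    n_new <- tri_normal_rows(V, cand)
    avg_old <- colSums(n_old)
    if (q_new > q_old * 1.05 && all(n_new %*% avg_old > 0)) {
      Tr[t1, ] <- cand[1, ]; Tr[t2, ] <- cand[2, ]
      touched[c(t1, t2)] <- TRUE
    }
  }
  Tr
}

# build the flipped triangle pair preserving orientation: in triangle t1 the
# shared edge appears directed (s1 -> s2) or (s2 -> s1); the flipped pair
# replaces edge (s1, s2) by (o1, o2) keeping the winding of the wings
flip_tri <- function(t1, t2, shared, o1, o2) {
  s1 <- shared[1]; s2 <- shared[2]
  d1 <- directed_has(t1, s1, s2)
  if (is.na(d1)) return(NULL)
  if (!d1) { tmp <- s1; s1 <- s2; s2 <- tmp }   # now t1 has s1 -> s2
  # t1 = (s1, s2, o1) up to rotation; t2 = (s2, s1, o2)
  rbind(c(s1, o2, o1), c(s2, o1, o2))
}

directed_has <- function(tv, a, b) {
  ed <- rbind(tv[c(1, 2)], tv[c(2, 3)], tv[c(3, 1)])
  if (any(ed[, 1] == a & ed[, 2] == b)) return(TRUE)
  if (any(ed[, 1] == b & ed[, 2] == a)) return(FALSE)
  NA
}

remesh_smooth <- function(V, Tr, lambda) {
  bv <- boundary_vertices(Tr)
  n <- nrow(V)
  acc <- matrix(0, n, 3); cnt <- numeric(n)
  for (k in 1:3) {
    for (j in setdiff(1:3, k)) {
      idx <- Tr[, k]
      acc[, 1] <- acc[, 1] + tab_sum(V[Tr[, j], 1], idx, n)
      acc[, 2] <- acc[, 2] + tab_sum(V[Tr[, j], 2], idx, n)
      acc[, 3] <- acc[, 3] + tab_sum(V[Tr[, j], 3], idx, n)
      cnt <- cnt + tab_sum(rep(1, nrow(Tr)), idx, n)
    }
  }
  target <- acc / pmax(cnt, 1)
  disp <- target - V
  # project onto the tangent plane of each vertex
  vn <- surf_vertex_normals(surface_mesh(V, Tr))
  disp <- disp - vn * rowSums(disp * vn)
  keep <- rep(TRUE, n); keep[bv] <- FALSE
  V[keep, ] <- V[keep, ] + lambda * disp[keep, ]
  V
}

tab_sum <- function(x, idx, n) {
  out <- numeric(n)
  t_ <- tapply(x, idx, sum)
  out[as.integer(names(t_))] <- t_
  out
}

#' One-sided Hausdorff-type distance between surfaces
#'
#' Maximum over samples of `a` (vertices and face centroids) of the distance
#' to the closest face of `b`.
#'
#' @param a,b surface meshes
#' @return distance (mm)
#' @export
surf_distance <- function(a, b) {
  smp <- rbind(a$vertices,
               (a$vertices[a$tri[, 1], ] + a$vertices[a$tri[, 2], ] +
                a$vertices[a$tri[, 3], ]) / 3)
  p1 <- b$vertices[b$tri[, 1], , drop = FALSE]
  p2 <- b$vertices[b$tri[, 2], , drop = FALSE]
  p3 <- b$vertices[b$tri[, 3], , drop = FALSE]
  ctr <- (p1 + p2 + p3) / 3
  rad <- sqrt(pmax(rowSums((p1 - ctr)^2),
                   rowSums((p2 - ctr)^2), rowSums((p3 - ctr)^2)))
  mx <- 0
  for (i in seq_len(nrow(smp))) {
    p <- smp[i, ]
    d_ctr <- sqrt(colSums((t(ctr) - p)^2))
    cand <- which(d_ctr <= min(d_ctr) + max(rad) + 1e-12)
    d <- min(point_tri_dist(p, p1[cand, , drop = FALSE],
                            p2[cand, , drop = FALSE],
                            p3[cand, , drop = FALSE]))
    mx <- max(mx, d)
  }
  mx
}

# distance from point p to triangles (rows), exact projection
point_tri_dist <- function(p, a, b, c_) {
  n <- nrow(a)
  out <- numeric(n)
  for (k in seq_len(n)) {
    A <- a[k, ]; B <- b[k, ]; C <- c_[k, ]
    ab <- B - A; ac <- C - A; ap <- p - A
    d1 <- sum(ab * ap); d2 <- sum(ac * ap)
    if (d1 <= 0 && d2 <= 0) { out[k] <- sqrt(sum(ap^2)); next }
    bp <- p - B; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
    if (d3 >= 0 && d4 <= d3) { out[k] <- sqrt(sum(bp^2)); next }
    vc <- d1 * d4 - d3 * d2
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      v <- d1 / (d1 - d3); out[k] <- sqrt(sum((ap - v * ab)^2)); next
    }
    cp <- p - C; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
    if (d6 >= 0 && d5 <= d6) { out[k] <- sqrt(sum(cp^2)); next }
    vb <- d5 * d2 - d1 * d6
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      w <- d2 / (d2 - d6); out[k] <- sqrt(sum((ap - w * ac)^2)); next
    }
    va <- d3 * d6 - d5 * d4
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
      out[k] <- sqrt(sum((bp - w * (C - B))^2)); next
    }
    den <- va + vb + vc
    v <- vb / den; w <- vc / den
    out[k] <- sqrt(sum((ap - v * ab - w * ac)^2))
  }
  out
}
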