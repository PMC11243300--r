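# Mounting bulges on the artery ---------------------------------------------
#
# PCA coarse fit of the bulge neck ring to the artery neck opening, ICP
# similarity refinement, then the fixed post-transform: shift 0.3 mm along
# the opening normal and upscale by 1.1 about the neck barycenter, making
# room for the stitch band; nearest-neighbour ring zipper closes the surface.

# rotation taking unit vector u to unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    ax <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- ax - sum(ax * u) * u; w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  Wx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + Wx + Wx %*% Wx / (1 + c_)
}

#' Mount a bulge on the artery
#'
#' @param bulge `labeled_bulge`
#' @param artery `artery_surface` with a neck opening
#' @param shift_mm post-fit shift along the opening normal (default 0.3)
#' @param upscale post-fit scale about the neck barycenter (default 1.1)
#' @return list: `surface` (merged watertight surface), `report`
#'   (MountingReport: icp info, applied shift/scale, stitch triangle count,
#'   audits), `bulge_idx`/`artery_idx` vertex ranges, `transform`
#' @export
mount_bulge <- function(bulge, artery, shift_mm = 0.3, upscale = 1.1) {
  if (!length(artery$hole_ring))
    abort_sf("artery has no neck opening to mount on", "sacflow_topology_error")
  ring_t <- artery$vertices[artery$hole_ring, , drop = FALSE]
  pca_t <- neck_pca(ring_t)
  n_t <- pca_t$normal
  # orient the opening normal away from the tube centerline
  tube_ctr_dir <- pca_t$center -
    artery$params$centerline_radius * c(cos(atan2(pca_t$center[2], pca_t$center[1])),
                                        sin(atan2(pca_t$center[2], pca_t$center[1])), 0)
  if (sum(n_t * tube_ctr_dir) < 0) n_t <- -n_t

  ring_s <- bulge$vertices[bulge$neck_ring, , drop = FALSE]
  pca_s <- neck_pca(ring_s)
  n_s <- pca_s$normal
  apexv <- bulge$vertices[bulge$dome_apex, ]
  if (sum((apexv - pca_s$center) * n_s) < 0) n_s <- -n_s

  R0 <- rotation_between(n_s, n_t)
  s0 <- mean(pca_t$extents[1:2]) / mean(pca_s$extents[1:2])
  t0 <- pca_t$center - s0 * as.vector(R0 %*% pca_s$center)
  init <- rigid_similarity(R0, t0, s0)
  icp <- icp_align(ring_s, ring_t, init = init, with_scale = TRUE)
  tf <- icp$transform

  verts_b <- apply_similarity(tf, bulge$vertices)
  ring_b <- verts_b[bulge$neck_ring, , drop = FALSE]
  ctr_b <- colMeans(ring_b)
  # fixed post-transform: shift along the opening normal, upscale about the
  # (shifted) neck barycenter
  verts_b <- sweep(verts_b, 2, -shift_mm * n_t)
  ctr_b <- ctr_b + shift_mm * n_t
  verts_b <- sweep(sweep(verts_b, 2, ctr_b) * upscale, 2, -ctr_b)

  nb <- nrow(verts_b)
  verts <- rbind(verts_b, artery$vertices)
  tri <- rbind(bulge$tri, artery$tri + nb)
  ring_a_idx <- artery$hole_ring + nb
  ring_b_idx <- bulge$neck_ring

  band <- stitch_rings(verts, ring_b_idx, ring_a_idx)
  merged <- surface_mesh(verts, rbind(tri, band))
  au <- surf_audit(merged)
  if (!au$edge_manifold || !au$oriented || au$n_boundary_edges != 0)
    abort_sf("stitched surface failed the topology audit (self-intersecting band?)",
             "sacflow_topology_error")
  report <- list(scale_applied = upscale, shift_applied = shift_mm,
                 icp_rms = icp$rms, icp_iters = icp$iters,
                 icp_scale = tf$s,
                 stitch_triangles = nrow(band),
                 euler = au$euler, watertight = au$n_boundary_edges == 0)
  list(surface = merged, report = report,
       bulge_idx = seq_len(nb), artery_idx = nb + seq_len(nrow(artery$vertices)),
       neck_normal = n_t, transform = tf)
}

# nearest-neighbour zipper between two ordered boundary loops.  Loop arrays
# are in boundary direction (surface on the left); the band traverses loop A
# forward and loop B in the opposite spatial sense so that every boundary
# edge is matched in reverse, keeping the merged surface oriented.
stitch_rings <- function(verts, loop_a, loop_b) {
  A <- loop_a
  B <- loop_b
  pa <- verts[A, , drop = FALSE]; pb <- verts[B, , drop = FALSE]
  # relative winding about the common axis
  ctr <- colMeans(rbind(pa, pb))
  pc <- neck_pca(rbind(pa, pb))
  e1 <- pc$axes[, 1]; e2 <- pc$axes[, 2]
  ang <- function(p) atan2(as.vector(sweep(p, 2, ctr) %*% e2),
                           as.vector(sweep(p, 2, ctr) %*% e1))
  wind <- function(th) sum(sign(diff_wrap(th)))
  # the band walks both rings in the same spatial sense; with outward
  # surfaces the two boundary loops wind oppositely, so reverse B when needed
  if (wind(ang(pa)) * wind(ang(pb)) < 0) B <- rev(B)
  pb <- verts[B, , drop = FALSE]
  # start B at the node nearest to A[1]
  j0 <- which.min(rowSums(sweep(pb, 2, verts[A[1], ])^2))
  B <- c(B[j0:length(B)], B[seq_len(j0 - 1)])
  pb <- verts[B, , drop = FALSE]
  na <- length(A); nb <- length(B)
  tri <- matrix(0L, na + nb, 3)
  i <- 1; j <- 1; k <- 1
  while (i <= na || j <= nb) {
    ai <- A[(i - 1) %% na + 1]; ai1 <- A[i %% na + 1]
    bj <- B[(j - 1) %% nb + 1]; bj1 <- B[j %% nb + 1]
    adv_a <- if (i > na) FALSE else if (j > nb) TRUE else {
      sum((verts[ai1, ] - verts[bj, ])^2) <=
        sum((verts[bj1, ] - verts[ai, ])^2)
    }
    if (adv_a) { tri[k, ] <- c(ai1, ai, bj); i <- i + 1 }
    else       { tri[k, ] <- c(bj, bj1, ai); j <- j + 1 }
    k <- k + 1
  }
  tri
}

diff_wrap <- function(th) {
  d <- diff(c(th, th[1]))
  d[d > pi] <- d[d > pi] - 2 * pi
  d[d < -pi] <- d[d < -pi] + 2 * pi
  d
}
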