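# Morphometric descriptors ---------------------------------------------------

#' Principal component analysis of a point set (neck ring)
#'
#' @param points n x 3 matrix (>= 3 non-collinear points)
#' @return list(center, axes 3x3 columns ordered by decreasing variance,
#'   extents standard deviations along the axes, normal = smallest axis)
#' @export
neck_pca <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  ext <- sv$d / sqrt(nrow(points) - 1)
  if (ext[2] < 1e-10 * max(ext[1], 1))
    abort_sf("collinear points: neck PCA is rank deficient",
             "sacflow_rank_error")
  list(center = ctr, axes = sv$v, extents = ext, normal = sv$v[, 3])
}

#' Morphometric descriptors of a labelled bulge
#'
#' D_eq = (6V/pi)^(1/3) from the capped volume; alpha = angle between the
#' neck normal (oriented toward the dome) and the direction from the neck
#' barycenter to the surface barycenter; aspect ratio = maximal perpendicular
#' height over the average neck diameter (perimeter/pi); NSI =
#' 1 - (18 pi)^(1/3) V^(2/3) / S with S the dome area (neck cap excluded).
#'
#' @param bulge `labeled_bulge` (or surface mesh with `neck_ring`)
#' @return list(D_eq, alpha, aspect_ratio, NSI, volume, surface) (mm, deg)
#' @export
compute_descriptors <- function(bulge) {
  if (is.null(bulge$neck_ring))
    abort_sf("bulge has no neck ring labels", "sacflow_topology_error")
  loops <- surf_boundary_loops(bulge)
  if (length(loops) != 1)
    abort_sf("bulge surface must have exactly one boundary loop (the neck)",
             "sacflow_topology_error")
  ring <- bulge$vertices[bulge$neck_ring, , drop = FALSE]
  pca <- neck_pca(ring)
  nrm <- pca$normal
  V <- abs(surf_volume(bulge))
  S <- surf_area(bulge)
  # orient the normal toward the dome
  fa <- surf_face_areas(bulge)
  ctr3 <- (bulge$vertices[bulge$tri[, 1], , drop = FALSE] +
           bulge$vertices[bulge$tri[, 2], , drop = FALSE] +
           bulge$vertices[bulge$tri[, 3], , drop = FALSE]) / 3
  bary <- colSums(ctr3 * fa) / sum(fa)
  dirv <- bary - pca$center
  if (sum(dirv * nrm) < 0) nrm <- -nrm
  alpha <- acos(pmin(1, pmax(-1, sum(dirv * nrm) / sqrt(sum(dirv^2))))) *
    180 / pi
  height <- max(as.vector(sweep(bulge$vertices, 2, pca$center) %*% nrm))
  per <- sum(sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2)))
  d_neck <- per / pi
  nsi <- 1 - (18 * pi)^(1 / 3) * V^(2 / 3) / S
  list(D_eq = (6 * V / pi)^(1 / 3), alpha = alpha,
       aspect_ratio = height / d_neck, NSI = nsi, volume = V, surface = S)
}

#' Cohort descriptor table
#' @param cohort result of [generate_cohort()]
#' @return data.frame of descriptors, one row per case
#' @export
cohort_descriptors <- function(cohort) {
  do.call(rbind, lapply(seq_along(cohort), function(i) {
    d <- compute_descriptors(cohort[[i]]$mesh)
    data.frame(case = i, D_eq = d$D_eq, alpha = d$alpha,
               aspect_ratio = d$aspect_ratio, NSI = d$NSI,
               volume = d$volume, surface = d$surface)
  }))
}
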