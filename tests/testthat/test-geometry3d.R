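test_that("a smooth symmetric spec yields a hemispherical cap", {
  b <- hemisphere_bulge(r = 1.2)
  d <- compute_descriptors(b)
  expect_lt(abs(d$NSI), 1e-3)
  expect_lt(abs(d$aspect_ratio - 0.5), 1e-3)
  expect_lt(abs(d$alpha), 0.1)
})

test_that("generated volume matches the target diameter (pi D^3/6)", {
  sp <- bulge_spec(seed = 3, target_diameter = 6, height_ratio = 0.8,
                   tilt = 10, lobulation_amp = 0.2, neck_radius = 1.3)
  b <- generate_bulge(sp)
  expect_lt(abs(abs(surf_volume(b)) - pi * 6^3 / 6) / (pi * 6^3 / 6), 0.05)
  d <- compute_descriptors(b)
  expect_lt(abs(d$D_eq - 6) / 6, 0.05)
})

test_that("D_eq inverts the volume formula exactly", {
  b <- hemisphere_bulge(r = 2)
  d <- compute_descriptors(b)
  expect_equal(d$D_eq, (6 * d$volume / pi)^(1 / 3), tolerance = 1e-12)
  # a 113.097 mm^3 bulge has D_eq = 6 mm
  expect_equal((6 * 113.097336 / pi)^(1 / 3), 6, tolerance = 1e-6)
})

test_that("bulge generation is deterministic and seed-sensitive", {
  sp <- bulge_spec(seed = 5, lobulation_amp = 0.2)
  b1 <- generate_bulge(sp, segments = 24, rings = 12)
  b2 <- generate_bulge(sp, segments = 24, rings = 12)
  expect_identical(b1$vertices, b2$vertices)
  sp2 <- bulge_spec(seed = 6, lobulation_amp = 0.2)
  b3 <- generate_bulge(sp2, segments = 24, rings = 12)
  expect_false(isTRUE(all.equal(b1$vertices, b3$vertices)))
})

test_that("every generated bulge passes the labelled-mesh invariants", {
  co <- generate_cohort(8, seed = 3, segments = 24, rings = 12)
  for (cs in co) {
    au <- surf_audit(cs$mesh)
    expect_true(au$edge_manifold); expect_true(au$oriented)
    loops <- surf_boundary_loops(cs$mesh)
    expect_length(loops, 1)
    expect_setequal(loops[[1]], cs$mesh$neck_ring)
    ring <- cs$mesh$vertices[cs$mesh$neck_ring, ]
    pc <- neck_pca(ring)
    dev <- abs(as.vector(sweep(ring, 2, pc$center) %*% pc$normal))
    expect_lt(max(dev), 0.05)  # coplanar ring
    expect_gt(abs(surf_volume(cs$mesh)), 0)
  }
})

test_that("degenerate bulge specs raise parameter errors", {
  expect_error(bulge_spec(neck_radius = -1), class = "sacflow_parameter_error")
  expect_error(bulge_spec(height_ratio = 0.01), class = "sacflow_parameter_error")
  expect_error(bulge_spec(lobulation_amp = 0.9), class = "sacflow_parameter_error")
  expect_error(generate_cohort(0), class = "sacflow_parameter_error")
})

test_that("cohort diameters are stratified over the full size range", {
  ds <- cohort_descriptors(generate_cohort(20, seed = 0, segments = 24, rings = 12))
  expect_lt(min(ds$D_eq), 4)
  expect_gt(max(ds$D_eq), 8)
  ds50 <- cohort_descriptors(generate_cohort(50, seed = 1, segments = 16, rings = 8))
  expect_lt(min(ds50$D_eq), 3.2)
  expect_gt(max(ds50$D_eq), 8.8)
})

test_that("descriptor volume agrees with Monte-Carlo integration", {
  set.seed(8)
  co <- generate_cohort(3, seed = 12, segments = 32, rings = 16)
  for (cs in co) {
    b <- cs$mesh
    d <- compute_descriptors(b)
    lo <- apply(b$vertices, 2, min); hi <- apply(b$vertices, 2, max)
    lo[3] <- 0                       # the bulge occupies z > 0
    npt <- 2e5
    pts <- cbind(runif(npt, lo[1], hi[1]), runif(npt, lo[2], hi[2]),
                 runif(npt, lo[3], hi[3]))
    inside <- raycast_inside(b, pts)
    vol_mc <- mean(inside) * prod(hi - lo)
    expect_lt(abs(vol_mc - d$volume) / d$volume, 0.02)
  }
})

test_that("neck PCA recovers plane, symmetry and axis ratios", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  circ <- cbind(2 * cos(th), 2 * sin(th), rep(0, 60))
  p <- neck_pca(circ)
  expect_lt(p$extents[3], 1e-10)
  expect_lt(abs(p$extents[1] - p$extents[2]), 1e-6)
  ell <- cbind(2 * cos(th), 1 * sin(th), rep(0, 60))
  pe <- neck_pca(ell)
  expect_equal(pe$extents[1] / pe$extents[2], 2, tolerance = 1e-3)
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(neck_pca(line), class = "sacflow_rank_error")
})

test_that("ICP recovers a known similarity from a coarse start", {
  # asymmetric (lobulated) cloud under a 20 deg rotation + 1.1 scale +
  # translation; the coarse fit carries a 5 deg rotation error, i.e. a
  # misalignment at the point-spacing scale, as a PCA prefit provides
  b <- generate_bulge(bulge_spec(seed = 4, target_diameter = 4^(1 / 3),
                                 height_ratio = 0.7, tilt = 12,
                                 lobulation_amp = 0.2, neck_radius = 1),
                      segments = 24, rings = 12)
  src <- b$vertices
  rot <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
  tgt <- t(rot(20 * pi / 180) %*% t(src)) * 1.1 +
    matrix(c(1, 2, 3), nrow(src), 3, byrow = TRUE)
  R0 <- rot(15 * pi / 180)
  init <- rigid_similarity(R0, colMeans(tgt) - 1.1 * as.vector(R0 %*% colMeans(src)),
                           1.1)
  fit <- icp_align(src, tgt, init = init, max_iter = 200)
  moved <- apply_similarity(fit$transform, src)
  expect_lt(sqrt(mean(rowSums((moved - tgt)^2))), 1e-6)
})

test_that("ICP is the identity on identical clouds and tracks noise", {
  set.seed(2)
  src <- matrix(rnorm(150), 50, 3)
  fit <- icp_align(src, src)
  expect_lt(max(abs(fit$transform$R - diag(3))), 1e-12)
  expect_lt(fit$rms, 1e-12)
  rms <- replicate(10, {
    noisy <- src + matrix(rnorm(150, 0, 0.01), 50, 3)
    icp_align(src, noisy)$rms
  })
  expect_lt(abs(mean(rms) - 0.01 * sqrt(3)) / (0.01 * sqrt(3)), 0.5)
})

test_that("the idealized artery matches its stated dimensions", {
  full <- make_artery(neck_hole = FALSE)
  expect_equal(max(full$vertices[, 2]), 8, tolerance = 1e-9)
  art <- make_artery()
  au <- surf_audit(art)
  expect_true(au$edge_manifold); expect_true(au$oriented)
  # tube cross-section diameter via the cap ring (max pairwise distance)
  th0 <- 40 * pi / 180
  sel <- abs(art$vertices[, 1] * sin(th0) - art$vertices[, 2] * cos(th0)) < 1e-9
  rng <- art$vertices[sel, , drop = FALSE]
  expect_lt(abs(max(dist(rng)) - 4) / 4, 0.01)
  # equal cap areas by symmetry (counted as fans around the two centers)
  expect_equal(length(art$hole_ring) > 0, TRUE)
})

test_that("mounting is watertight with the prescribed shift/scale and zipper count", {
  art <- make_artery()
  b <- generate_bulge(bulge_spec(seed = 5, target_diameter = 5, height_ratio = 0.7,
                                 tilt = 15, lobulation_amp = 0.15,
                                 neck_radius = 1.1),
                      segments = 48, rings = 24)
  mt <- mount_bulge(b, art)
  expect_equal(mt$report$scale_applied, 1.1)
  expect_equal(mt$report$shift_applied, 0.3)
  expect_true(mt$report$watertight)
  expect_equal(mt$report$euler, 2)
  expect_equal(mt$report$stitch_triangles,
               length(art$hole_ring) + length(b$neck_ring))
})

test_that("re-fitting an already mounted neck is a near-identity correction", {
  art <- make_artery()
  b <- hemisphere_bulge(r = 1.1, segments = 32, rings = 16)
  mt <- mount_bulge(b, art)
  ring_now <- mt$surface$vertices[mt$bulge_idx[b$neck_ring], , drop = FALSE]
  # undo the fixed post-transform (scale about barycenter, then shift)
  ctr <- colMeans(ring_now)
  ring_fit <- sweep(sweep(ring_now, 2, ctr) / 1.1, 2, -ctr)
  ring_fit <- sweep(ring_fit, 2, 0.3 * mt$neck_normal)
  fit2 <- icp_align(ring_fit, art$vertices[art$hole_ring, , drop = FALSE])
  expect_lt(sqrt(sum(fit2$transform$t^2)), 1e-4)
})
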