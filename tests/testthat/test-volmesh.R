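test_that("boundary-layer thicknesses follow the exact geometric progression", {
  t5 <- bl_thicknesses(5)
  expect_equal(t5, 0.02 * 1.2^(0:4), tolerance = 1e-15)
  expect_equal(sum(t5) * 1e3, 20 * (1.2^5 - 1) / 0.2, tolerance = 1e-9)
  expect_equal(t5[1], 0.02)   # first layer 20 um exactly
})

test_that("shell extrusion gives equal layers and exact offsets", {
  # flat square patch
  g <- sacflow:::grid_to_tri(outer(0:4, rep(1, 5)), outer(rep(1, 5), 0:4))
  patch <- surface_mesh(cbind(g$nodes, 0), g$tri)
  sh <- extrude_solid(patch, thickness_mm = 0.25, layers = 4)
  expect_equal(sh$layer_thickness, 0.0625, tolerance = 1e-12)
  nv <- nrow(patch$vertices)
  for (l in 1:4) {
    d <- sh$vertices[l * nv + seq_len(nv), ] - sh$vertices[(l - 1) * nv + seq_len(nv), ]
    expect_equal(max(abs(sqrt(rowSums(d^2)) - 0.0625)), 0, tolerance = 1e-9)
  }
  # prism volumes = area x thickness for a flat patch
  expect_equal(shell_volume(sh), surf_area(patch) * 0.25, tolerance = 1e-9)
})

test_that("extruding a sphere moves vertices to the offset radius", {
  s <- make_uv_sphere(r = 5, nseg = 48, nring = 24)
  sh <- extrude_solid(s, thickness_mm = 0.25, layers = 4)
  outer_r <- sqrt(rowSums(sh$vertices[sh$outer_idx, ]^2))
  expect_lt(max(abs(outer_r - 5.25)), 1e-6)
})

test_that("extrusion reports self-intersection on concave creases", {
  # sharp v-groove: extruding outward along the averaged normals collapses
  gx <- seq(-2, 2, by = 0.5)
  prof <- abs(gx)                      # v-shaped in z
  X <- outer(gx, rep(1, 5)); Y <- outer(rep(1, length(gx)), seq(0, 2, by = 0.5))
  Z <- outer(prof, rep(1, 5))
  g <- sacflow:::grid_to_tri(X, Y)
  vg <- surface_mesh(cbind(as.vector(X), as.vector(Y), as.vector(Z)), g$tri)
  expect_error(extrude_solid(vg, thickness_mm = 2, layers = 2),
               class = "sacflow_extrusion_error")
})

test_that("2D fluid meshes carry the exact BL stack and refine monotonically", {
  m <- generate_fluid_mesh(list(type = "rectangle", lx = 8, ly = 4),
                           n_bl = 4, core_size = 0.5)
  ys <- sort(unique(round(m$nodes[, 2], 9)))
  expect_equal(diff(ys)[1:4], 0.02 * 1.2^(0:3), tolerance = 1e-9)
  expect_equal(rev(diff(ys))[1:4], 0.02 * 1.2^(0:3), tolerance = 1e-9)
  n1 <- nrow(generate_fluid_mesh(list(type = "rectangle", lx = 8, ly = 4),
                                 core_size = 0.8)$tri)
  n2 <- nrow(generate_fluid_mesh(list(type = "rectangle", lx = 8, ly = 4),
                                 core_size = 0.4)$tri)
  n3 <- nrow(generate_fluid_mesh(list(type = "rectangle", lx = 8, ly = 4),
                                 core_size = 0.2)$tri)
  expect_true(n1 < n2 && n2 < n3)
})

test_that("3D boundary-layer stack is exact and the star-shaped core closes", {
  s <- make_uv_sphere(r = 5, nseg = 24, nring = 12)
  fm <- generate_fluid_mesh(s, n_bl = 5)
  expect_equal(fm$layer_thicknesses, 0.02 * 1.2^(0:4), tolerance = 1e-12)
  expect_equal(sum(fm$layer_thicknesses) * 1e3, 148.832, tolerance = 1e-3)
  expect_true(fm$report$star_shaped)
  expect_false(is.null(fm$core))
  # offsets measured on the stack
  nv <- nrow(s$vertices)
  d1 <- sqrt(rowSums((fm$stack_vertices[nv + seq_len(nv), ] -
                      fm$stack_vertices[seq_len(nv), ])^2))
  expect_lt(max(abs(d1 - 0.02)), 1e-9)
})
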