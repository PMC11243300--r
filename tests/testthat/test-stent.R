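test_that("the deployed braid has 48 wires apposed to the lumen", {
  art <- make_artery()
  wires <- deploy_braid(art, braid_spec())
  expect_length(wires, 48)
  for (w in wires[c(1, 13, 25, 48)]) {
    r <- sqrt(w[, 1]^2 + w[, 2]^2)
    tube_d <- sqrt((r - 6)^2 + w[, 3]^2)
    expect_lt(max(abs(tube_d - (2 - 0.02))), 1e-9)
  }
})

test_that("pitch calibration lands the patch porosity near the target and agrees with sampling", {
  art <- make_artery()
  pr <- compute_porosity(deploy_braid(art, braid_spec()))
  expect_gte(pr$analytic, 0.67); expect_lte(pr$analytic, 0.71)
  expect_gte(pr$range[1], 0.67); expect_lte(pr$range[2], 0.71)
  expect_lt(abs(pr$analytic - pr$sampled), 0.01)
})

test_that("analytic and sampled porosity agree across random braid specs", {
  art <- make_artery()
  set.seed(6)
  for (k in 1:20) {
    sp <- braid_spec(n_wires = sample(c(24, 32, 48), 1),
                     wire_diameter_um = runif(1, 30, 60),
                     pitch_mm = runif(1, 4, 12))
    pr <- compute_porosity(deploy_braid(art, sp))
    expect_lt(abs(pr$analytic - pr$sampled), 0.01)
  }
})

test_that("metal coverage grows monotonically as the pitch shrinks", {
  art <- make_artery()
  pitches <- c(12, 8, 6, 4.5, 3.5)
  por <- sapply(pitches, function(p)
    compute_porosity(deploy_braid(art, braid_spec(pitch_mm = p)))$analytic)
  expect_true(all(diff(por) < 0))
})

test_that("zero wires leave the porosity and the mesh untouched", {
  expect_equal(compute_porosity(list())$analytic, 1)
  m <- mesh_rectangle(4, 2, 16, 8)
  m2 <- immerse_2d(m, NULL)
  expect_identical(nrow(m2$nodes), nrow(m$nodes))
  expect_equal(porosity_2d(30, 0.04, 4), 0.70, tolerance = 1e-12)
})

test_that("2D immersion carves tagged holes and rejects overlapping wires", {
  m <- mesh_rectangle(4, 2, 200, 100)      # 20 um grid
  wires <- data.frame(x = c(1.3, 2.0, 2.7), y = 1, r = 0.02)
  m2 <- immerse_2d(m, wires)
  expect_lt(nrow(m2$nodes), nrow(m$nodes))
  loops <- stent_hole_loops(m2)
  expect_length(loops, 3)
  bad <- data.frame(x = c(2, 2.01), y = 1, r = 0.02)
  expect_error(immerse_2d(m, bad), class = "sacflow_parameter_error")
})
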