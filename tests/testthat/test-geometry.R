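ref_frame <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.4, 0.3, 1),
                   c(2, 1, 0.5))

test_that("superposing a frame onto itself is the identity", {
  spec <- metric_spec(ref_frame, alignment_indices = 1:5)
  out <- superpose(ref_frame, spec)
  expect_equal(out, ref_frame, tolerance = 1e-12)
  expect_equal(subset_rmsd(ref_frame, spec), 0, tolerance = 1e-12)
})

test_that("a rigidly transformed copy superposes back to RMSD ~ 0", {
  spec <- metric_spec(ref_frame, alignment_indices = 1:5)
  for (s in 1:5) {
    moved <- random_rigid_transform(ref_frame, seed = s)
    expect_lt(subset_rmsd(moved, spec), 1e-8)
  }
  # explicit 90-degree rotation about z plus a translation
  R90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  moved <- sweep(ref_frame %*% t(R90), 2, c(3, -2, 7), `+`)
  expect_lt(subset_rmsd(moved, spec), 1e-10)
})

test_that("alignment RMSD matches a brute-force rotation-grid oracle", {
  spec <- metric_spec(ref_frame[1:4, ], alignment_indices = 1:4)
  set.seed(31)
  for (rep in 1:3) {
    perturbed <- ref_frame[1:4, ] + matrix(rnorm(12, sd = 0.2), 4, 3)
    mobile <- random_rigid_transform(perturbed, seed = rep)
    aligned <- superpose(mobile, spec)
    kabsch_rmsd <- sqrt(mean(rowSums((aligned - ref_frame[1:4, ])^2)))
    oracle <- grid_search_rmsd(mobile, ref_frame[1:4, ])
    expect_equal(kabsch_rmsd, oracle, tolerance = 1e-3)
    expect_lte(kabsch_rmsd, oracle + 1e-9)  # Kabsch is the global optimum
  }
})

test_that("measurement subset translated after perfect alignment reads RMSD = d", {
  # alignment points 1:3 identical; measurement points 4:5 shifted by d
  spec <- metric_spec(ref_frame, alignment_indices = 1:3,
                      measurement_indices = 4:5)
  d <- 0.37
  mobile <- ref_frame
  mobile[4:5, 1] <- mobile[4:5, 1] + d
  expect_equal(subset_rmsd(mobile, spec), d, tolerance = 1e-10)
})

test_that("subset RMSD equals the direct formula after oracle superposition", {
  set.seed(7)
  for (rep in 1:5) {
    mob <- ref_frame + matrix(rnorm(15, sd = 0.3), 5, 3)
    spec <- metric_spec(ref_frame, alignment_indices = 1:5,
                        measurement_indices = c(2, 4))
    aligned <- superpose(mob, spec)
    direct <- sqrt(sum((aligned[c(2, 4), ] - ref_frame[c(2, 4), ])^2) / 2)
    expect_equal(subset_rmsd(mob, spec), direct, tolerance = 1e-12)
  }
})

test_that("degenerate alignment sets are rejected with the offending indices", {
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(metric_spec(collinear, alignment_indices = 1:4),
               "degenerate.*1, 2, 3, 4")
})

test_that("rmsd to reference is invariant under rigid motion of the mobile frame", {
  spec <- metric_spec(ref_frame, alignment_indices = 1:5,
                      measurement_indices = 1:5)
  mob <- ref_frame + matrix(seq(-0.2, 0.2, length.out = 15), 5, 3)
  base <- subset_rmsd(mob, spec)
  for (s in 11:13)
    expect_equal(subset_rmsd(random_rigid_transform(mob, s), spec), base,
                 tolerance = 1e-9)
})

test_that("reference-aligned metric coordinates obey the triangle inequality", {
  spec <- metric_spec(ref_frame, alignment_indices = 1:5,
                      measurement_indices = 1:5)
  set.seed(19)
  frames <- array(NA_real_, c(6, 5, 3))
  for (i in 1:6)
    frames[i, , ] <- random_rigid_transform(
      ref_frame + matrix(rnorm(15, sd = 0.4), 5, 3), seed = 100 + i)
  prep <- prepare_metric_coords(frames, spec)
  d <- as.matrix(dist(prep$coords)) / prep$scale
  for (a in 1:6) for (b in 1:6) for (c in 1:6)
    expect_lte(d[a, b], d[a, c] + d[c, b] + 1e-12)
})

test_that("distance features match elementwise hand computation", {
  coords <- array(0, c(2, 3, 3))
  coords[1, 2, ] <- c(3, 4, 0)   # frame 1: point 2 at (3,4,0)
  coords[2, 2, ] <- c(1, 1, 1)
  coords[, 3, ] <- 5
  fs <- distance_features(coords, list(c(1, 2), c(1, 1)), frame_interval = 2)
  expect_equal(fs$values[, "d_1_2"], c(5, sqrt(3)))
  expect_equal(fs$values[, "d_1_1"], c(0, 0))   # coincident points
  expect_equal(fs$frame_interval, 2)
  set.seed(3)
  rnd <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  pairs <- list(c(1, 4), c(2, 6), c(3, 3))
  fs2 <- distance_features(rnd, pairs)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    manual <- sqrt(rowSums((rnd[, p[1], ] - rnd[, p[2], ])^2))
    expect_equal(unname(fs2$values[, k]), manual, tolerance = 1e-12)
  }
  expect_error(distance_features(rnd, list(c(1, 9))), "out of range")
})

test_that("the feature-space metric degenerates to Euclidean distance", {
  spec <- metric_spec(reference_frame = c(1, 2, 3, 4),
                      measurement_indices = c(1, 3))
  expect_equal(subset_rmsd(c(2, 0, 5, 0), spec), sqrt((1 + 4) / 2))
})
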