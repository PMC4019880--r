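test_that("thresholding uses the inclusive >= convention", {
  a <- array(100, c(3, 3, 2))
  expect_true(all(threshold_stack(a, 100)))
  expect_false(any(threshold_stack(a, 101)))
  b <- array(c(10, 200), c(4, 4, 2))
  m <- threshold_stack(b, 100)
  expect_equal(m, b == 200, ignore_attr = TRUE)
})

test_that("connectivity semantics separate or join cubes as expected", {
  a <- array(FALSE, c(10, 10, 6))
  a[1:3, 1:3, 1:3] <- TRUE
  a[6:8, 6:8, 4:6] <- TRUE          # separated by >= 2 voxels on every axis
  expect_equal(n_labels(connected_components_3d(a, 26)), 2L)
  b <- array(FALSE, c(8, 8, 4))
  b[1:3, 1:3, 1:3] <- TRUE
  b[4:6, 1:3, 1:3] <- TRUE          # face-sharing cubes
  for (conn in c(6, 18, 26))
    expect_equal(n_labels(connected_components_3d(b, conn)), 1L)
  d <- array(FALSE, c(4, 4, 4))
  d[2, 2, 2] <- TRUE
  d[3, 3, 3] <- TRUE                # corner contact only
  expect_equal(n_labels(connected_components_3d(d, 26)), 1L)
  expect_equal(n_labels(connected_components_3d(d, 18)), 2L)
  expect_equal(n_labels(connected_components_3d(d, 6)), 2L)
  e <- array(FALSE, c(4, 4, 4))
  e[2, 2, 2] <- TRUE
  e[3, 3, 2] <- TRUE                # in-plane edge contact
  expect_equal(n_labels(connected_components_3d(e, 18)), 1L)
  expect_equal(n_labels(connected_components_3d(e, 6)), 2L)
})

test_that("labeling is deterministic in raster-scan first-voxel order", {
  m <- random_mask(c(12, 10, 5), 0.4, seed = 6)
  v1 <- connected_components_3d(m, 26)
  v2 <- connected_components_3d(m, 26)
  expect_identical(unclass(v1), unclass(v2))
  # first foreground voxel in storage order always carries label 1
  expect_equal(unclass(v1)[which(m)[1]], 1L)
  expect_equal(unclass(v1), canonical_labels(v1), ignore_attr = TRUE)
})

test_that("component partitions match the min-propagation oracle", {
  for (s in 1:10) {
    dims <- c(sample(8:20, 1), sample(8:20, 1), sample(4:10, 1))
    m <- random_mask(dims, runif(1, 0.2, 0.5), seed = 100 + s)
    for (conn in c(6, 18, 26)) {
      got <- canonical_labels(connected_components_3d(m, conn))
      expect_identical(got, oracle_cc(m, conn))
    }
  }
})

test_that("size filter removes strictly-smaller regions and compacts labels", {
  a <- array(FALSE, c(30, 30, 8))
  a[1:10, 1:10, 1:5] <- TRUE                 # 500 voxels
  a[20:29, 20:29, 1:2] <- TRUE               # 200 voxels
  a[15, 15, 8] <- TRUE                       # 1 voxel
  v <- connected_components_3d(a, 26)
  expect_equal(sort(label_sizes(v)), c(1L, 200L, 500L))
  f <- size_filter(v, 200)
  expect_equal(sort(label_sizes(f)), c(200L, 500L))   # boundary case kept
  expect_equal(n_labels(size_filter(v, 201)), 1L)     # 200 strictly smaller
  expect_identical(unclass(size_filter(v, 0)), unclass(v))
  # voxel conservation: removed voxels all become background
  expect_equal(sum(unclass(f) > 0) + sum(unclass(f) == 0), length(f))
  expect_equal(sum(label_sizes(f)), sum(unclass(f) > 0))
})

test_that("raising the threshold never adds foreground", {
  set.seed(17)
  a <- array(sample(0:255, 2000, TRUE), c(20, 20, 5))
  counts <- vapply(c(0, 50, 120, 200, 256), function(l)
    sum(threshold_stack(a, l)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detector recovers well-separated bright cells exactly", {
  p <- tiny_profile(width = 96, height = 96, n_planes = 16)
  pop <- cell_population(10, min_separation = 7, allow_boundary_cut = FALSE)
  g <- generate_stack(p, pop, noise_model(), seed = 12)
  out <- detect_cells(g$stack, detector_params(threshold = 70,
                                               min_voxels = 25))
  expect_equal(n_labels(out$labels), 10L)
  expect_equal(nrow(out$markers), 10L)
  m <- match_markers(g$markers, out$markers, tolerance_spec(3, 2))
  expect_equal(m$n_tp, 10L)
  # empty stack
  g0 <- generate_stack(p, cell_population(0), noise_model(), seed = 12)
  out0 <- detect_cells(g0$stack, detector_params(threshold = 70,
                                                 min_voxels = 25))
  expect_equal(nrow(out0$markers), 0L)
})

test_that("touching cells merge into one region (known failure mode)", {
  p <- acquisition_profile("close", 0.25, 0.25, 0.5, 31, 31, 17,
                           modality = "fluorescence",
                           label_target = "nucleus")
  pop <- cell_population(2, radius_xy_range = c(2.4, 2.5),
                         radius_z_range = c(2.4, 2.5), min_separation = 2,
                         allow_boundary_cut = FALSE)
  g <- generate_stack(p, pop, noise_model(), seed = 9)
  out <- detect_cells(g$stack, detector_params(threshold = 70,
                                               min_voxels = 25))
  expect_equal(nrow(g$markers), 2L)
  expect_equal(n_labels(out$labels), 1L)
})

test_that("size-filter voxel volumes reproduce the published cubic-micron figures", {
  p <- preset_profiles()
  expect_equal(round_half_away(size_filter_volume_um3(1000, p[["3A"]]), 1), 5.2)
  expect_equal(round_half_away(size_filter_volume_um3(1000, p[["3C"]]), 1), 5.2)
  expect_equal(round_half_away(size_filter_volume_um3(25, p[["3B"]]), 1), 5.3)
  expect_equal(round_half_away(size_filter_volume_um3(1000, p[["3D"]]), 1), 2.8)
})
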