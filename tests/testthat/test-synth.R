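test_that("acquisition presets match the published stack geometries", {
  p <- preset_profiles()
  expect_named(p, c("3A", "3B", "3C", "3D"))
  expect_equal(p[["3B"]]$lateral_spacing_x, 0.46056)
  expect_equal(p[["3B"]]$lateral_spacing_y, 0.46056)
  expect_equal(p[["3B"]]$axial_spacing, 1.0)
  expect_equal(c(p[["3B"]]$width, p[["3B"]]$height, p[["3B"]]$n_planes),
               c(512L, 512L, 51L))
  expect_equal(c(p[["3A"]]$width, p[["3A"]]$height, p[["3A"]]$n_planes),
               c(1388L, 1040L, 45L))
  expect_equal(p[["3A"]]$axial_spacing, 0.5)
  expect_equal(p[["3A"]]$lateral_spacing_x, 0.102134)
  expect_equal(p[["3D"]]$modality, "brightfield_rgb")
  expect_equal(p[["3D"]]$lateral_spacing_x, 0.075173)
  expect_equal(p[["3C"]]$label_target, "cytoplasm")
})

test_that("empty population yields pure background and empty truth", {
  p <- tiny_profile()
  g <- generate_stack(p, cell_population(0), noise_model(), seed = 1)
  expect_equal(nrow(g$markers), 0L)
  expect_equal(n_labels(g$labels), 0L)
  expect_true(all(unclass(g$labels) == 0L))
  # background noise only: values concentrated near the background level
  expect_lt(max(unclass(g$stack)), 0.25 * 255)
})

test_that("identical profile, population, noise and seed are bit-identical", {
  p <- tiny_profile()
  pop <- cell_population(8, min_separation = 5)
  g1 <- generate_stack(p, pop, noise_model(), seed = 77)
  g2 <- generate_stack(p, pop, noise_model(), seed = 77)
  expect_identical(unclass(g1$stack), unclass(g2$stack))
  expect_identical(unclass(g1$labels), unclass(g2$labels))
  expect_equal(as.data.frame(g1$markers), as.data.frame(g2$markers))
  g3 <- generate_stack(p, pop, noise_model(), seed = 78)
  expect_false(identical(unclass(g1$stack), unclass(g3$stack)))
})

test_that("interior-only populations never touch the stack faces", {
  p <- tiny_profile(width = 64, height = 64, n_planes = 16)
  pop <- cell_population(20, min_separation = 5, allow_boundary_cut = FALSE)
  g <- generate_stack(p, pop, noise_model(), seed = 13)
  expect_equal(nrow(g$markers), 20L)
  expect_true(all(g$markers$boundary == 0L))
  a <- unclass(g$labels)
  d <- dim(a)
  faces <- c(a[1, , ], a[d[1], , ], a[, 1, ], a[, d[2], ], a[, , 1],
             a[, , d[3]])
  expect_true(all(faces == 0L))
})

test_that("marker boundary flags agree with a face scan of the labels", {
  p <- tiny_profile(width = 40, height = 40, n_planes = 12)
  pop <- cell_population(12, min_separation = 5, allow_boundary_cut = TRUE)
  g <- generate_stack(p, pop, noise_model(), seed = 29)
  flags <- oracle_face_flags(g$labels)
  expect_gt(sum(flags), 0)          # the scenario does produce cut cells
  expect_gt(sum(!flags), 0)
  expect_equal(as.logical(g$markers$boundary), flags)
  expect_equal(boundary_touch_flags(g$labels), flags)
})

test_that("voxel-mean centroids of interior cells sit at the placement centers", {
  p <- tiny_profile(width = 64, height = 64, n_planes = 16)
  pop <- cell_population(15, min_separation = 5, allow_boundary_cut = FALSE)
  g <- generate_stack(p, pop, noise_model(), seed = 41)
  rc <- region_centroids(g$labels)
  rc <- rc[order(rc$label), ]
  sp <- attr(g$labels, "spacing")
  for (i in seq_len(nrow(rc))) {
    m <- g$markers[g$markers$id == rc$label[i], ]
    expect_lt(abs(rc$x_um[i] - m$x_um) / sp["x"], 0.5)
    expect_lt(abs(rc$y_um[i] - m$y_um) / sp["y"], 0.5)
    expect_lt(abs(rc$z_um[i] - m$z_um) / sp["z"], 0.5)
  }
})

test_that("heavier noise strictly degrades contrast-to-noise", {
  p <- tiny_profile()
  pop <- cell_population(6, min_separation = 5)
  cnr <- vapply(c(0.02, 0.06, 0.12), function(sdv) {
    g <- generate_stack(p, pop, noise_model(gaussian_sd = sdv), seed = 55)
    contrast_to_noise(g$stack, g$labels)
  }, numeric(1))
  expect_true(all(diff(cnr) < 0))
})

test_that("impossible placements fail explicitly", {
  p <- tiny_profile(width = 16, height = 16, n_planes = 6)
  pop <- cell_population(40, min_separation = 6, allow_boundary_cut = TRUE)
  expect_error(generate_stack(p, pop, noise_model(), seed = 2),
               "failed to place")
  pop2 <- cell_population(1, radius_xy_range = c(30, 31),
                          radius_z_range = c(30, 31),
                          allow_boundary_cut = FALSE)
  expect_error(generate_stack(p, pop2, noise_model(), seed = 2),
               "cannot fit")
})

test_that("thomas-process clustering concentrates cells around parents", {
  p <- tiny_profile(width = 96, height = 96, n_planes = 20)
  pop_u <- cell_population(30, min_separation = 2,
                           radius_xy_range = c(1, 1.2),
                           radius_z_range = c(1, 1.2))
  pop_c <- pop_u
  pop_c$clustering <- 3
  g_u <- generate_stack(p, pop_u, noise_model(), seed = 8)
  g_c <- generate_stack(p, pop_c, noise_model(), seed = 8)
  mean_nn <- function(m) {
    d <- as.matrix(dist(cbind(m$x_um, m$y_um, m$z_um)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(mean_nn(g_c$markers), mean_nn(g_u$markers))
})

test_that("median-plane ground-truth z snaps to image planes", {
  p <- tiny_profile()
  pop <- cell_population(6, min_separation = 5)
  g <- generate_stack(p, pop, noise_model(), seed = 3, gt_z = "median_plane")
  sz <- p$axial_spacing
  expect_true(all(abs(g$markers$z_um / sz - round(g$markers$z_um / sz)) < 1e-9))
})

test_that("brightfield rendering darkens cells in red but brightens chromaticity", {
  p <- tiny_profile(modality = "brightfield_rgb")
  pop <- cell_population(5, radius_xy_range = c(2, 2.5), min_separation = 6)
  g <- generate_stack(p, pop, noise_model(), seed = 19)
  fg <- unclass(g$labels) > 0
  red <- unclass(g$stack)[, , , 1]
  expect_lt(mean(red[fg]), mean(red[!fg]))
  r <- unclass(red_chromaticity(g$stack))
  expect_gt(mean(r[fg]), mean(r[!fg]))
})

test_that("all-background brightfield keeps the red channel near its level", {
  lbl <- labeled_volume(array(0L, c(20, 20, 6)), c(0.5, 0.5, 1))
  s <- render_brightfield(lbl, array(0, c(20, 20, 6)), seed = 4,
                          background_level = 0.9, noise_sd = 0.02)
  red <- unclass(s)[, , , 1]
  expect_true(all(red > (0.9 - 3.5 * 0.02) * 255))
  expect_error(render_brightfield(lbl, array(0, c(10, 10, 6)), seed = 1),
               "geometry")
})
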