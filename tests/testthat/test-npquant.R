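test_that("the analysis slab excludes 10% of the major radius per side", {
  st <- zstack(array(0, c(4, 4, 40)), dz = 0.35, dxy = 0.1, np_diameter = 200)
  slab <- analysis_slab(st, major_radius = 7)      # ceil(0.7/0.35) = 2
  expect_equal(slab, 3:38)
  st15 <- zstack(array(0, c(4, 4, 40)), dz = 0.15, dxy = 0.1, np_diameter = 44)
  expect_equal(analysis_slab(st15, 7), 6:35)       # ceil(0.7/0.15) = 5
  thin <- zstack(array(0, c(4, 4, 4)), dz = 0.35, dxy = 0.1, np_diameter = 200)
  expect_error(analysis_slab(thin, 7), "too thin")
  # monotonicity: a larger radius never retains more slices
  lens <- vapply(seq(1, 20, by = 0.5), function(r) {
    length(analysis_slab(st, r))
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("occupied volume converts to particle count by the nominal volume", {
  # 0.0419 um^3 of 200 nm spheres is 10 particles
  v_single <- (4 / 3) * pi * 0.1^3
  expect_equal(0.0419 / v_single, 10, tolerance = 5e-3)
  st <- zstack(array(0, c(8, 8, 8)), dz = 0.35, dxy = 0.05, np_diameter = 200)
  expect_warning(q <- count_particles(st, threshold = 1), "zero counts")
  expect_equal(q$voxel_count, 0)
  expect_equal(q$particle_count, 0)
})

test_that("occupied volume scales linearly in dz and quadratically in dxy", {
  g <- gen_zstack(3, 200, seed = 61, snr = Inf)
  v <- g$stack$voxels
  thr <- 0.02
  base <- count_particles(zstack(v, 0.35, 0.05, 200), threshold = thr)
  dz2 <- count_particles(zstack(v, 0.70, 0.05, 200), threshold = thr)
  dxy2 <- count_particles(zstack(v, 0.35, 0.10, 200), threshold = thr)
  expect_equal(dz2$occupied_volume / base$occupied_volume, 2)
  expect_equal(dxy2$occupied_volume / base$occupied_volume, 4)
})

test_that("planted particle counts are recovered through calibration", {
  ref <- gen_np_reference(96, 200, seed = 62)
  thr <- calibrate_np_threshold(ref$stack, 96)
  for (n in c(25, 40)) {
    g <- gen_zstack(n, 200, seed = 600 + n)
    slab <- analysis_slab(g$stack, g$cell_semi_axes[1])
    q <- count_particles(g$stack, slab, thr)
    expect_lt(abs(q$particle_count - n) / n, 0.10)
  }
})

test_that("the 44 nm mode reports voxel count only", {
  g <- gen_zstack(10, 44, dz = 0.15, cell_semi_axes = c(2.5, 2.5, 1.8),
                  seed = 63)
  ref <- gen_np_reference(49, 44, dz = 0.15, spacing_um = 0.8, seed = 64)
  thr <- calibrate_np_threshold(ref$stack, 49)
  q <- count_particles(g$stack, NULL, thr)
  expect_true(is.na(q$particle_count))
  expect_gt(q$voxel_count, 0)
})

test_that("brightest-pixel thresholds sit near the blob peak", {
  g <- gen_zstack(5, 200, seed = 65, snr = Inf)
  thr4 <- np_threshold_brightest(g$stack)
  expect_gt(thr4, 0.8 * max(g$stack$voxels))
})

test_that("delivery efficiency is a guarded ratio", {
  expect_equal(delivery_efficiency(120, 10)$ratio, 12)
  expect_equal(delivery_efficiency(60, 10)$ratio, 6)
  e0 <- delivery_efficiency(5, 0)
  expect_true(e0$undefined)
  expect_true(is.na(e0$ratio))
  expect_error(delivery_efficiency(-1, 10), "non-negative")
})

test_that("colocalization fraction converts pixels to particles", {
  expect_equal(colocalization_fraction(30, 10, 20), 15)
  expect_equal(colocalization_fraction(0, 10, 20), 0)
  expect_warning(pc <- colocalization_fraction(300, 10, 20), "capping")
  expect_equal(pc, 100)
  expect_error(colocalization_fraction(10, 10, 0), "total_nps")
})
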