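make_disk_image <- function(size, cx, cy, r, value = 200) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  ifelse((xs - cx)^2 + (ys - cy)^2 <= r^2, value, 0)
}

test_that("a filled disk is segmented to its circle within tolerance", {
  img <- make_disk_image(512, 256, 256, 100)
  seg <- segment_cell_circle(img)
  expect_lt(abs(seg$centroid["x"] - 256), 1)
  expect_lt(abs(seg$centroid["y"] - 256), 1)
  expect_lt(abs(seg$cell_radius - 100) / 100, 0.02)
})

test_that("blank images are rejected and small speckles ignored", {
  expect_error(segment_cell_circle(matrix(0, 64, 64)), "foreground")
  img <- make_disk_image(512, 256, 256, 100)
  img[20:22, 20:22] <- 200   # speckle, area << disk
  seg <- segment_cell_circle(img)
  expect_lt(abs(seg$cell_radius - 100) / 100, 0.02)
  img[10:160, 10:160] <- 200   # comparable second region
  expect_warning(segment_cell_circle(img), "comparable")
})

test_that("red-channel windowing detects points inclusively and by cluster", {
  img <- array(0, c(32, 32, 3))
  img[10, 10, 1] <- 150
  img[20, 20, 1] <- 100
  img[25, 25, 1] <- 200
  pts <- detect_high_tension_points(img)
  expect_equal(nrow(pts), 1)
  expect_equal(c(pts$x, pts$y), c(10, 10))
  # window edges are inclusive
  img2 <- array(0, c(8, 8, 3)); img2[2, 2, 1] <- 120; img2[5, 5, 1] <- 180
  expect_equal(nrow(detect_high_tension_points(img2)), 2)
  # 3x3 cluster collapses to one centroid
  img3 <- array(0, c(16, 16, 3)); img3[6:8, 6:8, 1] <- 150
  p3 <- detect_high_tension_points(img3)
  expect_equal(nrow(p3), 1)
  expect_equal(c(p3$x, p3$y), c(7, 7))
  expect_equal(p3$n_pixels, 9L)
  expect_error(detect_high_tension_points(array(3000, c(4, 4, 3))), "8-bit")
})

test_that("polar mapping follows the counter-clockwise y-up convention", {
  ctr <- c(50, 50); r <- 30
  pts <- data.frame(x = c(80, 50, 50), y = c(50, 20, 50))
  pm <- polarize_points(pts, ctr, r)
  expect_equal(pm$norm_r, c(1, 1, 0))
  expect_equal(pm$theta, c(0, 90, 0))   # image y down -> up is +90
  expect_false(any(pm$outside_cell))
  out <- polarize_points(data.frame(x = 90, y = 50), ctr, r)
  expect_true(out$outside_cell)
  expect_error(polarize_points(pts, ctr, 0), "positive")
})

test_that("angular concentration over the 8 fixed 45-degree bins", {
  one_sector <- data.frame(theta = runif(16, 10, 30))
  ac <- angular_concentration(one_sector)
  expect_equal(length(ac$counts), 8)
  expect_equal(sum(ac$counts), 16)
  expect_equal(ac$max_bin_fraction, 100)
  expect_equal(ac$baseline, 12.5)

  even <- data.frame(theta = seq(22.5, 337.5, by = 45))
  ace <- angular_concentration(even)
  expect_equal(unname(ace$counts), rep(1L, 8))
  expect_equal(ace$max_bin_fraction, 12.5)

  half <- data.frame(theta = c(runif(5, 100, 130), runif(5, 0, 360)))
  half$theta[6:10] <- c(5, 50, 200, 250, 300)  # one per distinct other bin
  expect_equal(angular_concentration(half)$max_bin_fraction, 50)
  expect_error(angular_concentration(data.frame(theta = numeric(0))), "no points")
})

test_that("rotating the image by 90 degrees shifts theta and nothing else", {
  g <- gen_tension_image(cell_radius = 60, point_angles = c(0, 35, 200))
  analyse <- function(img) {
    seg <- segment_cell_circle(img[, , 1] + img[, , 2])
    pts <- detect_high_tension_points(img)
    polarize_points(pts, seg$centroid, seg$cell_radius)
  }
  pm <- analyse(g$image)
  rot <- array(0, dim(g$image))
  for (ch in 1:3) rot[, , ch] <- rot90_img(g$image[, , ch])
  pmr <- analyse(rot)
  expect_equal(sort(pmr$theta %% 360), sort((pm$theta + 90) %% 360),
               tolerance = 0.05)
  expect_equal(sort(pmr$norm_r), sort(pm$norm_r), tolerance = 0.02)
  expect_equal(angular_concentration(pmr)$max_bin_fraction,
               angular_concentration(pm)$max_bin_fraction)
})

test_that("planted single-sector maps concentrate as expected", {
  set.seed(7)
  for (i in 1:10) {
    start <- runif(1, 0, 360)
    angles <- (start + runif(16, 0, 40)) %% 360
    g <- gen_tension_image(cell_radius = 60, point_angles = angles)
    seg <- segment_cell_circle(g$image[, , 1] + g$image[, , 2])
    pts <- detect_high_tension_points(g$image)
    ac <- angular_concentration(polarize_points(pts, seg$centroid,
                                                seg$cell_radius))
    expect_gte(ac$max_bin_fraction, 50)
  }
  aligned <- 10 + runif(16, 0, 30)   # inside [0, 45)
  g <- gen_tension_image(cell_radius = 60, point_angles = aligned)
  seg <- segment_cell_circle(g$image[, , 1] + g$image[, , 2])
  ac <- angular_concentration(polarize_points(
    detect_high_tension_points(g$image), seg$centroid, seg$cell_radius))
  expect_equal(ac$max_bin_fraction, 100)
})

test_that("uniform angles reproduce the 12.5% per-bin baseline on average", {
  set.seed(8)
  fr <- replicate(1000, {
    ac <- angular_concentration(data.frame(theta = runif(16, 0, 360)))
    100 * ac$counts[[1]] / ac$n_points
  })
  expect_lt(abs(mean(fr) - 12.5), 1)
})

test_that("cortex ring metrics follow their definitions", {
  expect_equal(cortex_metrics(cortex_ring(8.0, 6.6))$thickness_um, 0.7)
  expect_error(cortex_ring(7, 7), "r_major > r_minor")
  m <- cortex_metrics(cortex_ring(10, 9, total_intensity = 1000))
  expect_equal(m$normalized_intensity, 1000 / (pi * 19))
})

test_that("ring radii are recovered from a synthetic cortex image", {
  g <- gen_ring_image(8.0, 6.6, intensity = 100, dxy = 0.1, noise_sd = 2,
                      seed = 9)
  ring <- estimate_cortex_ring(g$image, g$dxy)
  met <- cortex_metrics(ring)
  expect_equal(met$thickness_um, 0.7, tolerance = 0.1)
  expect_gt(met$normalized_intensity, 0)
})
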