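test_that("make_oblate halves diameters and enforces the oblate invariant", {
  s <- make_oblate(20, 12)
  expect_equal(c(s$a, s$b, s$c), c(10, 10, 6))
  sp <- make_oblate(16.66, 16.66)
  expect_equal(sp$a, sp$c)
  expect_equal(sp$a, 8.33)
  expect_error(make_oblate(12, 20), "prolate")
  expect_error(make_oblate(-1, 1), "positive")
  expect_error(make_oblate(10, 0), "positive")
})

test_that("squared eccentricity matches hand arithmetic and limits", {
  expect_equal(squared_eccentricity(make_oblate(20, 12)), 0.64)
  expect_equal(squared_eccentricity(make_oblate(7, 7)), 0)
  e2 <- squared_eccentricity(make_oblate(20, 1e-6))
  expect_gt(e2, 1 - 1e-10)
  expect_lt(e2, 1)
})

test_that("curvature profile reproduces the equator and pole closed forms", {
  cp <- curvature_profile(make_oblate(20, 12), phi_deg = c(0, 90))
  # equator: rho1 = c^2/a, rho2 = a
  expect_equal(cp$rho1[1], 3.6)
  expect_equal(cp$rho2[1], 10)
  expect_equal(cp$J[1], 1 / 3.6 + 1 / 10)
  # pole: umbilic point, rho1 = rho2 = a^2/c
  expect_equal(cp$rho1[2], 100 / 6)
  expect_equal(cp$rho2[2], 100 / 6)
  expect_equal(cp$J[2], 0.12)
  expect_error(curvature_profile(make_oblate(20, 12), phi_deg = -5), "phi")
  expect_error(curvature_profile(make_oblate(20, 12), phi_deg = 91), "phi")
})

test_that("sphere limit gives constant curvature 1/a in both variants", {
  s <- make_oblate(16.66, 16.66)
  for (v in c("classical", "exponent32")) {
    cp <- curvature_profile(s, phi_deg = seq(0, 90, by = 5), variant = v)
    expect_equal(cp$C1, rep(1 / 8.33, nrow(cp)))
    expect_equal(cp$C2, rep(1 / 8.33, nrow(cp)))
  }
})

test_that("curvature radii agree with the finite-difference oracle", {
  set.seed(41)
  phi <- 0:90
  for (i in 1:50) {
    a <- runif(1, 5, 15)
    c_ <- runif(1, 0.3, 1) * a
    cp <- curvature_profile(make_oblate(2 * a, 2 * c_), phi_deg = phi)
    orc <- oracle_radii(a, c_, phi)
    expect_lt(max(abs(cp$rho1 - orc["rho1", ]) / orc["rho1", ]), 1e-6)
    expect_lt(max(abs(cp$rho2 - orc["rho2", ]) / orc["rho2", ]), 1e-6)
  }
})

test_that("total curvature is maximal at the equator and non-increasing", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 5, 15)
    cp <- curvature_profile(make_oblate(2 * a, 2 * runif(1, 0.2, 1) * a))
    expect_true(all(diff(cp$J) <= 1e-12))
    expect_equal(which.max(cp$J), 1)
  }
})

test_that("compression force scales cubically, linearly and quadratically", {
  expect_equal(compression_force_scale(1, 1, 1, 1), 1)
  expect_equal(compression_force_scale(2, 1, 1, 1), 8)
  expect_equal(compression_force_scale(1, 1, 1, 2), 4)
  # log-linear slopes (3, 1, 1, 2)
  g <- exp(seq(-1, 1, length.out = 9))
  base <- list(beta = 1.3, eta = 0.7, lam = 2.1, u_max = 0.4)
  slopes <- vapply(seq_along(base), function(j) {
    y <- vapply(g, function(v) {
      args <- base; args[[j]] <- base[[j]] * v
      do.call(compression_force_scale, args)
    }, numeric(1))
    unname(coef(lm(log(y) ~ log(g)))[2])
  }, numeric(1))
  expect_equal(slopes, c(3, 1, 1, 2), tolerance = 1e-10)
  expect_error(compression_force_scale(0, 1, 1, 1), "positive")
})

test_that("per-cell curvature table round-trips through CSV", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(cell_id = c("c1", "c2"),
                       d2a_um = c(16.66, 19.2), d2c_um = c(16.66, 12.4)),
            f, row.names = FALSE)
  tab <- cell_curvature_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$parallel_curvature[1], 1 / 8.33)
  # compressed cell: steeper meridional curvature at the equator
  expect_gt(tab$C1_equator[2], tab$C1_equator[1])
  long <- cell_curvature_table(f, phi_deg = c(0, 45, 90), full_profile = TRUE)
  expect_equal(nrow(long), 6)
  expect_error(cell_curvature_table(data.frame(x = 1)), "columns")
})

test_that("osmolarity dilution arithmetic", {
  expect_equal(dilute_osmolarity(274.001, 0.5), 137.0005)
  expect_error(dilute_osmolarity(274, 1.5), "factor")
})
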