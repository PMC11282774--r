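small_domain <- function(pore, ...) {
  pore_domain(cell_radius = 3, pore_diameter = pore, h = 0.25,
              box_radius = 6, box_height = 12, ...)
}

test_that("Stokes-Einstein diffusivities scale inversely with diameter", {
  d1 <- stokes_einstein_D(310, 0.7e-3, 200)
  d2 <- stokes_einstein_D(310, 0.7e-3, 400)
  expect_equal(d1 / d2, 2)
  expect_gt(d1, 1)           # ~3 um^2/s for 200 nm at 37 C
  expect_lt(d1, 10)
  expect_error(stokes_einstein_D(0, 1e-3, 200), "positive")
})

test_that("domain construction guards geometry and pore resolution", {
  expect_s3_class(small_domain(1.5), "pore_domain")
  expect_s3_class(small_domain(0.5), "pore_domain")
  expect_error(pore_domain(cell_radius = 3, pore_diameter = 0.5, h = 1,
                           box_radius = 6, box_height = 12),
               "under-resolved")
  expect_error(pore_domain(cell_radius = 3, pore_diameter = 0, h = 0.25,
                           box_radius = 3, box_height = 12), "box too small")
  expect_error(small_domain(1.5, D_membrane = 100), "out-diffuse")
})

test_that("a sealed membrane admits nothing and mass is conserved", {
  res <- solve_uptake(small_domain(0), t_end = 30, dt = 1)
  expect_true(all(res$intracellular_amount == 0))
  expect_lt(res$mass_error, 1e-6)
})

test_that("uptake through a pore is positive, monotone in time and pore size", {
  r15 <- solve_uptake(small_domain(1.5), t_end = 60, dt = 1)
  r05 <- solve_uptake(small_domain(0.5), t_end = 60, dt = 1)
  expect_lt(r15$mass_error, 1e-6)
  expect_true(all(diff(r15$intracellular_amount) > -1e-12))
  expect_gt(min(r15$intracellular_amount), 0)
  n <- length(r15$times)
  expect_gte(r15$intracellular_amount[n], r05$intracellular_amount[n])
  # and monotone in membrane permeability
  rperm <- solve_uptake(small_domain(0, D_membrane = 0.5), t_end = 60, dt = 1)
  expect_gt(rperm$intracellular_amount[n], 0)
})

test_that("without a membrane the interior equilibrates to the bulk", {
  D <- 2
  dom <- small_domain(0, D_bulk = D, D_cell = D, D_membrane = D,
                      membrane_thickness = 1e-9)
  res <- solve_uptake(dom, t_end = 400, dt = 2, keep_field = TRUE)
  vol_cell <- sum(dom$V[dom$inside])
  vol_tot <- sum(dom$V)
  # uniform equilibrium: intracellular share = cell volume share
  expect_lt(abs(utils::tail(res$intracellular_amount, 1) -
                  vol_cell / vol_tot) / (vol_cell / vol_tot), 0.05)
})

test_that("uniform-diffusivity evolution matches the analytic heat kernel", {
  D <- 0.5
  dom <- pore_domain(cell_radius = 3, pore_diameter = 0, h = 0.125,
                     box_radius = 6, box_height = 12,
                     D_bulk = D, D_cell = D, D_membrane = D,
                     membrane_thickness = 1e-9)
  r2 <- outer(dom$r_c^2, (dom$z_c - dom$z_center)^2, `+`)
  t0 <- 2; t1 <- 4
  init <- as.vector(heat_kernel3(sqrt(r2), D, t0))
  res <- solve_uptake(dom, t_end = t1 - t0, dt = 0.02, init = init,
                      keep_field = TRUE)
  expected <- heat_kernel3(sqrt(r2), D, t1)
  interior <- sqrt(r2) < 4      # away from the no-flux boundary
  rms <- sqrt(mean((res$field[interior] - expected[interior])^2))
  expect_lt(rms / max(expected), 0.02)
})

test_that("halving the grid changes the final uptake by under 2%", {
  # at the study process time (5 min)
  up <- vapply(c(0.125, 0.0625), function(h) {
    dom <- pore_domain(cell_radius = 3, pore_diameter = 1.0, h = h,
                       box_radius = 6, box_height = 12)
    utils::tail(solve_uptake(dom, t_end = 300, dt = 1)$intracellular_amount, 1)
  }, numeric(1))
  expect_lt(abs(up[2] - up[1]) / up[1], 0.02)
})

test_that("uptake ratios are guarded against empty denominators", {
  a <- solve_uptake(small_domain(1.5), t_end = 30, dt = 1)
  b <- solve_uptake(small_domain(0), t_end = 30, dt = 1)
  expect_equal(uptake_ratio(a, a)$ratio, 1)
  rr <- uptake_ratio(a, b)
  expect_true(rr$undefined)
  expect_true(is.na(rr$ratio))
})
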