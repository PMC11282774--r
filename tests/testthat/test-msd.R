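test_that("MSD closed forms: ballistic, stationary, Brownian ensemble", {
  n <- 41; dt <- 0.5
  tt <- (seq_len(n) - 1) * dt
  ballistic <- trajectory(tt, cbind(tt * 1.0, 0))   # v = 1 um/s
  mb <- compute_msd(ballistic, max_lag_fraction = 0.5)
  expect_equal(mb$msd, mb$lag^2)
  still <- trajectory(tt, cbind(rep(2, n), rep(3, n)))
  expect_true(all(compute_msd(still)$msd == 0))

  set.seed(51)
  D <- 0.1
  curves <- replicate(200, {
    s <- sqrt(2 * D * dt)
    xy <- cbind(cumsum(c(0, rnorm(n - 1, 0, s))),
                cumsum(c(0, rnorm(n - 1, 0, s))))
    compute_msd(trajectory(tt, xy), max_lag_fraction = 0.25)$msd
  })
  ens <- rowMeans(curves)
  lag <- compute_msd(ballistic, max_lag_fraction = 0.25)$lag
  expect_true(all(abs(ens - 4 * D * lag) / (4 * D * lag) < 0.10))
})

test_that("power-law fits are exact on closed-form curves", {
  lag <- seq(0.5, 5, by = 0.5)
  flin <- fit_power_law(data.frame(lag = lag, msd = 4 * 0.1 * lag))
  expect_equal(flin$alpha, 1, tolerance = 1e-12)
  expect_equal(flin$r_squared, 1, tolerance = 1e-12)
  expect_equal(flin$D_est, 0.1, tolerance = 1e-12)
  fsq <- fit_power_law(data.frame(lag = lag, msd = lag^2))
  expect_equal(fsq$alpha, 2, tolerance = 1e-12)
  expect_equal(fsq$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_power_law(data.frame(lag = 1:3, msd = c(0, 0, 1))),
               "fewer than 3")
})

test_that("classification follows the alpha and R-squared rules", {
  mkfit <- function(alpha, r2) {
    structure(list(alpha = alpha, prefactor = 1, r_squared = r2,
                   D_est = 0.25, n_points = 10), class = "power_law_fit")
  }
  expect_equal(classify_transport(mkfit(0.8, 0.9))$label, "diffusive")
  expect_equal(classify_transport(mkfit(1.0, 0.9))$label, "diffusive")
  expect_equal(classify_transport(mkfit(1.5, 0.9))$label, "transported")
  expect_equal(classify_transport(mkfit(1.5, 0.5))$label, "rejected")
  expect_equal(classify_transport(mkfit(1.5, 0.75))$label, "rejected")
  expect_warning(cl <- classify_transport(mkfit(2.3, 0.9)), "ballistic")
  expect_equal(cl$label, "transported")
  expect_true(cl$boundary)
})

test_that("population fractions sum to 100 over accepted tracks", {
  mk <- function(lab) list(label = lab, alpha = 1, r_squared = 0.9)
  p <- population_fractions(c(replicate(40, mk("diffusive"), simplify = FALSE),
                              replicate(40, mk("transported"), simplify = FALSE)))
  expect_equal(p$pct_diffusive, 50)
  expect_equal(p$pct_transported, 50)
  pall <- population_fractions(replicate(5, mk("diffusive"), simplify = FALSE))
  expect_equal(pall$pct_diffusive, 100)
  expect_error(population_fractions(replicate(3, mk("rejected"),
                                              simplify = FALSE)),
               "rejected")
})

test_that("time-origin shifts leave MSD, alpha and labels unchanged", {
  g <- gen_trajectories(5, 0.4, seed = 52)
  tr <- g$tracks[g$tracks$track_id == 1, ]
  t1 <- trajectory(tr$frame * 0.5, cbind(tr$x_um, tr$y_um))
  t2 <- trajectory(tr$frame * 0.5 + 100, cbind(tr$x_um, tr$y_um))
  expect_identical(compute_msd(t1), compute_msd(t2))
  expect_identical(fit_power_law(compute_msd(t1))$alpha,
                   fit_power_law(compute_msd(t2))$alpha)
})

test_that("ballistic and Brownian motion separate cleanly in alpha", {
  set.seed(53)
  n <- 41; dt <- 0.5; tt <- (seq_len(n) - 1) * dt
  for (v in c(0.3, 0.6, 1)) {
    th <- runif(1, 0, 2 * pi)
    traj <- trajectory(tt, cbind(tt * v * cos(th), tt * v * sin(th)))
    expect_gt(fit_power_law(compute_msd(traj))$alpha, 1.8)
  }
  # ensemble-mean Brownian fit
  D <- 0.05
  curves <- replicate(200, {
    s <- sqrt(2 * D * dt)
    xy <- cbind(cumsum(c(0, rnorm(n - 1, 0, s))),
                cumsum(c(0, rnorm(n - 1, 0, s))))
    compute_msd(trajectory(tt, xy))$msd
  })
  lag <- (1:10) * dt
  fe <- fit_power_law(data.frame(lag = lag, msd = rowMeans(curves)))
  expect_gt(fe$alpha, 0.9); expect_lt(fe$alpha, 1.1)
})

test_that("single-track Brownian alpha stays within [0.6, 1.4] most of the time", {
  set.seed(54)
  g <- gen_trajectories(200, frac_directed = 0, D = 0.05)
  res <- analyze_tracks(g$tracks)
  expect_gte(mean(res$alpha >= 0.6 & res$alpha <= 1.4), 0.90)
})

test_that("directed tracks are recovered as transported", {
  g <- gen_trajectories(40, frac_directed = 1, v = 0.5, D_directed = 0.01,
                        seed = 55)
  res <- analyze_tracks(g$tracks)
  acc <- res$label != "rejected"
  expect_gte(mean(res$label[acc] == "transported"), 0.95)
})
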