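#' Particle trajectory
#'
#' Uniformly sampled 2-D track of one particle (default acquisition:
#' 20 s time-lapse at 0.5 s sampling).
#'
#' @param t Times, s; uniform spacing, at least 10 frames.
#' @param xy Two-column matrix of positions, um.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t, xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) != length(t)) {
    stop_input("xy must be an (n x 2) matrix matching t")
  }
  if (length(t) < 10) stop_input("a trajectory needs at least 10 frames")
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop_input("sampling must be uniform and increasing")
  }
  structure(list(t = as.numeric(t), xy = unname(xy)), class = "trajectory")
}

#' Time-averaged mean squared displacement
#'
#' For each lag `k * dt` up to `max_lag_fraction` of the trajectory
#' length, averages the squared displacement over all frame pairs at that
#' lag. The default fraction 0.25 restricts the curve to short lags where
#' the time-averaged estimator has usable variance.
#'
#' @param traj A [trajectory()].
#' @param max_lag_fraction Fraction of the trajectory length to use,
#'   in (0, 1].
#' @return An object of class `msd_curve`: data frame with columns
#'   `lag` (s) and `msd` (um^2).
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  if (max_lag_fraction <= 0 || max_lag_fraction > 1) {
    stop_input("max_lag_fraction must be in (0, 1]")
  }
  n <- nrow(traj$xy)
  dt <- traj$t[2] - traj$t[1]
  kmax <- max(1L, floor(max_lag_fraction * (n - 1)))
  if (kmax < 2) stop_input("fewer than 2 usable lags")
  msd <- vapply(seq_len(kmax), function(k) {
    d <- traj$xy[(1 + k):n, , drop = FALSE] - traj$xy[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  structure(data.frame(lag = seq_len(kmax) * dt, msd = msd),
            class = c("msd_curve", "data.frame"))
}

#' Power-law fit of an MSD curve
#'
#' Ordinary least squares of `log(MSD)` on `log(lag)`: the slope is the
#' anomalous scaling exponent alpha, and for 2-D diffusion
#' (`MSD = 4 D lag`) the prefactor over 4 estimates the diffusion
#' coefficient. Non-positive MSD points are dropped before taking logs.
#'
#' @param msd An [compute_msd()] result or data frame with `lag`, `msd`.
#' @return An object of class `power_law_fit` with `alpha`, `prefactor`
#'   (um^2 / s^alpha), `r_squared`, `D_est` (um^2/s, prefactor / 4), and
#'   `n_points`.
#' @export
fit_power_law <- function(msd) {
  ok <- is.finite(msd$msd) & msd$msd > 0 & msd$lag > 0
  if (sum(ok) < 3) stop_input("fewer than 3 positive MSD points")
  lx <- log(msd$lag[ok]); ly <- log(msd$msd[ok])
  fit <- lm(ly ~ lx)
  alpha <- unname(coef(fit)[2])
  prefactor <- exp(unname(coef(fit)[1]))
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  structure(list(alpha = alpha, prefactor = prefactor, r_squared = r2,
                 D_est = prefactor / 4, n_points = sum(ok)),
            class = "power_law_fit")
}

#' Transport classification from a power-law fit
#'
#' Fits with `r_squared <= 0.75` are rejected. Accepted fits are labelled
#' `diffusive` for alpha <= 1 and `transported` (active transport) for
#' 1 < alpha < 2; alpha >= 2 exceeds the ballistic limit of the
#' transported range and is labelled `transported` with a boundary
#' warning.
#'
#' @param fit A [fit_power_law()] result.
#' @param r2_threshold Acceptance threshold on R^2 (strict, exclusive).
#' @return List with `label` (`"diffusive"`, `"transported"` or
#'   `"rejected"`), `alpha`, `r_squared`, `boundary` (TRUE when
#'   alpha >= 2).
#' @export
classify_transport <- function(fit, r2_threshold = 0.75) {
  stopifnot(inherits(fit, "power_law_fit"))
  boundary <- FALSE
  if (!(fit$r_squared > r2_threshold)) {
    label <- "rejected"
  } else if (fit$alpha <= 1) {
    label <- "diffusive"
  } else {
    label <- "transported"
    if (fit$alpha >= 2) {
      boundary <- TRUE
      warning("alpha >= 2: at or beyond the ballistic boundary of the ",
              "transported range", call. = FALSE)
    }
  }
  list(label = label, alpha = fit$alpha, r_squared = fit$r_squared,
       boundary = boundary)
}

#' Population transport fractions
#'
#' Percentages of diffusive and actively transported particles among the
#' accepted (non-rejected) trajectories, plus tracking bookkeeping.
#'
#' @param classifications List of [classify_transport()] results.
#' @return List with `pct_diffusive`, `pct_transported` (sum to 100 over
#'   accepted tracks), `n_tracked`, `n_accepted`, `n_rejected`.
#' @export
population_fractions <- function(classifications) {
  if (length(classifications) == 0) stop_input("no classifications supplied")
  labels <- vapply(classifications, `[[`, character(1), "label")
  n_acc <- sum(labels != "rejected")
  if (n_acc == 0) {
    stop_input("all ", length(labels), " trajectories rejected (R^2 filter); ",
               "no accepted tracks to summarize")
  }
  list(pct_diffusive = 100 * sum(labels == "diffusive") / n_acc,
       pct_transported = 100 * sum(labels == "transported") / n_acc,
       n_tracked = length(labels),
       n_accepted = n_acc,
       n_rejected = sum(labels == "rejected"))
}

#' Per-track transport analysis of a trajectory table
#'
#' Convenience wrapper: computes the MSD, fits the power law and
#' classifies each track of a long-format table.
#'
#' @param df Data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt Sampling interval, s.
#' @param max_lag_fraction Passed to [compute_msd()].
#' @return Data frame with one row per track: `track_id`, `alpha`,
#'   `r_squared`, `D_est` (`NA` unless labelled diffusive), `label`.
#' @export
analyze_tracks <- function(df, dt = 0.5, max_lag_fraction = 0.25) {
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop_input("need columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(df$track_id)
  rows <- lapply(ids, function(id) {
    tr <- df[df$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    traj <- trajectory(t = tr$frame * dt, xy = cbind(tr$x_um, tr$y_um))
    fit <- fit_power_law(compute_msd(traj, max_lag_fraction))
    cl <- suppressWarnings(classify_transport(fit))
    data.frame(track_id = id, alpha = fit$alpha, r_squared = fit$r_squared,
               D_est = if (cl$label == "diffusive") fit$D_est else NA_real_,
               label = cl$label)
  })
  do.call(rbind, rows)
}
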