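#' Photon decay trace
#'
#' Container for a binned fluorescence photon-arrival histogram.
#'
#' @param t Time-bin centres, ns; strictly increasing, at least 8 bins.
#' @param counts Non-negative photon counts per bin; total > 0.
#' @return An object of class `decay_trace`.
#' @export
decay_trace <- function(t, counts) {
  if (length(t) != length(counts)) stop_input("t and counts differ in length")
  if (length(t) < 8) stop_input("a decay trace needs at least 8 time bins")
  if (any(diff(t) <= 0)) stop_input("time bins must be strictly increasing")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("counts must be non-negative integers")
  }
  if (sum(counts) <= 0) stop_input("decay trace has no photons")
  structure(list(t = as.numeric(t), counts = as.numeric(counts)),
            class = "decay_trace")
}

#' Biexponential fit of a fluorescence decay
#'
#' Fits `I1 * exp(-t/tau1) + I2 * exp(-t/tau2)` (plus an optional constant
#' background) to a photon decay histogram by bounded weighted nonlinear
#' least squares, with Poisson-motivated weights `1/(counts + 1)` and
#' multi-start over log-spaced lifetime pairs. Components are ordered
#' canonically by signal share `I * tau`, so `tau1` is always the
#' majority-signal lifetime — the membrane-tension readout of the
#' Flipper-TR probe (higher lifetime, higher lipid order / tension).
#'
#' @param d A [decay_trace()].
#' @param initial_guess Optional numeric vector of two lifetimes (ns) added
#'   to the start grid.
#' @param background If `TRUE`, include a constant background term.
#' @return An object of class `biexp_fit` with fields `tau1`, `tau2`,
#'   `I1`, `I2`, `background`, `residual_norm` (weighted RMS residual),
#'   and `converged` (FALSE flags a failed fit, never silent).
#' @examples
#' d <- gen_decay(tau1 = 4.7, tau2 = 1.0, i1 = 9, i2 = 1,
#'                n_photons = 1e5, seed = 1)
#' fit_biexponential(d)
#' @export
fit_biexponential <- function(d, initial_guess = NULL, background = FALSE) {
  stopifnot(inherits(d, "decay_trace"))
  n_par <- if (background) 5L else 4L
  if (length(d$t) < n_par) stop_input("fewer bins than fit parameters")
  w <- 1 / (d$counts + 1)
  tot <- max(d$counts)
  starts <- expand.grid(t1 = c(1, 2.5, 5, 8), t2 = c(0.3, 1, 2))
  if (!is.null(initial_guess)) {
    starts <- rbind(starts, data.frame(t1 = max(initial_guess),
                                       t2 = min(initial_guess)))
  }
  dat <- data.frame(t = d$t, counts = d$counts)
  form <- if (background) {
    counts ~ a1 * exp(-t / t1) + a2 * exp(-t / t2) + bg
  } else {
    counts ~ a1 * exp(-t / t1) + a2 * exp(-t / t2)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- list(a1 = 0.8 * tot, a2 = 0.2 * tot,
                  t1 = starts$t1[i], t2 = starts$t2[i])
    lower <- c(0, 0, 1e-3, 1e-3)
    upper <- c(Inf, Inf, 100, 100)
    if (background) {
      start$bg <- 0
      lower <- c(lower, 0); upper <- c(upper, Inf)
    }
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      form, data = dat, start = start, weights = w,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)
    )), silent = TRUE)
    if (!inherits(f, "try-error")) {
      rss <- sum(w * residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(tau1 = NA_real_, tau2 = NA_real_, I1 = NA_real_,
                          I2 = NA_real_, background = NA_real_,
                          residual_norm = NA_real_, converged = FALSE),
                     class = "biexp_fit"))
  }
  co <- coef(best$fit)
  comp <- data.frame(I = c(co[["a1"]], co[["a2"]]),
                     tau = c(co[["t1"]], co[["t2"]]))
  comp <- comp[order(comp$I * comp$tau, decreasing = TRUE), ]
  structure(list(
    tau1 = comp$tau[1], tau2 = comp$tau[2],
    I1 = comp$I[1], I2 = comp$I[2],
    background = if (background) co[["bg"]] else 0,
    residual_norm = sqrt(best$rss / length(d$t)),
    converged = TRUE
  ), class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("biexponential fit: DID NOT CONVERGE\n")
  } else {
    cat(sprintf(
      "biexponential fit: tau1 = %.3f ns (I1 = %.3g), tau2 = %.3f ns (I2 = %.3g)\n",
      x$tau1, x$I1, x$tau2, x$I2))
  }
  invisible(x)
}

#' Fit a lifetime image from per-pixel decay traces
#'
#' Applies [fit_biexponential()] to every masked pixel of a decay stack and
#' returns the tau1 map plus the mean over valid (converged) pixels.
#'
#' @param stack 3-D array `(time bin, y, x)` of photon counts.
#' @param mask Logical or 0/1 matrix `(y, x)`; pixels to fit.
#' @param t Time-bin centres, ns (length `dim(stack)[1]`).
#' @param ... Passed to [fit_biexponential()].
#' @return List with `tau1_map` (matrix, `NA` where unfitted or failed),
#'   `mean_tau1`, `n_fitted`, `n_failed`.
#' @export
fit_lifetime_image <- function(stack, mask, t, ...) {
  if (length(dim(stack)) != 3) stop_input("stack must be (t, y, x)")
  if (!all(dim(stack)[2:3] == dim(mask))) {
    stop_input("stack and mask spatial shapes differ")
  }
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_input("mask selects no pixels")
  tau1_map <- matrix(NA_real_, dim(stack)[2], dim(stack)[3])
  n_failed <- 0L
  for (k in seq_len(nrow(idx))) {
    counts <- stack[, idx[k, 1], idx[k, 2]]
    fit <- if (sum(counts) > 0) {
      fit_biexponential(decay_trace(t, counts), ...)
    } else {
      list(converged = FALSE)
    }
    if (isTRUE(fit$converged)) {
      tau1_map[idx[k, 1], idx[k, 2]] <- fit$tau1
    } else {
      n_failed <- n_failed + 1L
    }
  }
  valid <- tau1_map[!is.na(tau1_map)]
  list(tau1_map = tau1_map,
       mean_tau1 = if (length(valid)) mean(valid) else NA_real_,
       n_fitted = length(valid), n_failed = n_failed)
}
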