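# Independent numerical oracles used across the suite.

# Finite-difference differential-geometry oracle for the principal radii
# of an oblate spheroid's meridian ellipse x = a cos(t), z = c sin(t).
# phi is the geodetic latitude (angle of the surface normal from the
# equatorial plane); the parametric latitude satisfies tan(t) = (c/a) tan(phi).
# rho1 comes from the curvature of the numerically differentiated curve;
# rho2 is the distance along the numerical normal to the rotation axis.
# At the pole (phi = 90) the two radii coincide by axisymmetry.
oracle_radii <- function(a, c_, phi_deg, h = 1e-4) {
  vapply(phi_deg, function(phi) {
    phi_r <- phi * pi / 180
    t0 <- if (phi >= 90) pi / 2 else atan2((c_ / a) * tan(phi_r), 1)
    p <- function(t) c(a * cos(t), c_ * sin(t))
    d1 <- (p(t0 + h) - p(t0 - h)) / (2 * h)
    d2 <- (p(t0 + h) - 2 * p(t0) + p(t0 - h)) / h^2
    speed2 <- sum(d1^2)
    kappa <- abs(d1[1] * d2[2] - d1[2] * d2[1]) / speed2^(3 / 2)
    rho1 <- 1 / kappa
    if (phi >= 90) {
      rho2 <- rho1            # umbilic pole
    } else {
      n_hat <- c(d1[2], -d1[1]) / sqrt(speed2)  # normal to the curve
      rho2 <- abs(p(t0)[1] / n_hat[1])          # along-normal reach to z-axis
    }
    c(rho1 = rho1, rho2 = rho2)
  }, c(rho1 = 0, rho2 = 0))
}

# Brute-force Kruskal-Wallis H statistic from the rank definition
# (no tie correction; suitable for untied data).
oracle_kruskal_H <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  R <- mapply(function(s, e) sum(r[s:e]), starts, ends)
  12 / (n * (n + 1)) * sum(R^2 / sizes) - 3 * (n + 1)
}

# Free-space 3-D heat kernel (unit mass point source).
heat_kernel3 <- function(r, D, t) {
  (4 * pi * D * t)^(-3 / 2) * exp(-r^2 / (4 * D * t))
}

# 90-degree counter-clockwise rotation of an image matrix [y, x]
# (in the mathematical convention with y pointing up).
rot90_img <- function(m) {
  out <- t(m)[ncol(m):1, , drop = FALSE]
  out
}
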