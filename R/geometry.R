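#' Oblate spheroid cell shape
#'
#' A compressed cell is modelled as an oblate spheroid with equatorial
#' semi-axes `a = b` and polar semi-axis `c <= a` (all in micrometres).
#' Semi-axes are supplied as in-flow measured diameters `2a` and `2c`.
#'
#' @param diameter_2a Equatorial diameter 2a, um.
#' @param diameter_2c Polar diameter 2c, um.
#' @return An object of class `oblate_spheroid` with fields `a`, `b`, `c`.
#' @examples
#' make_oblate(20, 12)     # a = b = 10, c = 6
#' make_oblate(16.66, 16.66) # sphere
#' @export
make_oblate <- function(diameter_2a, diameter_2c) {
  if (!is.numeric(diameter_2a) || !is.numeric(diameter_2c) ||
      length(diameter_2a) != 1L || length(diameter_2c) != 1L) {
    stop_input("diameters must be single numeric values")
  }
  if (!is.finite(diameter_2a) || !is.finite(diameter_2c) ||
      diameter_2a <= 0 || diameter_2c <= 0) {
    stop_input("shape violation: diameters must be positive and finite")
  }
  if (diameter_2c > diameter_2a) {
    stop_input("shape violation: polar diameter exceeds equatorial diameter ",
               "(prolate shapes are not admitted)")
  }
  structure(
    list(a = diameter_2a / 2, b = diameter_2a / 2, c = diameter_2c / 2),
    class = "oblate_spheroid"
  )
}

#' @export
print.oblate_spheroid <- function(x, ...) {
  cat(sprintf("oblate spheroid: a = b = %.3f um, c = %.3f um%s\n",
              x$a, x$c, if (x$a == x$c) " (sphere)" else ""))
  invisible(x)
}

#' Squared eccentricity of an oblate spheroid
#'
#' Returns `(a^2 - c^2) / a^2`, the squared first eccentricity of the
#' meridian ellipse. This is the quantity used as e^2 in the curvature
#' radius formulas; it is 0 for a sphere and approaches 1 as the spheroid
#' flattens.
#'
#' @param s An [make_oblate()] object.
#' @return Dimensionless value in `[0, 1)`.
#' @export
squared_eccentricity <- function(s) {
  stopifnot(inherits(s, "oblate_spheroid"))
  (s$a^2 - s$c^2) / s$a^2
}

#' Principal curvature profile along the meridian of an oblate spheroid
#'
#' For each meridian angle phi (geodetic latitude; 0 deg at the equator,
#' 90 deg at the pole) the two principal radii of curvature are
#' \deqn{\rho_1 = a (1 - e^2) / (1 - e^2 \sin^2\phi)^{3/2}}
#' (meridional) and
#' \deqn{\rho_2 = a / (1 - e^2 \sin^2\phi)^{1/2}}
#' (prime vertical, `variant = "classical"`), with `e^2` the
#' [squared_eccentricity()]. The curvatures are `C1 = 1/rho1`,
#' `C2 = 1/rho2` and the total curvature `J = C1 + C2`, maximal at the
#' equator. `variant = "exponent32"` instead applies the exponent 3/2 to
#' both radii and squares the supplied eccentricity value once more — a
#' transcription of the radius formulas that circulates in the applied
#' literature; it is kept for auditability but does not reproduce the
#' classical equator/pole limits and is not validated by the
#' differential-geometry oracle.
#'
#' @param s An [make_oblate()] object.
#' @param phi_deg Meridian angle grid in degrees, each in `[0, 90]`.
#' @param variant `"classical"` (default) or `"exponent32"`.
#' @return A `data.frame` of class `curvature_profile` with columns
#'   `phi`, `rho1`, `rho2`, `C1`, `C2`, `J`, and attributes `e2` (the
#'   squared eccentricity used), `parallel_curvature` (`1/a`) and
#'   `sphere_curvature` (`1/a` when `a == c`, otherwise `NA`).
#' @examples
#' s <- make_oblate(20, 12)
#' cp <- curvature_profile(s)
#' cp[cp$phi == 0, ]  # steepest curvature at the equator
#' @export
curvature_profile <- function(s, phi_deg = 0:90,
                              variant = c("classical", "exponent32")) {
  stopifnot(inherits(s, "oblate_spheroid"))
  variant <- match.arg(variant)
  if (any(!is.finite(phi_deg)) || any(phi_deg < 0) || any(phi_deg > 90)) {
    stop_input("phi values must lie in [0, 90] degrees")
  }
  e2 <- squared_eccentricity(s)
  if (variant == "exponent32") e2 <- e2^2
  sin2 <- sin(phi_deg * pi / 180)^2
  w <- 1 - e2 * sin2
  rho1 <- s$a * (1 - e2) / w^(3 / 2)
  rho2 <- if (variant == "exponent32") s$a / w^(3 / 2) else s$a / sqrt(w)
  out <- data.frame(
    phi = phi_deg, rho1 = rho1, rho2 = rho2,
    C1 = 1 / rho1, C2 = 1 / rho2, J = 1 / rho1 + 1 / rho2
  )
  attr(out, "e2") <- e2
  attr(out, "parallel_curvature") <- 1 / s$a
  attr(out, "sphere_curvature") <- if (s$a == s$c) 1 / s$a else NA_real_
  attr(out, "variant") <- variant
  class(out) <- c("curvature_profile", "data.frame")
  out
}

#' Viscoelastic compression-force scaling
#'
#' Relative magnitude of the elastic compression force exerted on an
#' aligned cell by viscoelastic focusing flow,
#' \deqn{F \propto \beta^3 \eta \lambda U_{max}^2,}
#' where beta is the confinement ratio (cell diameter over channel
#' height), eta the fluid viscosity (Pa s), lambda the fluid relaxation
#' time (s) and U_max the maximum velocity in the channel cross-section
#' (m/s). The proportionality constant is fixed at 1, so the result is in
#' relative units and only ratios between parameter settings are
#' meaningful.
#'
#' @param beta,eta,lam,u_max Strictly positive scalars.
#' @return Relative force, arbitrary units.
#' @examples
#' compression_force_scale(1, 1, 1, 1)              # 1
#' compression_force_scale(2, 1, 1, 1)              # 8: cubic in beta
#' @export
compression_force_scale <- function(beta, eta, lam, u_max) {
  vals <- c(beta = beta, eta = eta, lam = lam, u_max = u_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_input("all force-scale parameters must be strictly positive")
  }
  beta^3 * eta * lam * u_max^2
}

#' Per-cell curvature table from measured in-flow diameters
#'
#' Reads a CSV of measured cell diameters (columns `cell_id`, `d2a_um`,
#' `d2c_um`) or takes an equivalent `data.frame`, and returns equatorial
#' total curvature, parallel curvature and optionally the full per-phi
#' profile in long format.
#'
#' @param x Path to a CSV file or a `data.frame`.
#' @param phi_deg Angle grid passed to [curvature_profile()].
#' @param full_profile If `TRUE`, return one row per cell per phi;
#'   otherwise one summary row per cell.
#' @return A `data.frame`. Summary columns: `cell_id`, `a_um`, `c_um`,
#'   `J_equator`, `C1_equator`, `C2_equator`, `parallel_curvature`.
#' @export
cell_curvature_table <- function(x, phi_deg = 0:90, full_profile = FALSE) {
  df <- if (is.character(x)) read.csv(x) else as.data.frame(x)
  need <- c("cell_id", "d2a_um", "d2c_um")
  if (!all(need %in% names(df))) {
    stop_input("input must have columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    s <- make_oblate(df$d2a_um[i], df$d2c_um[i])
    cp <- curvature_profile(s, phi_deg)
    if (full_profile) {
      cbind(cell_id = df$cell_id[i], a_um = s$a, c_um = s$c, as.data.frame(cp))
    } else {
      eq <- cp[which.min(cp$phi), ]
      data.frame(
        cell_id = df$cell_id[i], a_um = s$a, c_um = s$c,
        J_equator = eq$J, C1_equator = eq$C1, C2_equator = eq$C2,
        parallel_curvature = attr(cp, "parallel_curvature")
      )
    }
  })
  do.call(rbind, rows)
}

#' Osmolarity of a diluted buffer
#'
#' Dilution arithmetic used to design iso- and hypo-osmotic conditions:
#' the osmolarity of a buffer diluted by `factor` is `mosmol * factor`
#' (e.g. 1x PBS at ~274 mOsmol diluted 0.5x gives ~137 mOsmol).
#'
#' @param mosmol Stock osmolarity, mOsmol.
#' @param factor Dilution factor in (0, 1].
#' @return Osmolarity of the dilution, mOsmol.
#' @export
dilute_osmolarity <- function(mosmol, factor) {
  if (mosmol <= 0 || factor <= 0 || factor > 1) {
    stop_input("need mosmol > 0 and dilution factor in (0, 1]")
  }
  mosmol * factor
}
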