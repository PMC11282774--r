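#' Stokes-Einstein diffusivity
#'
#' `D = kB T / (3 pi mu d)` for a particle of diameter `d` in a fluid of
#' viscosity `mu`.
#'
#' @param temperature K.
#' @param viscosity Pa s.
#' @param particle_diameter_nm Particle diameter, nm.
#' @return Diffusivity, um^2/s.
#' @export
stokes_einstein_D <- function(temperature, viscosity, particle_diameter_nm) {
  if (temperature <= 0 || viscosity <= 0 || particle_diameter_nm <= 0) {
    stop_input("temperature, viscosity and particle diameter must be positive")
  }
  kb <- 1.380649e-23
  d_m <- particle_diameter_nm * 1e-9
  1e12 * kb * temperature / (3 * pi * viscosity * d_m)
}

#' Axisymmetric diffusion domain for pore-mediated nanoparticle uptake
#'
#' A spherical cell of radius `cell_radius` sits on the symmetry axis of a
#' cylindrical box filled with a uniform particle suspension. The plasma
#' membrane is modelled as an internal barrier on the finite-volume faces
#' crossing the sphere surface: a series resistance
#' `membrane_thickness / D_membrane` (impermeable when `D_membrane = 0`).
#' A circular pore of diameter `pore_diameter` centred on the +z pole
#' removes the barrier locally, restoring bulk diffusive contact.
#' Diffusivities may be given directly or derived from compartment
#' viscosities via the Stokes-Einstein relation.
#'
#' @param cell_radius Cell radius, um.
#' @param pore_diameter Pore diameter, um (0 = sealed membrane).
#' @param membrane_thickness Membrane thickness, um (default 0.05).
#' @param D_bulk,D_cell,D_membrane Diffusivities, um^2/s. If `NULL`,
#'   derived from `temperature`, the viscosities and
#'   `particle_diameter_nm`.
#' @param temperature K (default 310).
#' @param viscosity_bulk Pa s (default 0.7e-3, water at 37 C).
#' @param viscosity_cell Pa s (default 3x bulk, crowded cytoplasm).
#' @param particle_diameter_nm Particle diameter for Stokes-Einstein, nm.
#' @param box_radius,box_height Domain size, um; default 2x / 4x cell
#'   radius.
#' @param h Grid spacing, um.
#' @param verbose Print a one-line summary.
#' @return An object of class `pore_domain` containing the assembled
#'   sparse conductance operator, cell volumes and geometry masks.
#' @export
pore_domain <- function(cell_radius = 7.5, pore_diameter = 1.5,
                        membrane_thickness = 0.05,
                        D_bulk = NULL, D_cell = NULL, D_membrane = 0,
                        temperature = 310,
                        viscosity_bulk = 0.7e-3, viscosity_cell = 2.1e-3,
                        particle_diameter_nm = 200,
                        box_radius = 2 * cell_radius,
                        box_height = 4 * cell_radius,
                        h = 0.125, verbose = FALSE) {
  if (cell_radius <= 0 || membrane_thickness <= 0 || h <= 0) {
    stop_input("lengths must be positive")
  }
  if (pore_diameter < 0) stop_input("pore_diameter must be >= 0")
  if (pore_diameter > 0 && pore_diameter < 2 * h) {
    stop_input("pore under-resolved: a ", pore_diameter,
               " um pore needs grid spacing <= ", pore_diameter / 2,
               " um (got ", h, ")")
  }
  if (is.null(D_bulk)) {
    D_bulk <- stokes_einstein_D(temperature, viscosity_bulk, particle_diameter_nm)
  }
  if (is.null(D_cell)) {
    D_cell <- stokes_einstein_D(temperature, viscosity_cell, particle_diameter_nm)
  }
  if (D_membrane > D_bulk) stop_input("membrane cannot out-diffuse the bulk")
  if (box_radius < cell_radius + 2 * h || box_height < 2 * cell_radius + 4 * h) {
    stop_input("box too small for the cell")
  }

  nr <- round(box_radius / h)
  nz <- round(box_height / h)
  r_c <- (seq_len(nr) - 0.5) * h
  z_c <- (seq_len(nz) - 0.5) * h
  zc <- box_height / 2
  inside <- outer(r_c^2, (z_c - zc)^2, `+`) <= cell_radius^2  # nr x nz
  Dfield <- ifelse(inside, D_cell, D_bulk)
  V <- matrix(2 * pi * r_c * h^2, nr, nz)

  theta_pore <- if (pore_diameter > 0) {
    asin(min(1, (pore_diameter / 2) / cell_radius))
  } else {
    -1
  }
  # conductance of the face between two adjacent cells with centre
  # diffusivities D1, D2 and face area A. `crossing` marks membrane
  # faces; `w_pore` is the fraction of the face lying inside the pore
  # cone (partially open faces split into open and barrier parallel
  # conductances for smooth grid convergence).
  face_G <- function(D1, D2, A, crossing, w_pore) {
    res_open <- h / (2 * D1) + h / (2 * D2)
    res_memb <- res_open + if (D_membrane > 0) {
      membrane_thickness / D_membrane
    } else {
      Inf
    }
    g_plain <- A / res_open
    w <- ifelse(crossing, w_pore, 1)
    g_barrier <- ifelse(is.finite(res_memb), A / res_memb, 0)
    w * g_plain + (1 - w) * ifelse(crossing, g_barrier, 0)
  }
  # fraction of a face inside the pore cone, sampled along its extent
  pore_frac <- function(r_lo, r_hi, z_lo, z_hi) {
    if (theta_pore < 0) return(rep(0, length(r_lo)))
    K <- 7
    acc <- 0
    for (q in seq_len(K)) {
      f <- (q - 0.5) / K
      rr <- r_lo + f * (r_hi - r_lo)
      zz <- z_lo + f * (z_hi - z_lo)
      acc <- acc + (atan2(rr, zz - zc) <= theta_pore)
    }
    acc / K
  }
  idx <- function(i, j) (j - 1L) * nr + i

  # radial faces between (i, j) and (i+1, j)
  ii <- rep(seq_len(nr - 1L), nz)
  jj <- rep(seq_len(nz), each = nr - 1L)
  A_r <- 2 * pi * (ii * h) * h
  cross_r <- inside[cbind(ii, jj)] != inside[cbind(ii + 1L, jj)]
  w_r <- pore_frac(ii * h, ii * h, z_c[jj] - h / 2, z_c[jj] + h / 2)
  G_r <- face_G(Dfield[cbind(ii, jj)], Dfield[cbind(ii + 1L, jj)],
                A_r, cross_r, w_r)
  # axial faces between (i, j) and (i, j+1)
  i2 <- rep(seq_len(nr), nz - 1L)
  j2 <- rep(seq_len(nz - 1L), each = nr)
  A_z <- 2 * pi * r_c[i2] * h
  cross_z <- inside[cbind(i2, j2)] != inside[cbind(i2, j2 + 1L)]
  w_z <- pore_frac(r_c[i2] - h / 2, r_c[i2] + h / 2,
                   rep(j2 * h, 1), rep(j2 * h, 1))
  G_z <- face_G(Dfield[cbind(i2, j2)], Dfield[cbind(i2, j2 + 1L)],
                A_z, cross_z, w_z)

  from <- c(idx(ii, jj), idx(i2, j2))
  to <- c(idx(ii + 1L, jj), idx(i2, j2 + 1L))
  G <- c(G_r, G_z)
  n <- nr * nz
  S <- Matrix::sparseMatrix(
    i = c(from, to, from, to),
    j = c(to, from, from, to),
    x = c(-G, -G, G, G),
    dims = c(n, n)
  )
  if (verbose) {
    message(sprintf(
      "pore_domain: %d x %d grid (h = %g um), D_bulk = %.3g, D_cell = %.3g um^2/s, pore %.3g um",
      nr, nz, h, D_bulk, D_cell, pore_diameter))
  }
  structure(list(
    S = S, V = as.vector(V), inside = as.vector(inside),
    nr = nr, nz = nz, h = h,
    cell_radius = cell_radius, pore_diameter = pore_diameter,
    membrane_thickness = membrane_thickness,
    D_bulk = D_bulk, D_cell = D_cell, D_membrane = D_membrane,
    temperature = temperature,
    box_radius = box_radius, box_height = box_height,
    r_c = r_c, z_c = z_c, z_center = zc
  ), class = "pore_domain")
}

#' Solve the uptake problem on a pore domain
#'
#' Backward-Euler finite-volume stepping of Fick's second law with
#' spatially varying diffusivity and no-flux outer boundaries. The sparse
#' operator is factorized once (Cholesky) and reused for every step, so
#' the scheme is unconditionally stable and conserves mass to solver
#' precision. The intracellular amount is the concentration integrated
#' over the cell region, normalized by the total mass in the domain.
#'
#' @param domain A [pore_domain()].
#' @param t_end End time, s.
#' @param dt Time step, s.
#' @param init Initial concentration: `NULL` for the standard dosing
#'   condition (1 outside the cell, 0 inside), or a numeric vector of
#'   length `nr * nz`.
#' @param record_every Record the state every this many steps.
#' @param mass_tol Abort if relative mass drift exceeds this.
#' @param keep_field If `TRUE`, include the final concentration field.
#' @return An object of class `uptake_result`: list with `times`,
#'   `intracellular_amount` (fraction of total mass), `total_mass`,
#'   `mass_error` (max relative drift), and optionally `field`
#'   (`nr x nz` matrix).
#' @export
solve_uptake <- function(domain, t_end, dt = 1, init = NULL,
                         record_every = 1L, mass_tol = 1e-6,
                         keep_field = FALSE) {
  stopifnot(inherits(domain, "pore_domain"))
  if (t_end <= 0 || dt <= 0) stop_input("t_end and dt must be positive")
  n <- domain$nr * domain$nz
  c0 <- if (is.null(init)) as.numeric(!domain$inside) else {
    if (length(init) != n) stop_input("init has wrong length")
    as.numeric(init)
  }
  V <- domain$V
  M <- Matrix::Diagonal(x = V / dt) + domain$S
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M))
  n_steps <- ceiling(t_end / dt)
  mass0 <- sum(V * c0)
  times <- numeric(0); uptake <- numeric(0); masses <- numeric(0)
  cc <- c0
  for (s in seq_len(n_steps)) {
    cc <- as.numeric(Matrix::solve(ch, V * cc / dt))
    if (s %% record_every == 0L || s == n_steps) {
      m <- sum(V * cc)
      drift <- abs(m - mass0) / mass0
      if (drift > mass_tol) {
        stop_input("mass drift ", signif(drift, 3), " exceeds tolerance ",
                   mass_tol, " at t = ", s * dt, " s")
      }
      times <- c(times, s * dt)
      uptake <- c(uptake, sum(V[domain$inside] * cc[domain$inside]) / mass0)
      masses <- c(masses, m)
    }
  }
  structure(list(times = times, intracellular_amount = uptake,
                 total_mass = masses,
                 mass_error = max(abs(masses - mass0) / mass0),
                 field = if (keep_field) matrix(cc, domain$nr, domain$nz),
                 domain = domain),
            class = "uptake_result")
}

#' Uptake ratio between two simulated conditions
#'
#' Ratio of intracellular amounts at a common time, e.g. pore vs sealed
#' membrane or large vs small pore.
#'
#' @param with_pore,without_pore [solve_uptake()] results on a shared
#'   time grid.
#' @param t Comparison time, s (defaults to the last common time).
#' @return List with `t`, `numerator`, `denominator`, `ratio` (`NA` with
#'   `undefined = TRUE` when the denominator is zero).
#' @export
uptake_ratio <- function(with_pore, without_pore, t = NULL) {
  stopifnot(inherits(with_pore, "uptake_result"),
            inherits(without_pore, "uptake_result"))
  if (is.null(t)) t <- min(max(with_pore$times), max(without_pore$times))
  pick <- function(res) {
    k <- which(abs(res$times - t) < 1e-9)
    if (!length(k)) {
      stop_input("results were not recorded at a common time t = ", t)
    }
    res$intracellular_amount[k[1]]
  }
  num <- pick(with_pore)
  den <- pick(without_pore)
  if (den == 0) {
    return(list(t = t, numerator = num, denominator = 0,
                ratio = NA_real_, undefined = TRUE))
  }
  list(t = t, numerator = num, denominator = den,
       ratio = num / den, undefined = FALSE)
}
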