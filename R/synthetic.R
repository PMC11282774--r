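#' Synthetic biexponential photon decay
#'
#' Draws `n_photons` photon arrivals from the binned biexponential decay
#' density `i1 exp(-t/tau1) + i2 exp(-t/tau2)` (multinomial counts over
#' `n_bins` bins spanning `[0, t_max]` ns, bin probabilities equal to the
#' exact integral of the density over each bin).
#'
#' @param tau1,tau2 Lifetimes, ns (> 0).
#' @param i1,i2 Component amplitudes (relative).
#' @param n_photons Total photon count (> 0).
#' @param n_bins Number of time bins.
#' @param t_max Record length, ns.
#' @param seed Optional RNG seed (generator is a pure function of
#'   parameters and seed).
#' @return A [decay_trace()].
#' @export
gen_decay <- function(tau1, tau2 = 1, i1 = 9, i2 = 1, n_photons = 1e5,
                      n_bins = 256, t_max = 25, seed = NULL) {
  if (tau1 <= 0 || tau2 <= 0) stop_input("lifetimes must be positive")
  if (n_photons <= 0) stop_input("n_photons must be positive")
  if (i1 < 0 || i2 < 0 || i1 + i2 <= 0) stop_input("invalid amplitudes")
  with_seed(seed, {
    edges <- seq(0, t_max, length.out = n_bins + 1)
    lo <- edges[-length(edges)]; hi <- edges[-1]
    p <- i1 * tau1 * (exp(-lo / tau1) - exp(-hi / tau1)) +
      i2 * tau2 * (exp(-lo / tau2) - exp(-hi / tau2))
    counts <- as.vector(rmultinom(1, n_photons, p / sum(p)))
    decay_trace(t = (lo + hi) / 2, counts = counts)
  })
}

#' Synthetic per-pixel decay stack
#'
#' Renders a `(time, y, x)` photon-count stack in which every pixel of
#' `tau1_map` decays biexponentially with the given dominant lifetime.
#'
#' @param tau1_map Matrix of dominant lifetimes, ns (`NA` = dark pixel).
#' @param tau2,i1,i2,n_photons,n_bins,t_max As in [gen_decay()];
#'   `n_photons` is per pixel.
#' @param seed Optional RNG seed.
#' @return List with `stack` (array `(t, y, x)`), `t` (bin centres) and
#'   `mask` (non-dark pixels).
#' @export
gen_decay_image <- function(tau1_map, tau2 = 1, i1 = 9, i2 = 1,
                            n_photons = 1e4, n_bins = 64, t_max = 25,
                            seed = NULL) {
  with_seed(seed, {
    dm <- dim(tau1_map)
    stack <- array(0, c(n_bins, dm[1], dm[2]))
    tt <- NULL
    for (iy in seq_len(dm[1])) for (ix in seq_len(dm[2])) {
      if (!is.na(tau1_map[iy, ix])) {
        d <- gen_decay(tau1_map[iy, ix], tau2, i1, i2, n_photons,
                       n_bins, t_max)
        stack[, iy, ix] <- d$counts
        tt <- d$t
      }
    }
    list(stack = stack, t = tt, mask = !is.na(tau1_map))
  })
}

#' Synthetic RGB tension map with planted high-tension points
#'
#' Paints a circular cell silhouette and single-pixel (or square-cluster)
#' high-tension points on the cell rim at the requested angles, using the
#' mathematical angle convention of [polarize_points()]. The silhouette's
#' red channel (60) lies outside the default detection window so only the
#' planted points are detectable.
#'
#' @param cell_radius Cell radius, px.
#' @param point_angles Angles of planted points, degrees (normalized to
#'   `[0, 360)`).
#' @param point_red_value Red-channel value of planted points; detectable
#'   when inside `[120, 180]`.
#' @param cluster_size Side of the square pixel cluster per point (1 =
#'   single pixel).
#' @param size Image side, px (default fits the cell with a margin).
#' @param seed Unused (deterministic); kept for generator-interface
#'   uniformity.
#' @return List with `image` (array `(y, x, 3)`, 8-bit values), `truth`
#'   (data frame of planted angles and pixel positions), `centroid`,
#'   `cell_radius`.
#' @export
gen_tension_image <- function(cell_radius = 100, point_angles = numeric(0),
                              point_red_value = 150, cluster_size = 1,
                              size = NULL, seed = NULL) {
  if (cell_radius <= 0) stop_input("cell_radius must be positive")
  size <- size %||% (2 * ceiling(cell_radius) + 41)
  cx <- (size + 1) / 2; cy <- (size + 1) / 2
  img <- array(0, c(size, size, 3))
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  disk <- (xs - cx)^2 + (ys - cy)^2 <= cell_radius^2
  for (ch in 1:3) img[, , ch][disk] <- 60
  ang <- point_angles %% 360
  px <- round(cx + cell_radius * cos(ang * pi / 180))
  py <- round(cy - cell_radius * sin(ang * pi / 180))
  half <- (cluster_size - 1) %/% 2
  for (k in seq_along(ang)) {
    ix <- pmax(1, pmin(size, (px[k] - half):(px[k] + half)))
    iy <- pmax(1, pmin(size, (py[k] - half):(py[k] + half)))
    img[iy, ix, 1] <- point_red_value
    img[iy, ix, 2] <- 30
    img[iy, ix, 3] <- 30
  }
  list(image = img,
       truth = data.frame(angle = ang, x = px, y = py),
       centroid = c(x = cx, y = cy), cell_radius = cell_radius)
}

# Render one PSF-blurred spherical particle into a coarse-grid stack by
# local fine-grid convolution (blur before sampling: the PSF acts on the
# continuous specimen, slices are sampled afterwards). Integrated
# intensity is normalized to the particle volume in voxel units.
render_np_blob <- function(stack, center_um, r_um, dxy, dz, psf_sigma,
                           fgen = c(4, 4, 4)) {
  dm <- dim(stack)
  r_vox <- c(r_um / dxy, r_um / dxy, r_um / dz)
  sig <- psf_sigma   # in coarse voxels: (px, px, slices)
  margin <- ceiling(4 * sig + 1)
  c_vox <- c(center_um[1] / dxy, center_um[2] / dxy, center_um[3] / dz) + 1
  i0 <- pmax(1, floor(c_vox - r_vox - margin))
  i1 <- pmin(dm, ceiling(c_vox + r_vox + margin))
  flen <- (i1 - i0) * fgen + 1
  c_f <- (c_vox - i0) * fgen + 1
  r_f <- r_vox * fgen
  ax <- function(n, c0, r) ((seq_len(n) - c0) / r)^2
  fine <- array(0, flen)
  rho2 <- outer(outer(ax(flen[1], c_f[1], r_f[1]), ax(flen[2], c_f[2], r_f[2]), `+`),
                ax(flen[3], c_f[3], r_f[3]), `+`)
  w <- pmin(1, pmax(0, (1 - sqrt(rho2)) * mean(r_f) + 0.5))  # soft edge
  target_mass <- (4 / 3) * pi * prod(r_vox)
  fine <- array(w * (target_mass / sum(w)) * prod(fgen), flen)
  fine <- fft_blur3(fine, sig * fgen)
  sub <- fine[seq(1, flen[1], by = fgen[1]),
              seq(1, flen[2], by = fgen[2]),
              seq(1, flen[3], by = fgen[3])]
  stack[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
    stack[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] + sub
  stack
}

# Peak intensity of one isolated rendered bead (noise scaling reference).
np_blob_peak <- function(np_diameter, dxy, dz, psf_sigma) {
  r_um <- np_diameter / 2000
  ext <- c(2 * r_um + 10 * psf_sigma[1] * dxy,
           2 * r_um + 10 * psf_sigma[2] * dxy,
           2 * r_um + 10 * psf_sigma[3] * dz)
  dm <- c(ceiling(ext[1] / dxy), ceiling(ext[2] / dxy), ceiling(ext[3] / dz))
  dm <- dm + dm %% 2
  a <- array(0, dm)
  ctr <- c((dm[1] / 2) * dxy, (dm[2] / 2) * dxy, (dm[3] / 2) * dz)
  max(render_np_blob(a, ctr, r_um, dxy, dz, psf_sigma))
}

#' Synthetic nanoparticle z-stack with known ground truth
#'
#' Places `n_particles` non-overlapping spheres of nominal diameter
#' `np_diameter` uniformly inside the inner 80% of a cell ellipsoid
#' (keeping them inside the axial analysis slab), images them with a
#' Gaussian PSF applied before slice sampling, and adds Gaussian camera
#' noise with standard deviation `peak / snr` (peak = single-bead peak
#' intensity).
#'
#' @param n_particles Planted particle count.
#' @param np_diameter Particle diameter, nm.
#' @param cell_semi_axes `c(a, b, c)` of the cell ellipsoid, um.
#' @param dz,dxy Voxel sizes, um.
#' @param psf_sigma PSF sigma `c(px, px, slices)`.
#' @param snr Peak signal-to-noise ratio; `Inf` for clean stacks.
#' @param margin_px,margin_slices Empty border around the cell.
#' @param sep_um Minimum centre separation scales `c(x, y, z)`, um:
#'   candidates closer than Mahalanobis distance 1 under these scales are
#'   rejected, so planted particles remain optically distinguishable
#'   (the axial scale reflects the elongated confocal PSF).
#' @param max_tries Rejection-sampling budget per particle.
#' @param seed Optional RNG seed.
#' @return List with `stack` (a [zstack()]), `truth` (planted count and
#'   centres, um), `cell_semi_axes`, `peak`, `noise_sd`.
#' @export
gen_zstack <- function(n_particles, np_diameter = 200,
                       cell_semi_axes = c(5.0, 5.0, 3.2),
                       dz = 0.35, dxy = 0.05,
                       psf_sigma = c(1, 1, 1.2), snr = 10,
                       margin_px = 10, margin_slices = 5,
                       sep_um = c(0.3, 0.3, 1.5),
                       max_tries = 2000, seed = NULL) {
  if (n_particles < 0) stop_input("n_particles must be >= 0")
  r_um <- np_diameter / 2000
  a <- cell_semi_axes[1]; b <- cell_semi_axes[2]; cc <- cell_semi_axes[3]
  if (r_um >= 0.8 * min(cell_semi_axes)) stop_input("particles larger than cell")
  nx <- 2 * ceiling(a / dxy) + 2 * margin_px
  ny <- 2 * ceiling(b / dxy) + 2 * margin_px
  nz <- 2 * ceiling(cc / dz) + 2 * margin_slices
  nx <- nx + nx %% 2; ny <- ny + ny %% 2; nz <- nz + nz %% 2
  ctr <- c(nx / 2 * dxy, ny / 2 * dxy, nz / 2 * dz)
  with_seed(seed, {
    centers <- matrix(NA_real_, n_particles, 3)
    for (p in seq_len(n_particles)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        u <- runif(3, -1, 1)
        cand <- ctr + u * (0.8 * cell_semi_axes - r_um)
        if (sum((u * (0.8 * cell_semi_axes - r_um) / cell_semi_axes)^2) > 0.64) next
        if (p > 1) {
          dd <- sweep(centers[seq_len(p - 1), , drop = FALSE], 2, cand)
          if (min(sqrt(rowSums(dd^2))) < 2.2 * r_um) next
          sc <- pmax(sep_um, 2.2 * r_um)
          if (min(rowSums(sweep(dd, 2, sc, `/`)^2)) < 1) next
        }
        centers[p, ] <- cand
        ok <- TRUE
        break
      }
      if (!ok) stop_input("could not place ", n_particles,
                          " non-overlapping particles (density infeasible)")
    }
    stack <- array(0, c(nx, ny, nz))
    for (p in seq_len(n_particles)) {
      stack <- render_np_blob(stack, centers[p, ], r_um, dxy, dz, psf_sigma)
    }
    peak <- np_blob_peak(np_diameter, dxy, dz, psf_sigma)
    noise_sd <- if (is.finite(snr)) peak / snr else 0
    if (noise_sd > 0) stack <- stack + rnorm(length(stack), 0, noise_sd)
    list(stack = zstack(stack, dz = dz, dxy = dxy, np_diameter = np_diameter),
         truth = list(n = n_particles, centers_um = centers),
         cell_semi_axes = cell_semi_axes, peak = peak, noise_sd = noise_sd)
  })
}

#' Synthetic reference bead field for threshold calibration
#'
#' Isolated beads of one nominal size on a jittered grid, imaged exactly
#' like [gen_zstack()] stacks (same PSF and noise model). Used by
#' [calibrate_np_threshold()].
#'
#' @param n_beads Number of beads.
#' @param np_diameter,dz,dxy,psf_sigma,snr As in [gen_zstack()].
#' @param spacing_um Grid spacing between beads, um.
#' @param seed Optional RNG seed.
#' @return List with `stack` (a [zstack()]) and `n_beads`.
#' @export
gen_np_reference <- function(n_beads = 96, np_diameter = 200,
                             dz = 0.35, dxy = 0.05,
                             psf_sigma = c(1, 1, 1.2), snr = 10,
                             spacing_um = NULL, seed = NULL) {
  r_um <- np_diameter / 2000
  spacing_um <- spacing_um %||% max(1.2, 6 * r_um)
  per_side <- ceiling(sqrt(n_beads))    # single layer: no axial neighbours
  nxy <- ceiling((per_side + 1) * spacing_um / dxy)
  nxy <- nxy + nxy %% 2
  nz <- 2 * ceiling((psf_sigma[3] * 6 * dz + 2) / dz)
  with_seed(seed, {
    stack <- array(0, c(nxy, nxy, nz))
    z_mid <- nz * dz / 2
    placed <- 0
    for (gy in seq_len(per_side)) {
      for (gx in seq_len(per_side)) {
        if (placed >= n_beads) break
        ctr <- c(gx * spacing_um + runif(1, -0.25, 0.25) * spacing_um,
                 gy * spacing_um + runif(1, -0.25, 0.25) * spacing_um,
                 z_mid + runif(1, -0.5, 0.5) * dz)
        stack <- render_np_blob(stack, ctr, r_um, dxy, dz, psf_sigma)
        placed <- placed + 1
      }
    }
    peak <- np_blob_peak(np_diameter, dxy, dz, psf_sigma)
    if (is.finite(snr)) stack <- stack + rnorm(length(stack), 0, peak / snr)
    list(stack = zstack(stack, dz = dz, dxy = dxy, np_diameter = np_diameter),
         n_beads = n_beads)
  })
}

#' Synthetic particle trajectories with known motion labels
#'
#' Brownian tracks take per-axis Gaussian steps with variance `2 D dt`;
#' directed tracks add a constant drift `v dt` along a random fixed
#' direction on top of (optionally weaker) Brownian motion. Default
#' sampling mimics a 20 s time-lapse at 0.5 s intervals.
#'
#' @param n Number of tracks.
#' @param frac_directed Fraction of actively transported tracks, in
#'   `[0, 1]`.
#' @param D Diffusion coefficient of Brownian tracks, um^2/s.
#' @param v Drift speed of directed tracks, um/s.
#' @param D_directed Residual diffusion of directed tracks, um^2/s.
#' @param dt Sampling interval, s.
#' @param n_frames Frames per track (>= 10).
#' @param seed Optional RNG seed.
#' @return List with `tracks` (long data frame: `track_id`, `frame`,
#'   `x_um`, `y_um`) and `labels` (data frame: `track_id`, `label`).
#' @export
gen_trajectories <- function(n, frac_directed = 0.4, D = 0.05, v = 0.5,
                             D_directed = 0.01, dt = 0.5, n_frames = 41,
                             seed = NULL) {
  if (frac_directed < 0 || frac_directed > 1) {
    stop_input("frac_directed must be in [0, 1]")
  }
  if (dt <= 0) stop_input("dt must be positive")
  if (n_frames < 10) stop_input("need at least 10 frames")
  with_seed(seed, {
    n_dir <- round(n * frac_directed)
    labels <- c(rep("transported", n_dir), rep("diffusive", n - n_dir))
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      directed <- labels[k] == "transported"
      Dk <- if (directed) D_directed else D
      s <- sqrt(2 * Dk * dt)
      x <- cumsum(c(0, rnorm(n_frames - 1, 0, s)))
      y <- cumsum(c(0, rnorm(n_frames - 1, 0, s)))
      if (directed) {
        th <- runif(1, 0, 2 * pi)
        drift <- (seq_len(n_frames) - 1) * dt * v
        x <- x + drift * cos(th)
        y <- y + drift * sin(th)
      }
      rows[[k]] <- data.frame(track_id = k, frame = seq_len(n_frames) - 1,
                              x_um = x, y_um = y)
    }
    list(tracks = do.call(rbind, rows),
         labels = data.frame(track_id = seq_len(n), label = labels))
  })
}

#' Synthetic actin-cortex ring image
#'
#' Paints an annulus of the given radii and intensity, optionally blurred
#' and with Gaussian noise, centred in a square image.
#'
#' @param r_major,r_minor Outer/inner ring radii, um.
#' @param intensity Ring intensity, a.u.
#' @param dxy Pixel size, um.
#' @param blur_px PSF sigma, px.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Optional RNG seed.
#' @return List with `image` (matrix), `truth` (a [cortex_ring()] built
#'   from the planted radii with the planted total intensity) and `dxy`.
#' @export
gen_ring_image <- function(r_major, r_minor, intensity = 100, dxy = 0.05,
                           blur_px = 1, noise_sd = 0, seed = NULL) {
  if (r_major <= r_minor) stop_input("need r_major > r_minor")
  size <- 2 * ceiling(r_major / dxy) + 21
  cx <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  r_px <- sqrt((xs - cx)^2 + (ys - cx)^2) * dxy
  img <- ifelse(r_px >= r_minor & r_px <= r_major, intensity, 0)
  with_seed(seed, {
    if (blur_px > 0) {
      img3 <- fft_blur3(array(img, c(size, size, 1)), c(blur_px, blur_px, 0))
      img <- img3[, , 1]
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    list(image = img,
         truth = cortex_ring(r_major, r_minor,
                             total_intensity = sum(img[r_px >= r_minor & r_px <= r_major])),
         dxy = dxy)
  })
}
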