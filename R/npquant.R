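#' Confocal z-stack container for nanoparticle quantification
#'
#' @param voxels 3-D numeric array `(x, y, z)` of intensities.
#' @param dz Z-spacing, um (0.35 default acquisitions; 0.15 for 44 nm
#'   particles).
#' @param dxy Lateral pixel size, um.
#' @param np_diameter Nominal particle diameter, nm; one of 44, 200, 500,
#'   1000.
#' @return An object of class `zstack`.
#' @export
zstack <- function(voxels, dz, dxy, np_diameter) {
  if (length(dim(voxels)) != 3) stop_input("voxels must be a 3-D array")
  if (dz <= 0 || dxy <= 0) stop_input("dz and dxy must be positive")
  if (!np_diameter %in% c(44, 200, 500, 1000)) {
    stop_input("np_diameter must be one of 44, 200, 500, 1000 nm")
  }
  structure(list(voxels = voxels, dz = dz, dxy = dxy,
                 np_diameter = np_diameter),
            class = "zstack")
}

# Nominal single-particle volume, um^3.
single_np_volume <- function(np_diameter_nm) {
  (4 / 3) * pi * (np_diameter_nm / 2000)^3
}

#' Axial analysis slab of a z-stack
#'
#' Slices near the top and bottom of the cell suffer background and
#' scattering artefacts. A depth of 10% of the cell's major radius is
#' excluded from each end, converted to whole slices by ceiling
#' (conservative exclusion), and the retained contiguous slice range is
#' returned.
#'
#' @param stack A [zstack()].
#' @param major_radius Cell major radius, um.
#' @return Integer vector of retained slice indices (1-based).
#' @examples
#' # 40 slices at dz = 0.35, radius 7 um: ceil(0.7/0.35) = 2 excluded per side
#' @export
analysis_slab <- function(stack, major_radius) {
  stopifnot(inherits(stack, "zstack"))
  if (major_radius <= 0) stop_input("major_radius must be positive")
  nz <- dim(stack$voxels)[3]
  n_excl <- ceiling(round(0.10 * major_radius / stack$dz, 9))
  if (nz - 2 * n_excl < 1) {
    stop_input("stack too thin: ", nz, " slices with ", n_excl,
               " excluded per side leaves nothing to analyse")
  }
  (n_excl + 1):(nz - n_excl)
}

#' Calibrate the counting threshold on a reference bead field
#'
#' The counting threshold is the intensity at which the mean apparent
#' (above-threshold) volume of an isolated reference bead equals the
#' nominal volume of one particle, `(4/3) pi (d/2)^3`. Pooling the sorted
#' voxel intensities of a reference field containing `n_beads` isolated
#' beads, this is the intensity at rank `n_beads * V_single / V_voxel`.
#' The reference field must be acquired and pre-processed exactly like the
#' stacks to be counted (same optics, noise and [count_particles()]
#' filter settings), e.g. a bead calibration slide, or
#' [gen_np_reference()] for synthetic work.
#'
#' @param reference A [zstack()] containing only isolated beads.
#' @param n_beads Number of beads in the reference field.
#' @param smooth,upsample Pre-processing parameters; must match those used
#'   in [count_particles()].
#' @return Threshold intensity (scalar) for [count_particles()].
#' @export
calibrate_np_threshold <- function(reference, n_beads,
                                   smooth = c(1, 1, 1.2),
                                   upsample = c(2, 2, 4)) {
  stopifnot(inherits(reference, "zstack"))
  if (n_beads <= 0) stop_input("n_beads must be positive")
  u <- fft_smooth_upsample3(reference$voxels, smooth, upsample)
  vvox <- reference$dxy^2 * reference$dz / prod(upsample)
  k <- round(n_beads * single_np_volume(reference$np_diameter) / vvox)
  if (k + 1 > length(u)) stop_input("reference field too small for calibration")
  v <- -as.vector(u)
  s <- -sort(v, partial = c(k, k + 1))[c(k, k + 1)]
  mean(s)
}

#' Threshold from the mean of the brightest reference pixels
#'
#' The mean intensity of the `n` brightest voxels of a reference particle
#' region. Note that after point-spread blurring this lies close to the
#' blob peak, so it is generally far too high for volumetric counting; it
#' is provided for comparison with [calibrate_np_threshold()].
#'
#' @param reference A [zstack()] or 3-D array.
#' @param n Number of brightest voxels to average (default 4).
#' @return Threshold intensity.
#' @export
np_threshold_brightest <- function(reference, n = 4) {
  v <- if (inherits(reference, "zstack")) reference$voxels else reference
  mean(sort(as.vector(v), decreasing = TRUE)[seq_len(n)])
}

#' Count nanoparticles in a z-stack by calibrated volumetric thresholding
#'
#' Within the analysis slab, the stack is smoothed with a small matched
#' filter and resampled to a finer grid by Fourier interpolation (the
#' coarse axial sampling at dz = 0.35 um otherwise quantizes sub-slice
#' particles), then voxels above the threshold are counted. The occupied
#' volume is `voxel count x voxel volume` and the particle count is the
#' occupied volume divided by the nominal single-particle volume; for
#' 44 nm particles only the voxel count is reported (the conversion is not
#' meaningful at that size) — voxel counts for 44 nm stacks are reported
#' on the acquisition (pre-resampling) voxel grid.
#'
#' @param stack A [zstack()].
#' @param slab Retained slice indices from [analysis_slab()]; default all.
#' @param threshold Counting threshold, typically from
#'   [calibrate_np_threshold()].
#' @param smooth,upsample Matched-filter sigma (vox) and Fourier upsampling
#'   factors per axis; must match the calibration settings.
#' @return List with `slices_used`, `voxel_count` (acquisition-grid
#'   equivalent), `occupied_volume` (um^3), `particle_count` (real-valued;
#'   `NA` in 44 nm mode).
#' @export
count_particles <- function(stack, slab = NULL, threshold,
                            smooth = c(1, 1, 1.2), upsample = c(2, 2, 4)) {
  stopifnot(inherits(stack, "zstack"))
  nz <- dim(stack$voxels)[3]
  if (is.null(slab)) slab <- seq_len(nz)
  if (any(slab < 1 | slab > nz)) stop_input("slab indices outside the stack")
  v <- stack$voxels[, , slab, drop = FALSE]
  if (threshold > max(v)) {
    warning("threshold above stack maximum; zero counts", call. = FALSE)
    return(list(slices_used = slab, voxel_count = 0,
                occupied_volume = 0,
                particle_count = if (stack$np_diameter == 44) NA_real_ else 0))
  }
  u <- fft_smooth_upsample3(v, smooth, upsample)
  n_up <- sum(u > threshold)
  vvox_up <- stack$dxy^2 * stack$dz / prod(upsample)
  occupied <- n_up * vvox_up
  voxel_count <- n_up / prod(upsample)   # acquisition-grid equivalent
  particle_count <- if (stack$np_diameter == 44) {
    NA_real_
  } else {
    occupied / single_np_volume(stack$np_diameter)
  }
  list(slices_used = slab, voxel_count = voxel_count,
       occupied_volume = occupied, particle_count = particle_count)
}

#' Delivery efficiency relative to the uncompressed control
#'
#' Ratio of the particle count in treated cells (recovered at T0 or T1
#' after in-flow compression) to the count in untreated control cells.
#'
#' @param n_treated,n_ctrl Non-negative particle counts.
#' @return List with `n_treated`, `n_ctrl`, `ratio` (`NA` with
#'   `undefined = TRUE` when the control count is zero).
#' @examples
#' delivery_efficiency(120, 10)$ratio  # 12
#' @export
delivery_efficiency <- function(n_treated, n_ctrl) {
  if (n_treated < 0 || n_ctrl < 0) stop_input("counts must be non-negative")
  if (n_ctrl == 0) {
    return(list(n_treated = n_treated, n_ctrl = 0, ratio = NA_real_,
                undefined = TRUE))
  }
  list(n_treated = n_treated, n_ctrl = n_ctrl,
       ratio = n_treated / n_ctrl, undefined = FALSE)
}

#' Colocalization fraction of internalized particles
#'
#' Converts a colocalized-pixel count (particle channel overlapping the
#' membrane/endosome marker channel) into a particle count using the
#' apparent pixels-per-particle conversion, and expresses it as a
#' percentage of all internalized particles. Used as an endocytosis proxy:
#' purely diffusive pore entry gives low colocalization.
#'
#' @param colocalized_pixels Number of colocalized voxels.
#' @param pixels_per_np Apparent voxels per particle (> 0).
#' @param total_nps Total internalized particle count (> 0).
#' @return Percentage in `[0, 100]`; capped at 100 with a warning if the
#'   conversion overshoots.
#' @examples
#' colocalization_fraction(30, 10, 20)  # 15
#' @export
colocalization_fraction <- function(colocalized_pixels, pixels_per_np,
                                    total_nps) {
  if (pixels_per_np <= 0) stop_input("pixels_per_np must be positive")
  if (total_nps <= 0) stop_input("total_nps must be positive")
  if (colocalized_pixels < 0) stop_input("colocalized_pixels must be >= 0")
  pct <- 100 * (colocalized_pixels / pixels_per_np) / total_nps
  if (pct > 100) {
    warning("colocalized volume exceeds total particle volume; capping at 100%",
            call. = FALSE)
    pct <- 100
  }
  pct
}
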