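#' Segment a cell silhouette and fit its bounding circle
#'
#' Thresholds a single-cell grayscale image (Otsu), keeps the largest
#' connected foreground region, and fits a circle to its boundary pixels by
#' least squares. The circle centre and radius define the normalized polar
#' coordinate system for tension-point mapping.
#'
#' Image convention: matrices are indexed `[y, x]` with y increasing
#' downwards (row order); coordinates returned are in pixel units with
#' `x = column`, `y = row`.
#'
#' @param image 2-D numeric matrix.
#' @return List with `centroid = c(x, y)`, `cell_radius` (px), `area_px`.
#' @export
segment_cell_circle <- function(image) {
  if (!is.matrix(image)) stop_input("image must be a 2-D matrix")
  rng <- range(image)
  if (rng[2] <= rng[1]) stop_input("no foreground region found (flat image)")
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg)) stop_input("no foreground region found")
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  main <- which.max(areas)
  others <- areas[-main]
  if (length(others) && any(others >= 0.5 * areas[main])) {
    warning("multiple comparable regions; fitting the largest", call. = FALSE)
  }
  comp <- lab == main
  # boundary: component pixels with a 4-neighbour outside the component
  pad <- matrix(FALSE, nrow(comp) + 2, ncol(comp) + 2)
  pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
  inner <- pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] &
    pad[1:nrow(comp), 2:(ncol(comp) + 1)] &
    pad[3:(nrow(comp) + 2), 2:(ncol(comp) + 1)] &
    pad[2:(nrow(comp) + 1), 1:ncol(comp)] &
    pad[2:(nrow(comp) + 1), 3:(ncol(comp) + 2)]
  edge <- comp & !inner
  idx <- which(edge, arr.ind = TRUE)
  fit <- fit_circle(x = idx[, 2], y = idx[, 1])
  list(centroid = c(x = fit$cx, y = fit$cy),
       cell_radius = fit$r, area_px = sum(comp))
}

#' Detect high-tension points in an RGB lifetime colour map
#'
#' In FLIM colour maps, high membrane tension renders as red. Pixels whose
#' red-channel value falls inside the window (default 120-180 on an 8-bit
#' scale, inclusive) are taken as high-tension pixels; connected clusters
#' are collapsed to their centroid so one physical spot counts once.
#'
#' @param rgb_image Numeric array `(y, x, 3)` with 8-bit values (0-255).
#' @param window Length-2 inclusive red-channel window; defaults to
#'   `c(120, 180)` which requires 8-bit input.
#' @return Data frame with columns `x`, `y` (cluster centroids, px) and
#'   `n_pixels` (cluster size).
#' @export
detect_high_tension_points <- function(rgb_image, window = c(120, 180)) {
  if (length(dim(rgb_image)) != 3 || dim(rgb_image)[3] < 3) {
    stop_input("rgb_image must be a (y, x, 3) array")
  }
  red <- rgb_image[, , 1]
  if (max(red) > 255 || min(red) < 0) {
    stop_input("image is not 8-bit; supply an explicit intensity window ",
               "matched to its range")
  }
  hit <- red >= window[1] & red <= window[2]
  if (!any(hit)) {
    return(data.frame(x = numeric(0), y = numeric(0), n_pixels = integer(0)))
  }
  lab <- EBImage::bwlabel(hit)
  ids <- sort(unique(lab[lab > 0]))
  cent <- t(vapply(ids, function(i) {
    p <- which(lab == i, arr.ind = TRUE)
    c(mean(p[, 2]), mean(p[, 1]), nrow(p))
  }, numeric(3)))
  data.frame(x = cent[, 1], y = cent[, 2], n_pixels = as.integer(cent[, 3]))
}

#' Map detected points to normalized polar coordinates on the cell
#'
#' Each point is expressed as a normalized radius `norm_r` (distance to the
#' cell centroid over the cell radius; ~1 at the membrane) and an angle
#' `theta` in degrees. The angular convention is mathematical:
#' counter-clockwise from the +x axis with the y axis pointing up, so image
#' row coordinates (y down) are flipped internally. Points with
#' `norm_r > 1.1` are flagged `outside_cell` but kept. A point exactly at
#' the centroid gets `theta = 0` by convention.
#'
#' @param points Data frame with columns `x`, `y` (px, image convention).
#' @param centroid Numeric `c(x, y)` px.
#' @param cell_radius Cell radius, px; must be positive.
#' @return An object of class `tension_point_map`: a data frame with
#'   `x`, `y`, `norm_r`, `theta`, `outside_cell`, and attributes
#'   `centroid`, `cell_radius`.
#' @export
polarize_points <- function(points, centroid, cell_radius) {
  if (cell_radius <= 0) stop_input("cell_radius must be positive")
  dx <- points$x - centroid[1]
  dy <- -(points$y - centroid[2])   # flip image y to mathematical y
  norm_r <- sqrt(dx^2 + dy^2) / cell_radius
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  theta[norm_r == 0] <- 0
  out <- data.frame(x = points$x, y = points$y, norm_r = norm_r,
                    theta = theta, outside_cell = norm_r > 1.1)
  attr(out, "centroid") <- centroid
  attr(out, "cell_radius") <- cell_radius
  class(out) <- c("tension_point_map", "data.frame")
  out
}

#' Angular concentration of tension points over 45-degree bins
#'
#' Bins point angles into the 8 fixed sectors `[0,45), [45,90), ...,
#' [315,360)` and reports the largest bin's share of all points. Under a
#' uniform angular distribution each bin is expected to hold 12.5% of the
#' points; a max-bin fraction well above this baseline indicates that the
#' high-tension points (and hence the expected pore site) concentrate in a
#' single sector.
#'
#' @param map A [polarize_points()] result, or any data frame with a
#'   `theta` column (degrees).
#' @param phase_scan If `TRUE`, also compute the maximum max-bin fraction
#'   over all integer-degree rotations of the bin grid (not the default
#'   statistic; provided for sensitivity checks).
#' @return List with `counts` (named integer vector, 8 bins),
#'   `max_bin_fraction` (percent), `baseline` (12.5), `n_points`, and
#'   optionally `max_bin_fraction_phase_free`.
#' @export
angular_concentration <- function(map, phase_scan = FALSE) {
  theta <- map$theta
  if (length(theta) == 0) stop_input("no points to bin")
  edges <- seq(0, 360, by = 45)
  counts <- table(cut(theta %% 360, breaks = edges, right = FALSE,
                      include.lowest = FALSE))
  counts <- as.integer(counts)
  names(counts) <- paste0("[", edges[-9], ",", edges[-1], ")")
  out <- list(counts = counts,
              max_bin_fraction = 100 * max(counts) / length(theta),
              baseline = 100 / 8,
              n_points = length(theta))
  if (phase_scan) {
    best <- max(vapply(0:44, function(off) {
      cc <- table(cut((theta - off) %% 360, breaks = edges, right = FALSE))
      max(as.integer(cc))
    }, numeric(1)))
    out$max_bin_fraction_phase_free <- 100 * best / length(theta)
  }
  out
}

#' Actin cortex ring
#'
#' Annular region of interest describing the actin cortex: outer radius
#' `r_major`, inner radius `r_minor` (um), with the total fluorescence
#' intensity measured inside the annulus.
#'
#' @param r_major,r_minor Outer and inner ring radii, um.
#' @param total_intensity Summed intensity in the annulus, a.u.
#' @return An object of class `cortex_ring`.
#' @export
cortex_ring <- function(r_major, r_minor, total_intensity = NA_real_) {
  if (!is.finite(r_major) || !is.finite(r_minor) ||
      r_minor <= 0 || r_major <= r_minor) {
    stop_input("need r_major > r_minor > 0")
  }
  structure(list(r_major = r_major, r_minor = r_minor,
                 total_intensity = total_intensity,
                 ring_area = pi * (r_major^2 - r_minor^2)),
            class = "cortex_ring")
}

#' Cortex thickness and area-normalized intensity
#'
#' Thickness is defined as `(r_major - r_minor) / 2`; the ring intensity
#' is normalized by the annulus area `pi (r_major^2 - r_minor^2)`.
#'
#' @param ring A [cortex_ring()].
#' @return List with `thickness_um` and `normalized_intensity`
#'   (a.u. per um^2; `NA` if the ring has no intensity measurement).
#' @examples
#' cortex_metrics(cortex_ring(8.0, 6.6))$thickness_um  # 0.7
#' @export
cortex_metrics <- function(ring) {
  stopifnot(inherits(ring, "cortex_ring"))
  list(thickness_um = (ring$r_major - ring$r_minor) / 2,
       normalized_intensity = ring$total_intensity / ring$ring_area)
}

#' Estimate cortex ring radii from a radial intensity profile
#'
#' For a fluorescent ring image centred on the cell, computes the mean
#' intensity in 1-px-wide radial shells around the image centre and takes
#' the ring as the contiguous radial span where the profile exceeds half
#' its peak. Radii are returned in micrometres.
#'
#' @param image 2-D numeric matrix of the actin channel.
#' @param dxy Pixel size, um.
#' @param center Optional `c(x, y)` centre, px; defaults to image centre.
#' @return A [cortex_ring()] with `total_intensity` summed over the
#'   estimated annulus.
#' @export
estimate_cortex_ring <- function(image, dxy, center = NULL) {
  if (!is.matrix(image)) stop_input("image must be a 2-D matrix")
  if (is.null(center)) center <- c((ncol(image) + 1) / 2, (nrow(image) + 1) / 2)
  xs <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  ys <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  r <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  shell <- floor(r)
  prof <- tapply(image, shell, mean)
  radii <- as.numeric(names(prof)) + 0.5
  if (max(prof) <= 0) stop_input("no ring signal found")
  above <- prof >= max(prof) / 2
  peak <- which.max(prof)
  lo <- peak; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak; while (hi < length(prof) && above[hi + 1]) hi <- hi + 1
  r_in <- radii[lo] - 0.5
  r_out <- radii[hi] + 0.5
  sel <- r >= r_in & r <= r_out
  cortex_ring(r_major = r_out * dxy, r_minor = max(r_in, 0.5) * dxy,
              total_intensity = sum(image[sel]))
}
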