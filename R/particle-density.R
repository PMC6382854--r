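# Plasma-membrane particle density with Golgi subtraction, and foci
# counting per fixed-size window.

#' Detect the cell area of a membrane image
#'
#' Smooths with a wide Gaussian kernel (default sigma 1.33 um) and applies
#' an automatic (Otsu) threshold; the largest connected component, holes
#' filled, is the cell.
#'
#' @param img A [calibrated_image()] (the pixel size converts sigma to
#'   pixels).
#' @param sigma_um Gaussian sigma in micrometres.
#' @return Logical cell mask.
#' @export
detect_cell <- function(img, sigma_um = 1.33) {
  stopifnot(is_calibrated_image(img))
  sm <- gaussian_smooth(img, sigma_um)
  thr <- otsu_threshold(sm)                  # errors on constant image
  mask <- as_pixels(sm) > thr
  if (!any(mask)) stop("no foreground after thresholding")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  largest <- lab == which.max(sizes)
  matrix(as.numeric(EBImage::fillHull(largest + 0)) > 0,
         nrow(largest), ncol(largest))
}

.detect_blobs <- function(img, sigma_um, noise_tolerance, cell_mask,
                          log_scale = 1.5) {
  stopifnot(is_calibrated_image(img))
  sm <- gaussian_smooth(img, sigma_um)
  resp <- log_ridge(sm, smoothing_scale = log_scale)
  mx <- find_maxima(resp, noise_tolerance)$maxima
  if (!is.null(cell_mask) && nrow(mx) > 0) {
    cell_mask <- .as_mask(cell_mask)
    ri <- pmin(pmax(round(mx$row), 1L), nrow(cell_mask))
    ci <- pmin(pmax(round(mx$col), 1L), ncol(cell_mask))
    mx <- mx[cell_mask[cbind(ri, ci)], , drop = FALSE]
  }
  mx
}

#' Detect diffraction-limited particles
#'
#' Gaussian smoothing at the particle scale, a Laplacian
#' (ridge-enhancing) image at the same scale, and prominence-based maxima
#' detection, restricted to the cell mask when given.
#'
#' @param img A [calibrated_image()].
#' @param sigma_um Particle scale (micrometres).
#' @param noise_tolerance Maxima prominence threshold, in intensity units
#'   of the Laplacian image; the default assumes a 16-bit intensity range.
#' @param cell_mask Optional logical mask restricting detections.
#' @return A [point_set()] of subpixel particle centers with intensities.
#' @export
detect_particles <- function(img, sigma_um = 0.2, noise_tolerance = 800,
                             cell_mask = NULL) {
  .detect_blobs(img, sigma_um, noise_tolerance, cell_mask)
}

#' Detect Golgi-scale blobs
#'
#' As [detect_particles()] at the Golgi scale (default sigma 0.8 um,
#' noise tolerance 120).
#'
#' @inheritParams detect_particles
#' @return A [point_set()] of Golgi centers.
#' @export
detect_golgi <- function(img, sigma_um = 0.8, noise_tolerance = 120,
                         cell_mask = NULL) {
  .detect_blobs(img, sigma_um, noise_tolerance, cell_mask)
}

#' Plasma-membrane particle density with Golgi subtraction
#'
#' Counts particle-scale and Golgi-scale detections inside the cell and
#' reports `(n_particles - n_golgi) / cell area` in particles per um^2.
#' The subtraction is at count level (Golgi detections are not matched to
#' particle detections). A negative numerator flags the result invalid.
#'
#' @param img A [calibrated_image()].
#' @param cell_mask Optional precomputed cell mask; default
#'   [detect_cell()].
#' @param particle_sigma_um,particle_tolerance Particle detection scale
#'   and prominence.
#' @param golgi_sigma_um,golgi_tolerance Golgi detection scale and
#'   prominence.
#' @return A `density_result`: list with `particles`, `golgi` (point
#'   sets), `cell_mask`, `cell_area_um2`, `n_particles`, `n_golgi`,
#'   `density` (per um^2), `valid`.
#' @export
particle_density <- function(img, cell_mask = NULL,
                             particle_sigma_um = 0.2, particle_tolerance = 800,
                             golgi_sigma_um = 0.8, golgi_tolerance = 120) {
  stopifnot(is_calibrated_image(img))
  if (is.null(cell_mask)) cell_mask <- detect_cell(img)
  particles <- detect_particles(img, particle_sigma_um, particle_tolerance,
                                cell_mask)
  golgi <- detect_golgi(img, golgi_sigma_um, golgi_tolerance, cell_mask)
  area <- sum(cell_mask) * img$pixel_size^2
  np <- nrow(particles); ng <- nrow(golgi)
  structure(list(particles = particles, golgi = golgi,
                 cell_mask = cell_mask, cell_area_um2 = area,
                 n_particles = np, n_golgi = ng,
                 density = (np - ng) / area,
                 valid = np >= ng),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "<density_result> %.4g particles/um^2 ((%d - %d) / %.4g um^2)%s\n",
    x$density, x$n_particles, x$n_golgi, x$cell_area_um2,
    if (x$valid) "" else " [invalid: more Golgi than particles]"))
  invisible(x)
}

#' Count fluorescent foci in a square window
#'
#' Particle detections whose centers fall inside a `window_px` x
#' `window_px` window anchored at `origin` (top-left corner, row/col).
#'
#' @param img A [calibrated_image()].
#' @param origin Integer (row, col) of the window's top-left pixel.
#' @param window_px Window edge length in pixels (default 50).
#' @param ... Passed to [detect_particles()].
#' @return Integer count of foci in the window.
#' @export
foci_per_window <- function(img, origin = c(1L, 1L), window_px = 50L, ...) {
  px <- as_pixels(img)
  if (origin[1L] < 1L || origin[2L] < 1L ||
      origin[1L] + window_px - 1L > nrow(px) ||
      origin[2L] + window_px - 1L > ncol(px))
    stop("window outside image")
  pts <- detect_particles(img, ...)
  sum(pts$row >= origin[1L] & pts$row < origin[1L] + window_px &
      pts$col >= origin[2L] & pts$col < origin[2L] + window_px)
}
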