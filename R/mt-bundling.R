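# Microtubule bundling as skeleton-based mean fiber diameter: wider
# detected fibers mean more microtubules traveling together.

#' Detect the cell boundary for bundling analysis
#'
#' [detect_cell()] at a very wide scale (default sigma 10 um), so the
#' fiber texture is averaged away and only the cell outline thresholds.
#'
#' @param img A [calibrated_image()].
#' @param sigma_um Gaussian sigma in micrometres.
#' @return Logical single-component cell mask.
#' @export
detect_cell_boundary <- function(img, sigma_um = 10) {
  detect_cell(img, sigma_um = sigma_um)
}

#' Segment microtubule fibers
#'
#' Laplacian ridge image at the given smoothing scale, despeckled,
#' thresholded (user value per image, or Otsu of the positive response in
#' `"auto"` mode), then size-filtered at `min_size` pixels and restricted
#' to the cell mask.
#'
#' @param img A [calibrated_image()] or matrix.
#' @param smoothing Laplacian smoothing scale in pixels (default 1.5).
#' @param threshold `"auto"` or a response threshold.
#' @param min_size Minimum component size in pixels (default 20).
#' @param cell_mask Optional logical mask restricting the result.
#' @return Logical fiber mask.
#' @export
segment_fibers <- function(img, smoothing = 1.5, threshold = "auto",
                           min_size = 20L, cell_mask = NULL) {
  resp <- despeckle(log_ridge(img, smoothing))
  if (identical(threshold, "auto")) {
    pos <- resp[resp > 0]
    if (length(unique(pos)) < 2L) return(resp > Inf)
    threshold <- otsu_threshold(matrix(pos, ncol = 1L))
  }
  mask <- resp > threshold
  if (!is.null(cell_mask)) mask <- mask & .as_mask(cell_mask)
  if (!any(mask)) return(mask)
  filter_components(mask, min_size)
}

#' Mean fiber diameter of a segmented mask
#'
#' Skeletonizes the fiber mask and reads the local fiber diameter at each
#' skeleton pixel from the Euclidean distance transform. The distance is
#' measured to the object boundary (half a pixel inside the nearest
#' background pixel center), so `diameter = 2 * EDT - 1`: a width-1 line
#' scores 1 px and a width-w ribbon scores w.
#'
#' @param mask Logical fiber mask (non-empty).
#' @param pixel_size Optional physical pixel size to also report the mean
#'   diameter in physical units.
#' @param cell_mask Optional mask the fibers live in (carried through to
#'   the result).
#' @return A `bundling_result`: list with `fiber_mask`, `skeleton`,
#'   `diameters_px` (per skeleton pixel), `mean_fiber_diameter_px`, and
#'   `mean_fiber_diameter_um` when `pixel_size` is given.
#' @export
fiber_diameter <- function(mask, pixel_size = NULL, cell_mask = NULL) {
  mask <- .as_mask(mask)
  if (!any(mask)) stop("empty fiber mask")
  skel <- skeletonize(mask)
  edt <- distance_transform(mask)
  d <- 2 * edt[skel] - 1
  structure(list(cell_mask = cell_mask, fiber_mask = mask, skeleton = skel,
                 diameters_px = d,
                 mean_fiber_diameter_px = mean(d),
                 mean_fiber_diameter_um = if (!is.null(pixel_size))
                   mean(d) * pixel_size else NA_real_),
            class = "bundling_result")
}

#' @export
print.bundling_result <- function(x, ...) {
  cat(sprintf("<bundling_result> mean fiber diameter %.3g px over %d skeleton px\n",
              x$mean_fiber_diameter_px, length(x$diameters_px)))
  invisible(x)
}

#' Bundling analysis of a microtubule image
#'
#' Composes [detect_cell_boundary()], [segment_fibers()] and
#' [fiber_diameter()].
#'
#' @param img A [calibrated_image()].
#' @param smoothing,threshold,min_size Passed to [segment_fibers()].
#' @param boundary_sigma_um Cell boundary detection scale.
#' @return A `bundling_result` (see [fiber_diameter()]).
#' @export
bundling <- function(img, smoothing = 1.5, threshold = "auto",
                     min_size = 20L, boundary_sigma_um = 10) {
  cell <- detect_cell_boundary(img, boundary_sigma_um)
  fibers <- segment_fibers(img, smoothing, threshold, min_size, cell)
  fiber_diameter(fibers, pixel_size = img$pixel_size, cell_mask = cell)
}
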