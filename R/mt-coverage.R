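# Cortical microtubule coverage: Sobel edge detection of microtubules,
# region closing of the edge pixels into a cell mask, coverage =
# microtubule area / cell area.

#' Detect microtubule edge pixels
#'
#' Thresholds the Sobel gradient magnitude. In `"auto"` mode the threshold
#' is the Otsu value of the nonzero gradient magnitudes (making detection
#' invariant to positive intensity rescaling); a numeric threshold mirrors
#' the per-image manual choice of the original analysis.
#'
#' @param img A [calibrated_image()] or matrix.
#' @param threshold `"auto"` or a gradient-magnitude threshold.
#' @return Logical edge-pixel mask.
#' @export
detect_microtubules <- function(img, threshold = "auto") {
  g <- as_pixels(sobel_magnitude(img))
  if (identical(threshold, "auto")) {
    nz <- g[g > 0]
    if (length(unique(nz)) < 2L)
      stop("constant image: no automatic threshold")
    threshold <- otsu_threshold(matrix(nz, ncol = 1L))
  }
  g > threshold
}

#' Cell mask from detected edge pixels
#'
#' Applies [close_region()] (dilation, closing, hole filling) to the edge
#' mask and keeps the largest connected component as the cell.
#'
#' @param edge_mask Logical mask of detected edges (non-empty).
#' @param radius Disc radius in pixels for the closing steps.
#' @return Logical single-component cell mask.
#' @export
cell_area_from_edges <- function(edge_mask, radius = 5L) {
  edge_mask <- .as_mask(edge_mask)
  if (!any(edge_mask)) stop("empty edge mask")
  closed <- close_region(edge_mask, radius)
  lab <- label_components(closed)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Microtubule coverage of the cell cortex
#'
#' Composes [detect_microtubules()] and [cell_area_from_edges()]:
#' coverage is the fraction of the cell mask occupied by detected
#' microtubule (edge) pixels.
#'
#' @param img A [calibrated_image()] or matrix.
#' @param threshold `"auto"` or a numeric gradient threshold.
#' @param radius Closing disc radius in pixels.
#' @return A `coverage_result`: list with `threshold_used`, `mt_mask`,
#'   `cell_mask`, `mt_area_px`, `cell_area_px`, `coverage` in \[0, 1\].
#' @export
coverage <- function(img, threshold = "auto", radius = 5L) {
  g <- as_pixels(sobel_magnitude(img))
  thr <- if (identical(threshold, "auto")) {
    nz <- g[g > 0]
    if (length(unique(nz)) < 2L) stop("constant image: no automatic threshold")
    otsu_threshold(matrix(nz, ncol = 1L))
  } else threshold
  edges <- g > thr
  if (!any(edges)) {
    cell <- matrix(TRUE, nrow(g), ncol(g))   # featureless frame: whole field
    mt <- edges
  } else {
    cell <- cell_area_from_edges(edges, radius)
    mt <- edges & cell
  }
  structure(list(threshold_used = thr, mt_mask = mt, cell_mask = cell,
                 mt_area_px = sum(mt), cell_area_px = sum(cell),
                 coverage = sum(mt) / sum(cell)),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> coverage %.3f (%d / %d px, threshold %.4g)\n",
              x$coverage, x$mt_area_px, x$cell_area_px, x$threshold_used))
  invisible(x)
}
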