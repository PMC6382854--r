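#' Calibrated microscopy image
#'
#' The basic substrate of every imaging stage: a 2-D intensity raster plus
#' the physical size of one pixel. Light-microscopy images carry the pixel
#' size in micrometres, TEM rasters in nanometres; the unit is implied by
#' the modality and every downstream result is reported in the matching
#' physical unit.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities
#'   (rows = image rows, columns = image columns).
#' @param pixel_size Physical length of one pixel edge (> 0). Micrometres
#'   for `"confocal"`/`"tirf"`, nanometres for `"tem"`.
#' @param modality One of `"confocal"`, `"tirf"`, `"tem"`.
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `pixel_size` and `modality`.
#' @examples
#' img <- calibrated_image(matrix(0, 16, 16), pixel_size = 0.065)
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, pixel_size, modality = c("confocal", "tirf", "tem")) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite")
  if (any(pixels < 0))
    stop("all intensities must be >= 0")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size), modality = modality),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g units/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Is an object a calibrated image?
#' @param x Object to test.
#' @return `TRUE` for objects created by [calibrated_image()].
#' @export
is_calibrated_image <- function(x) inherits(x, "calibrated_image")

as_pixels <- function(img) {
  if (is_calibrated_image(img)) img$pixels
  else if (is.matrix(img)) {
    storage.mode(img) <- "double"
    img
  } else stop("expected a calibrated_image or a matrix")
}

#' Calibrated time-lapse stack
#'
#' An ordered sequence of frames of identical shape and calibration with a
#' constant frame interval.
#'
#' @param frames List of numeric matrices (>= 2) of identical dimensions,
#'   or a 3-D array with frames along the third dimension.
#' @param pixel_size Physical length per pixel, shared by all frames.
#' @param frame_interval Seconds between consecutive frames (> 0).
#' @param modality Imaging modality tag, as in [calibrated_image()].
#' @return An object of class `time_lapse` with fields `frames` (list of
#'   matrices), `pixel_size`, `frame_interval`, `modality`.
#' @export
time_lapse <- function(frames, pixel_size, frame_interval,
                       modality = c("confocal", "tirf", "tem")) {
  modality <- match.arg(modality)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (!is.list(frames) || length(frames) < 2L)
    stop("a time lapse needs at least 2 frames")
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) stop("each frame must be a matrix")
    storage.mode(f) <- "double"
    f
  })
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must have the same shape")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L || frame_interval <= 0)
    stop("`frame_interval` must be a single positive number")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(
    list(frames = frames, pixel_size = as.numeric(pixel_size),
         frame_interval = as.numeric(frame_interval), modality = modality),
    class = "time_lapse"
  )
}

#' @export
print.time_lapse <- function(x, ...) {
  cat(sprintf("<time_lapse> %d frames of %d x %d px, %.4g units/px, %.4g s/frame\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a time lapse
#' @param lapse A [time_lapse()].
#' @return Integer frame count.
#' @export
n_frames <- function(lapse) length(lapse$frames)

#' Subpixel point set
#'
#' Detected particles, gold-label centers and maxima are represented as a
#' data frame of real-valued (row, col) coordinates in the 1-based pixel
#' frame of the source image (pixel centers at integer coordinates).
#'
#' @param row,col Numeric coordinate vectors of equal length (may be empty).
#' @param intensity Optional per-point intensity.
#' @param frame Optional source frame index.
#' @return A data frame of class `point_set` with columns `row`, `col` and,
#'   when given, `intensity` and `frame`.
#' @export
point_set <- function(row = numeric(), col = numeric(),
                      intensity = NULL, frame = NULL) {
  if (length(row) != length(col)) stop("`row` and `col` must have equal length")
  df <- data.frame(row = as.numeric(row), col = as.numeric(col))
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  if (!is.null(frame)) df$frame <- as.integer(frame)
  class(df) <- c("point_set", "data.frame")
  df
}

# ---- raster IO --------------------------------------------------------------

#' Read a grayscale TIFF as a calibrated image
#'
#' Physical calibration is supplied by the caller; acquisition metadata is
#' not parsed. Multi-channel files must be resolved with `channel`;
#' multi-page files are rejected (use [read_stack()]).
#'
#' Intensities are returned on the scale stored in the file: the `tiff`
#' reader maps integer rasters to \[0, 1\], so values are rescaled back by
#' 2^bits - 1.
#'
#' @param path Path to a single-page grayscale TIFF.
#' @param pixel_size Physical length per pixel (> 0).
#' @param channel Channel index to extract when the file has multiple
#'   channels; an error is raised if channels are present and `channel`
#'   is `NULL`.
#' @param modality Modality tag, see [calibrated_image()].
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, pixel_size, channel = NULL,
                       modality = c("confocal", "tirf", "tem")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                  error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
  if (length(raw) != 1L)
    stop("multi-page file; use read_stack() for time series")
  px <- .tiff_page_to_matrix(raw[[1L]], channel)
  calibrated_image(px, pixel_size, modality)
}

.tiff_page_to_matrix <- function(page, channel = NULL) {
  bits <- attr(page, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (length(dim(page)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image: select a channel with `channel = `")
    if (channel < 1L || channel > dim(page)[3])
      stop("channel out of range")
    page <- page[, , channel]
  }
  out <- unclass(page) * (2^bits - 1)
  attributes(out) <- list(dim = dim(page))   # drop TIFF metadata attributes
  out
}

#' Write a calibrated image to TIFF
#'
#' Integer-valued rasters round-trip bit-exactly at the stated depth.
#'
#' @param img A [calibrated_image()] or matrix.
#' @param path Output path.
#' @param bits Bits per sample (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  px <- as_pixels(img)
  tiff::writeTIFF(px / (2^bits - 1), path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a multi-page TIFF as a time lapse
#'
#' @param path Path to a multi-page grayscale TIFF; frames are taken in
#'   page order. A single-page file signals that the input is not a time
#'   series and raises an error.
#' @param pixel_size Physical length per pixel.
#' @param frame_interval Seconds per frame.
#' @param modality Modality tag.
#' @return A [time_lapse()].
#' @export
read_stack <- function(path, pixel_size, frame_interval,
                       modality = c("confocal", "tirf", "tem")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(raw) < 2L)
    stop("single-page file is not a time series")
  frames <- lapply(raw, .tiff_page_to_matrix)
  time_lapse(frames, pixel_size, frame_interval, modality)
}

#' Write a time lapse to a multi-page TIFF
#'
#' @param lapse A [time_lapse()].
#' @param path Output path.
#' @param bits Bits per sample.
#' @return `path`, invisibly.
#' @export
write_stack <- function(lapse, path, bits = 16L) {
  pages <- lapply(lapse$frames, function(f) f / (2^bits - 1))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# ---- tables and sidecars ----------------------------------------------------

#' Write result records as delimited text
#'
#' One record per row with a header; numbers keep full double precision.
#' An empty record set yields a header-only file.
#'
#' @param records A data frame of homogeneous result records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  utils::write.csv(format(records, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a ground-truth sidecar
#'
#' Every synthetic artifact is paired with exactly one JSON sidecar holding
#' the generator name, seed, parameters and realized truth records.
#'
#' @param truth A `ground_truth` object (see the `gen_*` generators).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path JSON path written by [write_sidecar()].
#' @return A `ground_truth` list.
#' @export
read_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(x) <- "ground_truth"
  x
}
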