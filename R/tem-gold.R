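# Gold-label geometry on negative-stain TEM: particle centers from
# transect intensity dips, spacing statistics, labels per row and
# inter-row angles.

#' TEM transect intensity profile
#'
#' A uniformly sampled 1-D intensity profile taken along a row of gold
#' labels; gold particle centers appear as dips below the bright
#' negative-stain baseline.
#'
#' @param intensity Numeric intensity vector (>= 2 samples).
#' @param nm_per_px Nanometres per sample (> 0).
#' @return A `transect_profile`: list with `intensity`, `position_nm`
#'   (starting at 0) and `nm_per_px`.
#' @export
transect_profile <- function(intensity, nm_per_px) {
  if (!is.numeric(intensity) || length(intensity) < 2L)
    stop("`intensity` must be a numeric vector with >= 2 samples")
  if (!is.numeric(nm_per_px) || length(nm_per_px) != 1L || nm_per_px <= 0)
    stop("`nm_per_px` must be a single positive number")
  structure(list(intensity = as.numeric(intensity),
                 position_nm = (seq_along(intensity) - 1) * nm_per_px,
                 nm_per_px = as.numeric(nm_per_px)),
            class = "transect_profile")
}

#' @export
print.transect_profile <- function(x, ...) {
  cat(sprintf("<transect_profile> %d samples, %.3g nm/px, %.3g nm total\n",
              length(x$intensity), x$nm_per_px, max(x$position_nm)))
  invisible(x)
}

#' Detect gold-particle centers as intensity dips
#'
#' Local minima falling more than `k_sigma` robust standard deviations
#' below the baseline (median of the profile; scale from the median
#' absolute deviation) are taken as particle centers. Minima closer than
#' `min_separation_nm` are resolved greedily in favor of the deeper dip,
#' and centers are refined to subpixel positions by 3-point parabolic
#' interpolation. Both the baseline and the scale are relative measures,
#' so detection is invariant to affine intensity changes of the profile.
#'
#' @param profile A [transect_profile()] with >= 5 samples.
#' @param k_sigma Detection depth in robust sd units.
#' @param min_separation_nm Minimum center-to-center distance. The default
#'   of 3 nm is about three dip half-widths for 5-nm gold: a separation
#'   gate must sit at the optical resolution limit, not at the expected
#'   spacing, or it censors the lower tail of the spacing distribution
#'   being measured.
#' @return Numeric vector of center positions in nm (possibly empty; a
#'   flat profile yields no centers).
#' @export
detect_dips <- function(profile, k_sigma = 3, min_separation_nm = 3) {
  stopifnot(inherits(profile, "transect_profile"))
  v <- profile$intensity
  if (length(v) < 5L) stop("profile too short (< 5 samples)")
  baseline <- stats::median(v)
  sigma <- stats::mad(v)
  thr <- baseline - k_sigma * sigma
  n <- length(v)
  i <- 2:(n - 1L)
  is_min <- v[i] < v[i - 1L] & v[i] <= v[i + 1L] & v[i] < thr
  cand <- i[is_min]
  if (length(cand) == 0L) return(numeric(0))
  # greedy deepest-first separation gate
  ord <- cand[order(v[cand])]
  min_sep_px <- min_separation_nm / profile$nm_per_px
  kept <- numeric(0)
  for (p in ord) {
    if (length(kept) == 0L || min(abs(kept - p)) >= min_sep_px)
      kept <- c(kept, p)
  }
  kept <- sort(kept)
  # parabolic subpixel refinement on the three points around each minimum
  y0 <- v[kept - 1L]; y1 <- v[kept]; y2 <- v[kept + 1L]
  denom <- y0 - 2 * y1 + y2
  delta <- ifelse(denom > 0, 0.5 * (y0 - y2) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  (kept - 1 + delta) * profile$nm_per_px
}

#' Spacing statistics of gold-particle centers
#'
#' Successive-neighbor distances within each row or transect, pooled.
#'
#' @param centers Numeric vector of center positions (nm) along one
#'   transect, or a `gold_row_set` whose within-row positions are used.
#' @return A `spacing_stats` list: `spacings` (nm), `mean`, `sd`, `n`.
#' @export
spacing_stats <- function(centers) {
  sp <- if (inherits(centers, "gold_row_set")) {
    unlist(lapply(centers$rows, function(rw) {
      if (nrow(rw) < 2L) return(numeric(0))
      p <- .project_on_axis(rw)
      diff(sort(p))
    }))
  } else {
    if (length(centers) < 2L) stop("need >= 2 centers for spacings")
    diff(sort(as.numeric(centers)))
  }
  if (length(sp) < 1L) stop("need >= 2 centers for spacings")
  structure(list(spacings = sp, mean = mean(sp), sd = stats::sd(sp),
                 n = length(sp)),
            class = "spacing_stats")
}

#' @export
print.spacing_stats <- function(x, ...) {
  cat(sprintf("<spacing_stats> %.3g +/- %.3g nm (mean +/- SD, n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

# principal-axis (total-least-squares) coordinates of row points
.project_on_axis <- function(rw) {
  xy <- cbind(rw$x_nm, rw$y_nm)
  ctr <- colMeans(xy)
  dirv <- .row_direction(rw)
  as.vector((xy[, 1L] - ctr[1L]) * dirv[1L] + (xy[, 2L] - ctr[2L]) * dirv[2L])
}

.row_direction <- function(rw) {
  xy <- cbind(rw$x_nm, rw$y_nm)
  if (nrow(xy) < 2L) stop("degenerate row: fewer than 2 points")
  xc <- scale(xy, scale = FALSE)
  if (all(abs(xc) < 1e-12)) stop("degenerate row: all points coincident")
  v <- svd(xc)$v[, 1L]
  v / sqrt(sum(v^2))
}

#' Angles between adjacent gold-labeled rows
#'
#' Each row's direction is the principal axis of a total-least-squares
#' line fit; the angle between the two directions of each adjacent pair
#' (rows 1-2, 3-4, ...) is folded into \[0, 90\] degrees.
#'
#' @param rows A `gold_row_set` with an even number of rows ordered as
#'   adjacent pairs, each row holding >= 2 non-coincident points.
#' @return Numeric vector of angles in degrees, one per pair.
#' @export
row_angles <- function(rows) {
  stopifnot(inherits(rows, "gold_row_set"))
  n <- length(rows$rows)
  if (n < 2L) stop("need >= 2 rows")
  pairs <- seq_len(n %/% 2L)
  vapply(pairs, function(k) {
    d1 <- .row_direction(rows$rows[[2L * k - 1L]])
    d2 <- .row_direction(rows$rows[[2L * k]])
    ang <- acos(pmin(abs(sum(d1 * d2)), 1)) * 180 / pi
    .fold_angle(ang)
  }, numeric(1))
}

#' Labels per row
#'
#' @param rows A `gold_row_set`.
#' @return List with `counts` (per-row label counts), `mean`, `sd`,
#'   `range`; all empty/`NA` for an empty row set.
#' @export
labels_per_row <- function(rows) {
  stopifnot(inherits(rows, "gold_row_set"))
  counts <- vapply(rows$rows, nrow, integer(1))
  if (length(counts) == 0L)
    return(list(counts = integer(0), mean = NA_real_, sd = NA_real_,
                range = c(NA_real_, NA_real_)))
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
       range = range(counts))
}

#' Row length from mean label count and spacing
#'
#' The product `mean_labels * mean_spacing_nm`; with
#' `convention = "gaps"` the `(n - 1)`-gap alternative
#' `(mean_labels - 1) * mean_spacing_nm` is returned instead.
#'
#' @param mean_labels Mean number of labels per row (> 0).
#' @param mean_spacing_nm Mean label spacing in nm (> 0).
#' @param convention `"labels"` (default) or `"gaps"`.
#' @return Row length in nm.
#' @examples
#' row_length(8, 10)   # ~80 nm
#' @export
row_length <- function(mean_labels, mean_spacing_nm,
                       convention = c("labels", "gaps")) {
  convention <- match.arg(convention)
  if (mean_labels <= 0 || mean_spacing_nm <= 0)
    stop("inputs must be > 0")
  if (convention == "labels") mean_labels * mean_spacing_nm
  else max(mean_labels - 1, 0) * mean_spacing_nm
}
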