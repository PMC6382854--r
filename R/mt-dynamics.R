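# Microtubule end dynamics: time-phased image subtraction marks newly
# appeared (growing) and lost (shrinking) structure; kymographs along a
# line convert tip traces into velocities.

#' Time-phased image subtraction
#'
#' For each frame t computes `D_t = frame(t + shift) - frame(t)` and
#' thresholds it at `k_sigma` robust (MAD-based) noise sds: pixels above
#' are growth (new structure), pixels below the negative threshold are
#' shrinkage.
#'
#' @param movie A [time_lapse()] with at least `shift + 1` frames.
#' @param shift Frame shift (default 1).
#' @param k_sigma Threshold in robust noise sds.
#' @return A `tpis_result`: list with `growth` and `shrink` (lists of
#'   logical masks, one per subtracted pair), `sigma_noise` per pair,
#'   `shift`, `k_sigma`.
#' @export
time_phased_subtract <- function(movie, shift = 1L, k_sigma = 3) {
  stopifnot(inherits(movie, "time_lapse"))
  nf <- n_frames(movie)
  if (nf < shift + 1L) stop("movie shorter than shift + 1 frames")
  idx <- seq_len(nf - shift)
  growth <- vector("list", length(idx))
  shrink <- vector("list", length(idx))
  sig <- numeric(length(idx))
  for (t in idx) {
    d <- movie$frames[[t + shift]] - movie$frames[[t]]
    s <- stats::mad(d)                 # background-dominated scale
    if (s == 0) s <- stats::sd(d)
    sig[t] <- s
    growth[[t]] <- d > k_sigma * s
    shrink[[t]] <- d < -k_sigma * s
  }
  structure(list(growth = growth, shrink = shrink, sigma_noise = sig,
                 shift = shift, k_sigma = k_sigma),
            class = "tpis_result")
}

# bilinear interpolation of matrix m at real (row, col) positions
.interp_bilinear <- function(m, r, c) {
  r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
  r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Extract a kymograph along a line
#'
#' Samples every frame along a polyline at 1-px steps with bilinear
#' interpolation, averaging `width_px` parallel samples taken
#' perpendicular to the local line direction. Rows of the result are
#' positions along the line, columns are frames.
#'
#' @param movie A [time_lapse()].
#' @param line Two-column matrix of (row, col) polyline vertices inside
#'   the image.
#' @param width_px Odd number of perpendicular samples averaged (default
#'   3).
#' @return A `kymograph`: list with `values` (distance x time matrix),
#'   `line`, `width_px`, `pixel_size`, `frame_interval`.
#' @export
extract_kymograph <- function(movie, line, width_px = 3L) {
  stopifnot(inherits(movie, "time_lapse"))
  line <- matrix(as.numeric(line), ncol = 2L)
  d <- dim(movie$frames[[1L]])
  if (any(line[, 1L] < 1 | line[, 1L] > d[1L] |
          line[, 2L] < 1 | line[, 2L] > d[2L]))
    stop("line outside image")
  # resample polyline at 1-px arc steps, with local unit normals
  pr <- numeric(0); pc <- numeric(0); nr_ <- numeric(0); nc_ <- numeric(0)
  for (k in seq_len(nrow(line) - 1L)) {
    a <- line[k, ]; b <- line[k + 1L, ]
    len <- sqrt(sum((b - a)^2))
    s <- seq(0, len, by = 1)
    u <- (b - a) / len
    pr <- c(pr, a[1L] + s * u[1L]); pc <- c(pc, a[2L] + s * u[2L])
    nr_ <- c(nr_, rep(-u[2L], length(s))); nc_ <- c(nc_, rep(u[1L], length(s)))
  }
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)
  vals <- vapply(movie$frames, function(f) {
    acc <- 0
    for (o in offs) acc <- acc + .interp_bilinear(f, pr + o * nr_, pc + o * nc_)
    acc / length(offs)
  }, numeric(length(pr)))
  structure(list(values = matrix(vals, nrow = length(pr)),
                 line = line, width_px = width_px,
                 pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d positions x %d frames (width %d px)\n",
              nrow(x$values), ncol(x$values), x$width_px))
  invisible(x)
}

#' Velocity from a kymograph trace
#'
#' A manually (or automatically) traced segment of a tip trajectory in
#' kymograph coordinates: velocity is the traversed distance over the
#' elapsed time, reported as a positive magnitude in um/min with the kind
#' given by the sign of the tip displacement (tip-outward positive).
#'
#' @param kymo A `kymograph`.
#' @param t0,t1 Frame indices of the trace endpoints (`t1 > t0`).
#' @param s0,s1 Positions along the line (px) at the endpoints.
#' @return A `velocity_event`: list with `kind` (`"growth"` or
#'   `"shrink"`; a horizontal trace is growth at 0), `v_um_min`, `trace`.
#' @export
velocity_from_trace <- function(kymo, t0, s0, t1, s1) {
  stopifnot(inherits(kymo, "kymograph"))
  if (t1 <= t0) stop("zero or negative time span")
  dt_s <- (t1 - t0) * kymo$frame_interval
  ds_um <- (s1 - s0) * kymo$pixel_size
  v <- abs(ds_um) / dt_s * 60
  structure(list(kind = if (ds_um >= 0) "growth" else "shrink",
                 v_um_min = v,
                 trace = c(t0 = t0, s0 = s0, t1 = t1, s1 = s1)),
            class = "velocity_event")
}

#' @export
print.velocity_event <- function(x, ...) {
  cat(sprintf("<velocity_event> %s at %.3g um/min\n", x$kind, x$v_um_min))
  invisible(x)
}

#' Automatic tip traces from subtraction masks
#'
#' A reproducible default for what the original analysis traced by hand:
#' the tip position per subtracted frame pair is the extremal
#' growth/shrink pixel projected on the filament axis; runs of consistent
#' displacement sign are merged into constant-velocity events fitted by
#' least squares.
#'
#' @param movie A [time_lapse()].
#' @param tpis A `tpis_result` from [time_phased_subtract()]; computed
#'   when `NULL`.
#' @param axis `"cols"` if the filament runs along image columns (tip
#'   position = column index), `"rows"` otherwise.
#' @param min_run Minimum frames per event.
#' @param static_tol_px Median per-frame displacement below which a run
#'   counts as static and yields no event.
#' @return List of `velocity_event`s (possibly empty for a static movie).
#' @export
auto_tip_traces <- function(movie, tpis = NULL, axis = c("cols", "rows"),
                            min_run = 3L, static_tol_px = 0.25) {
  axis <- match.arg(axis)
  stopifnot(inherits(movie, "time_lapse"))
  if (is.null(tpis)) tpis <- time_phased_subtract(movie)
  np <- length(tpis$growth)
  tip <- rep(NA_real_, np + 1L)
  proj <- function(mask) {
    # isolated above-threshold pixels are noise; the swept tip region is a
    # coherent patch, so keep only components of a few pixels or more
    if (any(mask)) mask <- filter_components(mask, 5L)
    if (!any(mask)) return(NA_real_)
    idx <- which(mask, arr.ind = TRUE)
    if (axis == "cols") max(idx[, 2L]) else max(idx[, 1L])
  }
  for (t in seq_len(np)) {
    g <- proj(tpis$growth[[t]])        # leading edge after growth: tip at t+1
    s <- proj(tpis$shrink[[t]])        # trailing edge lost: tip at t
    if (!is.na(g)) tip[t + 1L] <- g
    if (!is.na(s) && is.na(tip[t])) tip[t] <- s
  }
  obs <- which(!is.na(tip))
  if (length(obs) < min_run + 1L) return(list())
  # classify inter-observation displacements and merge runs of equal sign
  d <- diff(tip[obs]) / diff(obs)
  sign_d <- ifelse(abs(d) <= static_tol_px, 0L, sign(d))
  runs <- rle(sign_d)
  events <- list()
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    seg <- obs[pos:(pos + len)]        # observation indices spanning the run
    pos <- pos + len
    if (runs$values[k] == 0L || len < min_run) next
    t_s <- (seg - 1L) * movie$frame_interval
    s_px <- tip[seg]
    fit <- stats::lm(s_px ~ t_s)
    v_px_s <- unname(stats::coef(fit)[2L])
    v_um_min <- abs(v_px_s) * movie$pixel_size * 60
    events[[length(events) + 1L]] <- structure(
      list(kind = if (v_px_s >= 0) "growth" else "shrink",
           v_um_min = v_um_min,
           trace = c(t0 = seg[1L], s0 = s_px[1L],
                     t1 = seg[length(seg)], s1 = s_px[length(seg)])),
      class = "velocity_event")
  }
  events
}
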