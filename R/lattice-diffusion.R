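# MSD-based lattice diffusion, foci lifetimes on single vs bundled
# microtubules, and microtubule-per-bundle counting by intensity
# quantization.

#' Time-averaged mean squared displacement of one track
#'
#' `MSD(tau)` averages `(x(t + tau) - x(t))^2` over all start times with
#' both ends observed, for lags `1 .. min(max_lag, floor(N/4))` frames.
#' Lags with fewer than `min_pairs` contributing pairs are dropped. The
#' diffusion coefficient follows the 1-D free-diffusion convention
#' `MSD = 2 D tau` : `D = slope / 2` from an unweighted least-squares fit
#' with free intercept (`slope / 4` under the 2-D convention).
#'
#' @param track Data frame with columns `frame` (strictly increasing
#'   integers, gaps allowed) and `position_um`; >= 11 frames.
#' @param frame_interval Seconds per frame.
#' @param max_lag Largest lag in frames considered (default 10).
#' @param min_pairs Minimum pair count for a lag to be reported.
#' @param dimensionality 1 or 2; divides the slope by `2 * dimensionality`.
#' @return An `msd_result`: list with `lags_s`, `msd_um2`, `n_pairs`,
#'   `D_um2_s`, `fit_intercept`, `fit_r2`, `valid` (`FALSE` for a negative
#'   slope).
#' @export
msd <- function(track, frame_interval, max_lag = 10L, min_pairs = 10L,
                dimensionality = 1L) {
  stopifnot(is.data.frame(track),
            all(c("frame", "position_um") %in% names(track)))
  if (is.unsorted(track$frame, strictly = TRUE))
    stop("`frame` must be strictly increasing")
  n <- nrow(track)
  if (n < 11L) stop("track too short: need >= 11 frames")
  frames <- track$frame - min(track$frame)     # re-indexing invariant
  x <- track$position_um
  pos <- rep(NA_real_, max(frames) + 1L)
  pos[frames + 1L] <- x
  lags <- seq_len(min(max_lag, floor(n / 4)))
  msd_v <- numeric(0); np <- integer(0); keep <- integer(0)
  for (L in lags) {
    d <- pos[(1L + L):length(pos)] - pos[seq_len(length(pos) - L)]
    d <- d[!is.na(d)]
    if (length(d) >= min_pairs) {
      keep <- c(keep, L)
      msd_v <- c(msd_v, mean(d^2))
      np <- c(np, length(d))
    }
  }
  if (length(keep) < 2L) stop("not enough lags with sufficient pairs")
  tau <- keep * frame_interval
  fit <- stats::lm(msd_v ~ tau)
  slope <- unname(stats::coef(fit)[2L])
  D <- slope / (2 * dimensionality)
  r2 <- summary(fit)$r.squared
  structure(list(lags_s = tau, msd_um2 = msd_v, n_pairs = np,
                 D_um2_s = D, fit_intercept = unname(stats::coef(fit)[1L]),
                 fit_r2 = r2, valid = D >= 0),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> D = %.4g um^2/s over %d lags (r^2 = %.3f)%s\n",
              x$D_um2_s, length(x$lags_s), x$fit_r2,
              if (x$valid) "" else " [negative fit]"))
  invisible(x)
}

#' Ensemble diffusion coefficient across tracks
#'
#' Per-track D from [msd()], then mean and SD across tracks.
#'
#' @param tracks Data frame with columns `id`, `frame`, `position_um`
#'   (long format, one row per observation).
#' @param frame_interval Seconds per frame.
#' @param ... Passed to [msd()].
#' @return List with `mean_D`, `sd_D`, `n`, and `per_track` (data frame
#'   `id`, `D_um2_s`, `fit_r2`, `valid`).
#' @export
ensemble_D <- function(tracks, frame_interval, ...) {
  stopifnot(all(c("id", "frame", "position_um") %in% names(tracks)))
  ids <- unique(tracks$id)
  per <- lapply(ids, function(i) {
    tr <- tracks[tracks$id == i, , drop = FALSE]
    res <- tryCatch(msd(tr, frame_interval, ...), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(id = i, D_um2_s = res$D_um2_s, fit_r2 = res$fit_r2,
               valid = res$valid)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) < 2L) stop("need >= 2 usable tracks")
  list(mean_D = mean(per$D_um2_s), sd_D = stats::sd(per$D_um2_s),
       n = nrow(per), per_track = per)
}

#' Foci lifetimes on single versus bundled microtubules
#'
#' Lifetime runs from the first appearance of a focus to its
#' disappearance: `(last frame - first frame + 1) * frame_interval`, so a
#' single-frame track lives one frame interval. Summaries are reported per
#' substrate group.
#'
#' @param tracks Data frame with columns `id`, `frame`.
#' @param substrate Named character vector or factor mapping track id to
#'   `"single"` or `"bundle"` (names = track ids), or an unnamed vector
#'   aligned with `unique(tracks$id)`.
#' @param frame_interval Seconds per frame.
#' @return List with `records` (data frame `id`, `lifetime_s`,
#'   `substrate`) and `summary` (per-group median and quartiles).
#' @export
lifetimes <- function(tracks, substrate, frame_interval) {
  ids <- unique(tracks$id)
  if (!is.null(names(substrate))) {
    sub <- substrate[as.character(ids)]
  } else {
    if (length(substrate) != length(ids))
      stop("unlabeled tracks: `substrate` must cover every track id")
    sub <- substrate
  }
  if (anyNA(sub)) stop("unlabeled tracks: missing substrate label")
  if (!all(sub %in% c("single", "bundle")))
    stop("substrate labels must be 'single' or 'bundle'")
  lt <- vapply(ids, function(i) {
    f <- tracks$frame[tracks$id == i]
    (max(f) - min(f) + 1) * frame_interval
  }, numeric(1))
  records <- data.frame(id = ids, lifetime_s = lt,
                        substrate = as.character(sub))
  qs <- lapply(split(records$lifetime_s, records$substrate), function(v)
    stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
  summary <- data.frame(
    substrate = names(qs),
    q25 = vapply(qs, `[`, numeric(1), 1L),
    median = vapply(qs, `[`, numeric(1), 2L),
    q75 = vapply(qs, `[`, numeric(1), 3L),
    n = as.vector(table(records$substrate)[names(qs)]))
  list(records = records, summary = summary)
}

#' Count microtubules per bundle by intensity quantization
#'
#' The integrated, background-subtracted cross-section intensity of a
#' bundle divided by the single-microtubule unit intensity, rounded to the
#' nearest integer and clamped to `[1, cap]` (intensity steps discriminate
#' up to about five microtubules).
#'
#' @param intensities Numeric vector of integrated cross-section
#'   intensities, one per region.
#' @param unit_intensity Single-microtubule unit intensity (> 0); estimate
#'   it with [estimate_unit_intensity()].
#' @param cap Maximum discriminable count.
#' @return Data frame `region`, `intensity`, `n_mt`.
#' @export
classify_substrate <- function(intensities, unit_intensity, cap = 5L) {
  if (!is.numeric(unit_intensity) || unit_intensity <= 0)
    stop("`unit_intensity` must be > 0")
  n_mt <- pmin(pmax(round(intensities / unit_intensity), 1L), cap)
  data.frame(region = seq_along(intensities),
             intensity = as.numeric(intensities),
             n_mt = as.integer(n_mt))
}

#' Unit intensity from designated single-microtubule cross-sections
#'
#' @param single_intensities Integrated intensities of regions the user
#'   designates as clearly visible single microtubules.
#' @return Their median.
#' @export
estimate_unit_intensity <- function(single_intensities) {
  if (length(single_intensities) < 1L) stop("need >= 1 reference region")
  stats::median(as.numeric(single_intensities))
}
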