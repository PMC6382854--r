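# Synthetic microscopy generators with ground-truth sidecars. Every
# generator is deterministic given (seed, parameters) and records the
# realized (not nominal) draws in its truth list, so downstream estimates
# can be compared closed-loop.
#
# Noise model throughout: Poisson shot noise on the rendered signal plus
# additive Gaussian read noise, emulating EMCCD acquisition without
# modeling EM gain.

.ground_truth <- function(generator, seed, params, truth) {
  structure(list(generator = generator, seed = seed,
                 params = params, truth = truth),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (seed %s): %s\n", x$generator,
              format(x$seed), paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

# bilinear deposition of point masses onto a pixel grid
.splat <- function(dims, r, c, w) {
  acc <- numeric(prod(dims))
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    rr <- r0 + corner[1L]; cc <- c0 + corner[2L]
    wt <- w * (if (corner[1L] == 0) 1 - fr else fr) *
              (if (corner[2L] == 0) 1 - fc else fc)
    ok <- rr >= 1 & rr <= dims[1L] & cc >= 1 & cc <= dims[2L] & wt > 0
    if (!any(ok)) next
    idx <- rr[ok] + (cc[ok] - 1) * dims[1L]
    tab <- rowsum(wt[ok], idx)
    acc[as.integer(rownames(tab))] <- acc[as.integer(rownames(tab))] + tab[, 1L]
  }
  matrix(acc, dims[1L], dims[2L])
}

.ellipse_mask <- function(dims, frac = 0.42) {
  r0 <- (dims[1L] + 1) / 2; c0 <- (dims[2L] + 1) / 2
  a <- frac * dims[1L]; b <- frac * dims[2L]
  outer(seq_len(dims[1L]), seq_len(dims[2L]),
        function(i, j) ((i - r0) / a)^2 + ((j - c0) / b)^2 <= 1)
}

.camera_noise <- function(signal, read_sd) {
  n <- length(signal)
  shot <- matrix(stats::rpois(n, pmax(signal, 0)), nrow(signal), ncol(signal))
  pmax(shot + matrix(stats::rnorm(n, 0, read_sd), nrow(signal)), 0)
}

#' Synthetic cortical microtubule array image
#'
#' Renders smooth curvilinear fibers with Gaussian cross-section inside an
#' elliptical cell over a dark exterior, with Poisson shot noise plus
#' Gaussian read noise. Bundles are co-rendered near-parallel fibers whose
#' intensities add. The truth sidecar stores the cell mask, the fiber mask
#' (pixels within half a fiber width of any centerline) and the realized
#' coverage fraction.
#'
#' @param seed Integer RNG seed.
#' @param n_fibers Total number of fibers (>= 0).
#' @param bundling_level Mean fibers per bundle (>= 1); bundle sizes are
#'   `1 + Poisson(bundling_level - 1)`.
#' @param fiber_width_px Fiber full width in pixels (Gaussian FWHM).
#' @param snr Peak fiber amplitude divided by the read-noise sd (> 0).
#' @param cell_shape `"ellipse"` (cell occupying the image center) or
#'   `"full"` (whole frame is cell).
#' @param dims Image dimensions (rows, cols).
#' @param pixel_size Micrometres per pixel.
#' @return List with `image` (a [calibrated_image()]) and `truth`
#'   (a `ground_truth` with `cell_mask`, `fiber_mask`, `coverage`).
#' @export
gen_mt_array <- function(seed, n_fibers = 20, bundling_level = 1,
                         fiber_width_px = 3, snr = 10,
                         cell_shape = c("ellipse", "full"),
                         dims = c(160L, 160L), pixel_size = 0.065) {
  cell_shape <- match.arg(cell_shape)
  if (n_fibers < 0) stop("`n_fibers` must be >= 0")
  if (snr <= 0) stop("`snr` must be > 0")
  if (fiber_width_px >= min(dims))
    stop("impossible geometry: fiber width >= image size")
  amp <- 10000; bg_in <- 4000; bg_out <- 150
  withr::with_seed(seed, {
    cell <- if (cell_shape == "ellipse") .ellipse_mask(dims)
            else matrix(TRUE, dims[1L], dims[2L])
    sigma_f <- fiber_width_px / 2.355
    step <- 0.5
    pts_r <- numeric(0); pts_c <- numeric(0)
    fibers_left <- n_fibers
    while (fibers_left > 0) {
      nb <- min(1L + stats::rpois(1L, max(bundling_level - 1, 0)), fibers_left)
      fibers_left <- fibers_left - nb
      theta <- stats::runif(1, 0, pi)
      # chord through a random interior point, sinusoidally perturbed
      m0 <- c(stats::runif(1, 0.25, 0.75) * dims[1L],
              stats::runif(1, 0.25, 0.75) * dims[2L])
      L <- sum(dims)                       # long enough to cross the frame
      tt <- seq(-L / 2, L / 2, by = step)
      wig_a <- stats::runif(1, 0, 4)
      wig_f <- stats::runif(1, 0.01, 0.03)
      wig_p <- stats::runif(1, 0, 2 * pi)
      for (k in seq_len(nb)) {
        # members pack side by side (~30 nm lattice spacing, about half a
        # pixel) and weave individually along the bundle, so bundles are
        # loosely fasciculated rather than perfectly fused
        off <- (k - (nb + 1) / 2) * 0.5 + stats::rnorm(1, 0, 0.1)
        weave <- if (nb > 1)
          0.8 * sin(stats::runif(1, 0.02, 0.06) * tt + stats::runif(1, 0, 2 * pi))
        else 0
        perp <- c(-sin(theta), cos(theta))
        lat <- wig_a * sin(wig_f * tt + wig_p) + off + weave
        r <- m0[1L] + tt * cos(theta) + lat * perp[1L]
        c <- m0[2L] + tt * sin(theta) + lat * perp[2L]
        keep <- r >= 1 & r <= dims[1L] & c >= 1 & c <= dims[2L]
        inside <- cell[cbind(pmin(pmax(round(r[keep]), 1), dims[1L]),
                             pmin(pmax(round(c[keep]), 1), dims[2L]))]
        pts_r <- c(pts_r, r[keep][inside])
        pts_c <- c(pts_c, c[keep][inside])
      }
    }
    mass <- amp * step * sqrt(2 * pi) * sigma_f
    acc <- .splat(dims, pts_r, pts_c, rep(mass, length(pts_r)))
    signal <- gaussian_smooth(acc, sigma_f)
    signal <- signal + ifelse(cell, bg_in, bg_out)
    img <- .camera_noise(signal, read_sd = amp / snr)

    if (length(pts_r) > 0) {
      center <- .splat(dims, pts_r, pts_c, rep(1, length(pts_r))) > 0
      dist_to_fiber <- distance_transform(!center)
      fiber_mask <- dist_to_fiber <= fiber_width_px / 2 & cell
    } else {
      fiber_mask <- matrix(FALSE, dims[1L], dims[2L])
    }
    coverage <- sum(fiber_mask) / sum(cell)
    list(
      image = calibrated_image(img, pixel_size, "confocal"),
      truth = .ground_truth("gen_mt_array", seed,
        params = list(n_fibers = n_fibers, bundling_level = bundling_level,
                      fiber_width_px = fiber_width_px, snr = snr,
                      cell_shape = cell_shape, dims = dims,
                      pixel_size = pixel_size),
        truth = list(cell_mask = cell, fiber_mask = fiber_mask,
                     coverage = coverage))
    )
  })
}

#' Synthetic plasma-membrane particle movie
#'
#' Diffraction-limited foci (cellulose-synthase-like particles) plus
#' larger, brighter Golgi-like blobs inside an elliptical cell on a noisy
#' background. Positions are static across frames; noise is redrawn per
#' frame. Peak amplitudes sit on a 16-bit scale so that the default
#' detection noise tolerances are meaningful; `snr` divides the particle
#' amplitude to give the read-noise sd.
#'
#' @param seed Integer RNG seed.
#' @param n_particles,n_golgi Number of foci / Golgi-like blobs.
#' @param particle_sigma_um,golgi_sigma_um Gaussian radii (micrometres).
#' @param snr Particle peak amplitude over read-noise sd.
#' @param n_frames Frames in the movie (>= 2).
#' @param dims Frame dimensions.
#' @param pixel_size Micrometres per pixel.
#' @param min_sep_px Minimum center-to-center distance enforced among all
#'   rendered structures.
#' @return List with `movie` (a [time_lapse()]) and `truth` holding
#'   `particles`, `golgi` (point sets), `cell_mask` and `cell_area_um2`.
#' @export
gen_particle_movie <- function(seed, n_particles = 60, n_golgi = 3,
                               particle_sigma_um = 0.2, golgi_sigma_um = 0.8,
                               snr = 25, n_frames = 2L,
                               dims = c(160L, 160L), pixel_size = 0.13,
                               min_sep_px = 10) {
  amp_p <- 20000; amp_g <- 25000; bg <- 4000
  withr::with_seed(seed, {
    cell <- .ellipse_mask(dims)
    interior <- distance_transform(cell) >= 4   # structures sit clear of the rim
    sp <- particle_sigma_um / pixel_size
    sg <- golgi_sigma_um / pixel_size
    place <- function(n, taken_r, taken_c, margin) {
      r <- numeric(0); c <- numeric(0); tries <- 0L
      while (length(r) < n && tries < 20000L) {
        tries <- tries + 1L
        cand_r <- stats::runif(1, 1 + margin, dims[1L] - margin)
        cand_c <- stats::runif(1, 1 + margin, dims[2L] - margin)
        if (!interior[round(cand_r), round(cand_c)]) next
        all_r <- c(taken_r, r); all_c <- c(taken_c, c)
        if (length(all_r) == 0 ||
            min((all_r - cand_r)^2 + (all_c - cand_c)^2) >= min_sep_px^2) {
          r <- c(r, cand_r); c <- c(c, cand_c)
        }
      }
      if (length(r) < n) stop("could not place structures at requested separation")
      list(r = r, c = c)
    }
    gp <- place(n_golgi, numeric(0), numeric(0), margin = 3 * sg)
    pp <- place(n_particles, gp$r, gp$c, margin = 3 * sp + 2)
    sig_p <- if (n_particles > 0)
      gaussian_smooth(.splat(dims, pp$r, pp$c,
                             rep(amp_p * 2 * pi * sp^2, n_particles)), sp)
      else matrix(0, dims[1L], dims[2L])
    sig_g <- if (n_golgi > 0)
      gaussian_smooth(.splat(dims, gp$r, gp$c,
                             rep(amp_g * 2 * pi * sg^2, n_golgi)), sg)
      else matrix(0, dims[1L], dims[2L])
    base <- sig_p + sig_g + ifelse(cell, bg, bg / 20)
    frames <- lapply(seq_len(n_frames),
                     function(i) .camera_noise(base, read_sd = amp_p / snr))
    list(
      movie = time_lapse(frames, pixel_size, frame_interval = 1, "confocal"),
      truth = .ground_truth("gen_particle_movie", seed,
        params = list(n_particles = n_particles, n_golgi = n_golgi,
                      particle_sigma_um = particle_sigma_um,
                      golgi_sigma_um = golgi_sigma_um, snr = snr,
                      n_frames = n_frames, dims = dims,
                      pixel_size = pixel_size, min_sep_px = min_sep_px),
        truth = list(particles = point_set(pp$r, pp$c),
                     golgi = point_set(gp$r, gp$c),
                     cell_mask = cell,
                     cell_area_um2 = sum(cell) * pixel_size^2))
    )
  })
}

#' Synthetic single-molecule lattice-diffusion tracks
#'
#' 1-D Brownian positions along a filament axis: increments are
#' `Normal(0, sqrt(2 D dt))`. Each track lives for an exponential lifetime
#' (class-specific mean, truncated to the movie length); the substrate
#' class (`single` or `bundle`) is drawn from `substrate_mix`. With the
#' default infinite lifetimes every track spans the full movie.
#'
#' @param seed Integer RNG seed.
#' @param n_tracks Number of tracks.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param frame_interval Seconds per frame.
#' @param n_frames Maximum frames per track.
#' @param lifetime_mean_s Named numeric `c(single = , bundle = )` mean
#'   lifetimes in seconds (may be `Inf`), or a single value for both.
#' @param substrate_mix Named probabilities `c(single = , bundle = )`.
#' @return List with `tracks` (data frame `id`, `frame`, `position_um`,
#'   `intensity`) and `truth` (per-track `D`, `substrate`, `lifetime_s`).
#' @export
gen_lattice_tracks <- function(seed, n_tracks = 50, D = 0.076,
                               frame_interval = 0.1, n_frames = 500,
                               lifetime_mean_s = c(single = Inf, bundle = Inf),
                               substrate_mix = c(single = 1, bundle = 0)) {
  if (D < 0) stop("`D` must be >= 0")
  if (length(lifetime_mean_s) == 1L)
    lifetime_mean_s <- c(single = unname(lifetime_mean_s),
                         bundle = unname(lifetime_mean_s))
  withr::with_seed(seed, {
    substrate <- sample(c("single", "bundle"), n_tracks, replace = TRUE,
                        prob = substrate_mix[c("single", "bundle")])
    rows <- vector("list", n_tracks)
    lifetimes <- numeric(n_tracks)
    for (i in seq_len(n_tracks)) {
      lt_mean <- lifetime_mean_s[[substrate[i]]]
      nf <- if (is.finite(lt_mean)) {
        min(n_frames, max(1L, ceiling(stats::rexp(1, 1 / lt_mean) / frame_interval)))
      } else n_frames
      lifetimes[i] <- nf * frame_interval
      pos <- cumsum(c(stats::runif(1, -1, 1),
                      stats::rnorm(nf - 1L, 0, sqrt(2 * D * frame_interval))))
      rows[[i]] <- data.frame(id = i, frame = seq_len(nf),
                              position_um = pos,
                              intensity = rep(1000, nf))
    }
    list(
      tracks = do.call(rbind, rows),
      truth = .ground_truth("gen_lattice_tracks", seed,
        params = list(n_tracks = n_tracks, D = D,
                      frame_interval = frame_interval, n_frames = n_frames,
                      lifetime_mean_s = as.list(lifetime_mean_s),
                      substrate_mix = as.list(substrate_mix)),
        truth = list(D = D, substrate = substrate, lifetime_s = lifetimes))
    )
  })
}

#' Synthetic TEM transect profile with gold-particle dips
#'
#' A bright baseline with inverted-Gaussian dips at centers whose
#' successive spacings are drawn from a normal distribution truncated at
#' the resolvable limit of two pixels; sub-limit draws are redrawn and the
#' truth stores the realized centers and spacings.
#'
#' @param seed Integer RNG seed.
#' @param n_dips Number of dips (>= 1).
#' @param spacing_mean_nm,spacing_sd_nm Spacing distribution (nm).
#' @param nm_per_px Sampling step of the transect (nm per sample).
#' @param dip_depth Dip depth in intensity units.
#' @param noise_sd Gaussian noise sd on the profile.
#' @param dip_sigma_nm Gaussian half-width of each dip.
#' @param baseline Baseline intensity.
#' @return List with `profile` (a [transect_profile()]) and `truth`
#'   (`centers_nm`, `spacings_nm`).
#' @export
gen_tem_transect <- function(seed, n_dips = 1800, spacing_mean_nm = 10,
                             spacing_sd_nm = 2.4, nm_per_px = 0.5,
                             dip_depth = 300, noise_sd = 20,
                             dip_sigma_nm = 1.0, baseline = 1000) {
  if (spacing_mean_nm <= 0 || nm_per_px <= 0)
    stop("`spacing_mean_nm` and `nm_per_px` must be > 0")
  min_sp <- 2 * nm_per_px
  if (spacing_mean_nm < min_sp)
    stop("requested mean spacing is below the 2-px resolvable limit")
  withr::with_seed(seed, {
    spacings <- if (n_dips > 1) {
      s <- stats::rnorm(n_dips - 1L, spacing_mean_nm, spacing_sd_nm)
      while (any(bad <- s < min_sp))
        s[bad] <- stats::rnorm(sum(bad), spacing_mean_nm, spacing_sd_nm)
      s
    } else numeric(0)
    margin <- 10 * dip_sigma_nm + 5
    centers <- margin + cumsum(c(0, spacings))
    len_px <- ceiling((max(centers) + margin) / nm_per_px)
    x <- (seq_len(len_px) - 1) * nm_per_px
    prof <- rep(baseline, len_px)
    # dips have compact support: accumulate locally
    for (ct in centers) {
      lo <- max(1L, floor((ct - 5 * dip_sigma_nm) / nm_per_px))
      hi <- min(len_px, ceiling((ct + 5 * dip_sigma_nm) / nm_per_px))
      idx <- lo:hi
      prof[idx] <- prof[idx] -
        dip_depth * exp(-(x[idx] - ct)^2 / (2 * dip_sigma_nm^2))
    }
    prof <- prof + stats::rnorm(len_px, 0, noise_sd)
    list(
      profile = transect_profile(prof, nm_per_px),
      truth = .ground_truth("gen_tem_transect", seed,
        params = list(n_dips = n_dips, spacing_mean_nm = spacing_mean_nm,
                      spacing_sd_nm = spacing_sd_nm, nm_per_px = nm_per_px,
                      dip_depth = dip_depth, noise_sd = noise_sd,
                      dip_sigma_nm = dip_sigma_nm, baseline = baseline),
        truth = list(centers_nm = centers, spacings_nm = spacings))
    )
  })
}

#' Synthetic gold-label row pairs
#'
#' Pairs of straight rows of gold-label points with a controlled inter-row
#' angle and per-row label counts (normal around 8 +/- 5 labels, clipped
#' to `labels_per_row_range`, matching the observed row-length statistics).
#'
#' @param seed Integer RNG seed.
#' @param n_row_pairs Number of adjacent-row pairs.
#' @param angle_mean_deg,angle_sd_deg Inter-row angle distribution; draws
#'   are folded into \[0, 90\] degrees.
#' @param labels_per_row_range Integer clip range for labels per row.
#' @param spacing_nm Within-row label spacing (nm).
#' @param jitter_nm Isotropic positional jitter sd (0 = noiseless).
#' @return List with `rows` (a `gold_row_set`: list of data frames with
#'   `x_nm`, `y_nm`) and `truth` (`angles_deg` per pair, `labels_per_row`).
#' @export
gen_gold_rows <- function(seed, n_row_pairs = 49, angle_mean_deg = 2.8,
                          angle_sd_deg = 3, labels_per_row_range = c(2L, 41L),
                          spacing_nm = 10, jitter_nm = 0) {
  withr::with_seed(seed, {
    rows <- list(); angles <- numeric(n_row_pairs); counts <- integer(0)
    for (i in seq_len(n_row_pairs)) {
      alpha <- .fold_angle(stats::rnorm(1, angle_mean_deg, angle_sd_deg))
      theta0 <- stats::runif(1, 0, 180)
      base <- c(stats::runif(1, 0, 500), stats::runif(1, 0, 500))
      nlab <- as.integer(pmin(pmax(round(stats::rnorm(2, 8, 5)),
                                   labels_per_row_range[1L]),
                              labels_per_row_range[2L]))
      mk <- function(theta_deg, offset) {
        th <- theta_deg * pi / 180
        n <- nlab[if (offset == 0) 1L else 2L]
        s <- (seq_len(n) - 1) * spacing_nm
        data.frame(
          x_nm = base[1L] + s * cos(th) - offset * sin(th) +
            stats::rnorm(n, 0, jitter_nm),
          y_nm = base[2L] + s * sin(th) + offset * cos(th) +
            stats::rnorm(n, 0, jitter_nm))
      }
      rows[[2L * i - 1L]] <- mk(theta0, 0)
      rows[[2L * i]] <- mk(theta0 + alpha, 25)
      angles[i] <- alpha
      counts <- c(counts, nlab)
    }
    list(
      rows = structure(list(rows = rows, nm_per_px = 1), class = "gold_row_set"),
      truth = .ground_truth("gen_gold_rows", seed,
        params = list(n_row_pairs = n_row_pairs,
                      angle_mean_deg = angle_mean_deg,
                      angle_sd_deg = angle_sd_deg,
                      labels_per_row_range = labels_per_row_range,
                      spacing_nm = spacing_nm, jitter_nm = jitter_nm),
        truth = list(angles_deg = angles, labels_per_row = counts))
    )
  })
}

.fold_angle <- function(a) {
  a <- abs(a) %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Synthetic growing/shrinking filament-tip movie
#'
#' A single straight filament along an image row whose tip advances and
#' retreats at piecewise-constant velocity; phases alternate
#' growth/shrink/growth... at the given switch times. The truth stores the
#' tip-position series and the per-segment signed velocities.
#'
#' @param seed Integer RNG seed.
#' @param growth_v_um_min,shrink_v_um_min Speeds in um/min (>= 0).
#' @param switch_times Seconds at which the phase flips (may be empty).
#' @param duration_s Movie duration in seconds.
#' @param frame_interval Seconds per frame.
#' @param dims Frame dimensions.
#' @param pixel_size Micrometres per pixel.
#' @param snr Filament amplitude over read-noise sd.
#' @return List with `movie` (a [time_lapse()]) and `truth`
#'   (`tip_position_um` per frame, `segment_velocity_um_min`,
#'   `switch_times`, `axis_row`, `base_col`).
#' @export
gen_tip_movie <- function(seed, growth_v_um_min = 4, shrink_v_um_min = 8,
                          switch_times = numeric(), duration_s = 120,
                          frame_interval = 2, dims = c(48L, 256L),
                          pixel_size = 0.065, snr = 15) {
  amp <- 8000; bg <- 300
  withr::with_seed(seed, {
    nf <- floor(duration_s / frame_interval) + 1L
    t_s <- (seq_len(nf) - 1L) * frame_interval
    bounds <- c(0, sort(switch_times), Inf)
    v_seg <- vapply(seq_len(length(bounds) - 1L), function(k) {
      if (k %% 2L == 1L) growth_v_um_min / 60 else -shrink_v_um_min / 60
    }, numeric(1))                               # um/s, signed
    tip <- numeric(nf); s0 <- 2                  # um from base
    pos <- s0
    for (i in seq_len(nf)) {
      tip[i] <- pos
      seg <- findInterval(t_s[i], bounds, rightmost.closed = FALSE)
      pos <- pos + v_seg[seg] * frame_interval
    }
    tip <- pmax(tip, 0.5)
    axis_row <- round(dims[1L] / 2)
    base_col <- 10
    sigma_w <- 1.3
    rowd <- (seq_len(dims[1L]) - axis_row)
    cross <- exp(-rowd^2 / (2 * sigma_w^2))
    frames <- lapply(seq_len(nf), function(i) {
      tip_col <- base_col + tip[i] / pixel_size
      cols <- seq_len(dims[2L])
      # soft end: intensity falls off over ~1 px at the tip
      axial <- stats::pnorm(tip_col - cols, 0, 0.5) *
        stats::pnorm(cols - base_col, 0, 0.5)
      signal <- outer(cross, axial) * amp + bg
      .camera_noise(signal, read_sd = amp / snr)
    })
    list(
      movie = time_lapse(frames, pixel_size, frame_interval, "tirf"),
      truth = .ground_truth("gen_tip_movie", seed,
        params = list(growth_v_um_min = growth_v_um_min,
                      shrink_v_um_min = shrink_v_um_min,
                      switch_times = switch_times, duration_s = duration_s,
                      frame_interval = frame_interval, dims = dims,
                      pixel_size = pixel_size, snr = snr),
        truth = list(tip_position_um = tip, time_s = t_s,
                     segment_velocity_um_min = v_seg[seq_len(length(bounds) - 1L)] * 60,
                     switch_times = switch_times,
                     axis_row = axis_row, base_col = base_col))
    )
  })
}

#' Synthetic dual-channel co-localization images
#'
#' Channel B foci are channel A foci translated by `true_shift_px` columns
#' for a `coloc_fraction` subset and placed independently elsewhere.
#'
#' @param seed Integer RNG seed.
#' @param n_foci Foci per channel.
#' @param true_shift_px Integer column shift applied to co-localized foci.
#' @param coloc_fraction Fraction of foci shared between channels, in
#'   \[0, 1\].
#' @param noise_sd Gaussian read-noise sd.
#' @param dims Image dimensions.
#' @param pixel_size Micrometres per pixel.
#' @return List with `channel_a`, `channel_b` ([calibrated_image()]s) and
#'   `truth` (`shift_px`, `NA` and flagged undefined when
#'   `coloc_fraction` is 0; `coloc_fraction`; foci point sets).
#' @export
gen_dual_channel <- function(seed, n_foci = 30, true_shift_px = 0,
                             coloc_fraction = 1, noise_sd = 200,
                             dims = c(128L, 128L), pixel_size = 0.1) {
  amp <- 8000; bg <- 400; sigma <- 1.8
  withr::with_seed(seed, {
    margin <- 25
    n_shared <- round(coloc_fraction * n_foci)
    ra <- stats::runif(n_foci, margin, dims[1L] - margin)
    ca <- stats::runif(n_foci, margin, dims[2L] - margin)
    rb <- c(ra[seq_len(n_shared)],
            stats::runif(n_foci - n_shared, margin, dims[1L] - margin))
    cb <- c(ca[seq_len(n_shared)] + true_shift_px,
            stats::runif(n_foci - n_shared, margin, dims[2L] - margin))
    render <- function(r, c) {
      sig <- gaussian_smooth(.splat(dims, r, c,
                                    rep(amp * 2 * pi * sigma^2, length(r))),
                             sigma) + bg
      .camera_noise(sig, noise_sd)
    }
    list(
      channel_a = calibrated_image(render(ra, ca), pixel_size, "confocal"),
      channel_b = calibrated_image(render(rb, cb), pixel_size, "confocal"),
      truth = .ground_truth("gen_dual_channel", seed,
        params = list(n_foci = n_foci, true_shift_px = true_shift_px,
                      coloc_fraction = coloc_fraction, noise_sd = noise_sd,
                      dims = dims, pixel_size = pixel_size),
        truth = list(
          shift_px = if (n_shared > 0) true_shift_px else NA_real_,
          shift_defined = n_shared > 0,
          coloc_fraction = coloc_fraction,
          foci_a = point_set(ra, ca), foci_b = point_set(rb, cb)))
    )
  })
}
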