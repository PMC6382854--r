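# Particle-density stage: cell mask, two-scale blob detection, and the
# count-subtraction density.

test_that("cell detection recovers a bright disk and scales out intensity", {
  disk <- matrix(0, 120, 120)
  disk[(row(disk) - 60)^2 + (col(disk) - 60)^2 <= 40^2] <- 5000
  withr::with_seed(1, noisy <- disk + matrix(runif(120^2, 0, 50), 120, 120))
  img <- calibrated_image(noisy, 0.1)
  mask <- detect_cell(img)
  expect_lt(abs(sum(mask) - pi * 40^2) / (pi * 40^2), 0.05)
  expect_equal(detect_cell(calibrated_image(noisy * 4, 0.1)), mask)
  expect_error(detect_cell(calibrated_image(matrix(5, 20, 20), 0.1)), "constant")
})

test_that("particle detection finds all well-separated foci within a pixel", {
  blank <- calibrated_image(matrix(400, 60, 60), 0.13)
  expect_equal(nrow(detect_particles(blank)), 0L)

  gm <- gen_particle_movie(21, n_particles = 20, n_golgi = 0)
  img <- calibrated_image(gm$movie$frames[[1]], gm$movie$pixel_size)
  pts <- detect_particles(img, cell_mask = gm$truth$truth$cell_mask)
  expect_equal(nrow(pts), 20L)
  m <- match_points(pts, gm$truth$truth$particles, radius_px = 1)
  expect_equal(m$n_matched, 20L)

  # doubling the tolerance can only drop detections
  more <- detect_particles(img, noise_tolerance = 1600,
                           cell_mask = gm$truth$truth$cell_mask)
  expect_lte(nrow(more), nrow(pts))
})

test_that("the two detection scales separate foci from Golgi-sized blobs", {
  golgi_only <- gen_particle_movie(22, n_particles = 0, n_golgi = 3)
  gi <- calibrated_image(golgi_only$movie$frames[[1]], golgi_only$movie$pixel_size)
  expect_equal(nrow(detect_golgi(gi, cell_mask = golgi_only$truth$truth$cell_mask)), 3L)

  foci_only <- gen_particle_movie(22, n_particles = 25, n_golgi = 0)
  fi <- calibrated_image(foci_only$movie$frames[[1]], foci_only$movie$pixel_size)
  expect_equal(nrow(detect_golgi(fi, cell_mask = foci_only$truth$truth$cell_mask)), 0L)
})

test_that("density subtracts Golgi counts from particle counts", {
  # constructed fixture: 12 gridded foci + 3 bright blobs that register
  # at both detection scales, flat cell over the whole frame
  dims <- c(150L, 150L)
  gr <- c(40, 75, 110); gc <- c(110, 40, 75)
  grid <- expand.grid(r = c(25, 60, 95, 130), c = c(25, 60, 95, 130))
  far <- apply(sqrt(outer(grid$r, gr, "-")^2 + outer(grid$c, gc, "-")^2),
               1, min) > 20
  pr <- grid$r[far][1:12]; pc <- grid$c[far][1:12]
  sp <- 0.2 / 0.13; sg <- 0.8 / 0.13
  spots <- gaussian_smooth(mapquant:::.splat(dims, pr, pc,
            rep(12000 * 2 * pi * sp^2, length(pr))), sp)
  blobs <- gaussian_smooth(mapquant:::.splat(dims, gr, gc,
            rep(60000 * 2 * pi * sg^2, 3)), sg)
  img <- calibrated_image(spots + blobs + 400, 0.13)
  all_mask <- matrix(TRUE, dims[1], dims[2])
  res <- particle_density(img, cell_mask = all_mask)
  area <- prod(dims) * 0.13^2
  expect_equal(res$n_particles, length(pr) + 3)   # blobs register as particles
  expect_equal(res$n_golgi, 3)
  expect_equal(res$density, length(pr) / area)
  expect_true(res$valid)

  # no structures at all, with an externally supplied cell mask
  flatnoise <- withr::with_seed(2, matrix(400 + rnorm(150^2, 0, 20), 150, 150))
  none <- particle_density(calibrated_image(pmax(flatnoise, 0), 0.13),
                           cell_mask = all_mask)
  expect_equal(none$density, 0)
})

test_that("density halves when the cell area doubles at fixed counts", {
  n <- 10; a1 <- 100
  expect_equal((n - 2) / (2 * a1), ((n - 2) / a1) / 2)
  # same identity through the result object
  gm <- gen_particle_movie(23, n_particles = 15, n_golgi = 0)
  img <- calibrated_image(gm$movie$frames[[1]], gm$movie$pixel_size)
  m1 <- gm$truth$truth$cell_mask
  r1 <- particle_density(img, cell_mask = m1)
  big <- calibrated_image(gm$movie$frames[[1]], gm$movie$pixel_size * sqrt(2))
  r2 <- particle_density(big, cell_mask = m1)
  expect_equal(r2$cell_area_um2, 2 * r1$cell_area_um2, tolerance = 1e-9)
})

test_that("foci are counted per 50 x 50 px window and windows add up", {
  gm <- gen_particle_movie(24, n_particles = 18, n_golgi = 0,
                           dims = c(150L, 150L))
  img <- calibrated_image(gm$movie$frames[[1]], gm$movie$pixel_size)
  tp <- gm$truth$truth$particles
  n_win <- sum(tp$row >= 31 & tp$row < 81 & tp$col >= 31 & tp$col < 81)
  expect_equal(foci_per_window(img, origin = c(31, 31), window_px = 50), n_win)

  blank <- calibrated_image(matrix(400, 80, 80), 0.13)
  expect_equal(foci_per_window(blank, c(1, 1), 50), 0L)
  expect_error(foci_per_window(blank, c(60, 60), 50), "outside")

  # counts over a disjoint window tiling sum to the whole-frame count
  origins <- expand.grid(r = c(1, 51, 101), c = c(1, 51, 101))
  total <- sum(mapply(function(r, c)
    foci_per_window(img, c(r, c), 50), origins$r, origins$c))
  expect_equal(total, nrow(detect_particles(img)))
})
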