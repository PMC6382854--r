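# Generators: determinism, truth consistency, and the statistical
# structure each downstream stage assumes.

test_that("generators are deterministic given seed and parameters", {
  a <- gen_mt_array(4, n_fibers = 8); b <- gen_mt_array(4, n_fibers = 8)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$truth, b$truth$truth)

  ta <- gen_lattice_tracks(4, n_tracks = 5, n_frames = 50)
  tb <- gen_lattice_tracks(4, n_tracks = 5, n_frames = 50)
  expect_identical(ta$tracks, tb$tracks)

  pa <- gen_tem_transect(4, n_dips = 30); pb <- gen_tem_transect(4, n_dips = 30)
  expect_identical(pa$profile$intensity, pb$profile$intensity)

  ma <- gen_tip_movie(4); mb <- gen_tip_movie(4)
  expect_identical(ma$movie$frames, mb$movie$frames)
})

test_that("microtubule array truth coverage behaves with fiber number", {
  zero <- gen_mt_array(1, n_fibers = 0)
  expect_equal(zero$truth$truth$coverage, 0)

  covs <- vapply(c(5, 10, 20), function(nf)
    gen_mt_array(3, n_fibers = nf)$truth$truth$coverage, numeric(1))
  expect_true(all(diff(covs) > 0))
  expect_error(gen_mt_array(1, n_fibers = 2, fiber_width_px = 300),
               "geometry")
})

test_that("particle movies carry exact truth and subpixel-faithful foci", {
  noise_only <- gen_particle_movie(2, n_particles = 0, n_golgi = 0)
  expect_equal(nrow(noise_only$truth$truth$particles), 0L)
  expect_equal(nrow(noise_only$truth$truth$golgi), 0L)

  gm <- gen_particle_movie(2, n_particles = 12, n_golgi = 2)
  expect_equal(nrow(gm$truth$truth$particles), 12L)
  expect_equal(nrow(gm$truth$truth$golgi), 2L)

  # center of mass of each rendered focus sits on the truth coordinate
  clean <- gen_particle_movie(2, n_particles = 6, n_golgi = 0, snr = 1e6)
  f <- clean$movie$frames[[1]]
  tp <- clean$truth$truth$particles
  for (k in seq_len(nrow(tp))) {
    rr <- round(tp$row[k]); cc <- round(tp$col[k])
    win <- f[(rr - 5):(rr + 5), (cc - 5):(cc + 5)]
    win <- win - min(win)
    com_r <- sum(row(win) * win) / sum(win) + rr - 6
    com_c <- sum(col(win) * win) / sum(win) + cc - 6
    expect_lt(abs(com_r - tp$row[k]), 0.25)
    expect_lt(abs(com_c - tp$col[k]), 0.25)
  }
})

test_that("lattice tracks have Brownian increments with the requested D", {
  frozen <- gen_lattice_tracks(5, n_tracks = 3, D = 0, n_frames = 30)
  spread <- tapply(frozen$tracks$position_um, frozen$tracks$id,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))

  big <- gen_lattice_tracks(6, n_tracks = 250, D = 0.076,
                            frame_interval = 0.1, n_frames = 500)
  incs <- unlist(tapply(big$tracks$position_um, big$tracks$id, diff))
  expect_gt(length(incs), 1e5)
  expect_equal(var(incs), 2 * 0.076 * 0.1, tolerance = 0.05)
})

test_that("TEM transect truth stores realized spacings and accurate dip centers", {
  single <- gen_tem_transect(3, n_dips = 1)
  expect_length(single$truth$truth$spacings_nm, 0)

  g <- gen_tem_transect(3, n_dips = 40)
  expect_equal(diff(g$truth$truth$centers_nm), g$truth$truth$spacings_nm,
               tolerance = 1e-12)

  quiet <- gen_tem_transect(3, n_dips = 25, noise_sd = 1e-9)
  found <- detect_dips(quiet$profile, min_separation_nm = 3)
  expect_equal(length(found), 25L)
  expect_lt(max(abs(found - quiet$truth$truth$centers_nm)),
            0.2 * quiet$profile$nm_per_px)

  expect_error(gen_tem_transect(1, spacing_mean_nm = 0.5, nm_per_px = 0.5),
               "resolvable")
})

test_that("gold row pairs honor requested angles and counts", {
  par0 <- gen_gold_rows(4, n_row_pairs = 5, angle_mean_deg = 0, angle_sd_deg = 0)
  expect_equal(par0$truth$truth$angles_deg, rep(0, 5))
  expect_equal(row_angles(par0$rows), rep(0, 5), tolerance = 1e-6)

  g <- gen_gold_rows(4, n_row_pairs = 8, jitter_nm = 0)
  expect_equal(row_angles(g$rows), g$truth$truth$angles_deg, tolerance = 0.1)
  expect_equal(labels_per_row(g$rows)$counts, g$truth$truth$labels_per_row)
})

test_that("tip movies advance the tip at the requested velocity", {
  still <- gen_tip_movie(5, growth_v_um_min = 0, shrink_v_um_min = 0)
  expect_equal(diff(range(still$truth$truth$tip_position_um)), 0)

  g <- gen_tip_movie(5, growth_v_um_min = 6, frame_interval = 2)
  dtip <- diff(g$truth$truth$tip_position_um)
  expect_equal(dtip, rep(6 / 60 * 2, length(dtip)), tolerance = 1e-12)
  # rendered bright-region edge follows the truth tip within rasterization
  f10 <- g$movie$frames[[10]]
  prof <- f10[g$truth$truth$axis_row, ]
  tip_col_est <- max(which(prof > 0.5 * max(prof)))
  tip_col_true <- g$truth$truth$base_col +
    g$truth$truth$tip_position_um[10] / g$movie$pixel_size
  expect_lt(abs(tip_col_est - tip_col_true), 1.5)
})

test_that("dual-channel truth flags undefined shifts", {
  full <- gen_dual_channel(6, coloc_fraction = 1, true_shift_px = 0, noise_sd = 50)
  expect_true(full$truth$truth$shift_defined)
  expect_gt(pearson_coloc(full$channel_a, full$channel_b), 0.9)

  none <- gen_dual_channel(6, coloc_fraction = 0, true_shift_px = 3)
  expect_false(none$truth$truth$shift_defined)
  expect_true(is.na(none$truth$truth$shift_px))

  shifted <- gen_dual_channel(6, true_shift_px = 5)
  expect_equal(shifted$truth$truth$shift_px, 5)
})
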