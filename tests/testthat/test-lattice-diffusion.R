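# Diffusion stage: time-averaged MSD, ensemble D, lifetimes, bundle
# counting by intensity quantization.

test_that("MSD matches the double-loop definition and handles edge cases", {
  still <- data.frame(frame = 1:50, position_um = rep(1.5, 50))
  r <- msd(still, frame_interval = 0.1)
  expect_true(all(r$msd_um2 == 0))
  expect_equal(r$D_um2_s, 0)

  for (seed in 1:5) {
    withr::with_seed(seed, x <- cumsum(rnorm(120, 0, 0.1)))
    tr <- data.frame(frame = seq_along(x), position_um = x)
    r <- msd(tr, frame_interval = 0.1)
    o <- oracle_msd(x, max_lag = 10)
    expect_equal(r$msd_um2, o$msd, tolerance = 1e-12)
    expect_equal(r$n_pairs, o$n_pairs)
  }

  expect_error(msd(data.frame(frame = 1:5, position_um = 1:5), 0.1), "short")
  expect_error(msd(data.frame(frame = c(1, 1, 2:12), position_um = 0), 0.1),
               "increasing")
})

test_that("ballistic drift is flagged by its quadratic MSD", {
  v <- 0.5
  tr <- data.frame(frame = 1:100, position_um = v * (1:100) * 0.1)
  r <- msd(tr, frame_interval = 0.1)
  expect_equal(r$msd_um2, v^2 * r$lags_s^2, tolerance = 1e-9)
  loglog <- stats::coef(stats::lm(log(r$msd_um2) ~ log(r$lags_s)))[2]
  expect_equal(unname(loglog), 2, tolerance = 1e-6)
})

test_that("ensemble D recovers the generating coefficient and scales with dt", {
  g <- gen_lattice_tracks(50)
  e <- ensemble_D(g$tracks, frame_interval = 0.1)
  expect_equal(e$n, 50L)
  expect_equal(e$mean_D, 0.076, tolerance = 0.1)

  one <- g$tracks[g$tracks$id == 1, ]
  copies <- rbind(one, transform(one, id = 2), transform(one, id = 3))
  es <- ensemble_D(copies, frame_interval = 0.1)
  expect_equal(es$sd_D, 0)

  # same displacements read at half the frame rate imply twice the D
  e2 <- ensemble_D(g$tracks, frame_interval = 0.05)
  expect_equal(e2$mean_D, 2 * e$mean_D, tolerance = 1e-9)
  expect_error(ensemble_D(g$tracks[g$tracks$id == 1, ], 0.1), "2 usable")
})

test_that("MSD estimator is unbiased across many simulated tracks", {
  g <- gen_lattice_tracks(99, n_tracks = 200)
  e <- ensemble_D(g$tracks, frame_interval = 0.1)
  expect_gt(e$mean_D / 0.076, 0.95)
  expect_lt(e$mean_D / 0.076, 1.05)
})

test_that("lifetimes follow the first-appearance-to-disappearance rule", {
  tracks <- data.frame(id = rep(c("a", "b"), c(8, 1)),
                       frame = c(3:10, 5))
  lt <- lifetimes(tracks, c(a = "single", b = "bundle"), frame_interval = 0.1)
  expect_equal(lt$records$lifetime_s[lt$records$id == "a"], 0.8)
  expect_equal(lt$records$lifetime_s[lt$records$id == "b"], 0.1)

  shifted <- transform(tracks, frame = frame + 1000L)
  lt2 <- lifetimes(shifted, c(a = "single", b = "bundle"), 0.1)
  expect_equal(lt2$records$lifetime_s, lt$records$lifetime_s)

  expect_error(lifetimes(tracks, c(a = "single"), 0.1), "unlabeled")
  expect_error(lifetimes(tracks, c(a = "single", b = "golgi"), 0.1), "single")
})

test_that("longer bundle lifetimes are recovered in group medians", {
  # group sizes follow the published experiment: 60 single, 37 bundled
  hits <- 0L
  for (seed in 1:20) {
    g <- gen_lattice_tracks(seed, n_tracks = 97, n_frames = 400,
                            lifetime_mean_s = c(single = 2, bundle = 4),
                            substrate_mix = c(single = 60 / 97, bundle = 37 / 97))
    lab <- stats::setNames(g$truth$truth$substrate, unique(g$tracks$id))
    lt <- lifetimes(g$tracks, lab, frame_interval = 0.1)
    med <- stats::setNames(lt$summary$median, lt$summary$substrate)
    if (med[["bundle"]] > med[["single"]]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("bundle counts quantize intensities against the unit microtubule", {
  expect_equal(classify_substrate(1000, unit_intensity = 1000)$n_mt, 1L)
  expect_equal(classify_substrate(2900, unit_intensity = 1000)$n_mt, 3L)
  expect_equal(classify_substrate(9000, unit_intensity = 1000, cap = 5)$n_mt, 5L)
  expect_equal(classify_substrate(10, unit_intensity = 1000)$n_mt, 1L)
  expect_error(classify_substrate(1000, unit_intensity = 0), "> 0")
  expect_equal(estimate_unit_intensity(c(900, 1000, 1300)), 1000)

  # rendered cross-sections: k overlapping fibers at SNR >= 5
  withr::with_seed(7, {
    n_ok <- 0L; n_tot <- 0L
    for (k in 1:5) for (rep in 1:8) {
      prof <- k * 1000 * exp(-(-15:15)^2 / (2 * 1.6^2)) + rnorm(31, 0, 200)
      n_tot <- n_tot + 1L
      est <- classify_substrate(sum(prof), unit_intensity = 1000 * 1.6 * sqrt(2 * pi))
      if (est$n_mt == k) n_ok <- n_ok + 1L
    }
    expect_gte(n_ok / n_tot, 0.9)
  })
})
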