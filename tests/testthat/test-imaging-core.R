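# The primitive operators, checked against closed forms and the naive
# reference implementations in helper-oracles.R (deeper multi-seed oracle
# sweeps live in test-acceptance.R).

test_that("gaussian smoothing reproduces the closed-form kernel", {
  const <- matrix(7, 15, 15)
  expect_equal(gaussian_smooth(const, 2), const, tolerance = 1e-12)

  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussian_smooth(imp, 2)
  expect_equal(sm[11, 11], 1 / (2 * pi * 4), tolerance = 1e-3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)     # interior support: mass kept
  expect_error(gaussian_smooth(imp, 0), "positive")
})

test_that("sobel magnitude matches a hand-convolved step and symmetries", {
  expect_equal(max(sobel_magnitude(matrix(5, 9, 9))), 0)

  step <- matrix(0, 8, 8); step[, 5:8] <- 100
  sm <- sobel_magnitude(step)
  expect_equal(sm[3, 4], 400)
  expect_equal(sm[3, 5], 400)
  expect_equal(max(sm[, 1:2]), 0)

  withr::with_seed(4, m <- matrix(runif(100, 0, 50), 10, 10))
  rot <- function(x) t(apply(x, 2, rev))
  expect_equal(sobel_magnitude(rot(m)), rot(sobel_magnitude(m)),
               tolerance = 1e-9)
})

test_that("log ridge response peaks on bright spots and flips sign on dark ones", {
  expect_equal(max(abs(log_ridge(matrix(3, 12, 12), 1.5))), 0, tolerance = 1e-9)

  spot <- outer(1:21, 1:21, function(i, j) 1000 * exp(-((i - 11)^2 + (j - 11)^2) / 8))
  resp <- log_ridge(spot, 1.5)
  expect_equal(unname(which(resp == max(resp), arr.ind = TRUE)[1, ]), c(11L, 11L))

  dark <- 1000 - spot
  expect_lt(log_ridge(dark, 1.5)[11, 11], 0)
})

test_that("otsu threshold separates a bimodal image and shifts with offsets", {
  bim <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr <- otsu_threshold(bim)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_equal(otsu_threshold(bim + 37.5) - thr, 37.5, tolerance = 1e-9)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
  for (seed in 1:5) {
    m <- random_image(seed, 16, 16, smooth = FALSE)
    expect_equal(otsu_threshold(m), oracle_otsu(as.vector(m)), tolerance = 1e-9)
  }
})

test_that("despeckle is the 3x3 median", {
  hot <- matrix(5, 9, 9); hot[5, 5] <- 1000
  expect_equal(despeckle(hot)[5, 5], 5)
  expect_equal(despeckle(matrix(2, 6, 6)), matrix(2, 6, 6))
  for (seed in 1:5) {
    m <- random_image(seed, 12, 12, smooth = FALSE)
    expect_equal(despeckle(m), oracle_median3(m), tolerance = 1e-12)
  }
})

test_that("component filtering is 8-connected with an inclusive size gate", {
  m19 <- matrix(FALSE, 12, 12); m19[2:4, 2:8] <- TRUE
  m19[4, 8] <- FALSE; m19[2, 2] <- FALSE     # 21 - 2 = 19 px
  expect_equal(sum(m19), 19)
  expect_false(any(filter_components(m19, 20)))

  m20 <- m19; m20[2, 2] <- TRUE
  expect_equal(filter_components(m20, 20), m20)

  diag2 <- matrix(FALSE, 6, 6); diag2[cbind(1:4, 1:4)] <- TRUE
  expect_equal(sum(filter_components(diag2, 4)), 4)  # diagonal chain connected

  for (seed in 1:8) {
    msk <- random_mask(seed, 32, 32)
    keep <- filter_components(msk, 5)
    lab <- oracle_label8(msk)
    sizes <- tabulate(lab[lab > 0])
    expect_equal(keep, matrix(lab %in% which(sizes >= 5), 32, 32))
  }
})

test_that("region closing fills rings and is extensive", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(close_region(empty, 3), empty)

  ring <- matrix(FALSE, 21, 21)
  th <- seq(0, 2 * pi, length.out = 120)
  ring[cbind(round(11 + 7 * cos(th)), round(11 + 7 * sin(th)))] <- TRUE
  closed <- close_region(ring, 2)
  expect_true(closed[11, 11])               # hole filled
  expect_true(all(closed[ring]))

  for (seed in 1:5) {
    msk <- random_mask(seed, 20, 20, p = 0.1)
    expect_true(all(close_region(msk, 2)[msk]))
  }
  expect_error(close_region(empty, 0), ">= 1")
})

test_that("skeletonization thins ribbons to unit width inside the mask", {
  rb <- matrix(FALSE, 11, 30); rb[4:8, ] <- TRUE
  sk <- skeletonize(rb)
  expect_true(all(!sk | rb))                       # skeleton subset of mask
  expect_true(all(colSums(sk)[5:26] == 1))         # 1 px wide away from ends
  expect_equal(max(label_components(sk)), 1L)      # stays connected
  expect_equal(skeletonize(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
})

test_that("maxima detection follows prominence-over-saddle semantics", {
  expect_equal(nrow(find_maxima(matrix(3, 10, 10), 0)$maxima), 0L)

  peak <- outer(1:15, 1:15, function(i, j) 1000 * exp(-((i - 8)^2 + (j - 8)^2) / 8))
  fm <- find_maxima(peak, 800)$maxima
  expect_equal(nrow(fm), 1L)
  expect_equal(c(fm$row, fm$col), c(8, 8))

  # two summits joined through a ridge at 900: lower summit prominence 100
  two <- matrix(0, 9, 21)
  two[5, ] <- 900; two[5, 4] <- 1500; two[5, 18] <- 1000
  expect_equal(nrow(find_maxima(two, 800)$maxima), 1L)
  expect_equal(nrow(find_maxima(two, 50)$maxima), 2L)

  plateau <- matrix(0, 9, 9); plateau[4:5, 4:6] <- 10
  fp <- find_maxima(plateau, 5)$maxima
  expect_equal(c(fp$row, fp$col), c(4.5, 5))

  expect_error(find_maxima(plateau, -1), ">= 0")
})

test_that("maxima count is non-increasing in noise tolerance", {
  for (seed in 1:6) {
    m <- random_image(seed, 20, 20)
    tols <- c(0, 10, 40, 160, 640)
    counts <- vapply(tols, function(tl) nrow(find_maxima(m, tl)$maxima), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("operators are translation-equivariant away from boundaries", {
  withr::with_seed(11, base <- gaussian_smooth(matrix(runif(26 * 26, 0, 100), 26, 26), 1))
  pad <- matrix(0, 46, 46)
  a <- pad; a[9:34, 9:34] <- base
  b <- pad; b[11:36, 12:37] <- base        # shifted by (2, 3)
  inner_a <- function(x) x[15:28, 15:28]   # > kernel radius from all edges
  inner_b <- function(x) x[17:30, 18:31]
  expect_equal(inner_b(gaussian_smooth(b, 1.5)), inner_a(gaussian_smooth(a, 1.5)),
               tolerance = 1e-9)
  expect_equal(inner_b(sobel_magnitude(b)), inner_a(sobel_magnitude(a)),
               tolerance = 1e-9)
  expect_equal(inner_b(despeckle(b)), inner_a(despeckle(a)), tolerance = 1e-12)
  expect_equal(inner_b(log_ridge(b, 1.5)), inner_a(log_ridge(a, 1.5)),
               tolerance = 1e-9)
})
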