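# Primitive image operators composed by every analysis stage. All filters
# operate in floating point with reflective boundary handling; connectivity
# is 8-connected throughout.

# reflect indices 1..n outward (abcd -> b a | a b c d | d c)
.reflect_idx <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  p <- ifelse(p < 0L, p + 2L * n, p)
  ifelse(p < n, p + 1L, 2L * n - p)
}

.pad_reflect <- function(m, rpad, cpad = rpad) {
  ri <- .reflect_idx(seq.int(1L - rpad, nrow(m) + rpad), nrow(m))
  ci <- .reflect_idx(seq.int(1L - cpad, ncol(m) + cpad), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 2-D convolution (correlation with flipped kernel) with reflective boundary
.conv2_reflect <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  p <- .pad_reflect(m, kr, kc)
  out <- matrix(0, nrow(m), ncol(m))
  k <- kernel[nrow(kernel):1L, ncol(kernel):1L, drop = FALSE]  # flip: convolution
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] *
        p[i:(i + nrow(m) - 1L), j:(j + ncol(m) - 1L), drop = FALSE]
    }
  }
  out
}

.gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3.5 * sigma_px))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma_px^2))
  k / sum(k)
}

# separable 1-D convolution along rows (dim 1) with reflective padding
.conv_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  ri <- .reflect_idx(seq.int(1L - r, nrow(m) + r), nrow(m))
  p <- m[ri, , drop = FALSE]
  f <- stats::filter(p, rev(k), sides = 2L)
  matrix(f[(r + 1L):(r + nrow(m)), ], nrow(m), ncol(m))
}

.keep_calibration <- function(img, pixels) {
  if (is_calibrated_image(img))
    calibrated_image(pmax(pixels, 0), img$pixel_size, img$modality)
  else pixels
}

.sigma_to_px <- function(img, sigma) {
  if (is_calibrated_image(img)) sigma / img$pixel_size else sigma
}

#' Gaussian smoothing
#'
#' Convolution with an isotropic Gaussian kernel, reflective boundary.
#' For a [calibrated_image()] `sigma` is a physical length and is converted
#' internally as `sigma / pixel_size`; for a bare matrix it is in pixels.
#'
#' @param img A [calibrated_image()] or numeric matrix.
#' @param sigma Gaussian standard deviation (> 0); physical units for
#'   calibrated images, pixels for matrices.
#' @return Smoothed image of the same class as the input. Total intensity
#'   is conserved up to boundary effects.
#' @export
gaussian_smooth <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  m <- as_pixels(img)
  k <- .gaussian_kernel_1d(.sigma_to_px(img, sigma))
  out <- t(.conv_sep(t(.conv_sep(m, k)), k))
  if (is_calibrated_image(img))
    calibrated_image(pmax(out, 0), img$pixel_size, img$modality)
  else out
}

#' Sobel gradient magnitude
#'
#' Per-pixel Euclidean magnitude of the horizontal and vertical 3x3 Sobel
#' responses, reflective boundary. A step of height h produces a magnitude
#' of 4h on the columns flanking the edge.
#'
#' @param img A [calibrated_image()] or matrix.
#' @return Gradient-magnitude image of the same class as the input.
#' @export
sobel_magnitude <- function(img) {
  m <- as_pixels(img)
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)      # column gradient
  gy <- t(gx)                                                # row gradient
  mag <- sqrt(.conv2_reflect(m, gx)^2 + .conv2_reflect(m, gy)^2)
  .keep_calibration(img, mag)
}

#' Laplacian-of-Gaussian ridge response
#'
#' Negated Laplacian of the Gaussian-smoothed image, so bright ridges and
#' spots map to positive values. The smoothing scale is in pixels (the
#' convention of the Laplacian plugin this mirrors).
#'
#' @param img A [calibrated_image()] or matrix.
#' @param smoothing_scale Gaussian sigma in pixels (> 0).
#' @return Response matrix (negative values allowed), always a plain
#'   matrix in the intensity units of the input.
#' @export
log_ridge <- function(img, smoothing_scale = 1.5) {
  if (smoothing_scale <= 0) stop("`smoothing_scale` must be positive")
  m <- as_pixels(img)
  k <- .gaussian_kernel_1d(smoothing_scale)
  sm <- t(.conv_sep(t(.conv_sep(m, k)), k))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  -.conv2_reflect(sm, lap)
}

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' spanning the image intensity range. Pixels strictly above the returned
#' value form the foreground class.
#'
#' @param img A [calibrated_image()] or matrix with at least two distinct
#'   values.
#' @return A single threshold intensity, strictly inside the intensity
#'   range.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(as_pixels(img))
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("constant image has no Otsu threshold")
  nb <- 256L
  bin <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  h <- as.numeric(tabulate(bin, nbins = nb))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nb))
  n <- w[nb]; mu_t <- mu[nb]
  k <- seq_len(nb - 1L)
  num <- (mu_t * w[k] - mu[k] * n)^2
  den <- as.double(w[k]) * (n - w[k])
  bcv <- ifelse(den > 0, num / den, -Inf)
  kstar <- mean(which(bcv == max(bcv)))          # ImageJ-style tie averaging
  lo + kstar / nb * (hi - lo)
}

#' Despeckle (3x3 median filter)
#'
#' @param img A [calibrated_image()] or matrix.
#' @return Median-filtered image, reflective boundary, same class as the
#'   input.
#' @export
despeckle <- function(img) {
  m <- as_pixels(img)
  p <- .pad_reflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  cols <- vector("list", 9L)
  idx <- 1L
  for (i in 0:2) for (j in 0:2) {
    cols[[idx]] <- as.vector(p[(1L + i):(nr + i), (1L + j):(nc + j)])
    idx <- idx + 1L
  }
  # vectorized 9-element median: bubble the stack with pmin/pmax
  for (a in 1:8) for (b in seq.int(9L, a + 1L)) {
    lo <- pmin(cols[[b - 1L]], cols[[b]])
    cols[[b]] <- pmax(cols[[b - 1L]], cols[[b]])
    cols[[b - 1L]] <- lo
  }
  .keep_calibration(img, matrix(cols[[5L]], nr, nc))
}

#' Label connected components (8-connected)
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 = background, components numbered from 1 in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask) {
  mask <- .as_mask(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  id <- match(seq_len(length(mask)), fg)      # pixel index -> vertex id
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1L]; c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    b <- r2[ok] + (c2[ok] - 1L) * nr
    in_fg <- mask[b]
    if (any(in_fg))
      edges <- c(edges, rbind(id[fg[ok][in_fg]], id[b[in_fg]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber in raster order of first occurrence
  comp <- match(comp, unique(comp))
  lab[fg] <- comp
  lab
}

.as_mask <- function(mask) {
  if (is.logical(mask) && is.matrix(mask)) return(mask)
  if (is.matrix(mask)) return(mask != 0)
  stop("`mask` must be a logical matrix")
}

#' Remove small connected components
#'
#' Keeps 8-connected components with at least `min_size` pixels, clearing
#' the rest (the size filter of particle-analysis tools).
#'
#' @param mask Logical matrix.
#' @param min_size Minimum component pixel count (>= 1).
#' @return Filtered logical matrix.
#' @export
filter_components <- function(mask, min_size = 20L) {
  if (min_size < 1) stop("`min_size` must be >= 1")
  mask <- .as_mask(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Close a region mask
#'
#' Dilation by a disc of the given radius, morphological closing and hole
#' filling; the output is always a superset of the input. Used to turn
#' detected edge pixels into enclosed regions.
#'
#' @param mask Logical matrix.
#' @param radius Disc radius in pixels (>= 1).
#' @return Closed logical matrix.
#' @export
close_region <- function(mask, radius = 5L) {
  if (radius < 1) stop("`radius` must be >= 1")
  mask <- .as_mask(mask)
  if (!any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  x <- EBImage::dilate(mask + 0, brush)
  x <- EBImage::closing(x, brush)
  x <- EBImage::fillHull(x)
  matrix(as.numeric(x) > 0, nrow(mask), ncol(mask)) | mask
}

#' Euclidean distance transform
#'
#' Distance from each foreground pixel to the nearest background pixel
#' center (0 on background).
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of distances in pixels.
#' @export
distance_transform <- function(mask) {
  mask <- .as_mask(mask)
  matrix(as.numeric(EBImage::distmap(mask + 0)), nrow(mask), ncol(mask))
}

#' Skeletonize a mask
#'
#' Topology-preserving thinning (Zhang-Suen) to 8-connected, 1-pixel-wide
#' curves. The skeleton is always a subset of the mask.
#'
#' @param mask Logical matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  m <- .as_mask(mask)
  if (!any(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- shift(m, -1L,  0L); p3 <- shift(m, -1L,  1L)
      p4 <- shift(m,  0L,  1L); p5 <- shift(m,  1L,  1L)
      p6 <- shift(m,  1L,  0L); p7 <- shift(m,  1L, -1L)
      p8 <- shift(m,  0L, -1L); p9 <- shift(m, -1L, -1L)
      bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      an <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
            (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- m & bn >= 2 & bn <= 6 & an == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bn >= 2 & bn <= 6 & an == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Prominence-based maxima detection
#'
#' Finds intensity maxima whose prominence over the highest saddle to any
#' higher region exceeds `noise_tolerance` (the semantics of the ImageJ
#' "Find Maxima" noise tolerance). Flooding proceeds from the brightest
#' pixel downward; when two basins meet, the basin with the lower peak is
#' accepted as a separate maximum only if its peak stands more than
#' `noise_tolerance` above the meeting level, otherwise it is absorbed.
#' An equal-valued summit plateau is reported at its centroid. A constant
#' image has no maxima.
#'
#' @param img A [calibrated_image()] or matrix.
#' @param noise_tolerance Minimum prominence, in intensity units (>= 0).
#' @return A `maxima_set`: list with `maxima` (a [point_set()] with per-point
#'   peak `intensity`, ordered by decreasing peak value) and
#'   `noise_tolerance`.
#' @export
find_maxima <- function(img, noise_tolerance) {
  if (!is.numeric(noise_tolerance) || noise_tolerance < 0)
    stop("`noise_tolerance` must be >= 0")
  m <- as_pixels(img)
  nr <- nrow(m); nc <- ncol(m)
  n <- length(m)
  ord <- order(m, decreasing = TRUE)
  rank <- integer(n); rank[ord] <- seq_len(n)

  parent <- seq_len(n)          # union-find over pixels (self = unassigned)
  assigned <- logical(n)
  peak_val <- numeric(n)        # indexed by root pixel
  pk_n <- numeric(n); pk_r <- numeric(n); pk_c <- numeric(n)  # summit plateau
  acc_r <- numeric(0); acc_c <- numeric(0); acc_v <- numeric(0)

  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }

  rows <- ((seq_len(n) - 1L) %% nr) + 1L
  cols <- ((seq_len(n) - 1L) %/% nr) + 1L
  for (p in ord) {
    r <- rows[p]; cc <- cols[p]; v <- m[p]
    roots <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; ccc <- cc + dc
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
      q <- rr + (ccc - 1L) * nr
      if (assigned[q]) roots <- c(roots, find(q))
    }
    roots <- unique(roots)
    assigned[p] <- TRUE
    if (length(roots) == 0L) {
      peak_val[p] <- v
      pk_n[p] <- 1; pk_r[p] <- r; pk_c[p] <- cc
      next
    }
    # attach to the root with the highest peak (stable: earliest on ties)
    best <- roots[which.max(peak_val[roots])]
    parent[p] <- best
    if (peak_val[best] == v) {   # extends the summit plateau
      pk_n[best] <- pk_n[best] + 1
      pk_r[best] <- pk_r[best] + r
      pk_c[best] <- pk_c[best] + cc
    }
    for (rt in setdiff(roots, best)) {
      # basins meet at level v; the lower-peaked basin dies here
      if (peak_val[rt] - v > noise_tolerance) {
        acc_r <- c(acc_r, pk_r[rt] / pk_n[rt])
        acc_c <- c(acc_c, pk_c[rt] / pk_n[rt])
        acc_v <- c(acc_v, peak_val[rt])
      } else if (peak_val[rt] == v && peak_val[best] == v) {
        # same summit plateau discovered twice: pool its pixels
        pk_n[best] <- pk_n[best] + pk_n[rt]
        pk_r[best] <- pk_r[best] + pk_r[rt]
        pk_c[best] <- pk_c[best] + pk_c[rt]
      }
      parent[rt] <- best
    }
  }
  # the last surviving basin holds the global maximum
  groot <- find(ord[1L])
  if (peak_val[groot] - min(m) > noise_tolerance) {
    acc_r <- c(acc_r, pk_r[groot] / pk_n[groot])
    acc_c <- c(acc_c, pk_c[groot] / pk_n[groot])
    acc_v <- c(acc_v, peak_val[groot])
  }
  o <- order(acc_v, decreasing = TRUE)
  structure(
    list(maxima = point_set(acc_r[o], acc_c[o], intensity = acc_v[o]),
         noise_tolerance = noise_tolerance),
    class = "maxima_set"
  )
}

#' @export
print.maxima_set <- function(x, ...) {
  cat(sprintf("<maxima_set> %d maxima (noise tolerance %.4g)\n",
              nrow(x$maxima), x$noise_tolerance))
  invisible(x)
}
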