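# Independent brute-force reference implementations used to validate the
# imaging primitives. Deliberately naive: per-pixel loops, direct
# definitions, no shared code with the package internals.

reflect1 <- function(i, n) {
  # half-sample reflection (edge repeated): 2 1 | 1 2 ... n | n n-1
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_conv2 <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (di in -kr:kr) for (dj in -kc:kc) {
      # convolution: kernel indexed with flipped offsets
      acc <- acc + kernel[kr + 1L - di, kc + 1L - dj] *
        m[reflect1(i + di, nrow(m)), reflect1(j + dj, ncol(m))]
    }
    out[i, j] <- acc
  }
  out
}

oracle_gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

oracle_median3 <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- numeric(9)
    idx <- 1L
    for (di in -1:1) for (dj in -1:1) {
      v[idx] <- m[reflect1(i + di, nrow(m)), reflect1(j + dj, ncol(m))]
      idx <- idx + 1L
    }
    out[i, j] <- stats::median(v)
  }
  out
}

oracle_otsu <- function(v) {
  lo <- min(v); hi <- max(v)
  nb <- 256L
  bin <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  best <- -Inf; best_k <- integer(0)
  for (k in seq_len(nb - 1L)) {
    g1 <- v[bin <= k]; g2 <- v[bin > k]
    if (length(g1) == 0L || length(g2) == 0L) next
    # between-class variance computed from raw class means of BIN INDICES
    m1 <- mean(bin[bin <= k]); m2 <- mean(bin[bin > k])
    w1 <- length(g1) / length(v); w2 <- 1 - w1
    bcv <- w1 * w2 * (m1 - m2)^2
    if (bcv > best + 1e-12) { best <- bcv; best_k <- k }
    else if (abs(bcv - best) <= 1e-12) best_k <- c(best_k, k)
  }
  lo + mean(best_k) / nb * (hi - lo)
}

oracle_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[1L]; queue <- queue[-1L]
      pi <- (p - 1L) %% nrow(mask) + 1L
      pj <- (p - 1L) %/% nrow(mask) + 1L
      for (di in -1:1) for (dj in -1:1) {
        qi <- pi + di; qj <- pj + dj
        if (qi < 1L || qi > nrow(mask) || qj < 1L || qj > ncol(mask)) next
        if (mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- cur
          queue <- c(queue, qi + (qj - 1L) * nrow(mask))
        }
      }
    }
  }
  lab
}

# Prominence-based maxima by exhaustive bottleneck-path search: a summit
# plateau is a connected set of equal values with no higher neighbor; its
# saddle to higher ground is the best (highest-minimum) path to any
# strictly higher pixel, found by widest-path Dijkstra. Accepted iff
# prominence > tol (global summit: relative to the image minimum).
oracle_maxima <- function(m, tol) {
  nr <- nrow(m); nc <- ncol(m)
  neigh <- function(i, j) {
    out <- NULL
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      qi <- i + di; qj <- j + dj
      if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc)
        out <- rbind(out, c(qi, qj))
    }
    out
  }
  plateau_lab <- oracle_label_plateaus(m)
  summits <- NULL
  for (pl in seq_len(max(plateau_lab))) {
    cells <- which(plateau_lab == pl, arr.ind = TRUE)
    v <- m[cells[1L, 1L], cells[1L, 2L]]
    higher <- FALSE
    for (r in seq_len(nrow(cells))) {
      nb <- neigh(cells[r, 1L], cells[r, 2L])
      if (any(m[nb] > v)) { higher <- TRUE; break }
    }
    if (!higher) summits <- c(summits, pl)
  }
  out_r <- numeric(0); out_c <- numeric(0); out_v <- numeric(0)
  for (pl in summits) {
    cells <- which(plateau_lab == pl, arr.ind = TRUE)
    v <- m[cells[1L, 1L], cells[1L, 2L]]
    if (!any(m > v)) {                          # global summit plateau
      prom <- v - min(m)
    } else {
      # widest path to strictly higher ground
      best <- matrix(-Inf, nr, nc)
      best[cells] <- v
      frontier <- cells
      saddle <- -Inf
      while (nrow(frontier) > 0) {
        nf <- NULL
        for (r in seq_len(nrow(frontier))) {
          i <- frontier[r, 1L]; j <- frontier[r, 2L]
          nb <- neigh(i, j)
          for (rr in seq_len(nrow(nb))) {
            qi <- nb[rr, 1L]; qj <- nb[rr, 2L]
            cand <- min(best[i, j], m[qi, qj])
            if (m[qi, qj] > v) {
              saddle <- max(saddle, min(best[i, j], v))
              next
            }
            if (cand > best[qi, qj]) {
              best[qi, qj] <- cand
              nf <- rbind(nf, c(qi, qj))
            }
          }
        }
        frontier <- if (is.null(nf)) matrix(0, 0, 2) else unique(nf)
      }
      prom <- v - saddle
    }
    if (prom > tol) {
      out_r <- c(out_r, mean(cells[, 1L]))
      out_c <- c(out_c, mean(cells[, 2L]))
      out_v <- c(out_v, v)
    }
  }
  o <- order(out_v, decreasing = TRUE)
  data.frame(row = out_r[o], col = out_c[o], value = out_v[o])
}

oracle_label_plateaus <- function(m) {
  # connected components of equal value (8-connected)
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (start in seq_along(m)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    v <- m[start]
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[1L]; queue <- queue[-1L]
      pi <- (p - 1L) %% nrow(m) + 1L
      pj <- (p - 1L) %/% nrow(m) + 1L
      for (di in -1:1) for (dj in -1:1) {
        qi <- pi + di; qj <- pj + dj
        if (qi < 1L || qi > nrow(m) || qj < 1L || qj > ncol(m)) next
        if (m[qi, qj] == v && lab[qi, qj] == 0L) {
          lab[qi, qj] <- cur
          queue <- c(queue, qi + (qj - 1L) * nrow(m))
        }
      }
    }
  }
  lab
}

oracle_msd <- function(x, max_lag) {
  # plain double loop over (start, lag) pairs
  n <- length(x)
  lags <- seq_len(max_lag)
  msd <- numeric(length(lags))
  npairs <- integer(length(lags))
  for (L in lags) {
    acc <- 0; cnt <- 0L
    for (t in seq_len(n - L)) {
      acc <- acc + (x[t + L] - x[t])^2
      cnt <- cnt + 1L
    }
    msd[L] <- acc / cnt
    npairs[L] <- cnt
  }
  list(msd = msd, n_pairs = npairs)
}

# deterministic small random images: smooth noise so plateaus are rare
random_image <- function(seed, nr = 16L, nc = 16L, smooth = TRUE) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(nr * nc, 0, 1000), nr, nc)
    if (smooth) m <- gaussian_smooth(m, 1.2)
    m
  })
}

random_mask <- function(seed, nr = 24L, nc = 24L, p = 0.35) {
  withr::with_seed(seed, matrix(stats::runif(nr * nc) < p, nr, nc))
}
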