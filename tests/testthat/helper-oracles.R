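# Independent reference implementations used as oracles.  These are written
# as literal pixel-enumeration loops, deliberately sharing no code with the
# package internals they check.

random_mask <- function(n, p, seed) {
  set.seed(seed)
  matrix(rbinom(n * n, 1, p), n, n) + 0
}

# brute-force per-pixel metric computation by explicit enumeration
oracle_score <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    a <- pred[i, j]; b <- ref[i, j]
    if (a == 1 && b == 1) tp <- tp + 1L
    else if (a == 1 && b == 0) fp <- fp + 1L
    else if (a == 0 && b == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  total <- tp + fp + fn + tn
  accuracy <- (tp + tn) / total
  overlap <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  precision <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { if (fp == 0) 1 else 0 } else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, tn = tn, accuracy = accuracy,
       overlap = overlap, precision = precision, recall = recall, f_measure = f)
}

# exhaustive-search Otsu: evaluate the between-class variance of every one of
# the 256 candidate split levels directly from the pixel values
oracle_otsu <- function(image) {
  lev <- as.integer(round(image * 255))
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- lev[lev <= t]; hi <- lev[lev > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(lev); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# naive loop-based Canny with the same operator definitions the package
# documents: Gaussian blur (truncated at 3 sigma, reflected boundary), 3x3
# Sobel, 4-sector non-maximum suppression (keep if mag > forward neighbor and
# mag >= backward neighbor), double threshold, 8-connected hysteresis
oracle_canny <- function(img, sigma = 1.0, low = 0.1, high = 0.2) {
  n1 <- nrow(img); n2 <- ncol(img)
  refl <- function(i, n) { i <- abs(i - 1L) + 1L; n - abs(n - i) }
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  sm <- matrix(0, n1, n2)
  tmp <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    s <- 0
    for (d in -r:r) s <- s + img[refl(i + d, n1), j] * k1[d + r + 1L]
    tmp[i, j] <- s
  }
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    s <- 0
    for (d in -r:r) s <- s + tmp[i, refl(j + d, n2)] * k1[d + r + 1L]
    sm[i, j] <- s
  }
  gx <- matrix(0, n1, n2); gy <- matrix(0, n1, n2)
  sob_d <- c(-1, 0, 1); sob_s <- c(1, 2, 1)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    sx <- 0; sy <- 0
    for (a in 1:3) for (b in 1:3) {
      v <- sm[refl(i + a - 2L, n1), refl(j + b - 2L, n2)]
      sx <- sx + v * sob_d[a] * sob_s[b]
      sy <- sy + v * sob_s[a] * sob_d[b]
    }
    gx[i, j] <- sx; gy[i, j] <- sy
  }
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0, n1, n2))
  offs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  keep <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    a <- atan2(gy[i, j], gx[i, j]); if (a < 0) a <- a + pi
    s <- floor((a + pi / 8) / (pi / 4)) %% 4
    d <- offs[[s + 1L]]
    nb <- function(di, dj) {
      ii <- min(max(i + di, 1L), n1); jj <- min(max(j + dj, 1L), n2)
      mag[ii, jj]
    }
    keep[i, j] <- mag[i, j] > nb(d[1], d[2]) && mag[i, j] >= nb(-d[1], -d[2])
  }
  strong <- keep & mag >= high * mmax
  weak <- keep & mag >= low * mmax & !strong
  lab <- matrix(0L, n1, n2); lab[weak] <- 1L; lab[strong] <- 2L
  repeat {
    changed <- FALSE
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      if (lab[i, j] != 1L) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2 && lab[ii, jj] == 2L) {
          lab[i, j] <- 2L; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  (lab == 2L) + 0
}

# small phantom parameter sets used across tests
tiny_params <- function(size = 32L, ...)
  segtrans::phantom_params(image_size = size, ...)

clean_params <- function(size = 32L)
  segtrans::phantom_params(image_size = size, noise_sd = 0,
                           nodule_count_range = c(0L, 0L), vessel_density = 0,
                           blur_sigma = 0)

# finite-difference gradient comparison helper
expect_grad_match <- function(analytic, numeric, tol = 1e-5) {
  testthat::expect_lt(abs(analytic - numeric), tol * (1 + abs(numeric)))
}
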