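# Fixture builders and brute-force oracles used across the suite.

two_level_image <- function(n = 32, lo = 40, hi = 200, frac_hi = 0.5,
                            extent_mm = 3, slab_kind = "SCP", seed = 1) {
  set.seed(seed)
  px <- matrix(lo, n, n)
  px[sample.int(n^2, round(frac_hi * n^2))] <- hi
  enface_image(px, extent_mm = extent_mm, slab_kind = slab_kind)
}

random_image <- function(n = 32, extent_mm = 3, slab_kind = "CC", seed = 1) {
  set.seed(seed)
  enface_image(matrix(runif(n^2, 0, 255), n, n), extent_mm = extent_mm,
               slab_kind = slab_kind)
}

# Naive exhaustive Otsu: loop over all 256 candidate thresholds, computing
# class weights and means directly from the pixel vector.
otsu_brute <- function(v) {
  v <- as.integer(round(v))
  n <- length(v)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    lo <- v <= t
    w0 <- sum(lo) / n
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(v[lo])
    mu1 <- mean(v[!lo])
    s <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (s > best + 1e-12) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

# Direct normalized cross-correlation over all integer shifts in [-m, m]^2,
# evaluated by explicit overlap subsetting (independent of the FFT path).
ncc_direct <- function(a, b, m) {
  out <- matrix(NA_real_, 2 * m + 1, 2 * m + 1)
  nr <- nrow(a); nc <- ncol(a)
  for (dy in -m:m) {
    for (dx in -m:m) {
      rows <- max(1, 1 - dy):min(nr, nr - dy)
      cols <- max(1, 1 - dx):min(nc, nc - dx)
      x <- as.numeric(a[rows, cols])
      y <- as.numeric(b[rows + dy, cols + dx])
      if (stats::sd(x) < 1e-9 || stats::sd(y) < 1e-9) next
      out[dy + m + 1, dx + m + 1] <- stats::cor(x, y)
    }
  }
  out
}

# Two-way ANOVA sums of squares written out from first principles.
icc31_oracle <- function(m1, m2) {
  n <- length(m1)
  k <- 2
  y <- cbind(m1, m2)
  grand <- mean(y)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_occ <- n * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_occ
  bms <- ss_subj / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}
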