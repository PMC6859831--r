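# Internal helpers shared across modules.

# Derive a child RNG seed from a base seed and a set of integer indices.
# Multiplicative-congruential mixing keeps everything inside 32-bit range
# (intermediate products stay below 2^53, exact in doubles).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 48271 + (as.double(idx[k]) + 1) * 69621) %% 2147483647
  }
  as.integer(h)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Shift a matrix by dx columns (rightwards) and dy rows (downwards);
# vacated cells take `fill`.  out[r, c] = m[r - dy, c - dx].
translate_matrix <- function(m, dx, dy, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  }
  out
}

# Gaussian blur by circular FFT convolution (adequate for stationary noise
# fields; wrap-around is immaterial there).
gauss_blur <- function(m, sigma) {
  nr <- nrow(m)
  nc <- ncol(m)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  gr <- exp(-2 * pi^2 * sigma^2 * fr^2)
  gc <- exp(-2 * pi^2 * sigma^2 * fc^2)
  ker <- outer(gr, gc)
  Re(stats::fft(stats::fft(m) * ker, inverse = TRUE)) / (nr * nc)
}

# Binary dilation with a disc structuring element of radius r (pixels).
dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    out <- out | translate_matrix(mask, off$dx[k], off$dy[k], fill = FALSE)
  }
  out
}

erode_disc <- function(mask, r) !dilate_disc(!mask, r)

# Morphological closing (dilate then erode) with a disc of radius r.
close_disc <- function(mask, r) erode_disc(dilate_disc(mask, r), r)

# 4-connected flood fill over the complement of `blocked`, starting from
# seed = c(row, col).  Returns the filled logical mask.
flood_fill4 <- function(blocked, seed) {
  stopifnot(length(seed) == 2)
  if (blocked[seed[1], seed[2]]) {
    stop("flood fill seed lies on a blocked pixel", call. = FALSE)
  }
  filled <- matrix(FALSE, nrow(blocked), ncol(blocked))
  filled[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- translate_matrix(filled, 1, 0, FALSE) |
      translate_matrix(filled, -1, 0, FALSE) |
      translate_matrix(filled, 0, 1, FALSE) |
      translate_matrix(filled, 0, -1, FALSE)
    new <- grown & !blocked & !filled
    if (!any(new)) break
    filled <- filled | new
  }
  filled
}

`%||%` <- function(a, b) if (is.null(a)) b else a
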