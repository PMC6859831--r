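#' Binarize a superficial-plexus slab for artifact overlay
#'
#' The superficial capillary plexus slab is binarized (Otsu global threshold,
#' brighter class = vessel) so that it can be overlaid on the choriocapillaris
#' slab to locate projection artifacts.
#'
#' @param scp a standardized SCP [enface_image()].
#' @return Logical vessel mask.
#' @export
binarize_scp_for_overlay <- function(scp) {
  binarize_otsu(scp)
}

#' Suppress projection artifacts in a choriocapillaris slab
#'
#' Pixels under the superficial-vessel overlay carry decorrelation shadows
#' that read as spurious flow deficits.  Their intensities are raised by a
#' linear rescale chosen so the mean over artifact pixels equals the mean
#' over non-artifact pixels; non-artifact pixels are untouched.  If the
#' artifact region has zero mean the correction degenerates to an additive
#' shift.  An all-true or all-false mask leaves the image unchanged with a
#' warning.
#'
#' @param cc choriocapillaris [enface_image()] (standardized).
#' @param scp_mask logical overlay mask from [binarize_scp_for_overlay()],
#'   same dimensions.
#' @return The corrected [enface_image()], clipped to [0, 255].
#' @export
remove_projection_artifacts <- function(cc, scp_mask) {
  stopifnot(inherits(cc, "enface_image"))
  px <- cc$pixels
  if (!all(dim(px) == dim(scp_mask))) {
    stop("choriocapillaris slab and overlay mask dimensions differ", call. = FALSE)
  }
  n_in <- sum(scp_mask)
  if (n_in == 0 || n_in == length(scp_mask)) {
    warning("overlay mask selects no or all pixels; image returned unchanged")
    return(cc)
  }
  m_in <- mean(px[scp_mask])
  m_out <- mean(px[!scp_mask])
  out <- px
  if (m_in > 1e-9) {
    out[scp_mask] <- px[scp_mask] * (m_out / m_in)
  } else {
    out[scp_mask] <- px[scp_mask] + m_out
  }
  new_enface(clip255(out), cc$mm_per_px, cc$slab_kind)
}

# Full cross-correlation sums over the shift window via zero-padded FFTs:
# out[dy, dx] = sum_{r,c in overlap} a[r, c] * b[r + dy, c + dx].
xcorr_window <- function(a, b, m) {
  P <- nrow(a) + m
  Q <- ncol(a) + m
  A <- matrix(0, P, Q); A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  B <- matrix(0, P, Q); B[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  C <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / (P * Q)
  lag_index <- function(l, n) ifelse(l >= 0, l + 1, n + l + 1)
  C[lag_index(-m:m, P), lag_index(-m:m, Q), drop = FALSE]
}

#' Estimate the inter-scan translation between two slabs
#'
#' Exhaustive search over integer shifts within `+/- max_shift_px` for the
#' offset maximizing the normalized cross-correlation over the overlap
#' region (translation only; same-visit scans without repositioning need no
#' rotation or scaling).  Ties are broken by the smallest `|dx| + |dy|`, then
#' lexicographically by `(dx, dy)`.  Shifts whose overlap is intensity-flat
#' are excluded; if every shift is flat (e.g. constant images) the zero
#' offset is returned.
#'
#' The returned offset satisfies `img1[r, c] ~ img2[r + dy, c + dx]` over the
#' overlap, i.e. `(dx, dy)` is the displacement of scan 2's content relative
#' to scan 1.
#'
#' @param img1,img2 [enface_image()]s (or matrices) of equal dimensions.
#' @param max_shift_px maximum shift magnitude searched; defaults to a tenth
#'   of the image side.
#' @return Named integer vector `c(dx, dy)`.
#' @export
register_translation <- function(img1, img2, max_shift_px = NULL) {
  x <- as_pixels(img1)
  y <- as_pixels(img2)
  if (!all(dim(x) == dim(y))) stop("images must share dimensions", call. = FALSE)
  m <- as.integer(max_shift_px %||% floor(nrow(x) / 10))
  if (m < 0) stop("max_shift_px must be non-negative", call. = FALSE)
  if (m == 0) return(c(dx = 0L, dy = 0L))
  ones <- matrix(1, nrow(x), ncol(x))
  N <- round(xcorr_window(ones, ones, m))
  Sx <- xcorr_window(x, ones, m)
  Sy <- xcorr_window(ones, y, m)
  Sxx <- xcorr_window(x * x, ones, m)
  Syy <- xcorr_window(ones, y * y, m)
  Sxy <- xcorr_window(x, y, m)
  vx <- Sxx - Sx^2 / N
  vy <- Syy - Sy^2 / N
  cv <- Sxy - Sx * Sy / N
  ncc <- matrix(NA_real_, nrow(N), ncol(N))
  ok <- vx > 1e-6 * N & vy > 1e-6 * N
  ncc[ok] <- cv[ok] / sqrt(vx[ok] * vy[ok])
  if (all(is.na(ncc))) return(c(dx = 0L, dy = 0L))   # flat images: all shifts tie
  best <- max(ncc, na.rm = TRUE)
  cand <- which(!is.na(ncc) & ncc >= best - 1e-9, arr.ind = TRUE)
  dy <- cand[, 1] - (m + 1L)
  dx <- cand[, 2] - (m + 1L)
  pick <- order(abs(dx) + abs(dy), dx, dy)[1]
  dx <- dx[pick]; dy <- dy[pick]
  if (N[dy + m + 1L, dx + m + 1L] < 0.25 * length(x)) {
    stop("alignment failure: best-shift overlap below 25% of the image", call. = FALSE)
  }
  c(dx = as.integer(dx), dy = as.integer(dy))
}

#' Crop two slabs to their overlapping area
#'
#' Given the offset from [register_translation()], both images are cropped to
#' the common physical region so that corresponding pixels sample the same
#' location.  Output dimensions are `(n_rows - |dy|) x (n_cols - |dx|)`.
#'
#' @param img1,img2 [enface_image()]s of equal dimensions.
#' @param offset named or positional vector `c(dx, dy)`.
#' @return A list of class `aligned_pair` with fields `image1`, `image2`,
#'   `offset_px` and `analyzed_area_mm2`.
#' @export
crop_to_overlap <- function(img1, img2, offset) {
  stopifnot(inherits(img1, "enface_image"), inherits(img2, "enface_image"))
  dx <- as.integer(offset[["dx"]] %||% offset[1])
  dy <- as.integer(offset[["dy"]] %||% offset[2])
  a <- img1$pixels
  b <- img2$pixels
  if (!all(dim(a) == dim(b))) stop("images must share dimensions", call. = FALSE)
  if (abs(dx) >= ncol(a) || abs(dy) >= nrow(a)) stop("empty overlap", call. = FALSE)
  rows <- max(1, 1 - dy):min(nrow(a), nrow(a) - dy)
  cols <- max(1, 1 - dx):min(ncol(a), ncol(a) - dx)
  c1 <- a[rows, cols, drop = FALSE]
  c2 <- b[rows + dy, cols + dx, drop = FALSE]
  i1 <- new_enface(c1, img1$mm_per_px, img1$slab_kind)
  i2 <- new_enface(c2, img2$mm_per_px, img2$slab_kind)
  structure(
    list(image1 = i1, image2 = i2, offset_px = c(dx = dx, dy = dy),
         analyzed_area_mm2 = length(c1) * img1$mm_per_px^2),
    class = "aligned_pair"
  )
}

#' Flow-deficit intensity threshold from the avascular slab
#'
#' The flow-void threshold is T = A_p + 1.96 * S_d, where A_p is the mean
#' pixel intensity of the avascular outer-retina slab and S_d the standard
#' deviation over its pixels (population form, fixed for bit
#' reproducibility).
#'
#' @param avascular standardized avascular [enface_image()] (or matrix).
#' @return Threshold intensity T.
#' @export
flow_void_threshold <- function(avascular) {
  px <- as.numeric(as_pixels(avascular))
  mu <- mean(px)
  sd_pop <- sqrt(mean((px - mu)^2))
  mu + 1.96 * sd_pop
}

#' Measure total flow-void area at a threshold
#'
#' Pixels with intensity at or below the threshold (inclusive) are flow
#' void; their summed area is the total flow void with no minimum-region
#' filtering.
#'
#' @param cc standardized, artifact-corrected, cropped choriocapillaris
#'   [enface_image()].
#' @param threshold_T intensity threshold from [flow_void_threshold()].
#' @param mm_per_px pixel pitch override; defaults to the image's own.
#' @return A list of class `flow_void_result` with fields `threshold_T`,
#'   `void_mask`, `void_area_mm2`, `analyzed_area_mm2`.
#' @export
measure_flow_void <- function(cc, threshold_T, mm_per_px = NULL) {
  px <- as_pixels(cc)
  mpp <- mm_per_px %||% if (inherits(cc, "enface_image")) cc$mm_per_px else
    stop("mm_per_px required for plain matrices", call. = FALSE)
  mask <- px <= threshold_T
  structure(
    list(threshold_T = threshold_T, void_mask = mask,
         void_area_mm2 = sum(mask) * mpp^2,
         analyzed_area_mm2 = length(px) * mpp^2),
    class = "flow_void_result"
  )
}

#' @export
print.flow_void_result <- function(x, ...) {
  cat(sprintf(
    "<flow_void_result> T = %.2f, flow void %.3f mm2 of %.3f mm2 analyzed\n",
    x$threshold_T, x$void_area_mm2, x$analyzed_area_mm2
  ))
  invisible(x)
}

#' Choriocapillaris flow-void pipeline for an intravisit pair
#'
#' Runs the full 6 x 6 mm chain on two same-visit scans: contrast
#' standardization of every slab, SCP binarization, projection-artifact
#' suppression on each CC slab with its own SCP overlay, translation
#' registration of the corrected CC slabs, cropping of CC and avascular
#' slabs to the overlap, per-scan flow-void threshold from the cropped
#' avascular slab, and flow-void measurement.  Both results share the same
#' analyzed area.
#'
#' @param scan1,scan2 [scan_record()]s containing `CC`, `SCP` and `avascular`
#'   slabs.
#' @param max_shift_px registration search radius (default image side / 10).
#' @param artifact_removal set `FALSE` to ablate the overlay correction.
#' @return A list of class `ccfv_pair_result` with fields `result1`,
#'   `result2` ([measure_flow_void()] outputs) and `offset_px`.
#' @export
ccfv_pipeline <- function(scan1, scan2, max_shift_px = NULL, artifact_removal = TRUE) {
  stopifnot(inherits(scan1, "scan_record"), inherits(scan2, "scan_record"))
  for (s in list(scan1, scan2)) {
    if (!all(c("CC", "SCP", "avascular") %in% names(s$slabs))) {
      stop("both scans need CC, SCP and avascular slabs", call. = FALSE)
    }
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("ccfv stage '%s' failed: %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  cc1 <- stage("standardize", contrast_stretch(scan1$slabs$CC))
  cc2 <- stage("standardize", contrast_stretch(scan2$slabs$CC))
  av1 <- stage("standardize", contrast_stretch(scan1$slabs$avascular))
  av2 <- stage("standardize", contrast_stretch(scan2$slabs$avascular))
  if (artifact_removal) {
    m1 <- stage("scp_binarize", binarize_scp_for_overlay(contrast_stretch(scan1$slabs$SCP)))
    m2 <- stage("scp_binarize", binarize_scp_for_overlay(contrast_stretch(scan2$slabs$SCP)))
    cc1 <- stage("artifact_removal", remove_projection_artifacts(cc1, m1))
    cc2 <- stage("artifact_removal", remove_projection_artifacts(cc2, m2))
  }
  offset <- stage("register", register_translation(cc1, cc2, max_shift_px))
  cc_pair <- stage("crop", crop_to_overlap(cc1, cc2, offset))
  av_pair <- stage("crop", crop_to_overlap(av1, av2, offset))
  T1 <- stage("threshold", flow_void_threshold(av_pair$image1))
  T2 <- stage("threshold", flow_void_threshold(av_pair$image2))
  r1 <- stage("measure", measure_flow_void(cc_pair$image1, T1))
  r2 <- stage("measure", measure_flow_void(cc_pair$image2, T2))
  structure(list(result1 = r1, result2 = r2, offset_px = offset),
            class = "ccfv_pair_result")
}

#' @export
print.ccfv_pair_result <- function(x, ...) {
  cat(sprintf(
    "<ccfv_pair_result> offset (%d, %d); flow void %.3f / %.3f mm2 of %.3f mm2\n",
    x$offset_px[["dx"]], x$offset_px[["dy"]],
    x$result1$void_area_mm2, x$result2$void_area_mm2,
    x$result1$analyzed_area_mm2
  ))
  invisible(x)
}
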