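#' Standardize slab brightness by reference-square contrast stretching
#'
#' Linearly rescales intensities so that the low/high percentiles of a central
#' reference square (half the image side, centered) map to 0 and 255, then
#' clips to the 8-bit range.  Using a central reference square makes the
#' mapping robust to dark field edges and vignetting, and puts repeat scans of
#' the same eye on a comparable intensity scale before thresholding.
#'
#' If the reference square has (numerically) zero intensity spread the image
#' is returned unchanged with a warning, since no meaningful stretch exists.
#'
#' @param image an [enface_image()].
#' @param p_lo,p_hi reference percentiles (defaults 0.01 and 0.99); percentile
#'   clipping guards the map against isolated extreme pixels.
#' @return The standardized [enface_image()] (same dimensions and metadata).
#' @export
contrast_stretch <- function(image, p_lo = 0.01, p_hi = 0.99) {
  stopifnot(inherits(image, "enface_image"))
  px <- image$pixels
  n <- nrow(px)
  if (n < 4 || ncol(px) < 4) stop("image too small to standardize", call. = FALSE)
  side_r <- max(2L, floor(n / 2))
  side_c <- max(2L, floor(ncol(px) / 2))
  r0 <- floor((n - side_r) / 2)
  c0 <- floor((ncol(px) - side_c) / 2)
  ref <- px[r0 + seq_len(side_r), c0 + seq_len(side_c)]
  q <- stats::quantile(ref, c(p_lo, p_hi), names = FALSE)
  if (q[2] - q[1] < 1e-9) {
    warning("degenerate standardization: reference square has no intensity spread; image returned unchanged")
    return(image)
  }
  a <- 255 / (q[2] - q[1])
  out <- clip255(a * (px - q[1]))
  new_enface(out, image$mm_per_px, image$slab_kind)
}

#' Horizontal motion-artifact severity score
#'
#' Motion during acquisition shows up as rows decorrelated from their
#' neighbours.  The score is the fraction of adjacent row pairs whose Pearson
#' correlation falls below `row_cor_cutoff`; 0 means no detected artifact.
#'
#' @param image an [enface_image()].
#' @param row_cor_cutoff correlation below which a row pair counts as
#'   decorrelated (default 0.2).
#' @return A score in [0, 1].
#' @export
motion_score <- function(image, row_cor_cutoff = 0.2) {
  px <- as_pixels(image)
  n <- nrow(px)
  if (n < 3) return(0)
  sds <- apply(px, 1, stats::sd)
  cors <- vapply(seq_len(n - 1), function(i) {
    if (sds[i] < 1e-12 || sds[i + 1] < 1e-12) return(1)
    stats::cor(px[i, ], px[i + 1, ])
  }, numeric(1))
  mean(cors < row_cor_cutoff)
}

#' Quality-control gate for a scan record
#'
#' Applies the cohort inclusion rules: scans with device signal strength
#' below 7/10 are excluded (`low_signal`), scans whose motion score exceeds
#' `motion_threshold` are excluded (`motion_artifact`), and scans carrying a
#' manual floater flag are excluded (`floater`).  Reasons may co-occur.
#'
#' @param record a [scan_record()].
#' @param motion_threshold maximum acceptable [motion_score()] (default 0.2).
#' @return A list of class `qc_decision` with fields `included` (logical) and
#'   `reasons` (character vector, empty iff included).
#' @export
qc_assess <- function(record, motion_threshold = 0.2) {
  stopifnot(inherits(record, "scan_record"))
  if (is.null(record$signal_strength) || is.na(record$signal_strength) ||
      is.null(record$motion_score) || is.na(record$motion_score)) {
    stop("record is missing signal_strength or motion_score", call. = FALSE)
  }
  reasons <- character(0)
  if (record$signal_strength < 7) reasons <- c(reasons, "low_signal")
  if (record$motion_score > motion_threshold) reasons <- c(reasons, "motion_artifact")
  if (isTRUE(record$floater)) reasons <- c(reasons, "floater")
  structure(list(included = length(reasons) == 0, reasons = reasons),
            class = "qc_decision")
}

#' Screen measurement differences against an image-quality metric
#'
#' Squared Pearson correlation between absolute paired-measurement
#' differences and a per-pair quality metric (e.g. mean signal strength or
#' amount of cropping).  Used to check whether scan quality drives
#' test-retest disagreement.
#'
#' @param abs_diffs absolute differences between paired measurements.
#' @param quality_metric per-pair quality values, same length.
#' @return r-squared in [0, 1].
#' @export
quality_difference_correlation <- function(abs_diffs, quality_metric) {
  if (length(abs_diffs) != length(quality_metric) || length(abs_diffs) < 3) {
    stop("need equal-length vectors with at least 3 entries", call. = FALSE)
  }
  if (stats::sd(abs_diffs) < 1e-12 || stats::sd(quality_metric) < 1e-12) {
    stop("zero variance in one of the inputs", call. = FALSE)
  }
  stats::cor(abs_diffs, quality_metric)^2
}
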