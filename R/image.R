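#' En-face OCTA slab image
#'
#' Container for one grayscale en-face angiography slab.  Pixel values are
#' held as real numbers on the 0--255 scale (stored 8-bit on disk); the
#' physical calibration is carried as millimetres per pixel so that cropped
#' (rectangular) views keep a valid area scale.
#'
#' @param pixels numeric matrix of intensities in [0, 255]; rows are image
#'   rows (y), columns are image columns (x).
#' @param extent_mm physical side length in mm of the (square) field of view,
#'   typically 3 or 6.
#' @param slab_kind one of `"SCP"`, `"DCP"`, `"avascular"`, `"CC"`.
#' @return An object of class `enface_image` with fields `pixels`,
#'   `mm_per_px` and `slab_kind`.
#' @export
enface_image <- function(pixels, extent_mm, slab_kind = c("SCP", "DCP", "avascular", "CC")) {
  slab_kind <- match.arg(slab_kind)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) {
    stop("en-face slabs are square; use crop helpers for rectangular views", call. = FALSE)
  }
  if (!is.numeric(extent_mm) || extent_mm <= 0) stop("extent_mm must be positive", call. = FALSE)
  if (any(pixels < -1e-9) || any(pixels > 255 + 1e-9)) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  new_enface(pixels, extent_mm / nrow(pixels), slab_kind)
}

# Internal constructor that permits rectangular (cropped) pixel grids.
new_enface <- function(pixels, mm_per_px, slab_kind) {
  structure(
    list(pixels = pixels, mm_per_px = mm_per_px, slab_kind = slab_kind),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf(
    "<enface_image> %s slab, %d x %d px, %.3f x %.3f mm\n",
    x$slab_kind, nrow(x$pixels), ncol(x$pixels),
    nrow(x$pixels) * x$mm_per_px, ncol(x$pixels) * x$mm_per_px
  ))
  invisible(x)
}

#' Physical area represented by an en-face image
#'
#' @param image an [enface_image()].
#' @return Area in mm^2 (pixel count times squared pixel pitch).
#' @export
image_area_mm2 <- function(image) {
  stopifnot(inherits(image, "enface_image"))
  length(image$pixels) * image$mm_per_px^2
}

as_pixels <- function(image) {
  if (inherits(image, "enface_image")) image$pixels else as.matrix(image)
}

#' Acquisition record for one OCTA scan
#'
#' Bundles the en-face slabs of a single acquisition with its metadata.
#' Two records with `scan_index` 1 and 2 from the same visit form an
#' intravisit pair.
#'
#' @param subject_id subject identifier.
#' @param slabs named list of [enface_image()] objects keyed by slab kind
#'   (e.g. `SCP`, `DCP`, `avascular`, `CC`).
#' @param scan_index 1 or 2 within the visit.
#' @param signal_strength device-reported quality score, integer 0--10.
#' @param motion_score non-negative motion-artifact severity (fraction of
#'   decorrelated adjacent row pairs; see [motion_score()]).
#' @param eye,visit_id free-form labels.
#' @param floater logical; manual flag for floater shadowing.
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(subject_id, slabs, scan_index = 1L, signal_strength = 10L,
                        motion_score = 0, eye = "OD", visit_id = "V1",
                        floater = FALSE) {
  if (!scan_index %in% c(1L, 2L)) stop("scan_index must be 1 or 2", call. = FALSE)
  if (signal_strength < 0 || signal_strength > 10) {
    stop("signal_strength must lie in [0, 10]", call. = FALSE)
  }
  if (motion_score < 0) stop("motion_score must be non-negative", call. = FALSE)
  stopifnot(is.list(slabs), length(slabs) >= 1)
  for (s in slabs) stopifnot(inherits(s, "enface_image"))
  structure(
    list(
      subject_id = as.character(subject_id), eye = eye, visit_id = visit_id,
      scan_index = as.integer(scan_index),
      signal_strength = as.numeric(signal_strength),
      motion_score = as.numeric(motion_score),
      floater = isTRUE(floater), slabs = slabs
    ),
    class = "scan_record"
  )
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf(
    "<scan_record> subject %s %s scan %d, signal %g/10, slabs: %s\n",
    x$subject_id, x$eye, x$scan_index, x$signal_strength,
    paste(names(x$slabs), collapse = ", ")
  ))
  invisible(x)
}

#' Read / write 8-bit grayscale slab images
#'
#' PNG round-trip for [enface_image()] objects.  Intensities are quantized to
#' 8 bits on write.
#'
#' @param path file path.
#' @param extent_mm,slab_kind calibration metadata to attach on read.
#' @param image an [enface_image()] to write.
#' @return `read_enface_png()` returns an [enface_image()];
#'   `write_enface_png()` returns `path` invisibly.
#' @export
read_enface_png <- function(path, extent_mm, slab_kind) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  enface_image(round(px * 255), extent_mm = extent_mm, slab_kind = slab_kind)
}

#' @rdname read_enface_png
#' @export
write_enface_png <- function(image, path) {
  stopifnot(inherits(image, "enface_image"))
  png::writePNG(round(image$pixels) / 255, target = path)
  invisible(path)
}
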