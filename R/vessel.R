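#' Otsu global binarization of an en-face slab
#'
#' Computes the 256-bin histogram of the (rounded) intensities and selects the
#' threshold maximizing the between-class variance; ties are broken towards
#' the lowest threshold.  The brighter class is labelled vessel (mask `TRUE`)
#' regardless of display polarity.
#'
#' @param image an [enface_image()] or numeric matrix; must not be constant.
#' @return Logical matrix, `TRUE` on vessel pixels, with the selected
#'   threshold attached as attribute `"threshold"`.
#' @export
binarize_otsu <- function(image) {
  px <- as_pixels(image)
  v <- as.integer(round(px))
  if (min(v) == max(v)) stop("cannot binarize a constant image", call. = FALSE)
  t_star <- otsu_threshold(v)
  mask <- matrix(v > t_star, nrow(px), ncol(px))
  attr(mask, "threshold") <- t_star
  mask
}

# Between-class-variance maximizing threshold over bins 0..255, computed with
# cumulative moments; first (lowest) maximizer wins.
otsu_threshold <- function(v) {
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- sum(counts)
  p <- counts / n
  omega <- cumsum(p)                    # class {<= t} weight, t = 0..255
  mu <- cumsum(p * (0:255))             # partial first moment
  mu_t <- mu[256]
  t_all <- 1:255                        # candidate thresholds t = 0..254
  w0 <- omega[t_all]
  num <- (mu_t * w0 - mu[t_all])^2
  den <- w0 * (1 - w0)
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  which.max(sigma_b) - 1L
}

#' Total vessel area
#'
#' Summation of all vessel pixels converted to physical area.
#'
#' @param mask logical vessel mask.
#' @param mm_per_px pixel pitch in mm.
#' @return Area in mm^2.
#' @export
total_vessel_area <- function(mask, mm_per_px) {
  sum(mask) * mm_per_px^2
}

#' Vessel density
#'
#' The ratio of total vessel area to the total analyzed image area,
#' VD = TVA / total area.
#'
#' @param tva_mm2 total vessel area in mm^2.
#' @param total_area_mm2 analyzed area in mm^2 (must be positive).
#' @return Dimensionless fraction in [0, 1].
#' @export
vessel_density <- function(tva_mm2, total_area_mm2) {
  if (total_area_mm2 <= 0) stop("total area must be positive", call. = FALSE)
  if (tva_mm2 < 0 || tva_mm2 > total_area_mm2 + 1e-9) {
    stop("vessel area must lie within [0, total area]", call. = FALSE)
  }
  tva_mm2 / total_area_mm2
}

#' FAZ delineation specifications
#'
#' `faz_manual()` describes an operator-traced simple polygon (vertices in
#' pixel coordinates, columns `x` then `y`); `faz_auto()` describes a seeded
#' automatic delineation that flood-fills the avascular region around a seed
#' point.
#'
#' @param polygon numeric matrix/data.frame with >= 3 rows and columns (x, y).
#' @param seed_point integer vector `c(x, y)` inside the grid, on a
#'   non-vessel pixel.
#' @return An object of class `faz_delineation`.
#' @export
faz_manual <- function(polygon) {
  polygon <- as.matrix(polygon)[, 1:2, drop = FALSE]
  if (nrow(polygon) >= 2 && all(polygon[1, ] == polygon[nrow(polygon), ])) {
    polygon <- polygon[-nrow(polygon), , drop = FALSE]   # drop explicit closure
  }
  if (nrow(polygon) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  if (!is_simple_polygon(polygon)) stop("polygon is self-intersecting", call. = FALSE)
  structure(list(mode = "manual_polygon", polygon = polygon), class = "faz_delineation")
}

#' @rdname faz_manual
#' @export
faz_auto <- function(seed_point) {
  stopifnot(length(seed_point) == 2)
  structure(list(mode = "seeded_auto", seed_point = as.integer(round(seed_point))),
            class = "faz_delineation")
}

# Segment-intersection test over non-adjacent polygon edges.
is_simple_polygon <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next   # adjacent edges share a vertex
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Foveal avascular zone area
#'
#' Manual mode evaluates the shoelace formula on the traced polygon.  Auto
#' mode closes the vessel mask with a disc (bridging small capillary gaps
#' that would let the fill leak), then 4-connected flood-fills the non-vessel
#' region from the seed and counts the filled pixels.
#'
#' @param mask logical vessel mask (used by auto mode).
#' @param delineation a [faz_manual()] or [faz_auto()] specification.
#' @param mm_per_px pixel pitch in mm.
#' @param closing_radius_px disc radius for the morphological closing applied
#'   before the fill (default 2).
#' @return FAZ area in mm^2.
#' @export
faz_area <- function(mask, delineation, mm_per_px, closing_radius_px = 2) {
  stopifnot(inherits(delineation, "faz_delineation"))
  if (delineation$mode == "manual_polygon") {
    p <- delineation$polygon
    n <- nrow(p)
    j <- c(2:n, 1)
    px_area <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
    return(px_area * mm_per_px^2)
  }
  closed <- close_disc(mask, closing_radius_px)
  seed <- delineation$seed_point     # (x, y) -> (row, col)
  if (seed[1] < 1 || seed[2] < 1 || seed[2] > nrow(mask) || seed[1] > ncol(mask)) {
    stop("seed point outside the image grid", call. = FALSE)
  }
  if (closed[seed[2], seed[1]]) {
    stop("seed point lies on a vessel pixel", call. = FALSE)
  }
  filled <- flood_fill4(closed, c(seed[2], seed[1]))
  sum(filled) * mm_per_px^2
}

#' Vessel-density and FAZ pipeline for a retinal plexus slab
#'
#' Runs the full 3 x 3 mm quantification chain on one slab of a scan:
#' contrast standardization, Otsu global binarization, total vessel area,
#' vessel density, and FAZ area.  Deep-plexus slabs are processed without
#' projection-artifact removal.
#'
#' @param scan a [scan_record()] containing the requested slab.
#' @param slab_kind `"SCP"` or `"DCP"`.
#' @param delineation a [faz_manual()] or [faz_auto()] specification; by
#'   default the FAZ is delineated automatically from the image center.
#' @param closing_radius_px passed to [faz_area()].
#' @return A list of class `vessel_result` with fields `vessel_mask`,
#'   `tva_mm2`, `vd_fraction`, `faz_area_mm2`, `total_area_mm2`.
#' @export
vessel_pipeline <- function(scan, slab_kind = c("SCP", "DCP"), delineation = NULL,
                            closing_radius_px = 2) {
  stopifnot(inherits(scan, "scan_record"))
  slab_kind <- match.arg(slab_kind)
  slab <- scan$slabs[[slab_kind]]
  if (is.null(slab)) stop(sprintf("scan has no %s slab", slab_kind), call. = FALSE)
  std <- contrast_stretch(slab)
  mask <- binarize_otsu(std)
  total <- image_area_mm2(std)
  tva <- total_vessel_area(mask, std$mm_per_px)
  vd <- vessel_density(tva, total)
  if (is.null(delineation)) {
    delineation <- faz_auto(c(ncol(mask) %/% 2, nrow(mask) %/% 2))
  }
  faz <- faz_area(mask, delineation, std$mm_per_px, closing_radius_px)
  structure(
    list(vessel_mask = mask, tva_mm2 = tva, vd_fraction = vd,
         faz_area_mm2 = faz, total_area_mm2 = total),
    class = "vessel_result"
  )
}

#' @export
print.vessel_result <- function(x, ...) {
  cat(sprintf(
    "<vessel_result> TVA %.3f mm2, VD %.3f, FAZ %.4f mm2 (of %.1f mm2)\n",
    x$tva_mm2, x$vd_fraction, x$faz_area_mm2, x$total_area_mm2
  ))
  invisible(x)
}
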