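# Synthetic en-face cohorts with known ground truth.
#
# The generators emulate the acquisition the quantification pipelines expect:
# paired same-visit scans of each subject, a vessel network with controllable
# density and a capillary-ring-bounded foveal avascular zone, choriocapillaris
# slabs with a controllable flow-deficit fraction and projection artifacts
# aligned to the superficial vessels, additive Gaussian pixel noise, and a
# small inter-scan translation.  Between-subject and within-subject standard
# deviations of the true index are configurable so the implied ICC,
# between^2 / (between^2 + within^2), is known exactly.

# Default scene intensity levels (0-255 scale).  Flow-bearing tissue renders
# bright, flow deficits dark; the avascular outer-retina slab is dark with a
# small bright residual-signal fraction so that its mean + 1.96 SD threshold
# falls between the deficit and perfused levels after standardization.
# Projection artifacts darken choriocapillaris pixels under superficial
# vessels deep enough to read as spurious flow deficits unless corrected.
.levels <- list(
  vessel = 200, background = 40,
  cc_flow = 200, cc_deficit = 40,
  avascular_base = 40, avascular_bright = 200, avascular_bright_fraction = 0.02,
  artifact_depth = 130
)

#' Configuration for a synthetic intravisit cohort
#'
#' @param n_subjects number of subjects (>= 2); each contributes one
#'   same-visit scan pair.
#' @param grid_px pixels per image side (>= 64; default 512).
#' @param extent_mm physical side length in mm (6 for choriocapillaris
#'   cohorts, 3 for vessel cohorts).
#' @param mean_index cohort mean of the true index (flow-void fraction or
#'   vessel-density fraction).
#' @param between_subject_sd SD of the true index across subjects (index
#'   units); its square is the between-subject variance component.
#' @param within_subject_sd SD of the per-scan measurement error (index
#'   units); its square is the measurement variance component.
#' @param noise_sd additive pixel-noise SD on the 0-255 intensity scale.
#' @param max_shift_px maximum inter-scan translation magnitude
#'   (< `grid_px / 4`).
#' @param slab_set `"cc"` for 6-mm choriocapillaris cohorts (CC + SCP +
#'   avascular slabs, index = flow-void fraction) or `"vessel"` for 3-mm
#'   plexus cohorts (SCP + DCP slabs, index = vessel-density fraction).
#' @param faz_radius_mm foveal avascular zone radius for vessel scenes.
#' @param seed integer RNG seed; all randomness derives from it through a
#'   per-subject/per-scan counter.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10, grid_px = 512, extent_mm = 6,
                          mean_index = if (slab_set == "cc") 0.2 else 0.3,
                          between_subject_sd = 0.05, within_subject_sd = 0.01,
                          noise_sd = 5, max_shift_px = 10,
                          slab_set = c("cc", "vessel"),
                          faz_radius_mm = 0.25, seed = 1) {
  slab_set <- match.arg(slab_set)
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  if (grid_px < 64) stop("grid_px must be at least 64", call. = FALSE)
  if (extent_mm <= 0) stop("extent_mm must be positive", call. = FALSE)
  if (between_subject_sd < 0 || within_subject_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (max_shift_px >= grid_px / 4) stop("max_shift_px must be below grid_px / 4", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), grid_px = as.integer(grid_px),
         extent_mm = extent_mm, mean_index = mean_index,
         between_subject_sd = between_subject_sd,
         within_subject_sd = within_subject_sd, noise_sd = noise_sd,
         max_shift_px = as.integer(max_shift_px), slab_set = slab_set,
         faz_radius_mm = faz_radius_mm, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic capillary network mask
#'
#' Thresholded band-pass (difference-of-Gaussians) spatial noise produces a
#' plausibly tortuous capillary texture whose vessel-pixel fraction is set by
#' rank thresholding, so the achieved density matches the target to within a
#' pixel.  The central foveal avascular zone is kept vessel-free and bounded
#' by a thin capillary ring (as the perifoveal arcade bounds the real FAZ),
#' which lets seeded flood-fill delineation recover its area.
#'
#' @param grid_px image side in pixels.
#' @param target_density desired vessel-pixel fraction in [0, 0.9]; 0 yields
#'   an empty mask.
#' @param faz_radius_mm avascular-zone radius (must be < `extent_mm / 2`).
#' @param extent_mm physical side length in mm.
#' @param seed RNG seed.
#' @return Logical vessel mask with attributes `faz_area_mm2` (disc area),
#'   `achieved_density` and `field` (the latent band-pass field, reused when
#'   perturbing density between scans).
#' @export
generate_vessel_network <- function(grid_px, target_density = 0.3,
                                    faz_radius_mm = 0.25, extent_mm = 3,
                                    seed = 1) {
  if (target_density < 0 || target_density > 0.9) {
    stop("target_density must lie in [0, 0.9]", call. = FALSE)
  }
  if (faz_radius_mm >= extent_mm / 2) {
    stop("faz_radius_mm must be below extent_mm / 2", call. = FALSE)
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(grid_px^2), grid_px, grid_px)
  # band-pass scales track physical vessel width but are floored so that
  # structures stay resolvable (>= ~2 px) on coarse grids
  field <- gauss_blur(z, max(1.2, grid_px / 340)) - gauss_blur(z, max(3.5, grid_px / 120))
  mm_per_px <- extent_mm / grid_px
  ctr <- (grid_px + 1) / 2
  d_mm <- sqrt(outer((seq_len(grid_px) - ctr)^2, (seq_len(grid_px) - ctr)^2, "+")) * mm_per_px
  disc <- d_mm <= faz_radius_mm
  ring <- d_mm > faz_radius_mm & d_mm <= faz_radius_mm + 2 * mm_per_px
  mask <- vessel_mask_from_field(field, target_density, disc, ring)
  attr(mask, "faz_area_mm2") <- pi * faz_radius_mm^2
  attr(mask, "achieved_density") <- mean(mask)
  attr(mask, "field") <- field
  attr(mask, "disc") <- disc
  attr(mask, "ring") <- ring
  mask
}

# Rank-threshold the latent field outside the avascular disc and its bounding
# ring so the total vessel count hits round(density * grid^2) exactly.
vessel_mask_from_field <- function(field, target_density, disc, ring) {
  n_total <- length(field)
  if (target_density == 0) return(matrix(FALSE, nrow(field), ncol(field)))
  n_target <- round(target_density * n_total)
  avail <- !disc & !ring
  k <- max(0L, n_target - sum(ring))
  k <- min(k, sum(avail))
  mask <- matrix(FALSE, nrow(field), ncol(field))
  if (k > 0) {
    vals <- field[avail]
    thr <- sort(vals, decreasing = TRUE)[k]
    sel <- avail & field >= thr
    # resolve ties so the count is exact
    extra <- sum(sel) - k
    if (extra > 0) {
      tie_idx <- which(sel & field == thr)
      sel[tie_idx[seq_len(extra)]] <- FALSE
    }
    mask <- sel
  }
  mask | ring
}

#' Render a vessel mask as a grayscale slab
#'
#' Vessel pixels are drawn at `vessel_level`, background at
#' `background_level`, with independent additive Gaussian noise of SD
#' `noise_sd`, clipped to [0, 255].
#'
#' @param vessel_mask logical mask.
#' @param vessel_level,background_level intensities with
#'   `0 <= background_level < vessel_level <= 255`.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed.
#' @param extent_mm,slab_kind calibration metadata for the returned image.
#' @return An [enface_image()].
#' @export
render_slab <- function(vessel_mask, vessel_level = 200, background_level = 40,
                        noise_sd = 5, seed = 1, extent_mm = 3, slab_kind = "SCP") {
  if (background_level < 0 || vessel_level > 255 || background_level >= vessel_level) {
    stop("need 0 <= background_level < vessel_level <= 255", call. = FALSE)
  }
  base <- matrix(background_level, nrow(vessel_mask), ncol(vessel_mask))
  base[vessel_mask] <- vessel_level
  set.seed(seed)
  if (noise_sd > 0) base <- base + stats::rnorm(length(base), 0, noise_sd)
  enface_image(clip255(base), extent_mm = extent_mm, slab_kind = slab_kind)
}

#' Generate a choriocapillaris slab with known flow-deficit ground truth
#'
#' A spatially correlated latent field is rank-thresholded to mark a known
#' pixel set (fraction `void_fraction`) as flow deficit at a dark level, with
#' the remaining pixels at the perfused level.  Pixels under the supplied
#' superficial-vessel mask are darkened by `artifact_depth` to simulate
#' projection artifacts; the recorded true void set predates artifact
#' injection.
#'
#' @param grid_px image side in pixels.
#' @param void_fraction true flow-deficit fraction in [0, 1].
#' @param scp_mask logical superficial-vessel mask (same dimensions) or
#'   `NULL` for no artifacts.
#' @param artifact_depth intensity decrement applied under `scp_mask`.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed.
#' @param extent_mm physical side length (default 6).
#' @return A list with `image` ([enface_image()]), `void_mask` (true deficit
#'   set) and `void_fraction` (realized, equal to the request to within one
#'   pixel).
#' @export
generate_cc_slab <- function(grid_px, void_fraction, scp_mask = NULL,
                             artifact_depth = 0, noise_sd = 5, seed = 1,
                             extent_mm = 6) {
  if (void_fraction < 0 || void_fraction > 1) {
    stop("void_fraction must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  field <- gauss_blur(matrix(stats::rnorm(grid_px^2), grid_px, grid_px),
                      max(1.5, grid_px / 256))
  void_mask <- void_mask_from_field(field, void_fraction)
  clean <- cc_clean_image(void_mask, scp_mask, artifact_depth)
  img <- clean
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  list(
    image = enface_image(clip255(img), extent_mm = extent_mm, slab_kind = "CC"),
    void_mask = void_mask,
    void_fraction = mean(void_mask)
  )
}

# Mark the lowest-ranked round(f * n) field pixels as flow deficit.
void_mask_from_field <- function(field, void_fraction) {
  n_void <- round(void_fraction * length(field))
  mask <- matrix(FALSE, nrow(field), ncol(field))
  if (n_void > 0) mask[order(field)[seq_len(n_void)]] <- TRUE
  mask
}

cc_clean_image <- function(void_mask, scp_mask, artifact_depth) {
  img <- matrix(.levels$cc_flow, nrow(void_mask), ncol(void_mask))
  img[void_mask] <- .levels$cc_deficit
  if (!is.null(scp_mask) && artifact_depth > 0) {
    if (!all(dim(scp_mask) == dim(void_mask))) stop("mask dimensions differ", call. = FALSE)
    img[scp_mask] <- img[scp_mask] - artifact_depth
  }
  pmax(img, 0)
}

# Dark avascular outer-retina slab with a small bright residual-signal
# fraction; drives the flow-void threshold.
avascular_clean_image <- function(grid_px, seed) {
  set.seed(seed)
  img <- matrix(.levels$avascular_base, grid_px, grid_px)
  n_bright <- round(.levels$avascular_bright_fraction * grid_px^2)
  img[sample.int(grid_px^2, n_bright)] <- .levels$avascular_bright
  img
}

# A scene is the noiseless truth shared by the two scans of a visit: clean
# slab matrices plus per-slab fill levels used when translating.
make_cc_scene <- function(grid_px, void_fraction, scp_density = 0.3,
                          artifact_depth = .levels$artifact_depth,
                          extent_mm = 6, seed = 1) {
  scp <- generate_vessel_network(grid_px, scp_density,
                                 faz_radius_mm = 0.25 * extent_mm / 3,
                                 extent_mm = extent_mm, seed = derive_seed(seed, 1))
  set.seed(derive_seed(seed, 2))
  field <- gauss_blur(matrix(stats::rnorm(grid_px^2), grid_px, grid_px),
                      max(1.5, grid_px / 256))
  void <- void_mask_from_field(field, void_fraction)
  scp_img <- matrix(.levels$background, grid_px, grid_px)
  scp_img[scp] <- .levels$vessel
  list(
    grid_px = grid_px, extent_mm = extent_mm,
    void_field = field, void_mask = void, scp_mask = scp,
    artifact_depth = artifact_depth,
    slabs = list(
      CC = cc_clean_image(void, scp, artifact_depth),
      SCP = scp_img,
      avascular = avascular_clean_image(grid_px, derive_seed(seed, 3))
    ),
    fills = c(CC = .levels$cc_flow, SCP = .levels$background,
              avascular = .levels$avascular_base),
    kinds = c(CC = "CC", SCP = "SCP", avascular = "avascular"),
    void_fraction = mean(void)
  )
}

make_vessel_scene <- function(grid_px, density, faz_radius_mm = 0.25,
                              extent_mm = 3, seed = 1) {
  scp <- generate_vessel_network(grid_px, density, faz_radius_mm, extent_mm,
                                 seed = derive_seed(seed, 1))
  dcp <- generate_vessel_network(grid_px, density, faz_radius_mm, extent_mm,
                                 seed = derive_seed(seed, 2))
  to_img <- function(m) {
    img <- matrix(.levels$background, grid_px, grid_px)
    img[m] <- .levels$vessel
    img
  }
  list(
    grid_px = grid_px, extent_mm = extent_mm,
    scp_mask = scp, dcp_mask = dcp, faz_radius_mm = faz_radius_mm,
    faz_area_mm2 = pi * faz_radius_mm^2,
    slabs = list(SCP = to_img(scp), DCP = to_img(dcp)),
    fills = c(SCP = .levels$background, DCP = .levels$background),
    kinds = c(SCP = "SCP", DCP = "DCP"),
    density = mean(scp)
  )
}

scene_to_record <- function(scene, subject_id, scan_index, shift, noise_sd, seed,
                            signal_strength = 10) {
  slabs <- list()
  for (nm in names(scene$slabs)) {
    clean <- translate_matrix(scene$slabs[[nm]], shift[1], shift[2],
                              fill = scene$fills[[nm]])
    set.seed(derive_seed(seed, match(nm, names(scene$slabs))))
    if (noise_sd > 0) clean <- clean + stats::rnorm(length(clean), 0, noise_sd)
    slabs[[scene$kinds[[nm]]]] <- enface_image(clip255(clean),
                                               extent_mm = scene$extent_mm,
                                               slab_kind = scene$kinds[[nm]])
  }
  scan_record(subject_id, slabs, scan_index = scan_index,
              signal_strength = signal_strength)
}

#' Generate an intravisit scan pair from one scene
#'
#' Scan 1 images the scene as-is; scan 2 images the same scene translated by
#' `shift_px` (content moved `dx` columns right and `dy` rows down), with
#' fresh pixel noise in both.  This mirrors two consecutive same-visit
#' acquisitions without repositioning.
#'
#' @param scene a scene from `make_cc_scene()` / `make_vessel_scene()`
#'   (internal builders used by [generate_cohort()]).
#' @param shift_px integer vector `c(dx, dy)`.
#' @param noise_sd additive pixel-noise SD.
#' @param seed RNG seed.
#' @param max_shift_px bound on `|dx|`, `|dy|`.
#' @param subject_id metadata label.
#' @return A list with `scan1` and `scan2` ([scan_record()]s with scan
#'   indices 1 and 2).
#' @export
generate_intravisit_pair <- function(scene, shift_px = c(0, 0), noise_sd = 5,
                                     seed = 1, max_shift_px = NULL,
                                     subject_id = "S1") {
  max_shift_px <- max_shift_px %||% floor(scene$grid_px / 4 - 1)
  if (any(abs(shift_px) > max_shift_px)) {
    stop("shift exceeds max_shift_px", call. = FALSE)
  }
  list(
    scan1 = scene_to_record(scene, subject_id, 1L, c(0L, 0L), noise_sd,
                            derive_seed(seed, 101)),
    scan2 = scene_to_record(scene, subject_id, 2L, shift_px, noise_sd,
                            derive_seed(seed, 102))
  )
}

#' Generate a synthetic intravisit cohort with known ground truth
#'
#' Each subject's true index (flow-void fraction for `"cc"` cohorts, vessel
#' density for `"vessel"` cohorts) is drawn around `mean_index` with SD
#' `between_subject_sd`; each of the two scans realizes the index with an
#' independent error of SD `within_subject_sd`, implemented through the image
#' construction itself (the per-scan deficit/vessel pixel count), so the
#' implied intraclass correlation
#' `between_subject_sd^2 / (between_subject_sd^2 + within_subject_sd^2)`
#' is recorded as ground truth.  Scan 2 of every pair is additionally
#' translated by a random shift within `max_shift_px`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort` with `pairs` (per-subject lists
#'   of `scan1`, `scan2`), `truth` (data frame of true and realized indices
#'   plus applied shifts), `true_icc` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  pairs <- vector("list", cfg$n_subjects)
  truth <- data.frame(subject_id = character(0), true_index = numeric(0),
                      index_scan1 = numeric(0), index_scan2 = numeric(0),
                      dx = integer(0), dy = integer(0))
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%03d", i)
    set.seed(derive_seed(cfg$seed, i, 1))
    t_i <- cfg$mean_index + stats::rnorm(1, 0, cfg$between_subject_sd)
    e_is <- stats::rnorm(2, 0, cfg$within_subject_sd)
    v_scan <- pmin(0.9, pmax(0.01, t_i + e_is))
    shift <- if (cfg$max_shift_px > 0) {
      sample(seq(-cfg$max_shift_px, cfg$max_shift_px), 2, replace = TRUE)
    } else c(0L, 0L)
    scene_seed <- derive_seed(cfg$seed, i, 2)
    if (cfg$slab_set == "cc") {
      scene <- make_cc_scene(cfg$grid_px, v_scan[1], extent_mm = cfg$extent_mm,
                             seed = scene_seed)
      scan1 <- scene_to_record(scene, sid, 1L, c(0L, 0L), cfg$noise_sd,
                               derive_seed(cfg$seed, i, 3))
      # scan 2 re-realizes the deficit set from the same latent field at its
      # own fraction (nested sets keep the shared structure registerable)
      scene2 <- scene
      scene2$void_mask <- void_mask_from_field(scene$void_field, v_scan[2])
      scene2$slabs$CC <- cc_clean_image(scene2$void_mask, scene$scp_mask,
                                        scene$artifact_depth)
      scan2 <- scene_to_record(scene2, sid, 2L, shift, cfg$noise_sd,
                               derive_seed(cfg$seed, i, 4))
    } else {
      scene <- make_vessel_scene(cfg$grid_px, v_scan[1],
                                 faz_radius_mm = cfg$faz_radius_mm,
                                 extent_mm = cfg$extent_mm, seed = scene_seed)
      scan1 <- scene_to_record(scene, sid, 1L, c(0L, 0L), cfg$noise_sd,
                               derive_seed(cfg$seed, i, 3))
      scene2 <- scene
      for (nm in c("scp", "dcp")) {
        mk <- scene[[paste0(nm, "_mask")]]
        m2 <- vessel_mask_from_field(attr(mk, "field"), v_scan[2],
                                     attr(mk, "disc"), attr(mk, "ring"))
        scene2[[paste0(nm, "_mask")]] <- m2
        img <- matrix(.levels$background, cfg$grid_px, cfg$grid_px)
        img[m2] <- .levels$vessel
        scene2$slabs[[toupper(nm)]] <- img
      }
      scan2 <- scene_to_record(scene2, sid, 2L, shift, cfg$noise_sd,
                               derive_seed(cfg$seed, i, 4))
    }
    pairs[[i]] <- list(scan1 = scan1, scan2 = scan2)
    truth <- rbind(truth, data.frame(
      subject_id = sid, true_index = t_i,
      index_scan1 = v_scan[1], index_scan2 = v_scan[2],
      dx = shift[1], dy = shift[2]
    ))
  }
  true_icc <- if (cfg$between_subject_sd == 0 && cfg$within_subject_sd == 0) NA_real_ else
    cfg$between_subject_sd^2 /
      (cfg$between_subject_sd^2 + cfg$within_subject_sd^2)
  structure(list(pairs = pairs, truth = truth, true_icc = true_icc,
                 config = cfg),
            class = "synthetic_cohort")
}

#' Simulate paired measurements from the two-variance-component model
#'
#' Draws subject true values around `mean` with SD `between_sd` and two
#' measurements per subject with independent error SD `within_sd` — the
#' measurement-level analogue of [generate_cohort()], convenient for
#' validating the agreement statistics at large n.  The implied ICC is
#' `between_sd^2 / (between_sd^2 + within_sd^2)`.
#'
#' @param n_subjects number of subjects.
#' @param mean cohort mean of the index.
#' @param between_sd,within_sd variance-component SDs.
#' @param seed RNG seed.
#' @param index label for the measurement column.
#' @return A [paired_measurements()] data frame with attribute `true_icc`.
#' @export
simulate_paired_measurements <- function(n_subjects, mean = 1, between_sd = 1,
                                         within_sd = 0.5, seed = 1,
                                         index = "index") {
  set.seed(seed)
  t_i <- stats::rnorm(n_subjects, mean, between_sd)
  m1 <- t_i + stats::rnorm(n_subjects, 0, within_sd)
  m2 <- t_i + stats::rnorm(n_subjects, 0, within_sd)
  pm <- paired_measurements(sprintf("S%04d", seq_len(n_subjects)), m1, m2,
                            index = index)
  attr(pm, "true_icc") <- between_sd^2 / (between_sd^2 + within_sd^2)
  pm
}

#' Jitter a FAZ polygon to emulate operator retracing variability
#'
#' Adds independent Gaussian displacement to every vertex, the source of
#' intraoperator variability for the manual delineation mode (the automated
#' indices are deterministic).
#'
#' @param delineation a [faz_manual()] object.
#' @param sd_px displacement SD in pixels.
#' @param seed RNG seed.
#' @return A jittered [faz_manual()] object.
#' @export
jitter_polygon <- function(delineation, sd_px = 1, seed = 1) {
  stopifnot(inherits(delineation, "faz_delineation"),
            delineation$mode == "manual_polygon")
  set.seed(seed)
  p <- delineation$polygon + matrix(stats::rnorm(2 * nrow(delineation$polygon), 0, sd_px),
                                    ncol = 2)
  faz_manual(p)
}
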