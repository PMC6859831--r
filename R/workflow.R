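# Cohort orchestration: manifests, on-disk cohorts, end-to-end runs.

manifest_columns <- c("subject_id", "eye", "scan_index", "slab_kind", "path",
                      "signal_strength", "extent_mm")

#' Read and validate a cohort manifest
#'
#' The manifest is a CSV with one row per slab image and columns
#' `subject_id`, `eye`, `scan_index`, `slab_kind`, `path`, `signal_strength`,
#' `extent_mm` (optional extra columns, e.g. `floater`, pass through).
#' Duplicate `(subject_id, eye, scan_index, slab_kind)` keys are rejected.
#'
#' @param path manifest CSV path.
#' @return A validated data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(mf))
  if (length(missing) > 0) {
    stop(sprintf("manifest schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  key <- paste(mf$subject_id, mf$eye, mf$scan_index, mf$slab_kind, sep = "|")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate manifest key: %s", key[duplicated(key)][1]), call. = FALSE)
  }
  if (!all(mf$scan_index %in% c(1, 2))) {
    stop("scan_index must be 1 or 2", call. = FALSE)
  }
  mf
}

#' Write a synthetic cohort to disk
#'
#' Writes every slab as an 8-bit grayscale PNG plus a manifest CSV and a
#' ground-truth CSV, producing a self-contained on-disk cohort that
#' [run_full()] can consume.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pair in cohort$pairs) {
    for (scan in pair) {
      for (kind in names(scan$slabs)) {
        img <- scan$slabs[[kind]]
        fn <- sprintf("%s_%s_scan%d_%s.png", scan$subject_id, scan$eye,
                      scan$scan_index, kind)
        write_enface_png(img, file.path(dir, "images", fn))
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = scan$subject_id, eye = scan$eye,
          scan_index = scan$scan_index, slab_kind = kind,
          path = file.path("images", fn),
          signal_strength = scan$signal_strength,
          extent_mm = nrow(img$pixels) * img$mm_per_px,
          floater = scan$floater,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  mf <- do.call(rbind, rows)
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Load scan records described by a manifest
#'
#' @param manifest a data frame from [read_manifest()].
#' @param base_dir directory that image paths are relative to.
#' @return A named list of [scan_record()]s keyed by
#'   `subject_id|eye|scan_index`.
#' @export
load_scan_records <- function(manifest, base_dir = ".") {
  keys <- unique(manifest[, c("subject_id", "eye", "scan_index")])
  records <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- manifest$subject_id == keys$subject_id[i] &
      manifest$eye == keys$eye[i] & manifest$scan_index == keys$scan_index[i]
    sub <- manifest[sel, ]
    slabs <- list()
    for (j in seq_len(nrow(sub))) {
      p <- file.path(base_dir, sub$path[j])
      if (!file.exists(p)) {
        stop(sprintf("unreadable image for row %s|%s|scan%d|%s: %s",
                     sub$subject_id[j], sub$eye[j], sub$scan_index[j],
                     sub$slab_kind[j], p), call. = FALSE)
      }
      slabs[[sub$slab_kind[j]]] <- read_enface_png(p, sub$extent_mm[j], sub$slab_kind[j])
    }
    rec <- scan_record(keys$subject_id[i], slabs,
                       scan_index = as.integer(keys$scan_index[i]),
                       signal_strength = sub$signal_strength[1],
                       eye = keys$eye[i],
                       floater = isTRUE(as.logical(sub$floater[1])))
    # score motion on a structured (vessel-bearing) slab: speckle-like slabs
    # have uncorrelated adjacent rows by nature and would always flag
    motion_slab <- slabs[["SCP"]] %||% slabs[["DCP"]] %||% slabs[[1]]
    rec$motion_score <- motion_score(motion_slab)
    records[[paste(keys$subject_id[i], keys$eye[i], keys$scan_index[i], sep = "|")]] <- rec
  }
  records
}

#' Read a run configuration from YAML
#'
#' Recognized fields: `manifest`, `out_dir`, `max_shift_px`,
#' `motion_threshold`, `faz_mode` (`"auto"` or `"manual"`),
#' `artifact_removal`, `seed`.  The confidence level for interval estimates
#' is fixed at 95%.
#'
#' @param path YAML file path.
#' @return A named list of options.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(max_shift_px = NULL, motion_threshold = 0.2,
                   faz_mode = "auto", artifact_removal = TRUE, seed = 1)
  utils::modifyList(defaults, cfg)
}

#' Run the full quantification and repeatability workflow
#'
#' Applies the quality-control gate, runs the choriocapillaris flow-void
#' pipeline on every included 6-mm pair and the vessel pipeline (SCP and
#' DCP) on every included 3-mm pair, assembles paired measurements per
#' index, and computes the agreement report.  Per-record failures are
#' logged and skipped so one bad scan does not abort the run.  Reruns with
#' the same inputs are deterministic.
#'
#' @param manifest_path path to a cohort manifest CSV.
#' @param out_dir optional output directory; when given, the report
#'   (`report.csv`, `report.json`), per-pair measurements
#'   (`measurements.csv`), the QC table (`qc.csv`) and a run log are
#'   written there.
#' @param motion_threshold QC motion cutoff (see [qc_assess()]).
#' @param max_shift_px registration search radius.
#' @param artifact_removal toggle for the CC overlay correction.
#' @return A list with `report` ([repeatability_report()] output),
#'   `measurements`, `qc` and `log`.
#' @export
run_full <- function(manifest_path, out_dir = NULL, motion_threshold = 0.2,
                     max_shift_px = NULL, artifact_removal = TRUE) {
  base_dir <- dirname(manifest_path)
  manifest <- read_manifest(manifest_path)
  records <- load_scan_records(manifest, base_dir)
  log_lines <- sprintf("run_full: %d scan records from %s",
                       length(records), manifest_path)

  qc_rows <- list()
  included <- list()
  for (key in names(records)) {
    dec <- qc_assess(records[[key]], motion_threshold)
    qc_rows[[key]] <- data.frame(
      record = key, included = dec$included,
      reasons = paste(dec$reasons, collapse = ";"), stringsAsFactors = FALSE
    )
    if (dec$included) included[[key]] <- records[[key]]
    else log_lines <- c(log_lines, sprintf("excluded %s: %s", key,
                                           paste(dec$reasons, collapse = ",")))
  }
  qc <- do.call(rbind, qc_rows)
  log_lines <- c(log_lines, sprintf("qc: %d included + %d excluded = %d input",
                                    sum(qc$included), sum(!qc$included), nrow(qc)))

  # pair up scans 1 and 2 per subject/eye that both survived QC
  subj_eye <- unique(sub("\\|[12]$", "", names(included)))
  meas <- list(cc_fv = list(), scp_vd = list(), dcp_vd = list(),
               scp_faz = list(), dcp_faz = list())
  for (se in subj_eye) {
    k1 <- paste0(se, "|1"); k2 <- paste0(se, "|2")
    if (is.null(included[[k1]]) || is.null(included[[k2]])) next
    s1 <- included[[k1]]; s2 <- included[[k2]]
    sid <- s1$subject_id
    if (all(c("CC", "SCP", "avascular") %in% names(s1$slabs))) {
      res <- tryCatch(
        ccfv_pipeline(s1, s2, max_shift_px = max_shift_px,
                      artifact_removal = artifact_removal),
        error = function(e) {
          log_lines <<- c(log_lines, sprintf("ccfv failed for %s: %s", se,
                                             conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) {
        meas$cc_fv[[sid]] <- c(res$result1$void_area_mm2, res$result2$void_area_mm2)
        log_lines <- c(log_lines, sprintf(
          "ccfv %s: offset (%d,%d), areas %.4f / %.4f mm2", se,
          res$offset_px[["dx"]], res$offset_px[["dy"]],
          res$result1$void_area_mm2, res$result2$void_area_mm2))
      }
    }
    for (slab in intersect(c("SCP", "DCP"), intersect(names(s1$slabs), names(s2$slabs)))) {
      if ("CC" %in% names(s1$slabs)) next   # vessel metrics only for 3-mm scans
      r1 <- tryCatch(vessel_pipeline(s1, slab), error = function(e) {
        log_lines <<- c(log_lines, sprintf("vessel %s failed for %s scan1: %s",
                                           slab, se, conditionMessage(e)))
        NULL
      })
      r2 <- tryCatch(vessel_pipeline(s2, slab), error = function(e) {
        log_lines <<- c(log_lines, sprintf("vessel %s failed for %s scan2: %s",
                                           slab, se, conditionMessage(e)))
        NULL
      })
      if (is.null(r1) || is.null(r2)) next
      vd_key <- if (slab == "SCP") "scp_vd" else "dcp_vd"
      faz_key <- if (slab == "SCP") "scp_faz" else "dcp_faz"
      meas[[vd_key]][[sid]] <- c(r1$tva_mm2, r2$tva_mm2)
      meas[[faz_key]][[sid]] <- c(r1$faz_area_mm2, r2$faz_area_mm2)
    }
  }

  pm_list <- list()
  meas_rows <- list()
  for (idx in names(meas)) {
    if (length(meas[[idx]]) < 3) next
    sids <- names(meas[[idx]])
    m1 <- vapply(meas[[idx]], `[`, numeric(1), 1)
    m2 <- vapply(meas[[idx]], `[`, numeric(1), 2)
    pm_list[[idx]] <- paired_measurements(sids, m1, m2, index = idx)
    meas_rows[[idx]] <- data.frame(subject_id = sids, index = idx, m1 = m1, m2 = m2,
                                   stringsAsFactors = FALSE)
  }
  report <- repeatability_report(pm_list)
  measurements <- if (length(meas_rows) == 0) data.frame() else
    do.call(rbind, c(unname(meas_rows), list(make.row.names = FALSE)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(report = report, measurements = measurements, qc = qc, log = log_lines)
}
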