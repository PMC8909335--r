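## Orchestration: cohort simulation -> spectral + texture feature
## extraction -> tier comparison / model fit -> predicted-group survival,
## with CSV/JSON/RDS persistence and a reproducibility manifest.

#' Extract model rows for a simulated cohort
#'
#' Runs the spectral and texture stages on every patient's two scans and
#' assembles the 190-feature model rows.
#'
#' @param patients Cohort list from [simulate_cohort()].
#' @param reference Reference frames from [simulate_reference_frames()].
#' @param config An [acq_config()].
#' @param tex_config A [texture_config()].
#' @return Data frame: `patient_id`, `label`, `time`, `event`, then the 190
#'   model features.
#' @export
extract_cohort_features <- function(patients, reference, config = acq_config(),
                                    tex_config = texture_config()) {
  rows <- lapply(patients, function(p) {
    fv <- lapply(p$scans, function(sc) {
      qm <- build_parametric_maps(sc$frame, sc$roi, reference, config)
      scan_feature_vector(qm, tex_config)
    })
    feats <- assemble_features(fv$week0, fv$week4)
    cbind(data.frame(patient_id = p$patient_id, label = p$label,
                     time = p$outcome$time, event = p$outcome$event),
          as.data.frame(as.list(feats), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the feature table
#'
#' Model rows are stored as plain CSV with stable column order
#' (`patient_id`, `label`, `time`, `event`, then the 190 model features;
#' the difference prefix is the ASCII `d`).
#'
#' @param rows Model-row data frame.
#' @param path CSV path.
#' @return `read_feature_csv` returns the model-row data frame.
#' @export
write_feature_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  rows <- utils::read.csv(path, check.names = FALSE)
  rows$label <- factor(rows$label, levels = c("nonrecurrence", "recurrence"))
  rows
}

#' Persist / load a simulated cohort
#'
#' RF stacks and masks are written as an RDS payload (lossless float64);
#' ground truth, outcomes and the acquisition configuration go to a JSON
#' sidecar for inspection without loading the stacks.
#'
#' @param patients Cohort list from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `read_cohort` returns the cohort list.
#' @export
write_cohort <- function(patients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(patients, file.path(dir, "cohort.rds"))
  sidecar <- lapply(patients, function(p) list(
    patient_id = p$patient_id, label = as.character(p$label),
    outcome = list(time = p$outcome$time, event = p$outcome$event),
    truth = lapply(p$truth, function(ph) list(
      ASD_um = ph$scatterer_diameter * 1e6,
      AAC_dB = ph$acoustic_concentration,
      ACE_dB_cm_MHz = ph$attenuation,
      SAS_mm = if (is.na(ph$mean_spacing)) NULL else ph$mean_spacing * 1e3))))
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) readRDS(file.path(dir, "cohort.rds"))

object_checksum <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline end to end
#'
#' Simulates a two-time-point RF cohort, extracts the 190-feature model
#' rows, fits the balanced-subset ensemble with forward selection under
#' leave-one-patient-out cross-validation, and compares recurrence-free
#' survival between the predicted groups.  A manifest with configuration
#' checksums and the seed makes a rerun reproducible bit for bit.
#'
#' @param n_recurrence,n_nonrecurrence Cohort group sizes.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param config An [acq_config()].
#' @param tex_config A [texture_config()].
#' @param clf_config A [classifier_config()].
#' @param tier Feature tier for the model (see [feature_tier()]).
#' @param effect Ground-truth group effect (see [simulate_cohort()]).
#' @param out_dir Optional directory; if given, the feature CSV, the report
#'   JSON and the manifest are written there.
#' @return List (class `qus_pipeline`): `rows`, `model`, `survival`,
#'   `manifest`.
#' @export
run_qus_pipeline <- function(n_recurrence, n_nonrecurrence, seed = 1L,
                             config = acq_config(),
                             tex_config = texture_config(),
                             clf_config = classifier_config(),
                             tier = "all",
                             effect = default_cohort_effect(),
                             out_dir = NULL) {
  patients <- simulate_cohort(n_recurrence, n_nonrecurrence, effect = effect,
                              seed = derive_seed(seed, 1L), config = config)
  reference <- simulate_reference_frames(config, n_frames = 8L,
                                         seed = derive_seed(seed, 2L))
  rows <- extract_cohort_features(patients, reference, config, tex_config)
  model <- qus_model(rows, clf_config,
                     candidates = intersect(feature_tier(tier), names(rows)),
                     seed = derive_seed(seed, 3L))
  outcomes <- do.call(rbind, lapply(patients, `[[`, "outcome"))
  surv <- tryCatch(predicted_group_survival(model$preds, outcomes),
                   error = function(e) e)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("qusradiomics")),
    config_checksum = object_checksum(list(config, tex_config, clf_config,
                                           effect, n_recurrence,
                                           n_nonrecurrence)),
    rows_checksum = object_checksum(rows),
    n_patients = nrow(rows), tier = tier)
  res <- structure(list(rows = rows, model = model, survival = surv,
                        manifest = manifest),
                   class = "qus_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_csv(rows, file.path(out_dir, "features.csv"))
    report <- list(
      manifest = manifest,
      selected_features = model$selected,
      metrics = as.list(model$cv$metrics),
      ci = as.list(as.data.frame(t(model$cv$ci))),
      five_year_rfs = if (inherits(surv, "qus_survival"))
        as.list(surv$five_year_rfs) else NULL,
      logrank_p = if (inherits(surv, "qus_survival")) surv$test$p_value else NULL)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.qus_pipeline <- function(x, ...) {
  cat(sprintf("QUS radiomics pipeline run (seed %d, %d patients)\n",
              x$manifest$seed, x$manifest$n_patients))
  print(x$model)
  if (inherits(x$survival, "qus_survival")) print(x$survival)
  else cat("Survival comparison unavailable:",
           conditionMessage(x$survival), "\n")
  invisible(x)
}

#' Export a parametric map as a rendered PNG and float TIFF
#'
#' Colour rendering uses fixed display ranges per parameter where
#' conventional (e.g. ASD 40--200 um, AAC 7--65 dB); the TIFF stores the
#' raw float values with a JSON metadata sidecar.  Requires the `png` and
#' `tiff` packages.
#'
#' @param map A `parametric_map`.
#' @param path_base Output path without extension.
#' @param zlim Display range; defaults per parameter.
#' @return Invisibly, the written paths.
#' @export
export_parametric_map <- function(map, path_base, zlim = NULL) {
  defaults <- list(ASD = c(40, 200), AAC = c(7, 65))
  zlim <- zlim %||% defaults[[map$parameter]] %||%
    range(map$grid[is.finite(map$grid)])
  g <- map$grid
  norm <- pmin(pmax((g - zlim[1]) / diff(zlim), 0), 1)
  norm[!is.finite(norm)] <- 0
  pal <- grDevices::hcl.colors(256, "viridis")
  rgb <- grDevices::col2rgb(pal[pmax(1L, ceiling(norm * 255))]) / 255
  img <- array(0, c(nrow(g), ncol(g), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(g)); img[, , 2] <- matrix(rgb[2, ], nrow(g))
  img[, , 3] <- matrix(rgb[3, ], nrow(g))
  paths <- character(0)
  if (requireNamespace("png", quietly = TRUE)) {
    png::writePNG(img, paste0(path_base, ".png"))
    paths <- c(paths, paste0(path_base, ".png"))
  }
  if (requireNamespace("tiff", quietly = TRUE)) {
    gg <- g; gg[!is.finite(gg)] <- 0
    tiff::writeTIFF(gg / max(abs(gg), 1), paste0(path_base, ".tif"),
                    bits.per.sample = 32L)
    paths <- c(paths, paste0(path_base, ".tif"))
  }
  jsonlite::write_json(list(parameter = map$parameter, zlim = zlim,
                            window_size_m = map$window_size_m,
                            step_m = as.list(map$step_m)),
                       paste0(path_base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, paste0(path_base, ".json")))
}
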