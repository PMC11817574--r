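#' Pipeline configuration
#'
#' Collects everything a full run needs: the input mode (synthetic cohort
#' or a file manifest), the threshold series, the b-value, the reference
#' attenuation-correction method, the output directory and the master
#' seed. Validates the invariants (thresholds strictly increasing in
#' (0, 100], b-value positive) at construction so a run fails before any
#' computation.
#'
#' @param input_mode `"synthetic"` or `"files"`.
#' @param output_dir directory for run artifacts.
#' @param master_seed integer seed driving every random draw of the run.
#' @param thresholds strictly increasing integer percentages in (0, 100].
#' @param b_value high b-value (s/mm^2) for the ADC fit.
#' @param reference_method label of the reference PET reconstruction.
#' @param methods labels of all PET reconstructions to analyse.
#' @param n_subjects,n_pz,coupling_rho synthetic-mode cohort shape.
#' @param spec a [phantom_spec()] for synthetic mode (default
#'   `phantom_spec()`).
#' @param manifest for files mode: path to a cohort manifest CSV with
#'   columns `subject_id`, `zone`, and a `dir` column naming each
#'   subject's directory (as written by [write_subject()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "files"),
                            output_dir = tempfile("petadc_run_"),
                            master_seed = 1L,
                            thresholds = c(10L, 20L, 30L, 40L, 50L, 60L),
                            b_value = 800,
                            reference_method = "CT_reference",
                            methods = c("CT_reference", "MRI_like", "DL_like"),
                            n_subjects = 27L, n_pz = 17L,
                            coupling_rho = -0.5,
                            spec = phantom_spec(),
                            manifest = NULL) {
  input_mode <- match.arg(input_mode)
  thresholds <- as.integer(thresholds)
  if (length(thresholds) == 0L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0L) || any(thresholds > 100L)) {
    stop("`thresholds` must be strictly increasing in (0, 100]", call. = FALSE)
  }
  if (b_value <= 0) stop("`b_value` must be positive", call. = FALSE)
  if (!reference_method %in% methods) {
    stop("`reference_method` must be among `methods`", call. = FALSE)
  }
  if (input_mode == "files" && is.null(manifest)) {
    stop("files mode needs a `manifest` path", call. = FALSE)
  }
  structure(
    list(input_mode = input_mode, output_dir = output_dir,
         master_seed = as.integer(master_seed), thresholds = thresholds,
         b_value = b_value, reference_method = reference_method,
         methods = methods, n_subjects = as.integer(n_subjects),
         n_pz = as.integer(n_pz), coupling_rho = coupling_rho,
         spec = spec, manifest = manifest),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields of [pipeline_config()] may be given in the file;
#' unspecified fields keep their defaults. Phantom geometry always uses
#' [phantom_spec()] defaults unless set programmatically.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("input_mode", "output_dir", "master_seed", "thresholds",
               "b_value", "reference_method", "methods", "n_subjects",
               "n_pz", "coupling_rho", "manifest")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, cfg)
}

#' Write one subject to disk as NIfTI volumes plus a JSON sidecar
#'
#' Volumes (`dwi_b0`, `dwi_b800`, one `pet_<method>` per reconstruction,
#' `roi` as uint8) are written as NIfTI-1 with the voxel spacing in the
#' header; the dose record, zone, truth values and unit tags go to
#' `sidecar.json` (NIfTI has no units field for these quantities).
#'
#' @param subject a `subject_data` object.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "subject_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(grid, name, datatype = "double") {
    vals <- grid$values
    attr(vals, "pixdim") <- grid$spacing_mm
    img <- RNifti::asNifti(vals, datatype = datatype)
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(subject$dwi_b0, "dwi_b0")
  wr(subject$dwi_b800, "dwi_b800")
  for (m in names(subject$pet_by_method)) {
    wr(subject$pet_by_method[[m]], paste0("pet_", m))
  }
  roi_arr <- array(as.integer(subject$roi$mask), dim(subject$roi$mask))
  attr(roi_arr, "pixdim") <- subject$dwi_b0$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(roi_arr, datatype = "uint8"),
                     file.path(dir, "roi.nii.gz"))
  sidecar <- list(
    subject_id = subject$subject_id,
    zone = subject$roi$zone,
    dose = unclass(subject$dose),
    truth = subject$truth,
    units = list(dwi = "signal_au", pet = "activity_Bq_per_mL")
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one subject back from a directory written by [write_subject()]
#'
#' Loads the volumes with spacing taken from the NIfTI headers, restores
#' the dose record and zone from the sidecar, and enforces grid
#' congruence (shape identical, spacings within 1e-3 mm) across all
#' volumes — no resampling is performed; co-registration is a
#' precondition, not a pipeline step.
#'
#' @param dir subject directory.
#' @return A `subject_data` object (without true ADC/SUV fields if the
#'   directory holds real rather than synthetic data).
#' @export
read_subject <- function(dir) {
  sidecar_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing dose sidecar %s", sidecar_path), call. = FALSE)
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  dose <- dose_record(
    injected_activity_MBq = sidecar$dose$injected_activity_MBq,
    body_weight_kg = sidecar$dose$body_weight_kg,
    injection_to_scan_s = sidecar$dose$injection_to_scan_s,
    half_life_s = sidecar$dose$half_life_s,
    branching_factor = sidecar$dose$branching_factor
  )
  rd <- function(name, units) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(path)) stop(sprintf("missing volume %s", path),
                                 call. = FALSE)
    img <- RNifti::readNifti(path)
    voxel_grid(array(as.numeric(img), dim(img)),
               RNifti::pixdim(img)[1:3], units)
  }
  dwi_b0 <- rd("dwi_b0", "signal_au")
  dwi_b800 <- rd("dwi_b800", "signal_au")
  stopifnot_congruent(dwi_b0, dwi_b800, "DWI volumes")
  pet_files <- list.files(dir, pattern = "^pet_.*\\.nii\\.gz$")
  if (length(pet_files) == 0L) stop("no PET volumes found", call. = FALSE)
  pet_by_method <- lapply(pet_files, function(f) {
    g <- rd(sub("\\.nii\\.gz$", "", f), "activity_Bq_per_mL")
    stopifnot_congruent(dwi_b0, g, "PET vs DWI volumes")
    g
  })
  names(pet_by_method) <- sub("^pet_(.*)\\.nii\\.gz$", "\\1", pet_files)
  roi_img <- RNifti::readNifti(file.path(dir, "roi.nii.gz"))
  if (!identical(dim(roi_img), dim(dwi_b0$values))) {
    stop(sprintf("incongruent ROI: shape %s vs %s",
                 paste(dim(roi_img), collapse = "x"),
                 paste(dim(dwi_b0$values), collapse = "x")), call. = FALSE)
  }
  roi <- roi_mask(array(as.numeric(roi_img) > 0, dim(roi_img)),
                  zone = sidecar$zone)
  structure(
    list(subject_id = sidecar$subject_id, true_adc = NULL, true_suv = NULL,
         dwi_b0 = dwi_b0, dwi_b800 = dwi_b800,
         pet_by_method = pet_by_method, roi = roi, dose = dose,
         truth = sidecar$truth),
    class = "subject_data"
  )
}

#' Write a whole cohort plus a manifest CSV
#'
#' @param cohort list of subjects.
#' @param dir output directory; each subject goes to `dir/<subject_id>/`.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort_truth(cohort)
  truth$dir <- file.path(dir, truth$subject_id)
  for (s in cohort) write_subject(s, file.path(dir, s$subject_id))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(truth, manifest, row.names = FALSE)
  invisible(manifest)
}

read_cohort <- function(manifest) {
  rows <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  subjects <- list()
  exclusions <- list()
  for (i in seq_len(nrow(rows))) {
    res <- tryCatch(read_subject(rows$dir[i]), error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        subject_id = rows$subject_id[i], reason = conditionMessage(res))
    } else {
      subjects[[length(subjects) + 1L]] <- res
    }
  }
  attr(subjects, "exclusions") <- if (length(exclusions))
    dplyr::bind_rows(exclusions) else
      tibble::tibble(subject_id = character(), reason = character())
  subjects
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, then for every threshold level (the
#' manual ROI plus each percentage in the config) and every PET method
#' computes the cohort feature table and the ADC x SUV Spearman
#' correlation grid, and at the manual-ROI level computes the per-feature
#' attenuation-correction error report. All tables are written as CSV
#' with provenance columns (master seed, config hash); grids and the
#' error report are additionally serialized as JSON, and a run manifest
#' records the config, seed, hash and package version so a run can be
#' reproduced bit-identically.
#'
#' In files mode, unreadable or incongruent subjects are excluded with
#' logged reasons and the run proceeds if at least 3 subjects survive.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `cohort`, `feature_tables` (tibble),
#'   `grids` (list of [correlation_grid()]), `error_report`,
#'   `exclusions`, and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$input_mode == "synthetic") {
    cohort <- generate_cohort(config$spec, n_subjects = config$n_subjects,
                              n_pz = config$n_pz,
                              coupling_rho = config$coupling_rho,
                              seed = config$master_seed)
    exclusions <- tibble::tibble(subject_id = character(),
                                 reason = character())
  } else {
    cohort <- read_cohort(config$manifest)
    exclusions <- attr(cohort, "exclusions")
    if (length(cohort) < 3L) {
      stop(sprintf("only %d subjects readable (< 3); aborting", length(cohort)),
           call. = FALSE)
    }
  }

  cfg_hash <- rlang::hash(config[setdiff(names(config), "output_dir")])
  prov <- function(df) {
    df$master_seed <- config$master_seed
    df$config_hash <- cfg_hash
    df
  }

  levels <- c(0L, config$thresholds)
  all_features <- list()
  grids <- list()
  for (m in config$methods) {
    for (p in levels) {
      ft <- cohort_feature_table(cohort, method_label = m, threshold_pct = p,
                                 reference_label = config$reference_method,
                                 b_value_s_mm2 = config$b_value)
      key <- sprintf("%s_pct%02d", m, p)
      all_features[[key]] <- ft
      utils::write.csv(prov(as.data.frame(ft)),
                       file.path(config$output_dir,
                                 sprintf("features_%s.csv", key)),
                       row.names = FALSE)
      grid <- correlation_grid(ft)
      grids[[key]] <- grid
      td <- tidy(grid)
      utils::write.csv(prov(as.data.frame(td)),
                       file.path(config$output_dir,
                                 sprintf("correlation_%s.csv", key)),
                       row.names = FALSE)
      jsonlite::write_json(
        list(method_label = grid$method_label,
             threshold_pct = grid$threshold_pct, n = grid$n,
             rho = grid$rho, p_values = grid$p_values),
        file.path(config$output_dir, sprintf("correlation_%s.json", key)),
        auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
      )
    }
  }

  report <- feature_error_report(
    cohort, reference_label = config$reference_method,
    other_labels = setdiff(config$methods, config$reference_method),
    threshold_pct = 0L
  )
  utils::write.csv(prov(as.data.frame(report$errors)),
                   file.path(config$output_dir, "error_report.csv"),
                   row.names = FALSE)
  utils::write.csv(prov(as.data.frame(report$tests)),
                   file.path(config$output_dir, "error_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(errors = report$errors, tests = report$tests,
         reference_label = report$reference_label),
    file.path(config$output_dir, "error_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  if (length(exclusions) && nrow(exclusions)) {
    utils::write.csv(as.data.frame(exclusions),
                     file.path(config$output_dir, "exclusions.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    config = config[setdiff(names(config), c("spec", "output_dir"))],
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("petadc")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(cohort = cohort, feature_tables = all_features,
                 grids = grids, error_report = report,
                 exclusions = exclusions, output_dir = config$output_dir))
}
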