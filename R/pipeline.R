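#' Run the full synthetic-plaque analysis pipeline
#'
#' Chains the five stages — simulate phantoms and acquisitions, fit T1/T2*
#' maps, sample ROIs and extract features, fit and apply QDA, and write the
#' misclassification report — into one seeded, logged run. All intermediates
#' are written to `out_dir` (NIfTI volumes, CSV tables, JSON models and
#' reports), so each stage can also be re-run individually on saved files.
#' Re-running with the same configuration reproduces byte-identical CSV and
#' JSON outputs (the manifest's timestamps aside).
#'
#' @param config A `run_config` ([default_run_config()] /
#'   [read_run_config()]).
#' @param out_dir Output directory, created if missing.
#' @param seed Optional master-seed override.
#' @param quiet Suppress per-stage log lines.
#' @return A `run_manifest` list: config hash, per-stage file paths,
#'   warnings, timestamps. Also written to `manifest.json`.
#' @export
run_all <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  config <- validate_run_config(unclass(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed, stages = list(), warnings = list())

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res
    res
  }
  run_stage("simulate", function()
    stage_simulate(config, out_dir, log_line = log_line))
  run_stage("fitmaps", function()
    stage_fitmaps(out_dir, out_dir, log_line = log_line))
  run_stage("roi", function()
    stage_roi(config, out_dir, out_dir, log_line = log_line))
  run_stage("classify", function()
    stage_classify(file.path(out_dir, "features.csv"), out_dir,
                   scope = config$qda$scope %||% "per_plaque",
                   shrinkage = config$qda$shrinkage %||% 0.1,
                   priors = config$qda$priors %||% "empirical",
                   log_line = log_line))
  run_stage("report", function()
    stage_report(file.path(out_dir, "predictions.csv"),
                 file.path(out_dir, "qda_models.json"), out_dir,
                 log_line = log_line))

  manifest$started <- format(t0, "%Y-%m-%dT%H:%M:%S")
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("pipeline complete in %.1f s -> %s", manifest$elapsed_s, out_dir)
  invisible(structure(manifest, class = "run_manifest"))
}

config_hash <- function(config) {
  # content hash of the canonical JSON form; no external digest dependency
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # 32-bit FNV-1a over the UTF-8 bytes
  bytes <- as.integer(charToRaw(js))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("fnv1a-%08x", as.integer(h %% 2^31))
}

#' Pipeline stage: simulate phantoms and acquisitions
#'
#' Generates every configured phantom and both signal stacks (VFA and
#' multi-echo), writing label/ground-truth volumes and 4D stacks as NIfTI
#' plus JSON sidecars carrying protocol and class-table metadata.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @param log_line Logging callback, `function(fmt, ...)`.
#' @return List of written file paths (invisibly inside [run_all()]).
#' @export
stage_simulate <- function(config, out_dir,
                           log_line = function(...) invisible()) {
  config <- validate_run_config(unclass(config))
  classes <- config_classes(config)
  ph_dir <- file.path(out_dir, "phantoms")
  st_dir <- file.path(out_dir, "stacks")
  dir.create(ph_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(st_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (i in seq_along(config$plaques)) {
    p <- config$plaques[[i]]
    spec <- config_phantom_spec(p, derive_seed(config$seed, "simulate", i))
    ph <- generate_phantom(spec, classes)
    vx <- spec$voxel_size_um
    base <- file.path(ph_dir, p$plaque_id)
    write_nifti(ph$labels, paste0(base, "_labels.nii.gz"), vx,
                "tissue class ids", datatype = "int32")
    write_nifti(ph$t1_true, paste0(base, "_t1true.nii.gz"), vx,
                "ground-truth T1 [ms]", datatype = "float64")
    write_nifti(ph$t2s_true, paste0(base, "_t2strue.nii.gz"), vx,
                "ground-truth T2* [ms]", datatype = "float64")
    write_nifti(ph$m0_true, paste0(base, "_m0true.nii.gz"), vx,
                "ground-truth M0 [a.u.]", datatype = "float64")
    jsonlite::write_json(
      list(plaque_id = ph$plaque_id, class_table = ph$class_table,
           voxel_size_um = vx),
      paste0(base, "_meta.json"), auto_unbox = TRUE, digits = NA)
    for (mode in c("vfa", "multiecho")) {
      prot <- config_protocol(config$protocols[[mode]], mode,
                              derive_seed(config$seed,
                                          if (mode == "vfa") "noise_vfa"
                                          else "noise_me", i))
      stack <- simulate_acquisition(ph, prot)
      sbase <- file.path(st_dir, paste0(p$plaque_id, "_", mode))
      write_nifti(stack$frames, paste0(sbase, ".nii.gz"), vx,
                  paste(mode, "signal stack"), datatype = "float64")
      jsonlite::write_json(unclass(prot), paste0(sbase, "_protocol.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      files[[paste0(p$plaque_id, "_", mode)]] <- paste0(sbase, ".nii.gz")
    }
    log_line("simulate: %s (%s voxels, 2 stacks)", p$plaque_id,
             paste(spec$grid_shape, collapse = "x"))
  }
  list(phantom_dir = ph_dir, stack_dir = st_dir,
       n_plaques = length(config$plaques))
}

# read a saved stack + protocol sidecar back into a signal_stack
read_stack <- function(stack_path) {
  sbase <- sub("\\.nii(\\.gz)?$", "", stack_path)
  prot_path <- paste0(sbase, "_protocol.json")
  if (!file.exists(prot_path))
    stop("missing protocol sidecar ", prot_path, call. = FALSE)
  pr <- jsonlite::read_json(prot_path, simplifyVector = TRUE)
  prot <- acquisition_protocol(pr$mode, tr = pr$tr,
                               flip_angles = pr$flip_angles,
                               echo_times = pr$echo_times,
                               te_fixed = pr$te_fixed %||% 2,
                               flip_angle = pr$flip_angle %||% 10,
                               noise_model = pr$noise_model,
                               noise_sigma = pr$noise_sigma,
                               zero_fill_factor = pr$zero_fill_factor %||% 1L,
                               seed = pr$seed %||% 1L)
  nii <- read_nifti(stack_path)
  if (dim(nii$data)[1] != n_frames(prot))
    stop("stack ", stack_path, ": frame count does not match protocol",
         call. = FALSE)
  structure(list(frames = nii$data, protocol = prot,
                 phantom_id = sub("_(vfa|multiecho)$", "", basename(sbase))),
            class = "signal_stack")
}

#' Pipeline stage: fit relaxation maps from saved stacks
#'
#' Reads every `*_vfa.nii.gz` / `*_multiecho.nii.gz` stack in
#' `in_dir/stacks`, fits T1 and T2* maps and writes them (with M0/S0 maps
#' and uint8 validity masks) to `out_dir/maps`. The signal floor is set to
#' `3 * noise_sigma * max(signal)` of each stack when its protocol carries
#' noise, else 0.
#'
#' @param in_dir Directory containing `stacks/`.
#' @param out_dir Output directory (`maps/` is created inside).
#' @param log_line Logging callback.
#' @return List with the maps directory and per-plaque validity counts.
#' @export
stage_fitmaps <- function(in_dir, out_dir,
                          log_line = function(...) invisible()) {
  st_dir <- file.path(in_dir, "stacks")
  vfa_files <- sort(list.files(st_dir, "_vfa\\.nii\\.gz$", full.names = TRUE))
  if (!length(vfa_files)) stop("no VFA stacks in ", st_dir, call. = FALSE)
  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (vf in vfa_files) {
    pid <- sub("_vfa\\.nii\\.gz$", "", basename(vf))
    svfa <- read_stack(vf)
    sme <- read_stack(file.path(st_dir, paste0(pid, "_multiecho.nii.gz")))
    floor_vfa <- fit_floor(svfa)
    floor_me <- fit_floor(sme)
    t1f <- fit_t1_vfa(svfa, signal_floor = floor_vfa)
    t2f <- fit_t2star(sme, signal_floor = floor_me)
    vx <- read_nifti(vf)$voxel_size_um
    base <- file.path(maps_dir, pid)
    write_nifti(t1f$t1_map, paste0(base, "_t1.nii.gz"), vx, "T1 map [ms]",
                datatype = "float64")
    write_nifti(t1f$m0_map, paste0(base, "_m0.nii.gz"), vx, "M0 map [a.u.]",
                datatype = "float64")
    write_nifti(t1f$valid_mask + 0L, paste0(base, "_t1mask.nii.gz"), vx,
                "T1 validity mask", datatype = "uint8")
    write_nifti(t2f$t2s_map, paste0(base, "_t2s.nii.gz"), vx, "T2* map [ms]",
                datatype = "float64")
    write_nifti(t2f$s0_map, paste0(base, "_s0.nii.gz"), vx, "S0 map [a.u.]",
                datatype = "float64")
    write_nifti(t2f$valid_mask + 0L, paste0(base, "_t2smask.nii.gz"), vx,
                "T2* validity mask", datatype = "uint8")
    counts[[pid]] <- list(t1_valid = sum(t1f$valid_mask),
                          t2s_valid = sum(t2f$valid_mask),
                          n_voxels = length(t1f$valid_mask))
    log_line("fitmaps: %s  T1 valid %d/%d, T2* valid %d/%d", pid,
             counts[[pid]]$t1_valid, counts[[pid]]$n_voxels,
             counts[[pid]]$t2s_valid, counts[[pid]]$n_voxels)
  }
  list(maps_dir = maps_dir, validity = counts)
}

fit_floor <- function(stack) {
  if (stack$protocol$noise_model == "none" || stack$protocol$noise_sigma == 0)
    0
  else 3 * stack$protocol$noise_sigma * max(stack$frames)
}

# reload maps for one plaque as a relaxation_maps bundle
read_maps <- function(maps_dir, pid, tr = NA_real_) {
  rd <- function(sfx) read_nifti(file.path(maps_dir,
                                           paste0(pid, "_", sfx, ".nii.gz")))$data
  t1m <- rd("t1"); t1mask <- rd("t1mask") > 0
  t1m[!t1mask] <- NaN
  t2m <- rd("t2s"); t2mask <- rd("t2smask") > 0
  t2m[!t2mask] <- NaN
  t1f <- structure(list(t1_map = t1m, m0_map = rd("m0"),
                        slope_map = NULL, valid_mask = t1mask, tr = tr),
                   class = "t1_fit")
  t2f <- structure(list(t2s_map = t2m, s0_map = rd("s0"),
                        valid_mask = t2mask),
                   class = "t2s_fit")
  relaxation_maps(t1f, t2f)
}

#' Pipeline stage: sample ROIs and extract feature vectors
#'
#' Samples ROIs according to the configured plan (or loads an external ROI
#' CSV) for each plaque, extracts the seven predictors from the fitted maps
#' and writes `rois.csv`, `features.csv` and the Table-style `summary.csv`.
#'
#' @param config A `run_config` (used for the ROI plan and seed).
#' @param in_dir Directory containing `phantoms/` and `maps/`.
#' @param out_dir Output directory for the CSV tables.
#' @param roi_file Optional external ROI CSV; when given, sampling is
#'   skipped and these definitions are used for every plaque they mention.
#' @param log_line Logging callback.
#' @return List of written table paths and ROI counts.
#' @export
stage_roi <- function(config, in_dir, out_dir, roi_file = NULL,
                      log_line = function(...) invisible()) {
  config <- validate_run_config(unclass(config))
  ph_dir <- file.path(in_dir, "phantoms")
  maps_dir <- file.path(in_dir, "maps")
  all_rois <- list()
  all_feats <- list()
  if (!is.null(roi_file)) {
    ext <- read_roi_csv(roi_file)
    pids <- unique(ext$plaque_id)
  } else {
    pids <- vapply(config$plaques, `[[`, character(1), "plaque_id")
  }
  for (i in seq_along(pids)) {
    pid <- pids[i]
    meta <- jsonlite::read_json(file.path(ph_dir, paste0(pid, "_meta.json")),
                                simplifyVector = TRUE)
    if (is.null(roi_file)) {
      labels <- read_nifti(file.path(ph_dir,
                                     paste0(pid, "_labels.nii.gz")))$data
      ph <- structure(list(labels = labels, class_table = meta$class_table,
                           plaque_id = pid), class = "phantom")
      present <- meta$class_table$name[meta$class_table$id %in% unique(as.vector(labels))]
      plan <- config$roi_plan$n_per_class
      plan <- plan[names(plan) %in% present]
      rois <- sample_rois(ph, plan,
                          size_range = unlist(config$roi_plan$size_range),
                          seed = derive_seed(config$seed, "roi", i))
    } else {
      rois <- ext[ext$plaque_id == pid, , drop = FALSE]
    }
    maps <- read_maps(maps_dir, pid)
    feats <- extract_features(maps, rois)
    all_rois[[pid]] <- as.data.frame(rois)
    all_feats[[pid]] <- as.data.frame(feats)
    log_line("roi: %s  %d ROIs -> %d feature vectors", pid,
             length(unique(rois$roi_id)), nrow(feats))
  }
  rois_df <- do.call(rbind, all_rois)
  feats_df <- do.call(rbind, all_feats)
  rownames(rois_df) <- rownames(feats_df) <- NULL
  class(rois_df) <- c("roi_set", "data.frame")
  roi_path <- file.path(out_dir, "rois.csv")
  write_roi_csv(rois_df, roi_path)
  feat_path <- file.path(out_dir, "features.csv")
  utils::write.csv(feats_df, feat_path, row.names = FALSE)
  class(feats_df) <- c("roi_features", "data.frame")
  summ <- summarize_classes(feats_df)
  summ_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summ, summ_path, row.names = FALSE)
  list(rois = roi_path, features = feat_path, summary = summ_path,
       n_rois = length(unique(rois_df$roi_id)), n_features = nrow(feats_df))
}

#' Pipeline stage: fit QDA models and classify ROIs
#'
#' @param features_file Path to a `features.csv` written by [stage_roi()].
#' @param out_dir Output directory.
#' @param scope,shrinkage,priors QDA options, see [fit_qda()].
#' @param log_line Logging callback.
#' @return List with the model JSON and predictions CSV paths.
#' @export
stage_classify <- function(features_file, out_dir, scope = "per_plaque",
                           shrinkage = 0.1, priors = "empirical",
                           log_line = function(...) invisible()) {
  feats <- utils::read.csv(features_file, stringsAsFactors = FALSE)
  miss <- setdiff(c(qda_predictors(), "roi_id", "plaque_id", "tissue_label"),
                  names(feats))
  if (length(miss))
    stop("features file ", features_file, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  class(feats) <- c("roi_features", "data.frame")
  fit <- fit_qda(feats, scope = scope, shrinkage = shrinkage, priors = priors)
  preds <- classify_all(fit, feats)
  model_path <- file.path(out_dir, "qda_models.json")
  write_qda_json(fit, model_path)
  pred_path <- file.path(out_dir, "predictions.csv")
  utils::write.csv(as.data.frame(preds), pred_path, row.names = FALSE)
  if (!is.null(fit$not_applicable))
    for (i in seq_len(nrow(fit$not_applicable)))
      log_line("classify: scope %s excluded (%s)",
               fit$not_applicable$scope[i], fit$not_applicable$reason[i])
  log_line("classify: %d models, %d predictions, %d misclassified",
           length(fit$models), nrow(preds), sum(preds$misclassified))
  list(models = model_path, predictions = pred_path,
       n_models = length(fit$models),
       n_excluded = if (is.null(fit$not_applicable)) 0L
                    else nrow(fit$not_applicable))
}

#' Pipeline stage: misclassification report and scatter export
#'
#' Writes the per-plaque misclassification table (`report_per_plaque.csv`),
#' the overall report (`report.json`) and a scatter export of ROI-mean T1
#' vs T2* with misclassification flags (`scatter.csv`) for plotting.
#'
#' @param predictions_file `predictions.csv` from [stage_classify()].
#' @param models_file `qda_models.json` from [stage_classify()].
#' @param out_dir Output directory.
#' @param ci_level Confidence level of the t-interval, default 0.95.
#' @param features_file Optional `features.csv` for the scatter export
#'   (defaults to the one sitting next to `predictions_file`).
#' @param log_line Logging callback.
#' @return List of written report paths plus the report object.
#' @export
stage_report <- function(predictions_file, models_file, out_dir,
                         ci_level = 0.95, features_file = NULL,
                         log_line = function(...) invisible()) {
  preds <- utils::read.csv(predictions_file, stringsAsFactors = FALSE)
  fit <- read_qda_json(models_file)
  rep <- misclassification_report(preds, ci_level = ci_level,
                                  not_applicable = fit$not_applicable)
  per_path <- file.path(out_dir, "report_per_plaque.csv")
  utils::write.csv(rep$per_plaque, per_path, row.names = FALSE)
  rep_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(mean_rate = rep$mean_rate, ci_low = rep$ci_low,
         ci_high = rep$ci_high, ci_method = rep$ci_method,
         n_eligible_plaques = nrow(rep$per_plaque),
         excluded_plaques = rep$excluded_plaques,
         per_plaque = rep$per_plaque),
    rep_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(features_file))
    features_file <- file.path(dirname(predictions_file), "features.csv")
  scatter_path <- NULL
  if (file.exists(features_file)) {
    feats <- utils::read.csv(features_file, stringsAsFactors = FALSE)
    sc <- merge(feats[, c("roi_id", "plaque_id", "tissue_label",
                          "mean_t1", "mean_t2s")],
                preds[, c("roi_id", "predicted_label", "misclassified")],
                by = "roi_id", all.x = TRUE)
    sc <- sc[order(sc$plaque_id, sc$roi_id), ]
    scatter_path <- file.path(out_dir, "scatter.csv")
    utils::write.csv(sc, scatter_path, row.names = FALSE)
  }
  log_line("report: mean rate %.1f%% (CI %.1f-%.1f) over %d plaques",
           rep$mean_rate, rep$ci_low, rep$ci_high, nrow(rep$per_plaque))
  list(report = rep_path, per_plaque = per_path, scatter = scatter_path,
       mean_rate = rep$mean_rate)
}
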