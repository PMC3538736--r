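#' Write / read an ASL series as NIfTI plus a frame-label sidecar
#'
#' The frames are stored as a 4-d NIfTI volume (rows, cols, 1 slice, frames)
#' and the per-frame magnetic preparation as a CSV with columns
#' `frame_index` (1-based) and `preparation` (`M0`, `ssIR`, `nsIR`).
#'
#' @param series an [asl_series()].
#' @param nifti_path output `.nii`/`.nii.gz` path.
#' @param labels_path output CSV path.
#' @param pixel_size in-plane pixel size, mm.
#' @return invisibly, the two paths.
#' @export
write_asl_series <- function(series, nifti_path, labels_path, pixel_size = 0.5) {
  stopifnot(inherits(series, "asl_series"))
  d <- dim(series$frames)
  vol <- array(series$frames, dim = c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(vol, pixdim = c(pixel_size, pixel_size, 4,
                                         series$inter_image_time))
  RNifti::writeNifti(img, nifti_path)
  utils::write.csv(
    data.frame(frame_index = seq_len(d[3]), preparation = series$labels),
    labels_path, row.names = FALSE)
  invisible(c(nifti = nifti_path, labels = labels_path))
}

#' @rdname write_asl_series
#' @param ti inflow time, s (metadata, not stored in the NIfTI).
#' @param inter_image_time frame spacing, s.
#' @export
read_asl_series <- function(nifti_path, labels_path, ti = 1.2,
                            inter_image_time = 6) {
  vol <- as.array(RNifti::readNifti(nifti_path))
  if (length(dim(vol)) == 4L) {
    d <- dim(vol)
    vol <- array(vol, dim = c(d[1], d[2], d[4]))
  }
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("frame_index", "preparation") %in% names(lab)))
    stop("label CSV must have columns frame_index, preparation", call. = FALSE)
  if (nrow(lab) != dim(vol)[3])
    stop(sprintf("label CSV has %d rows but the series has %d frames",
                 nrow(lab), dim(vol)[3]), call. = FALSE)
  lab <- lab[order(lab$frame_index), ]
  asl_series(vol, lab$preparation, ti = ti, inter_image_time = inter_image_time)
}

#' Write / read a DCE series as 4-d NIfTI
#'
#' @param series a [dce_series()].
#' @param path output `.nii`/`.nii.gz` path.
#' @param pixel_size in-plane pixel size, mm.
#' @return invisibly, the path.
#' @export
write_dce_series <- function(series, path, pixel_size = 0.5) {
  stopifnot(inherits(series, "dce_series"))
  img <- RNifti::asNifti(series$volumes,
                         pixdim = c(pixel_size, pixel_size, 1.2, series$dt))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_dce_series
#' @param dt volume spacing, s; required on read (the pipeline takes it from
#'   its configuration rather than trusting header pixdims).
#' @param n_baseline pre-contrast volume count.
#' @export
read_dce_series <- function(path, dt, n_baseline) {
  if (missing(dt) || is.null(dt))
    stop("`dt` is required to read a DCE series; set it in the run config",
         call. = FALSE)
  vol <- as.array(RNifti::readNifti(path))
  vol <- array(as.numeric(vol), dim = dim(vol))
  dce_series(vol, dt = dt, n_baseline = n_baseline)
}

#' Write / read phantom masks as an integer label NIfTI
#'
#' Label codes as in [mask_labels()]: 0 background, 1 left cortex, 2 right
#' cortex, 3 left medulla, 4 right medulla, 5 aorta.
#'
#' @param truth a [make_phantom()] result (or an integer label matrix).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_mask_nifti <- function(truth, path) {
  lab <- if (inherits(truth, "ground_truth")) mask_labels(truth) else truth
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(lab), dim = dim(lab))),
                     path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  lab <- as.array(RNifti::readNifti(path))
  lab <- array(lab, dim = dim(lab)[1:2])
  list(cortex_left = lab == 1, cortex_right = lab == 2,
       medulla_left = lab == 3, medulla_right = lab == 4,
       aorta = lab == 5, labels = lab)
}

#' Default pipeline configuration
#'
#' All constants of the two quantification chains with the study defaults:
#' ASL inflow time 1.2 s, tissue T1 1.14 s, partition coefficient 0.8 ml/g;
#' DCE volume spacing 0.9 s, 15 baseline volumes, 50 first-pass volumes,
#' truncated-SVD cutoff 0.15. Values from a YAML file override these; any
#' `overrides` list wins over both.
#'
#' @param path optional YAML config path.
#' @param overrides optional named list of overrides.
#' @return nested configuration list.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1L,
    phantom = list(grid_shape = c(128L, 128L), f_cortex_left = 316,
                   f_cortex_right = 416, f_medulla = 150, m0_tissue = 100,
                   t1_tissue = 1.14, noise_sigma = 0.3),
    asl = list(ti = 1.2, t1 = 1.14, lambda = 0.8, n_pairs = 30L),
    dce = list(dt = 0.9, n_baseline = 15L, n_volumes = 50L,
               first_pass_volumes = 50L, threshold_fraction = 0.15,
               n_slices = 3L),
    stats = list(ddof_groups = 1L, ddof_diffs = 0L)
  )
  merge_list <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        merge_list(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_list(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_list(cfg, overrides)
  for (v in c(cfg$asl$ti, cfg$asl$t1, cfg$asl$lambda, cfg$dce$dt))
    stopifnot_scalar_pos(v, "config constant")
  cfg
}

#' Run the full simulate-quantify-compare pipeline
#'
#' Generates a seeded synthetic subject, quantifies it with both chains
#' (FAIR ASL and DCE deconvolution), summarises cortical ROIs, reproduces
#' the packaged per-animal table statistics, and writes every artefact
#' (series and map NIfTIs, frame-label and AIF CSVs, JSON report with a
#' provenance record) to `out_dir`. Deterministic for a fixed config and
#' seed.
#'
#' @param config a [run_config()] list.
#' @param out_dir output directory (created if needed).
#' @return the report list, invisibly; written as `report.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config

  if (cfg$dce$threshold_fraction == 0 && cfg$phantom$noise_sigma > 0)
    warning("threshold_fraction = 0: unregularised deconvolution of noisy data")

  spec <- phantom_spec(grid_shape = cfg$phantom$grid_shape,
                       f_cortex_left = cfg$phantom$f_cortex_left,
                       f_cortex_right = cfg$phantom$f_cortex_right,
                       f_medulla = cfg$phantom$f_medulla,
                       m0_tissue = cfg$phantom$m0_tissue,
                       t1_tissue = cfg$phantom$t1_tissue,
                       noise_sigma = cfg$phantom$noise_sigma,
                       seed = cfg$seed)
  truth <- make_phantom(spec)
  write_mask_nifti(truth, file.path(out_dir, "masks.nii.gz"))

  # --- ASL chain ---
  asl <- simulate_asl(truth, ti = cfg$asl$ti, n_pairs = cfg$asl$n_pairs,
                      lambda_bt = cfg$asl$lambda, seed = cfg$seed)
  write_asl_series(asl, file.path(out_dir, "asl_series.nii.gz"),
                   file.path(out_dir, "asl_labels.csv"))
  consts <- quant_constants(lambda_bt = cfg$asl$lambda, t1 = cfg$asl$t1)
  asl_map <- asl_quantify(asl, consts)
  RNifti::writeNifti(RNifti::asNifti(ifelse(asl_map$mask, asl_map$values, 0)),
                     file.path(out_dir, "asl_rbf.nii.gz"))
  asl_roi <- list(cortex_left = roi_mean(asl_map, truth$cortex_left),
                  cortex_right = roi_mean(asl_map, truth$cortex_right))

  # --- DCE chain ---
  dce <- simulate_dce(truth, dt = cfg$dce$dt, n_baseline = cfg$dce$n_baseline,
                      n_volumes = cfg$dce$n_volumes,
                      n_slices = cfg$dce$n_slices,
                      noise_sigma = cfg$phantom$noise_sigma,
                      seed = cfg$seed + 1L)
  write_dce_series(dce, file.path(out_dir, "dce_series.nii.gz"))
  quant_mask <- truth$cortex_left | truth$cortex_right |
    truth$medulla_left | truth$medulla_right
  dq <- dce_quantify(dce, truth$aorta, quant_mask,
                     first_pass_volumes = cfg$dce$first_pass_volumes,
                     threshold_fraction = cfg$dce$threshold_fraction)
  utils::write.csv(data.frame(time_s = dq$aif$times, conc = dq$aif$conc),
                   file.path(out_dir, "aif.csv"), row.names = FALSE)
  RNifti::writeNifti(
    RNifti::asNifti(ifelse(dq$maps[[1]]$mask, dq$maps[[1]]$values, 0)),
    file.path(out_dir, "dce_rbf.nii.gz"))
  dce_roi <- list(cortex_left = multislice_roi_mean(dq$maps, truth$cortex_left),
                  cortex_right = multislice_roi_mean(dq$maps, truth$cortex_right))

  # --- agreement statistics on the packaged per-animal tables ---
  stats_report <- table_report(read_rbf_table(), read_repeats_table())

  report <- list(
    provenance = list(package = "renperf",
                      version = as.character(utils::packageVersion("renperf")),
                      seed = cfg$seed, config = cfg),
    ground_truth = list(f_cortex_left = spec$f_cortex_left,
                        f_cortex_right = spec$f_cortex_right),
    asl = list(roi_means = asl_roi,
               lr_ratio = round(asl_roi$cortex_left / asl_roi$cortex_right, 2)),
    dce = list(roi_means = dce_roi,
               lr_ratio = round(dce_roi$cortex_left / dce_roi$cortex_right, 2)),
    table_stats = stats_report
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
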