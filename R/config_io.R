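#' Persist and reload a run configuration
#'
#' A [run_config()] is converted to a plain nested list (anchors, CVs,
#' acquisition, schedule, analysis parameters, seed) and written as YAML;
#' loading reconstructs an equivalent configuration, so a pipeline run is
#' reproducible from its persisted file.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `load_run_config()` returns a `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(serialize_run_config(config), path, precision = 15)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  deserialize_run_config(yaml::read_yaml(path))
}

serialize_run_config <- function(config) {
  cc <- config$cohort
  ser_kin <- function(kset) lapply(kset, function(k)
    list(tissue = k$tissue, time = k$anchors$time, suv = k$anchors$suv,
         interp = k$interp, subject_cv = k$subject_cv))
  list(
    n_attr = config$n_attr, n_non = config$n_non, seed = config$seed,
    cohort = list(
      grid_shape = cc$grid_shape, voxel_size_mm = cc$voxel_size_mm,
      acquisition = list(psf_fwhm_mm = cc$acquisition$psf_fwhm_mm,
                         sensitivity = cc$acquisition$sensitivity,
                         noise = cc$acquisition$noise),
      kinetics = lapply(cc$kinetics, ser_kin),
      dose_params = lapply(cc$dose_params, function(x)
        if (is.null(names(x))) x else as.list(x)),
      schedule = list(start_min = cc$schedule$start,
                      duration_min = cc$schedule$duration),
      units = cc$units, rho = cc$rho, half_life_min = cc$half_life_min),
    calibration = config$calibration,
    analysis = list(windows = config$analysis$windows,
                    k = config$analysis$k,
                    pid_threshold = config$analysis$pid_threshold,
                    classify_window = config$analysis$classify_window),
    out_dir = config$out_dir)
}

deserialize_run_config <- function(x) {
  des_kin <- function(l) lapply(l, function(k)
    tissue_kinetics(k$tissue, data.frame(time = unlist(k$time),
                                         suv = unlist(k$suv)),
                    interp = k$interp, subject_cv = k$subject_cv))
  dp <- lapply(x$cohort$dose_params, function(v)
    if (is.list(v)) unlist(v) else v)
  run_config(
    n_attr = x$n_attr, n_non = x$n_non, seed = x$seed,
    cohort = cohort_config(
      grid_shape = unlist(x$cohort$grid_shape),
      voxel_size_mm = x$cohort$voxel_size_mm,
      acquisition = acquisition_model(
        psf_fwhm_mm = x$cohort$acquisition$psf_fwhm_mm,
        sensitivity_cps_per_Bq_per_mL_per_voxel = x$cohort$acquisition$sensitivity,
        noise = x$cohort$acquisition$noise),
      kinetics = lapply(x$cohort$kinetics, des_kin),
      dose_params = dp,
      schedule = frame_schedule(unlist(x$cohort$schedule$start_min),
                                unlist(x$cohort$schedule$duration_min)),
      units = x$cohort$units, rho = x$cohort$rho,
      half_life_min = x$cohort$half_life_min),
    calibration = x$calibration,
    analysis = list(windows = lapply(x$analysis$windows, unlist),
                    k = x$analysis$k,
                    pid_threshold = x$analysis$pid_threshold,
                    classify_window = x$analysis$classify_window),
    out_dir = x$out_dir)
}
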