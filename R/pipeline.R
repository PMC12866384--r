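#' Run configuration for the end-to-end pipeline
#'
#' Bundles the cohort specification, the calibration-phantom specification
#' and the analysis parameters into a single reproducible configuration.
#' The configuration is plain data (no closures) and can be persisted with
#' [save_run_config()] and reloaded with [load_run_config()]; a run is
#' reproducible from the persisted configuration and its seed.
#'
#' @param n_attr,n_non cohort group sizes (defaults 8 and 11).
#' @param seed master seed for cohort generation and calibration noise.
#' @param cohort a [cohort_config()]; the pipeline generates count-rate
#'   images so that calibration is a real stage.
#' @param calibration list: `activity_MBq`, `volume_mL`, `duration_s` of
#'   the uniform calibration cylinder.
#' @param analysis list: `windows` (named list of `c(start, end)` minutes),
#'   `k` (segmentation threshold multiplier), `pid_threshold` (%ID/mL
#'   rule-in threshold), `classify_window` (window name used for the
#'   early-imaging classification).
#' @param out_dir optional output directory for tidy CSV tables.
#' @return A `run_config` object.
#' @export
run_config <- function(n_attr = 8, n_non = 11, seed = 1,
                       cohort = cohort_config(units = "counts/voxel/s"),
                       calibration = list(activity_MBq = 100, volume_mL = 5000,
                                          duration_s = 900),
                       analysis = list(
                         windows = list(`10` = c(10, 25), `30` = c(30, 45),
                                        `45` = c(45, 60), `90` = c(90, 105),
                                        `150` = c(150, 165)),
                         k = 1.0, pid_threshold = 0.003,
                         classify_window = "10"),
                       out_dir = NULL) {
  structure(list(n_attr = n_attr, n_non = n_non, seed = seed,
                 cohort = cohort, calibration = calibration,
                 analysis = analysis, out_dir = out_dir),
            class = "run_config")
}

# Small FNV-1a-style hash of the YAML form of the configuration,
# recorded in outputs.
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(serialize_run_config(config), precision = 15))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Quantify one subject's dynamic series
#'
#' Runs the per-subject analysis chain: calibration (if the image is in
#' count-rate units), decay correction to the dose assay time, myocardial
#' segmentation from the 150-min synthetic static by blood-pool
#' thresholding, VOI transfer, per-window synthetic statics, and the full
#' metric set (SUVmean, SUVmax, %ID/mL, myocardium/bone and
#' myocardium/blood-pool ratios).
#'
#' @param subject a `phantom_subject` (or list with `record` and `image`).
#' @param geometry the [build_phantom_geometry()] the subject was built on
#'   (supplies the anatomical LA_bp and LS VOIs and the myocardial search
#'   region).
#' @param cf a `calibration_factor`, required when the image is in
#'   counts/voxel/s.
#' @param windows named list of `c(start, end)` windows, minutes.
#' @param k segmentation threshold multiplier.
#' @param min_myo_voxels minimum volume (voxels) for the thresholded
#'   myocardial mask to be accepted as a contour; below this -- as for
#'   subjects whose myocardium never exceeds blood pool, where the
#'   threshold selects nothing or isolated noise voxels -- the anatomical
#'   myocardial VOI is used unchanged (see Details).
#' @param half_life_min physical half-life, minutes.
#' @param with_tac also extract per-frame time-activity curves?
#' @details The blood-pool-threshold contour is only meaningful when
#' myocardial activity exceeds the blood pool on the late image (uptake-
#' positive subjects); in uptake-negative subjects it would select nothing
#' or, with noise, speckle. Threshold contouring is therefore applied only
#' when the anatomical myocardial VOI mean exceeds `k` times the
#' blood-pool mean on the late image and the resulting contour has at
#' least `min_myo_voxels` voxels; otherwise the anatomical myocardial VOI
#' is used directly, mirroring CT-guided VOI placement in uptake-negative
#' subjects. The returned mask's `fallback` attribute records this.
#'
#' @return List with `quant` (long data.frame: one row per window x VOI),
#'   `metrics` (one row per window: myocardial metrics and ratios),
#'   `myo_mask` (the segmented [voi_mask()]) and optionally `tac`.
#' @export
quantify_subject <- function(subject, geometry, cf = NULL,
                             windows = list(`10` = c(10, 25), `30` = c(30, 45),
                                            `45` = c(45, 60), `90` = c(90, 105),
                                            `150` = c(150, 165)),
                             k = 1.0, min_myo_voxels = 30,
                             half_life_min = 360.4, with_tac = FALSE) {
  record <- subject$record
  image <- subject$image
  if (identical(image$units, "counts/voxel/s")) {
    if (is.null(cf)) stop("count-rate image requires a calibration factor")
    image <- apply_calibration(image, cf)
  }
  dose <- net_injected_activity(record, half_life_min = half_life_min)
  image <- decay_correct_image(image, dose$reference_time_min, half_life_min)

  late <- synthesize_static(image, 150, 165)
  # threshold contouring is only applicable when the myocardium as a whole
  # exceeds the blood-pool threshold on the late image (uptake-positive
  # pattern); otherwise the threshold selects nothing or noise speckle
  anat_mean <- voi_statistics(late, geometry$labels$LV_myo)$mean
  bp_mean <- voi_statistics(late, geometry$labels$LA_bp)$mean
  myo_mask <- NULL
  if (anat_mean > k * bp_mean)
    myo_mask <- tryCatch(
      segment_myocardium(late, geometry$labels$LA_bp,
                         geometry$labels$LV_myo, k = k),
      error = function(e) NULL)
  if (is.null(myo_mask) || sum(myo_mask$mask) < min_myo_voxels) {
    # threshold found no credible myocardial contour (uptake at or below
    # blood pool): fall back to the anatomical (CT-derived) myocardial VOI
    myo_mask <- voi_mask("LV_myo", geometry$labels$LV_myo,
                         source_image_id = "anatomical prior (threshold below blood pool)")
    attr(myo_mask, "k") <- k
    attr(myo_mask, "fallback") <- TRUE
  }
  masks <- list(LV_myo = myo_mask$mask, LA_bp = geometry$labels$LA_bp,
                LS = geometry$labels$LS)

  quant <- list(); metrics <- list()
  for (wn in names(windows)) {
    w <- windows[[wn]]
    st <- synthesize_static(image, w[1], w[2])
    sv <- lapply(masks, function(m) {
      s <- voi_statistics(st, m)
      list(mean = suv(s$mean, dose, record$weight_kg),
           max = suv(s$max, dose, record$weight_kg),
           volume_mL = s$volume_mL)
    })
    quant[[wn]] <- data.frame(
      subject_id = record$subject_id, group = record$group, window = wn,
      window_start = w[1], window_end = w[2], voi = names(masks),
      suv_mean = vapply(sv, `[[`, numeric(1), "mean"),
      suv_max = vapply(sv, `[[`, numeric(1), "max"),
      volume_mL = vapply(sv, `[[`, numeric(1), "volume_mL"))
    rat <- uptake_ratios(sv$LV_myo$mean, sv$LS$mean, sv$LA_bp$mean)
    metrics[[wn]] <- data.frame(
      subject_id = record$subject_id, group = record$group, window = wn,
      suv_mean_myo = sv$LV_myo$mean, suv_max_myo = sv$LV_myo$max,
      suv_mean_bp = sv$LA_bp$mean, suv_mean_bone = sv$LS$mean,
      pid_per_ml = percent_id_per_ml(sv$LV_myo$mean, record$weight_kg),
      ratio_myo_bone = rat$ratio_myo_bone, ratio_myo_bp = rat$ratio_myo_bp)
  }
  out <- list(quant = do.call(rbind, c(quant, make.row.names = FALSE)),
              metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
              myo_mask = myo_mask)
  if (with_tac)
    out$tac <- extract_tac(image, masks, dose, record$weight_kg)
  out
}

#' Run the full generate-calibrate-segment-quantify-classify pipeline
#'
#' Generates the synthetic cohort subject by subject (seeds derived from
#' the master seed exactly as in [generate_cohort()]), measures a
#' calibration factor from a simulated uniform cylinder under the same
#' acquisition model, quantifies every subject over the reporting windows,
#' classifies each subject at the early window with both quantitative
#' rules, and scores performance against the generator's group labels.
#'
#' @param config a [run_config()].
#' @return A `cohort_report`: list with `quant` (long per-subject,
#'   per-window, per-VOI table), `metrics` (per-subject, per-window
#'   myocardial metrics), `group_summary` (mean/SD/95% CI per group x
#'   window x VOI x metric), `diagnoses`, `performance` (per rule),
#'   `tac` (per-subject time-activity curves), `cf`, `config_hash`,
#'   `config`. With `config$out_dir` set, tidy CSVs are also written.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cc <- config$cohort
  geometry <- build_phantom_geometry(cc$grid_shape, cc$voxel_size_mm)
  hash <- config_hash(config)

  cyl <- simulate_uniform_cylinder(
    config$calibration$activity_MBq, config$calibration$volume_mL,
    grid_shape = cc$grid_shape, voxel_size_mm = cc$voxel_size_mm,
    acquisition = cc$acquisition, duration_s = config$calibration$duration_s,
    seed = derive_seed(config$seed, 999983L))
  cf <- compute_calibration_factor(cyl$image, cyl$mask,
                                   config$calibration$activity_MBq,
                                   config$calibration$volume_mL,
                                   acquisition_mode = "static")

  groups <- c(rep("ATTR", config$n_attr), rep("non-ATTR", config$n_non))
  quant <- list(); metrics <- list(); tacs <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    subj <- generate_subject(
      g, geometry, kinetics_set = cc$kinetics[[g]],
      acquisition = cc$acquisition, dose_params = cc$dose_params,
      seed = derive_seed(config$seed, i), schedule = cc$schedule,
      units = cc$units, rho = cc$rho, half_life_min = cc$half_life_min,
      subject_id = sprintf("S%02d_%s", i, sub("-", "", g)))
    res <- quantify_subject(subj, geometry,
                            cf = if (identical(cc$units, "counts/voxel/s")) cf,
                            windows = config$analysis$windows,
                            k = config$analysis$k,
                            half_life_min = cc$half_life_min, with_tac = TRUE)
    quant[[i]] <- res$quant; metrics[[i]] <- res$metrics
    tc <- res$tac
    tc$subject_id <- subj$record$subject_id; tc$group <- g
    tacs[[i]] <- tc
    rm(subj, res); gc(verbose = FALSE)
  }
  quant <- do.call(rbind, c(quant, make.row.names = FALSE))
  metrics <- do.call(rbind, c(metrics, make.row.names = FALSE))
  tac <- do.call(rbind, c(tacs, make.row.names = FALSE))

  group_summary <- summarize_groups(quant)

  cw <- config$analysis$classify_window
  mcw <- metrics[metrics$window == cw, ]
  mcw <- mcw[order(mcw$subject_id), ]
  diagnoses <- do.call(rbind, lapply(seq_len(nrow(mcw)), function(j) {
    bp <- classify_blood_pool_grade(mcw$suv_mean_myo[j], mcw$suv_mean_bp[j],
                                    mcw$subject_id[j], cw)
    pid <- classify_pid(mcw$pid_per_ml[j], config$analysis$pid_threshold,
                        mcw$subject_id[j], cw)
    data.frame(subject_id = mcw$subject_id[j], group = mcw$group[j],
               window = cw,
               rule = c(bp$rule, pid$rule), label = c(bp$label, pid$label))
  }))
  truth <- mcw$group == "ATTR"
  performance <- list(
    blood_pool_grade = diagnostic_performance(
      diagnoses$label[diagnoses$rule == "blood_pool_grade"] == "positive", truth),
    pid_threshold = diagnostic_performance(
      diagnoses$label[diagnoses$rule == "pid_threshold"] == "positive", truth))

  report <- structure(list(quant = quant, metrics = metrics,
                           group_summary = group_summary,
                           diagnoses = diagnoses, performance = performance,
                           tac = tac, cf = cf, config_hash = hash,
                           config = config),
                      class = "cohort_report")
  if (!is.null(config$out_dir)) write_report_csv(report, config$out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report [config %s]: %d subjects, %d windows\n",
              x$config_hash, length(unique(x$quant$subject_id)),
              length(unique(x$quant$window))))
  perf <- x$performance$blood_pool_grade
  cat(sprintf("  blood-pool grade @ early window: sens %.1f%% spec %.1f%% acc %.1f%%\n",
              perf$sensitivity, perf$specificity, perf$accuracy))
  invisible(x)
}

#' Group summary table (mean, SD, t-based 95% CI)
#'
#' Summarises the long per-subject quantitation table per group x window x
#' VOI x metric. Confidence intervals use the t distribution; a
#' single-subject group gets `NA` CIs (flagged by `ci_defined`).
#'
#' @param quant the `quant` table from [run_pipeline()] /
#'   [quantify_subject()] (columns `group`, `window`, `voi`, `suv_mean`,
#'   `suv_max`).
#' @param conf confidence level (default 0.95).
#' @return Tidy data.frame: `group`, `window`, `voi`, `metric`, `n`,
#'   `mean`, `sd`, `ci_lo`, `ci_hi`, `ci_defined`.
#' @export
summarize_groups <- function(quant, conf = 0.95) {
  stopifnot(nrow(quant) >= 1)
  rows <- list()
  for (metric in c("suv_mean", "suv_max")) {
    agg <- stats::aggregate(quant[[metric]],
                            by = quant[c("group", "window", "voi")],
                            FUN = function(v) c(n = length(v), mean = mean(v),
                                                sd = stats::sd(v)))
    m <- as.data.frame(agg$x)
    n <- m$n; mu <- m$mean; s <- m$sd
    half <- ifelse(n >= 2, stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n), NA)
    rows[[metric]] <- data.frame(agg[c("group", "window", "voi")],
                                 metric = metric, n = n, mean = mu, sd = s,
                                 ci_lo = mu - half, ci_hi = mu + half,
                                 ci_defined = n >= 2)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$metric, out$group, out$window, out$voi), , drop = FALSE]
}

#' Write a cohort report as tidy CSV tables
#'
#' Writes `quant.csv`, `metrics.csv`, `group_summary.csv`, `diagnoses.csv`,
#' `performance.csv` and `tac.csv` under `dir`, each carrying the
#' configuration hash in a `config_hash` column.
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  add_hash <- function(df) { df$config_hash <- report$config_hash; df }
  perf <- do.call(rbind, lapply(names(report$performance), function(r) {
    p <- report$performance[[r]]
    data.frame(rule = r, TP = p$TP, FP = p$FP, TN = p$TN, FN = p$FN,
               sensitivity = p$sensitivity, specificity = p$specificity,
               accuracy = p$accuracy)
  }))
  tabs <- list(quant = report$quant, metrics = report$metrics,
               group_summary = report$group_summary,
               diagnoses = report$diagnoses, performance = perf,
               tac = report$tac)
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(add_hash(tabs[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Plot group time-activity curves
#'
#' Base-graphics rendering of per-group mean SUVmean (or SUVmax) curves
#' for the three analysis VOIs, regenerated from the tidy TAC table.
#'
#' @param tac the `tac` table from [run_pipeline()].
#' @param metric `"suv_mean"` or `"suv_max"`.
#' @param max_time_min right edge of the time axis (default 65).
#' @return Invisibly, the plotted group-mean table.
#' @export
plot_group_tac <- function(tac, metric = c("suv_mean", "suv_max"),
                           max_time_min = 65) {
  metric <- match.arg(metric)
  tac <- tac[tac$time_min <= max_time_min, ]
  agg <- stats::aggregate(tac[[metric]],
                          by = tac[c("group", "voi", "time_min")], FUN = mean)
  cols <- c(LV_myo = "firebrick", LA_bp = "steelblue", LS = "darkolivegreen")
  groups <- unique(agg$group)
  graphics::par(mfrow = c(1, length(groups)))
  for (g in groups) {
    sub <- agg[agg$group == g, ]
    graphics::plot(NULL, xlim = c(0, max_time_min), ylim = c(0, max(sub$x) * 1.1),
                   xlab = "Time post-injection (min)", ylab = toupper(metric),
                   main = g)
    for (v in unique(sub$voi)) {
      sv <- sub[sub$voi == v, ]
      graphics::lines(sv$time_min, sv$x, col = cols[[v]] %||% "grey30", lwd = 2)
      graphics::points(sv$time_min, sv$x, col = cols[[v]] %||% "grey30", pch = 16,
                       cex = 0.6)
    }
    graphics::legend("topright", legend = unique(sub$voi), lwd = 2,
                     col = cols[unique(sub$voi)], bty = "n")
  }
  invisible(agg)
}
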