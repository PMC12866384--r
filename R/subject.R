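#' Subject dose/weight bookkeeping record
#'
#' Holds the per-subject quantities needed for SUV and %ID/mL: body weight,
#' the pre-injection syringe assay (activity and time), the post-injection
#' residual assay, and the injection time. All times are minutes relative
#' to injection (injection time = 0 by convention).
#'
#' @param subject_id character id.
#' @param group `"ATTR"` or `"non-ATTR"`.
#' @param weight_kg body weight, kg (> 0).
#' @param assay_activity_MBq pre-injection syringe assay, MBq.
#' @param assay_time_min time of the assay (<= injection time).
#' @param residual_activity_MBq post-injection residual syringe assay, MBq.
#' @param residual_time_min time of the residual assay (>= injection time).
#' @param injection_time_min tracer administration time (default 0).
#' @return A `subject_record` object.
#' @export
subject_record <- function(subject_id, group, weight_kg,
                           assay_activity_MBq, assay_time_min,
                           residual_activity_MBq, residual_time_min,
                           injection_time_min = 0) {
  group <- match.arg(group, c("ATTR", "non-ATTR"))
  if (weight_kg <= 0) stop("weight_kg must be > 0")
  if (!(assay_activity_MBq > residual_activity_MBq && residual_activity_MBq >= 0))
    stop("need assay_activity_MBq > residual_activity_MBq >= 0")
  if (!(assay_time_min <= injection_time_min &&
        injection_time_min <= residual_time_min))
    stop("need assay_time_min <= injection_time_min <= residual_time_min")
  structure(list(subject_id = subject_id, group = group, weight_kg = weight_kg,
                 assay_activity_MBq = assay_activity_MBq,
                 assay_time_min = assay_time_min,
                 residual_activity_MBq = residual_activity_MBq,
                 residual_time_min = residual_time_min,
                 injection_time_min = injection_time_min),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s [%s]: %.1f kg, assay %.1f MBq @ %.3g min, residual %.2f MBq @ %.3g min\n",
              x$subject_id, x$group, x$weight_kg, x$assay_activity_MBq,
              x$assay_time_min, x$residual_activity_MBq, x$residual_time_min))
  invisible(x)
}

#' Default dose/weight sampling parameters
#'
#' Group body-weight distributions and the injected-activity assay
#' distribution follow the emulated cohort's published mean +/- SD values
#' (weights 79.1 +/- 17.2 kg ATTR, 89.0 +/- 15.8 kg non-ATTR; assay
#' 887.9 +/- 84.8 MBq). Residual-syringe parameters and assay/residual
#' times are package defaults. Sampling is normal, truncated at +/- 3 SD.
#'
#' @return Named list of sampling parameters.
#' @export
default_dose_params <- function() {
  list(weight_mean_kg = c(ATTR = 79.1, `non-ATTR` = 89.0),
       weight_sd_kg = c(ATTR = 17.2, `non-ATTR` = 15.8),
       assay_mean_MBq = 887.9, assay_sd_MBq = 84.8,
       residual_mean_MBq = 10, residual_sd_MBq = 4,
       assay_time_min = -30, residual_time_min = 5)
}

# Normal sampling truncated at mean +/- 3 SD (and an optional hard floor),
# by resampling.
rnorm_trunc <- function(n, mean, sd, lower = mean - 3 * sd,
                        upper = mean + 3 * sd) {
  x <- stats::rnorm(n, mean, sd)
  for (k in 1:100) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

# --- inter-subject multiplier model ----------------------------------------
#
# Per subject, each tissue gets a multiplicative log-normal scale
#   m_t = exp(-sigma_t^2/2 + delta_t + sigma_t * (sqrt(rho) z0 + sqrt(1-rho) z_t))
# with a shared standard-normal component z0 (log-scale correlation rho
# across tissues) and tissue components z_t. sigma_t is set from the
# configured CV. Subjects violating their group's defining uptake ordering
# (ATTR: myocardium >= blood pool at all frame midpoints >= 10 min;
# non-ATTR: blood pool > myocardium at all frame midpoints) are resampled,
# and delta_t is the closed-form (Mills-ratio) offset that makes the
# ACCEPTED population's mean multiplier exactly 1 per tissue, so group
# anchor recovery is unbiased despite the selection.

lognormal_sigma <- function(cv) sqrt(log(1 + cv^2))

group_ordering <- function(group) {
  if (group == "ATTR")
    list(num = "myocardium", den = "blood", min_time = 10, strict = FALSE)
  else
    list(num = "blood", den = "myocardium", min_time = -Inf, strict = TRUE)
}

# Times at which the ordering is enforced: frame midpoints of frames whose
# start is >= min_time.
ordering_times <- function(schedule, min_time) {
  schedule$mid[schedule$start >= min_time - 1e-9]
}

# Closed-form selection compensation. Returns delta per tissue.
selection_compensation <- function(sigmas, rho, c_crit, num, den) {
  delta <- stats::setNames(rep(0, length(sigmas)), names(sigmas))
  sn <- sigmas[[num]]; sd_ <- sigmas[[den]]
  varD <- sd_^2 + sn^2 - 2 * rho * sd_ * sn
  if (varD <= 0) return(delta)           # degenerate: ordering deterministic
  sD <- sqrt(varD)
  covs <- vapply(names(sigmas), function(t) {
    st <- sigmas[[t]]
    if (t == den) st * (sd_ - rho * sn)
    else if (t == num) st * (rho * sd_ - sn)
    else st * rho * (sd_ - sn)
  }, numeric(1))
  for (it in 1:200) {
    muD <- (delta[[den]] - delta[[num]]) + (sn^2 - sd_^2) / 2
    alpha <- (c_crit - muD) / sD
    R <- stats::pnorm(alpha - covs / sD) / stats::pnorm(alpha)
    new_delta <- -log(R)
    if (max(abs(new_delta - delta)) < 1e-12) { delta <- new_delta; break }
    delta <- new_delta
  }
  delta
}

# Draw one subject's tissue multipliers (rejection-resampled; uses the
# current RNG stream). tacs: named list of curve functions.
draw_subject_multipliers <- function(kinetics_set, tacs, schedule,
                                     group, rho = 0.8) {
  tissues <- names(kinetics_set)
  sigmas <- lapply(kinetics_set, function(k) lognormal_sigma(k$subject_cv))
  ord <- group_ordering(group)
  tt <- ordering_times(schedule, ord$min_time)
  ok_order <- function(m) {
    lhs <- tacs[[ord$num]](tt) * m[[ord$num]]
    rhs <- tacs[[ord$den]](tt) * m[[ord$den]]
    if (ord$strict) all(lhs > rhs) else all(lhs >= rhs)
  }
  # critical log-ratio bound for the compensation
  c_crit <- min(log(tacs[[ord$num]](tt) / tacs[[ord$den]](tt)))
  delta <- selection_compensation(sigmas, rho, c_crit, ord$num, ord$den)
  for (try in 1:500) {
    z0 <- stats::rnorm(1)
    m <- vapply(tissues, function(t) {
      s <- sigmas[[t]]
      if (s == 0) return(1)
      exp(-s^2 / 2 + delta[[t]] + s * (sqrt(rho) * z0 +
                                         sqrt(1 - rho) * stats::rnorm(1)))
    }, numeric(1))
    if (ok_order(as.list(m))) return(m)
  }
  stop("could not draw ordering-consistent subject multipliers in 500 tries")
}

#' Generate one synthetic subject (record + dynamic image)
#'
#' Samples a [subject_record()] from `dose_params`, draws per-tissue
#' multiplicative scales (see Details), and fills the phantom geometry at
#' every frame midpoint with the true activity concentration
#' `C(t) = SUV_tissue(t) * m_tissue * ID_Bq / (weight_kg * 1000)` Bq/mL,
#' decayed physically from the dose reference (assay) time, then passes
#' each frame through the acquisition model (optional Gaussian blur and
#' Poisson count resampling).
#'
#' @details The per-subject, per-tissue scales are log-normal with the CVs
#' configured in `kinetics_set`, correlated across tissues on the log scale
#' (`rho`), rejection-resampled so every subject satisfies its group's
#' defining uptake ordering, with a closed-form offset that keeps the
#' accepted population's mean scale at exactly 1 per tissue.
#'
#' @param group `"ATTR"` or `"non-ATTR"`.
#' @param geometry a [build_phantom_geometry()] result.
#' @param kinetics_set named list of [tissue_kinetics()] covering tissues
#'   `myocardium`, `blood` and `bone` (plus optional `body`);
#'   see [default_tissue_kinetics()].
#' @param acquisition an [acquisition_model()].
#' @param dose_params see [default_dose_params()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param schedule a [frame_schedule()].
#' @param units output image units: `"Bq/mL"` (noisy concentration) or
#'   `"counts/voxel/s"` (count-rate image for the calibration pipeline).
#' @param rho log-scale correlation of tissue scales within subject.
#' @param half_life_min physical half-life (default 360.4 min, 99mTc).
#' @param subject_id id string.
#' @return A `phantom_subject`: list with `record`, `image` (a
#'   [dynamic_image()]), `multipliers`, and `true_suv` (function
#'   `(tissue, t)` giving the subject's noise-free SUV curve).
#' @export
generate_subject <- function(group, geometry, kinetics_set = default_tissue_kinetics(group),
                             acquisition = acquisition_model(),
                             dose_params = default_dose_params(), seed = NULL,
                             schedule = default_frame_schedule(),
                             units = c("Bq/mL", "counts/voxel/s"),
                             rho = 0.8, half_life_min = 360.4,
                             subject_id = paste0(substr(group, 1, 1), "001")) {
  units <- match.arg(units)
  group <- match.arg(group, c("ATTR", "non-ATTR"))
  needed <- unique(region_tissue_map()[c("LV_myo", "LV_bp", "LA_bp", "LS")])
  missing <- setdiff(needed, names(kinetics_set))
  if (length(missing))
    stop("kinetics_set missing tissue(s): ", paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  w <- rnorm_trunc(1, dose_params$weight_mean_kg[[group]],
                   dose_params$weight_sd_kg[[group]],
                   lower = max(1, dose_params$weight_mean_kg[[group]] -
                                 3 * dose_params$weight_sd_kg[[group]]))
  assay <- rnorm_trunc(1, dose_params$assay_mean_MBq, dose_params$assay_sd_MBq)
  resid <- rnorm_trunc(1, dose_params$residual_mean_MBq,
                       dose_params$residual_sd_MBq,
                       lower = max(0, dose_params$residual_mean_MBq -
                                     3 * dose_params$residual_sd_MBq))
  record <- subject_record(subject_id, group, w, assay,
                           dose_params$assay_time_min, resid,
                           dose_params$residual_time_min)
  dose <- net_injected_activity(record, half_life_min = half_life_min)

  tacs <- lapply(kinetics_set, make_tissue_tac)
  m <- draw_subject_multipliers(kinetics_set, tacs, schedule, group, rho)

  # region voxel index sets; soft tissue = body minus all labelled tissues
  lab <- geometry$labels
  soft <- lab$body & !(lab$LV_myo | lab$LV_bp | lab$LA_bp | lab$LS)
  reg_idx <- list(LV_myo = which(lab$LV_myo), LV_bp = which(lab$LV_bp),
                  LA_bp = which(lab$LA_bp), LS = which(lab$LS),
                  body = which(soft))
  rmap <- region_tissue_map()

  suv_to_conc <- dose$injected_activity_Bq / (record$weight_kg * 1000)
  d3 <- dim(lab$body)
  nfr <- nrow(schedule)
  data <- array(0, dim = c(d3, nfr))
  frame_len <- prod(d3)
  for (i in seq_len(nfr)) {
    t_mid <- schedule$mid[i]
    fr <- array(0, dim = d3)
    for (reg in names(reg_idx)) {
      tis <- rmap[[reg]]
      if (!tis %in% names(tacs)) next   # body kinetics optional
      fr[reg_idx[[reg]]] <- tacs[[tis]](t_mid) * m[[tis]] * suv_to_conc
    }
    # physical decay from the dose reference (assay) time to scan time
    fr <- fr * 2^(-(t_mid - record$assay_time_min) / half_life_min)
    fr <- measure_frame(fr, acquisition, schedule$duration[i] * 60,
                        geometry$voxel_size_mm, units = units)
    data[(i - 1) * frame_len + seq_len(frame_len)] <- fr
  }
  image <- dynamic_image(data, geometry$voxel_size_mm, schedule, units = units,
                         decay_corrected = FALSE)
  structure(list(record = record, image = image, multipliers = m,
                 true_suv = function(tissue, t) tacs[[tissue]](t) * m[[tissue]]),
            class = "phantom_subject")
}

#' Generate a synthetic two-group cohort
#'
#' Generates `n_attr` ATTR-CM and `n_non` non-ATTR-CM subjects (defaults
#' mirror the emulated study: 8 and 11) over a shared phantom geometry,
#' with per-subject seeds derived deterministically from `seed`.
#'
#' @param n_attr,n_non group sizes (>= 0).
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @return A `phantom_cohort`: list with `subjects` (list of
#'   `phantom_subject`), `geometry` and `config`.
#' @export
generate_cohort <- function(n_attr = 8, n_non = 11, config = cohort_config(),
                            seed = 1) {
  stopifnot(n_attr >= 0, n_non >= 0)
  geometry <- build_phantom_geometry(config$grid_shape, config$voxel_size_mm)
  groups <- c(rep("ATTR", n_attr), rep("non-ATTR", n_non))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    subjects[[i]] <- generate_subject(
      g, geometry, kinetics_set = config$kinetics[[g]],
      acquisition = config$acquisition, dose_params = config$dose_params,
      seed = derive_seed(seed, i), schedule = config$schedule,
      units = config$units, rho = config$rho,
      half_life_min = config$half_life_min,
      subject_id = sprintf("S%02d_%s", i, sub("-", "", g)))
  }
  structure(list(subjects = subjects, geometry = geometry, config = config,
                 seed = seed),
            class = "phantom_cohort")
}

#' Cohort generation configuration
#'
#' @param grid_shape,voxel_size_mm phantom grid (see
#'   [build_phantom_geometry()]).
#' @param acquisition an [acquisition_model()].
#' @param kinetics named list with elements `ATTR` and `non-ATTR`, each a
#'   kinetics set as from [default_tissue_kinetics()].
#' @param dose_params see [default_dose_params()].
#' @param schedule a [frame_schedule()].
#' @param units image units emitted by the generator.
#' @param rho log-scale correlation of per-subject tissue scales.
#' @param half_life_min physical half-life, minutes.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(grid_shape = 64, voxel_size_mm = 4.92,
                          acquisition = acquisition_model(),
                          kinetics = list(
                            ATTR = default_tissue_kinetics("ATTR"),
                            `non-ATTR` = default_tissue_kinetics("non-ATTR")),
                          dose_params = default_dose_params(),
                          schedule = default_frame_schedule(),
                          units = "Bq/mL", rho = 0.8, half_life_min = 360.4) {
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 acquisition = acquisition, kinetics = kinetics,
                 dose_params = dose_params, schedule = schedule,
                 units = units, rho = rho, half_life_min = half_life_min),
            class = "cohort_config")
}

# Deterministic per-subject seed derivation, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer(((seed %% 2147483647) * 48271 + i * 1299709) %% 2147483647)
}
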