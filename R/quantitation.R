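#' Radioactive decay correction
#'
#' Rescales a measured activity concentration from measurement time `t_min`
#' to the decay reference time: `C_corr = C * 2^((t - t_ref) / T_half)`.
#' (Activity measured later than the reference is scaled up.)
#'
#' @param concentration measured concentration (any activity unit).
#' @param t_min measurement time, minutes.
#' @param reference_time_min decay reference time, minutes.
#' @param half_life_min physical half-life, minutes (default 360.4, 99mTc).
#' @return Decay-corrected concentration.
#' @examples
#' decay_correct(100, 360.4, 0)   # one half-life later -> 200
#' @export
decay_correct <- function(concentration, t_min, reference_time_min,
                          half_life_min = 360.4) {
  if (half_life_min <= 0) stop("half_life_min must be > 0")
  concentration * 2^((t_min - reference_time_min) / half_life_min)
}

#' Net injected activity from syringe assays
#'
#' The residual activity measured after injection is decay-corrected back
#' to the assay time and subtracted from the pre-injection assay:
#' `ID = A_assay - A_residual * 2^((t_residual - t_assay) / T_half)`.
#' The resulting dose is referenced to the assay time, the reference used
#' for all decay corrections downstream.
#'
#' @param subject a [subject_record()].
#' @param half_life_min physical half-life, minutes.
#' @return A `dose_record`: list with `injected_activity_Bq`,
#'   `reference_time_min` and `half_life_min`.
#' @export
net_injected_activity <- function(subject, half_life_min = 360.4) {
  stopifnot(inherits(subject, "subject_record"))
  resid_at_assay <- decay_correct(subject$residual_activity_MBq,
                                  subject$residual_time_min,
                                  subject$assay_time_min, half_life_min)
  id_MBq <- subject$assay_activity_MBq - resid_at_assay
  if (id_MBq <= 0)
    stop("net injected activity is not positive (residual exceeds assay after decay referencing)")
  structure(list(injected_activity_Bq = id_MBq * 1e6,
                 reference_time_min = subject$assay_time_min,
                 half_life_min = half_life_min),
            class = "dose_record")
}

#' @rdname net_injected_activity
#' @param injected_activity_Bq net injected activity, Bq.
#' @param reference_time_min decay reference time of the dose.
#' @export
dose_record <- function(injected_activity_Bq, reference_time_min = 0,
                        half_life_min = 360.4) {
  if (injected_activity_Bq <= 0) stop("injected_activity_Bq must be > 0")
  if (half_life_min <= 0) stop("half_life_min must be > 0")
  structure(list(injected_activity_Bq = injected_activity_Bq,
                 reference_time_min = reference_time_min,
                 half_life_min = half_life_min),
            class = "dose_record")
}

#' Standardized uptake value
#'
#' `SUV = C * (weight_kg * 1000) / ID`, with the activity concentration `C`
#' (Bq/mL) already decay-corrected to the dose reference time and a tissue
#' density of 1 g/mL assumed, giving SUV in g/mL.
#'
#' @param concentration_Bq_per_mL decay-corrected concentration, Bq/mL.
#' @param dose a [dose_record()].
#' @param weight_kg body weight, kg.
#' @return SUV (g/mL).
#' @export
suv <- function(concentration_Bq_per_mL, dose, weight_kg) {
  if (weight_kg <= 0) stop("weight_kg must be > 0")
  if (dose$injected_activity_Bq <= 0) stop("dose must be > 0")
  concentration_Bq_per_mL * (weight_kg * 1000) / dose$injected_activity_Bq
}

#' Percent injected dose per millilitre
#'
#' `%ID/mL = 100 * SUVmean / (weight_kg * 1000)`: the percentage of the net
#' injected dose residing in one millilitre of tissue. Reported as a
#' percentage (0.005 means 0.005%).
#'
#' @param suv_mean myocardial SUVmean (g/mL).
#' @param weight_kg body weight, kg.
#' @return %ID/mL (percent).
#' @examples
#' percent_id_per_ml(3.86, 79.1)
#' @export
percent_id_per_ml <- function(suv_mean, weight_kg) {
  if (any(suv_mean < 0) || any(weight_kg <= 0)) stop("inputs must be positive")
  100 * suv_mean / (weight_kg * 1000)
}

#' Calibration-independent uptake ratios
#'
#' @param suv_myo,suv_bone,suv_bp SUVmean of myocardium, bone (lower
#'   thoracic spine) and blood pool (left atrium).
#' @return Named list `ratio_myo_bone`, `ratio_myo_bp`.
#' @export
uptake_ratios <- function(suv_myo, suv_bone, suv_bp) {
  if (any(suv_bone <= 0) || any(suv_bp <= 0))
    stop("ratio denominators must be > 0")
  list(ratio_myo_bone = suv_myo / suv_bone, ratio_myo_bp = suv_myo / suv_bp)
}

#' Activity unit conversion
#'
#' Exact conversions among Bq, kBq, MBq and mCi (1 mCi = 37 MBq).
#'
#' @param value numeric value(s).
#' @param from_unit,to_unit one of `"Bq"`, `"kBq"`, `"MBq"`, `"mCi"`.
#' @return Converted value(s).
#' @examples
#' activity_unit_convert(887.9, "MBq", "mCi")
#' @export
activity_unit_convert <- function(value, from_unit, to_unit) {
  to_Bq <- c(Bq = 1, kBq = 1e3, MBq = 1e6, mCi = 37e6)
  if (!from_unit %in% names(to_Bq)) stop("unknown unit: ", from_unit)
  if (!to_unit %in% names(to_Bq)) stop("unknown unit: ", to_unit)
  value * to_Bq[[from_unit]] / to_Bq[[to_unit]]
}
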