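#' Decay-correct a calibrated image series
#'
#' Applies [decay_correct()] frame-by-frame (using frame midpoints) or to a
#' static image (using its representative time), tagging the result with
#' the reference time.
#'
#' @param image a [dynamic_image()] or [static_image()] in Bq/mL.
#' @param reference_time_min decay reference time (the dose assay time).
#' @param half_life_min physical half-life, minutes.
#' @return The decay-corrected image.
#' @export
decay_correct_image <- function(image, reference_time_min,
                                half_life_min = 360.4) {
  if (!identical(image$units, "Bq/mL"))
    stop("decay correction expects a calibrated image (Bq/mL), got ", image$units)
  if (isTRUE(image$decay_corrected)) return(image)
  if (inherits(image, "dynamic_image")) {
    fac <- 2^((image$schedule$mid - reference_time_min) / half_life_min)
    for (i in seq_along(fac))
      image$data[, , , i] <- image$data[, , , i] * fac[i]
  } else {
    image$data <- decay_correct(image$data, image$mid_time_min,
                                reference_time_min, half_life_min)
  }
  image$decay_corrected <- TRUE
  image$reference_time_min <- reference_time_min
  image
}

#' Extract time-activity curves from a dynamic image
#'
#' Computes per-frame VOI statistics and converts them to SUV, yielding one
#' time-activity curve per mask. The image must be calibrated (Bq/mL) and
#' decay-corrected to the dose reference time.
#'
#' @param dynamic_image a calibrated, decay-corrected [dynamic_image()].
#' @param masks named list of masks (logical arrays or [voi_mask()]s).
#' @param dose a [dose_record()].
#' @param weight_kg body weight, kg.
#' @return A data.frame with columns `voi`, `frame`, `time_min` (frame
#'   midpoints), `suv_mean`, `suv_max`; class `time_activity_curve`.
#' @export
extract_tac <- function(dynamic_image, masks, dose, weight_kg) {
  stopifnot(inherits(dynamic_image, "dynamic_image"))
  if (!identical(dynamic_image$units, "Bq/mL"))
    stop("extract_tac expects a calibrated image (Bq/mL)")
  if (!isTRUE(dynamic_image$decay_corrected))
    stop("extract_tac expects a decay-corrected image")
  if (inherits(masks, "voi_mask") || is.array(masks)) masks <- list(VOI = masks)
  nfr <- nrow(dynamic_image$schedule)
  rows <- list()
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (inherits(m, "voi_mask")) m <- m$mask
    sm <- numeric(nfr); sx <- numeric(nfr)
    for (i in seq_len(nfr)) {
      st <- voi_statistics(image_frame(dynamic_image, i), m)
      sm[i] <- suv(st$mean, dose, weight_kg)
      sx[i] <- suv(st$max, dose, weight_kg)
    }
    rows[[nm]] <- data.frame(voi = nm, frame = seq_len(nfr),
                             time_min = dynamic_image$schedule$mid,
                             suv_mean = sm, suv_max = sx)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("time_activity_curve", "data.frame")
  out
}

#' Synthesize a static image by duration-weighted frame averaging
#'
#' Averages the frames of a dynamic series over a time window, weighting
#' each frame by the duration of its overlap with the window (frames
#' partially inside contribute proportionally, so the result is invariant
#' to how the window is framed in the noiseless limit). The window
#' convention is closed-open `[start, end)` minutes post-injection.
#'
#' @param dynamic_image a [dynamic_image()].
#' @param window_start,window_end window bounds, minutes post-injection.
#' @return A [static_image()] carrying the window as provenance.
#' @export
synthesize_static <- function(dynamic_image, window_start, window_end) {
  stopifnot(inherits(dynamic_image, "dynamic_image"),
            window_end > window_start)
  sch <- dynamic_image$schedule
  ov <- pmin(sch$end, window_end) - pmax(sch$start, window_start)
  ov[ov < 0] <- 0
  if (sum(ov) <= 0)
    stop(sprintf("window [%.4g, %.4g) min overlaps no acquisition frame",
                 window_start, window_end))
  w <- ov / sum(ov)
  d3 <- dim(dynamic_image$data)[1:3]
  acc <- array(0, dim = d3)
  for (i in which(w > 0))
    acc <- acc + w[i] * dynamic_image$data[, , , i]
  static_image(acc, dynamic_image$voxel_size_mm,
               window = c(window_start, window_end),
               units = dynamic_image$units,
               decay_corrected = dynamic_image$decay_corrected,
               reference_time_min = dynamic_image$reference_time_min,
               mid_time_min = sum(sch$mid * w))
}

#' Blood-pool subtraction for early-image interpretation
#'
#' Builds a blood-pool template `B` as the duration-weighted average of the
#' first 5 minutes of dynamic data, scales it so its left-atrial blood-pool
#' mean matches the target image's (`s = mean(target[LA_bp]) / mean(B[LA_bp])`,
#' overridable), and returns `max(target - s * B, 0)` voxelwise.
#'
#' @param target_image the [static_image()] to correct.
#' @param early_dynamic a [dynamic_image()] covering the 0--5 min bolus phase.
#' @param la_bp_mask left-atrial blood-pool mask.
#' @param scale optional manual override of the scale factor `s`.
#' @param template_window length-2 window over which the template is
#'   averaged (default `c(0, 5)` minutes).
#' @return A [static_image()] with attributes `scale` and `template_window`.
#' @export
blood_pool_subtract <- function(target_image, early_dynamic, la_bp_mask,
                                scale = NULL, template_window = c(0, 5)) {
  stopifnot(inherits(target_image, "static_image"))
  if (inherits(la_bp_mask, "voi_mask")) la_bp_mask <- la_bp_mask$mask
  templ <- synthesize_static(early_dynamic, template_window[1], template_window[2])
  if (!identical(dim(templ$data), dim(target_image$data)))
    stop("target and early dynamic grids differ")
  if (is.null(scale)) {
    b_mean <- mean(templ$data[la_bp_mask])
    if (b_mean <= 0)
      stop("degenerate input: zero blood-pool mean in the early template")
    scale <- mean(target_image$data[la_bp_mask]) / b_mean
  }
  out <- target_image
  out$data <- pmax(target_image$data - scale * templ$data, 0)
  attr(out, "scale") <- scale
  attr(out, "template_window") <- template_window
  out
}
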