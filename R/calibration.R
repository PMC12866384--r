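#' Simulate a uniform-cylinder calibration phantom acquisition
#'
#' Emits the count-rate image of a uniform cylinder of known activity,
#' the standard object used to calibrate a SPECT system for absolute
#' quantitation. Cylinder voxels have expected count rate
#' `(activity / volume) * sensitivity`; the background is zero; with noise
#' enabled, counts accumulated over `duration_s` are Poisson-resampled.
#'
#' @param activity_MBq phantom activity at the assay time, MBq (> 0).
#' @param volume_mL phantom volume, mL (> 0). The cylinder's height is 60%
#'   of the axial field of view; its radius follows from the volume.
#' @param grid_shape,voxel_size_mm image grid.
#' @param acquisition an [acquisition_model()].
#' @param duration_s acquisition duration for count statistics (default 900).
#' @param seed optional integer seed.
#' @return List with `image` (a [static_image()], counts/voxel/s), `mask`
#'   (logical cylinder mask), `activity_MBq`, `volume_mL`.
#' @export
simulate_uniform_cylinder <- function(activity_MBq, volume_mL,
                                      grid_shape = 64, voxel_size_mm = 4.92,
                                      acquisition = acquisition_model(),
                                      duration_s = 900, seed = NULL) {
  stopifnot(activity_MBq > 0, volume_mL > 0)
  if (!is.null(seed)) set.seed(seed)
  if (length(grid_shape) == 1L) grid_shape <- rep(as.integer(grid_shape), 3L)
  fov <- grid_shape * voxel_size_mm
  hz <- 0.6 * fov[3] / 2
  radius <- sqrt(volume_mL * 1000 / (pi * 2 * hz))     # mm
  if (radius > min(fov[1:2]) / 2 - voxel_size_mm)
    stop(sprintf("cylinder of volume %.0f mL (radius %.0f mm) does not fit the grid",
                 volume_mL, radius))
  ax <- lapply(1:3, function(i)
    (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * voxel_size_mm)
  u <- (ax[[1]] / radius)^2
  v <- (ax[[2]] / radius)^2
  w <- ifelse(abs(ax[[3]]) <= hz, 0, Inf)
  mask <- outer(outer(u, v, "+"), w, "+") <= 1
  conc <- activity_MBq * 1e6 / volume_mL               # Bq/mL
  truth <- array(0, dim = grid_shape)
  truth[mask] <- conc
  rate <- measure_frame(truth, acquisition, duration_s, voxel_size_mm,
                        units = "counts/voxel/s")
  img <- static_image(rate, voxel_size_mm, window = c(0, duration_s / 60),
                      units = "counts/voxel/s")
  list(image = img, mask = mask, activity_MBq = activity_MBq,
       volume_mL = volume_mL)
}

# 3D binary erosion by one 26-neighbourhood step, `steps` times
# (array-shift intersection; voxels on the array border are eroded away).
erode_mask <- function(mask, steps = 1L) {
  d <- dim(mask)
  for (s in seq_len(steps)) {
    out <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sh <- array(FALSE, dim = d)
      xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
      xd <- xs + dx; yd <- ys + dy; zd <- zs + dz
      okx <- xd >= 1 & xd <= d[1]; oky <- yd >= 1 & yd <= d[2]
      okz <- zd >= 1 & zd <= d[3]
      sh[xs[okx], ys[oky], zs[okz]] <- mask[xd[okx], yd[oky], zd[okz]]
      out <- out & sh
    }
    mask <- out
  }
  mask
}

#' Compute the calibration factor from a uniform-phantom image
#'
#' `cf = nominal concentration / mean count rate` over an eroded core of
#' the phantom mask (voxels within 2 voxel-widths of the boundary are
#' excluded, the usual guard against edge partial-volume spill-out).
#'
#' @param count_image a [static_image()] in counts/voxel/s.
#' @param mask logical phantom mask on the same grid.
#' @param activity_MBq,volume_mL the phantom's known activity and volume.
#' @param erode_voxels core-erosion width (default 2).
#' @param acquisition_mode `"static"` or `"dynamic"`, recorded as provenance.
#' @param assay_time_min decay reference of the phantom assay (provenance).
#' @return A `calibration_factor` object: list with `cf` (Bq/mL per
#'   counts/voxel/s), `phantom_activity_MBq`, `phantom_volume_mL`,
#'   `acquisition_mode`, `assay_time_min`, `n_core_voxels`.
#' @export
compute_calibration_factor <- function(count_image, mask, activity_MBq,
                                       volume_mL, erode_voxels = 2L,
                                       acquisition_mode = c("static", "dynamic"),
                                       assay_time_min = 0) {
  acquisition_mode <- match.arg(acquisition_mode)
  stopifnot(inherits(count_image, "static_image"))
  if (!identical(count_image$units, "counts/voxel/s"))
    stop("calibration expects a count-rate image (counts/voxel/s), got ",
         count_image$units)
  if (!any(mask)) stop("phantom mask is empty")
  core <- erode_mask(mask, erode_voxels)
  if (!any(core))
    stop("mask eroded to zero voxels; reduce erode_voxels or use a larger phantom")
  mean_rate <- mean(count_image$data[core])
  if (mean_rate <= 0) stop("degenerate input: zero mean count rate in phantom core")
  structure(list(cf = (activity_MBq * 1e6 / volume_mL) / mean_rate,
                 phantom_activity_MBq = activity_MBq,
                 phantom_volume_mL = volume_mL,
                 acquisition_mode = acquisition_mode,
                 assay_time_min = assay_time_min,
                 n_core_voxels = sum(core)),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("Calibration factor: %.6g Bq/mL per cps/voxel (%s mode, %d core voxels)\n",
              x$cf, x$acquisition_mode, x$n_core_voxels))
  invisible(x)
}

#' Apply a calibration factor to a count-rate image
#'
#' Voxelwise multiplication by `cf`; the result is tagged as an activity
#' concentration image (Bq/mL). Frame schedule / window provenance is
#' preserved.
#'
#' @param count_image a [dynamic_image()] or [static_image()] in
#'   counts/voxel/s.
#' @param cf a [compute_calibration_factor()] result (or a bare number).
#' @return Image of the same class in Bq/mL.
#' @export
apply_calibration <- function(count_image, cf) {
  cfv <- if (inherits(cf, "calibration_factor")) cf$cf else cf
  if (!identical(count_image$units, "counts/voxel/s"))
    stop("apply_calibration expects counts/voxel/s, got ", count_image$units)
  count_image$data <- count_image$data * cfv
  count_image$units <- "Bq/mL"
  count_image
}

#' Serialize / read a calibration factor as JSON
#'
#' @param cf a `calibration_factor`.
#' @param path output / input file path.
#' @return `read_calibration_factor()` returns a `calibration_factor`.
#' @export
write_calibration_factor <- function(cf, path) {
  jsonlite::write_json(unclass(cf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_factor
#' @export
read_calibration_factor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(x) <- "calibration_factor"
  x
}
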