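#' Image containers
#'
#' `dynamic_image()` wraps a 4D voxel array (x, y, z, frame) together with
#' isotropic grid spacing, a [frame_schedule()], a unit tag and decay-
#' correction provenance. `static_image()` wraps a 3D array with spacing,
#' units and the time window it represents.
#'
#' Recognised unit tags are `"counts/voxel/s"` (reconstructed count rate)
#' and `"Bq/mL"` (calibrated activity concentration).
#'
#' @param data numeric array; 4D for dynamic, 3D for static.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param schedule a [frame_schedule()] whose length matches `dim(data)[4]`.
#' @param units unit tag, `"counts/voxel/s"` or `"Bq/mL"`.
#' @param decay_corrected logical; have voxel values been decay-corrected?
#' @param reference_time_min decay reference time (minutes relative to
#'   injection) when `decay_corrected` is `TRUE`.
#' @return A `dynamic_image` or `static_image` object.
#' @export
dynamic_image <- function(data, voxel_size_mm, schedule,
                          units = c("Bq/mL", "counts/voxel/s"),
                          decay_corrected = FALSE, reference_time_min = NA_real_) {
  units <- match.arg(units)
  if (length(dim(data)) != 4L) stop("dynamic image data must be a 4D array")
  if (!inherits(schedule, "frame_schedule")) stop("schedule must be a frame_schedule")
  if (dim(data)[4] != nrow(schedule))
    stop("number of frames in data does not match the schedule")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 schedule = schedule, units = units,
                 decay_corrected = decay_corrected,
                 reference_time_min = reference_time_min),
            class = "dynamic_image")
}

#' @rdname dynamic_image
#' @param window numeric length-2, `(start_min, end_min)` the static image
#'   represents, or the acquisition window for true statics.
#' @param mid_time_min representative acquisition time (decay bookkeeping).
#' @export
static_image <- function(data, voxel_size_mm, window = c(NA_real_, NA_real_),
                         units = c("Bq/mL", "counts/voxel/s"),
                         decay_corrected = FALSE, reference_time_min = NA_real_,
                         mid_time_min = mean(window)) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L) stop("static image data must be a 3D array")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, window = window,
                 units = units, decay_corrected = decay_corrected,
                 reference_time_min = reference_time_min,
                 mid_time_min = mid_time_min),
            class = "static_image")
}

#' Extract one frame of a dynamic image as a static image
#'
#' @param image a `dynamic_image`.
#' @param i frame index.
#' @return A `static_image` for that frame.
#' @export
image_frame <- function(image, i) {
  stopifnot(inherits(image, "dynamic_image"), i >= 1, i <= nrow(image$schedule))
  static_image(image$data[, , , i, drop = TRUE], image$voxel_size_mm,
               window = c(image$schedule$start[i], image$schedule$end[i]),
               units = image$units, decay_corrected = image$decay_corrected,
               reference_time_min = image$reference_time_min,
               mid_time_min = image$schedule$mid[i])
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic image: %dx%dx%d voxels x %d frames @ %.3g mm [%s]%s\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm, x$units,
              if (isTRUE(x$decay_corrected))
                sprintf(", decay-corrected to t=%.3g min", x$reference_time_min)
              else ""))
  invisible(x)
}

#' @export
print.static_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Static image: %dx%dx%d voxels @ %.3g mm [%s], window %.4g-%.4g min\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$units, x$window[1], x$window[2]))
  invisible(x)
}

voxel_volume_mL <- function(voxel_size_mm) (voxel_size_mm / 10)^3

#' Write and read a subject's images as NIfTI with a JSON sidecar
#'
#' The dynamic series is written one NIfTI file per contiguous schedule
#' segment (`<prefix>_seg1.nii.gz`, ...), the phantom/VOI labels (if given)
#' as an integer-labelled NIfTI, and the frame schedule, unit tags and
#' subject record to `<prefix>.json`.
#'
#' @param image a [dynamic_image()].
#' @param prefix output path prefix.
#' @param subject optional [subject_record()] stored in the sidecar.
#' @param labels optional named list of logical 3D masks, written as one
#'   integer-labelled volume (1, 2, ... in list order).
#' @return Invisibly, the vector of files written.
#' @export
write_subject_nifti <- function(image, prefix, subject = NULL, labels = NULL) {
  stopifnot(inherits(image, "dynamic_image"))
  seg <- schedule_segments(image$schedule)
  files <- character(0)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    arr <- image$data[, , , idx, drop = FALSE]
    f <- sprintf("%s_seg%d.nii.gz", prefix, s)
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(image$voxel_size_mm, 3)), f)
    files <- c(files, f)
  }
  if (!is.null(labels)) {
    lab <- array(0L, dim = dim(image$data)[1:3])
    for (i in seq_along(labels)) lab[labels[[i]]] <- i
    f <- sprintf("%s_labels.nii.gz", prefix)
    RNifti::writeNifti(RNifti::asNifti(lab, pixdim = rep(image$voxel_size_mm, 3)), f)
    files <- c(files, f)
  }
  meta <- list(
    voxel_size_mm = image$voxel_size_mm,
    units = image$units,
    decay_corrected = image$decay_corrected,
    reference_time_min = image$reference_time_min,
    schedule = list(start_min = image$schedule$start,
                    duration_min = image$schedule$duration),
    segments = as.integer(seg),
    label_names = names(labels),
    subject = if (!is.null(subject)) unclass(subject)
  )
  jf <- paste0(prefix, ".json")
  jsonlite::write_json(meta, jf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, jf))
}

#' @rdname write_subject_nifti
#' @return `read_subject_nifti()` returns a list with elements `image`
#'   (a `dynamic_image`), `subject` (a `subject_record` or `NULL`) and
#'   `labels` (named list of masks or `NULL`).
#' @export
read_subject_nifti <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  sch <- frame_schedule(meta$schedule$start_min, meta$schedule$duration_min)
  seg <- meta$segments
  arrs <- lapply(unique(seg), function(s)
    as.array(RNifti::readNifti(sprintf("%s_seg%d.nii.gz", prefix, s))))
  d3 <- dim(arrs[[1]])[1:3]
  data <- array(0, dim = c(d3, nrow(sch)))
  for (k in seq_along(arrs)) {
    idx <- which(seg == unique(seg)[k])
    a <- arrs[[k]]
    if (length(dim(a)) == 3L) a <- array(a, dim = c(dim(a), 1L))
    data[, , , idx] <- a
  }
  img <- dynamic_image(data, meta$voxel_size_mm, sch, units = meta$units,
                       decay_corrected = isTRUE(meta$decay_corrected),
                       reference_time_min = meta$reference_time_min %||% NA_real_)
  labels <- NULL
  lf <- sprintf("%s_labels.nii.gz", prefix)
  if (!is.null(meta$label_names) && file.exists(lf)) {
    lab <- as.array(RNifti::readNifti(lf))
    labels <- lapply(seq_along(meta$label_names), function(i) lab == i)
    names(labels) <- meta$label_names
  }
  subject <- NULL
  if (!is.null(meta$subject)) {
    subject <- meta$subject
    class(subject) <- "subject_record"
  }
  list(image = img, subject = subject, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
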