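#' Volume-of-interest masks and statistics
#'
#' `voi_mask()` binds a logical 3D mask to a label and a provenance tag;
#' `voi_statistics()` summarises an image over a mask as the arithmetic
#' mean and maximum of the masked voxels plus the physical volume.
#'
#' @param label VOI label (`"LV_myo"`, `"LA_bp"`, `"LS"`, or custom).
#' @param mask logical 3D array.
#' @param source_image_id provenance tag of the image the mask was defined on.
#' @return `voi_mask()`: a `voi_mask` object.
#' @export
voi_mask <- function(label, mask, source_image_id = NA_character_) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3D array")
  if (!any(mask)) stop("VOI mask '", label, "' is empty")
  structure(list(label = label, mask = mask,
                 source_image_id = source_image_id),
            class = "voi_mask")
}

#' @rdname voi_mask
#' @param image a [static_image()] (or bare 3D array with a `voxel_size_mm`
#'   argument via `voxel_size_mm`).
#' @param voxel_size_mm used when `image` is a bare array.
#' @return `voi_statistics()`: a `voi_stats` list with `mean`, `max`,
#'   `volume_mL`, `n_voxels` (units follow the image's unit tag).
#' @export
voi_statistics <- function(image, mask, voxel_size_mm = NULL) {
  if (inherits(mask, "voi_mask")) mask <- mask$mask
  if (inherits(image, "static_image")) {
    arr <- image$data; vs <- image$voxel_size_mm
  } else {
    arr <- image
    vs <- voxel_size_mm %||% stop("voxel_size_mm required for bare arrays")
  }
  if (!identical(dim(arr), dim(mask)))
    stop("image and mask grids differ: ", paste(dim(arr), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  if (!any(mask)) stop("degenerate input: empty VOI mask")
  vals <- arr[mask]
  structure(list(mean = mean(vals), max = max(vals),
                 volume_mL = sum(mask) * voxel_volume_mL(vs),
                 n_voxels = sum(mask)),
            class = "voi_stats")
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf("VOI stats: mean %.4g, max %.4g over %d voxels (%.1f mL)\n",
              x$mean, x$max, x$n_voxels, x$volume_mL))
  invisible(x)
}

# Largest 26-connected component of a logical 3D mask (vectorised frontier
# flood fill over the mask's voxel index set).
largest_component_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(mask)
  comp <- integer(length(idx))               # component id per mask voxel
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  # linear offsets of the 26 neighbours
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  coord <- arrayInd(idx, d)
  cur <- 0L
  for (start in seq_along(idx)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier)) {
      cc <- coord[frontier, , drop = FALSE]
      nb <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nc <- sweep(cc, 2, offs[k, ], "+")
        ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] & nc[, 2] >= 1 & nc[, 2] <= d[2] &
          nc[, 3] >= 1 & nc[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * d[1] + (nc[ok, 3] - 1L) * d[1] * d[2]
        p <- pos[lin]
        nb <- c(nb, p[p > 0L])
      }
      nb <- unique(nb[comp[nb] == 0L])
      comp[nb] <- cur
      frontier <- nb
    }
  }
  best <- which.max(tabulate(comp))
  out <- array(FALSE, dim = d)
  out[idx[comp == best]] <- TRUE
  out
}

#' Blood-pool-threshold myocardial segmentation
#'
#' Semiautomated myocardial contouring from the late (150-min) image:
#' within an anatomical search region (the myocardial shell prior), voxels
#' whose value exceeds `k` times the blood-pool SUVmean measured in the
#' left-atrial VOI on the same image are kept, restricted to the largest
#' 26-connected component.
#'
#' @param late_image the late [static_image()] (calibrated; typically the
#'   150-min static).
#' @param la_bp_mask left-atrial blood-pool mask (logical array or
#'   [voi_mask()]).
#' @param search_region anatomical myocardial prior (logical array or
#'   [voi_mask()]).
#' @param k threshold multiplier (default 1.0: keep voxels above the
#'   blood-pool mean). Recorded in the output's provenance.
#' @return A [voi_mask()] labelled `"LV_myo"` with attributes `k` and
#'   `threshold` (the absolute threshold applied).
#' @export
segment_myocardium <- function(late_image, la_bp_mask, search_region, k = 1.0) {
  stopifnot(inherits(late_image, "static_image"))
  if (inherits(la_bp_mask, "voi_mask")) la_bp_mask <- la_bp_mask$mask
  if (inherits(search_region, "voi_mask")) search_region <- search_region$mask
  bp_mean <- voi_statistics(late_image, la_bp_mask)$mean
  thr <- k * bp_mean
  cand <- search_region & (late_image$data > thr)
  if (!any(cand))
    stop(sprintf("empty segmentation: no search-region voxel exceeds threshold %.4g (k = %.3g x blood-pool mean %.4g)",
                 thr, k, bp_mean))
  m <- voi_mask("LV_myo", largest_component_26(cand),
                source_image_id = sprintf("late[%.4g-%.4g min]",
                                          late_image$window[1],
                                          late_image$window[2]))
  attr(m, "k") <- k
  attr(m, "threshold") <- thr
  m
}

#' Transfer VOI masks to another image of the same subject
#'
#' Identity transfer on a shared grid (no re-contouring): the masks are
#' re-bound to the target image with updated provenance. Grids must match;
#' no resampling rule is defined.
#'
#' @param masks a [voi_mask()] or list of them.
#' @param target_image a [static_image()] or [dynamic_image()].
#' @param target_id provenance tag for the target image.
#' @return Masks of the same shape bound to the target image.
#' @export
transfer_vois <- function(masks, target_image, target_id = "target") {
  single <- inherits(masks, "voi_mask")
  if (single) masks <- list(masks)
  d3 <- dim(target_image$data)[1:3]
  out <- lapply(masks, function(m) {
    if (!identical(dim(m$mask), d3))
      stop("grid mismatch transferring VOI '", m$label, "': ",
           paste(dim(m$mask), collapse = "x"), " vs ",
           paste(d3, collapse = "x"), " (no resampling rule declared)")
    m$source_image_id <- paste0(m$source_image_id, " -> ", target_id)
    m
  })
  if (single) out[[1]] else out
}
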