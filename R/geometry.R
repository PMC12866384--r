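#' Digital thorax phantom geometry
#'
#' Builds a labelled voxel phantom holding the compartments used by the
#' quantitative analysis: a soft-tissue body, a left-ventricular myocardial
#' shell (`LV_myo`) enclosing the LV cavity blood pool (`LV_bp`), a left
#' atrial blood pool (`LA_bp`), and a lower-thoracic-spine bone cylinder
#' (`LS`). Compartments are ellipsoids/cylinders defined in physical mm
#' coordinates centred on the grid, so their physical volumes are grid-size
#' independent (up to voxelisation error).
#'
#' @param grid_shape integer length-1 or length-3: voxels per axis
#'   (default 64, i.e. a 64^3 grid).
#' @param voxel_size_mm isotropic voxel spacing in mm (default 4.92, the
#'   emulated reconstruction voxel size).
#' @return A `phantom_geometry` object: list with `grid_shape`,
#'   `voxel_size_mm`, `labels` (named list of logical 3D masks for `body`,
#'   `LV_myo`, `LV_bp`, `LA_bp`, `LS`, `background`) and
#'   `analytic_volumes_mL` (the exact volumes of the defining solids).
#' @examples
#' geo <- build_phantom_geometry(48, 4.92)
#' sapply(geo$labels, sum)
#' @export
build_phantom_geometry <- function(grid_shape = 64, voxel_size_mm = 4.92) {
  if (length(grid_shape) == 1L) grid_shape <- rep(as.integer(grid_shape), 3L)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 2L) || voxel_size_mm <= 0)
    stop("invalid grid specification")

  # compartment definitions (mm, relative to grid centre)
  body_semi <- c(105, 80); body_hz <- 100
  lv_c <- c(-35, 15, 0); lv_outer <- c(40, 40, 50); lv_inner <- c(28, 28, 38)
  la_c <- c(25, -25, 15); la_r <- 22
  ls_c <- c(0, 60, 0); ls_r <- 12; ls_hz <- 80

  half_fov <- grid_shape * voxel_size_mm / 2
  need <- list(
    body   = c(body_semi[1], body_semi[2], body_hz),
    LV_myo = abs(lv_c) + lv_outer,
    LA_bp  = abs(la_c) + la_r,
    LS     = abs(ls_c) + c(ls_r, ls_r, ls_hz)
  )
  for (nm in names(need)) {
    if (any(need[[nm]] > half_fov))
      stop(sprintf("grid too small to fit region '%s': needs half-extent (%s) mm but grid half-extent is (%s) mm",
                   nm, paste(round(need[[nm]], 1), collapse = ", "),
                   paste(round(half_fov, 1), collapse = ", ")))
  }

  ax <- lapply(1:3, function(i)
    (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * voxel_size_mm)

  ellipsoid <- function(centre, semi) {
    u <- ((ax[[1]] - centre[1]) / semi[1])^2
    v <- ((ax[[2]] - centre[2]) / semi[2])^2
    w <- ((ax[[3]] - centre[3]) / semi[3])^2
    outer(outer(u, v, "+"), w, "+") <= 1
  }
  zcyl <- function(centre, r, hz) {
    u <- ((ax[[1]] - centre[1]) / r)^2
    v <- ((ax[[2]] - centre[2]) / r)^2
    w <- ifelse(abs(ax[[3]] - centre[3]) <= hz, 0, Inf)
    outer(outer(u, v, "+"), w, "+") <= 1
  }

  # body: elliptic cylinder, semi-axes body_semi in-plane, half-height body_hz
  body <- outer(outer((ax[[1]] / body_semi[1])^2, (ax[[2]] / body_semi[2])^2, "+"),
                ifelse(abs(ax[[3]]) <= body_hz, 0, Inf), "+") <= 1
  lv_out <- ellipsoid(lv_c, lv_outer)
  lv_bp <- ellipsoid(lv_c, lv_inner)
  lv_myo <- lv_out & !lv_bp
  la_bp <- ellipsoid(la_c, rep(la_r, 3))
  ls <- zcyl(ls_c, ls_r, ls_hz)

  labels <- list(body = body, LV_myo = lv_myo, LV_bp = lv_bp,
                 LA_bp = la_bp, LS = ls, background = !body)
  tissue <- c("LV_myo", "LV_bp", "LA_bp", "LS")
  for (nm in tissue) {
    if (sum(labels[[nm]]) < 30L)
      stop(sprintf("region '%s' has only %d voxels (< 30) at this resolution",
                   nm, sum(labels[[nm]])))
    if (any(labels[[nm]] & !body))
      stop(sprintf("region '%s' is not contained in the body", nm))
  }
  for (i in seq_along(tissue)[-1]) for (j in seq_len(i - 1L))
    if (any(labels[[tissue[i]]] & labels[[tissue[j]]]))
      stop(sprintf("regions '%s' and '%s' overlap", tissue[i], tissue[j]))

  vol <- function(semi) 4 / 3 * pi * prod(semi)
  analytic <- c(
    body   = pi * prod(body_semi) * 2 * body_hz / 1000,
    LV_myo = (vol(lv_outer) - vol(lv_inner)) / 1000,
    LV_bp  = vol(lv_inner) / 1000,
    LA_bp  = vol(rep(la_r, 3)) / 1000,
    LS     = pi * ls_r^2 * 2 * ls_hz / 1000
  )

  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 labels = labels, analytic_volumes_mL = analytic),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("Phantom geometry: %s voxels @ %.3g mm\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm))
  v <- voxel_volume_mL(x$voxel_size_mm)
  for (nm in setdiff(names(x$labels), "background"))
    cat(sprintf("  %-7s %6d voxels (%.1f mL)\n", nm, sum(x$labels[[nm]]),
                sum(x$labels[[nm]]) * v))
  invisible(x)
}
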