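#' Acquisition (noise and resolution) model
#'
#' Emulates the count-statistics and resolution properties of reconstructed
#' emission images with two effects: an isotropic Gaussian post-smoothing of
#' the activity distribution (standing in for reconstruction resolution /
#' partial volume) and Poisson resampling of frame counts at a given system
#' sensitivity. Projection-domain physics (attenuation, scatter, vendor
#' reconstruction) is out of scope.
#'
#' @param psf_fwhm_mm Gaussian blur FWHM in mm; 0 disables blurring.
#'   When enabled, 12 mm is a representative reconstructed resolution.
#' @param sensitivity_cps_per_Bq_per_mL_per_voxel count rate recorded per
#'   voxel per unit activity concentration (counts/s per Bq/mL). Default
#'   2e-5 yields clinically plausible count levels for ~900 MBq injections.
#' @param noise logical; Poisson-resample frame counts?
#' @return An `acquisition_model` object.
#' @export
acquisition_model <- function(psf_fwhm_mm = 0,
                              sensitivity_cps_per_Bq_per_mL_per_voxel = 2e-5,
                              noise = TRUE) {
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  if (noise && sensitivity_cps_per_Bq_per_mL_per_voxel <= 0)
    stop("sensitivity must be > 0 when noise is enabled")
  structure(list(psf_fwhm_mm = psf_fwhm_mm,
                 sensitivity = sensitivity_cps_per_Bq_per_mL_per_voxel,
                 noise = noise),
            class = "acquisition_model")
}

# Separable 3D Gaussian smoothing, kernel truncated at +/- 3 sigma,
# zero-padded boundaries (background activity is zero).
gaussian_blur_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    # move `axis` first, convolve columns, move back
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    aperm(array(out, dm), order(perm))
  }
  for (axis in 1:3) arr <- conv_axis(arr, axis)
  arr
}

# Convert a true concentration frame (Bq/mL) to a measured frame.
# Returns the frame in the requested output units after optional blur and
# Poisson resampling of the counts accumulated over `duration_s`.
measure_frame <- function(conc, acquisition, duration_s, voxel_size_mm,
                          units = c("Bq/mL", "counts/voxel/s")) {
  units <- match.arg(units)
  if (acquisition$psf_fwhm_mm > 0)
    conc <- gaussian_blur_3d(conc, acquisition$psf_fwhm_mm, voxel_size_mm)
  s <- acquisition$sensitivity
  rate <- conc * s                       # counts/voxel/s
  if (acquisition$noise) {
    lam <- rate * duration_s
    counts <- array(stats::rpois(length(lam), lam), dim = dim(lam))
    rate <- counts / duration_s
  }
  if (units == "Bq/mL") rate / s else rate
}
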