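# Shared fixtures, built in code and cached for the test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_geometry <- function() cached("geo48", build_phantom_geometry(48, 4.92))

noiseless_acq <- function() acquisition_model(psf_fwhm_mm = 0, noise = FALSE)

# kinetics with inter-subject variability switched off
cv0_kinetics <- function(group) {
  lapply(default_tissue_kinetics(group), function(k) { k$subject_cv <- 0; k })
}

# a deterministic noiseless subject on the shared 48^3 geometry,
# calibrated (generator emits Bq/mL) and decay-corrected
noiseless_subject <- function(group, seed = 3) {
  cached(paste0("subj_", group, "_", seed), {
    s <- generate_subject(group, test_geometry(),
                          kinetics_set = cv0_kinetics(group),
                          acquisition = noiseless_acq(), seed = seed)
    dose <- net_injected_activity(s$record)
    s$image_dc <- decay_correct_image(s$image, dose$reference_time_min)
    s$dose <- dose
    s
  })
}

# tiny 3-frame dynamic image with constant voxel values per frame
const_dynamic <- function(values, durations, starts = cumsum(c(0, utils::head(durations, -1))),
                          dim3 = c(4, 4, 4), voxel = 4.92, units = "Bq/mL") {
  sch <- frame_schedule(starts, durations)
  arr <- array(0, dim = c(dim3, length(values)))
  for (i in seq_along(values)) arr[, , , i] <- values[i]
  dynamic_image(arr, voxel, sch, units = units,
                decay_corrected = TRUE, reference_time_min = 0)
}
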