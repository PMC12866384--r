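test_that("synthetic statics are duration-weighted frame averages", {
  img <- const_dynamic(c(2, 4), c(5, 10))
  st <- synthesize_static(img, 0, 15)
  expect_equal(unique(as.vector(st$data)), (2 * 5 + 4 * 10) / 15)
  expect_equal(unique(as.vector(st$data)), 10 / 3, tolerance = 1e-12)
  # all frames identical -> that value; exact single frame -> that frame
  img2 <- const_dynamic(c(7, 7, 7), c(1, 2, 3))
  expect_equal(unique(as.vector(synthesize_static(img2, 0, 6)$data)), 7)
  expect_equal(unique(as.vector(synthesize_static(img, 5, 15)$data)), 4)
  expect_error(synthesize_static(img, 20, 30), "overlaps no")
})

test_that("partial-frame overlap weighting is framing-invariant", {
  # same piecewise-constant signal framed two ways
  a <- const_dynamic(c(3, 3, 5), c(2, 2, 4))
  b <- const_dynamic(c(3, 5, 5), c(4, 2, 2))
  w <- c(1, 7)                           # cuts through frames on both framings
  expect_equal(synthesize_static(a, w[1], w[2])$data,
               synthesize_static(b, w[1], w[2])$data)
})

test_that("synthesize_static is linear in the image", {
  set.seed(9)
  arr <- array(runif(4^3 * 3), dim = c(4, 4, 4, 3))
  sch <- frame_schedule(c(0, 1, 2), c(1, 1, 1))
  img1 <- dynamic_image(arr, 4.92, sch)
  img2 <- dynamic_image(2 * arr + 1, 4.92, sch)
  s1 <- synthesize_static(img1, 0.5, 2.5)
  s2 <- synthesize_static(img2, 0.5, 2.5)
  expect_equal(s2$data, 2 * s1$data + 1, tolerance = 1e-12)
})

test_that("time-activity curves round-trip the generator kinetics", {
  s <- noiseless_subject("ATTR")
  geo <- test_geometry()
  tac <- extract_tac(s$image_dc, list(LV_myo = geo$labels$LV_myo),
                     s$dose, s$record$weight_kg)
  f <- make_tissue_tac(default_tissue_kinetics("ATTR")$myocardium)
  expect_equal(tac$suv_mean, f(tac$time_min), tolerance = 5e-3)
  # uniform fill: per-frame max equals mean
  expect_equal(tac$suv_max, tac$suv_mean, tolerance = 1e-9)
  # flat curve for a time-constant phantom
  flat <- const_dynamic(c(4, 4, 4), c(1, 1, 1))
  m <- array(TRUE, dim = c(4, 4, 4))
  tf <- extract_tac(flat, list(all = m), dose_record(1e8), 70)
  expect_equal(length(unique(round(tf$suv_mean, 9))), 1)
  # single frame: TAC equals the static VOI stats
  one <- const_dynamic(5, 2)
  t1 <- extract_tac(one, list(all = m), dose_record(1e8), 70)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$suv_mean,
               suv(voi_statistics(image_frame(one, 1), m)$mean,
                   dose_record(1e8), 70))
})

test_that("blood-pool subtraction nulls proportional images and recovers additive signal", {
  set.seed(10)
  d3 <- c(6, 6, 6)
  base <- array(runif(prod(d3), 1, 2), dim = d3)
  arr <- array(0, dim = c(d3, 2))
  arr[, , , 1] <- base; arr[, , , 2] <- base
  early <- dynamic_image(arr, 4.92, frame_schedule(c(0, 2.5), c(2.5, 2.5)),
                         decay_corrected = TRUE, reference_time_min = 0)
  la <- array(FALSE, dim = d3); la[1:2, 1:2, 1:2] <- TRUE
  # target exactly proportional to the template -> zero image
  target <- static_image(2 * base, 4.92, window = c(10, 25),
                         decay_corrected = TRUE, reference_time_min = 0)
  out <- blood_pool_subtract(target, early, la)
  expect_equal(max(abs(out$data)), 0)
  expect_equal(attr(out, "scale"), 2)
  # additive myocardial signal disjoint from LA_bp is recovered exactly
  M <- array(0, dim = d3); M[4:5, 4:5, 4:5] <- 3.7
  target2 <- static_image(1.5 * base + M, 4.92, window = c(10, 25),
                          decay_corrected = TRUE, reference_time_min = 0)
  out2 <- blood_pool_subtract(target2, early, la)
  expect_equal(out2$data, M, tolerance = 1e-12)
  # negative residuals are clamped at zero
  target3 <- static_image(0.5 * base - 0.2, 4.92, window = c(10, 25),
                          decay_corrected = TRUE, reference_time_min = 0)
  out3 <- blood_pool_subtract(target3, early, la, scale = 1)
  expect_gte(min(out3$data), 0)
  # degenerate zero template blood pool
  zero <- early; zero$data[] <- 0
  expect_error(blood_pool_subtract(target, zero, la), "degenerate")
})

test_that("subtraction separates blood-driven from genuine myocardial uptake", {
  geo <- test_geometry()
  for (group in c("non-ATTR", "ATTR")) {
    s <- noiseless_subject(group)
    t10 <- synthesize_static(s$image_dc, 10, 25)
    sub <- blood_pool_subtract(t10, s$image_dc, geo$labels$LA_bp)
    frac <- mean(sub$data[geo$labels$LV_myo]) /
      mean(t10$data[geo$labels$LV_myo])
    if (group == "non-ATTR") expect_lt(frac, 0.10) else expect_gt(frac, 0.50)
  }
})

test_that("decay-corrected images are tagged and idempotent", {
  img <- const_dynamic(c(1, 1), c(1, 1))
  img$decay_corrected <- FALSE
  dc <- decay_correct_image(img, -30)
  expect_true(dc$decay_corrected)
  expect_equal(dc$data[1, 1, 1, ], 2^((img$schedule$mid + 30) / 360.4))
  expect_identical(decay_correct_image(dc, -30)$data, dc$data)
  raw <- const_dynamic(c(1, 1), c(1, 1), units = "counts/voxel/s")
  raw$decay_corrected <- FALSE
  expect_error(decay_correct_image(raw, 0), "calibrated")
})
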