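test_that("VOI statistics match direct computation and a brute-force oracle", {
  img <- static_image(array(5, dim = c(4, 4, 4)), 4.92)
  m <- array(TRUE, dim = c(4, 4, 4))
  st <- voi_statistics(img, m)
  expect_equal(st$mean, 5); expect_equal(st$max, 5)
  expect_equal(st$volume_mL, 64 * (0.492)^3)

  arr <- array(0, dim = c(3, 3, 1)); arr[1:3] <- c(1, 2, 3)
  mk <- array(FALSE, dim = c(3, 3, 1)); mk[1:3] <- TRUE
  st <- voi_statistics(static_image(arr, 1), mk)
  expect_equal(st$mean, 2); expect_equal(st$max, 3); expect_equal(st$n_voxels, 3)

  set.seed(21)
  arr <- array(rnorm(20^3), dim = c(20, 20, 20))
  mk <- array(runif(20^3) < 0.3, dim = c(20, 20, 20))
  st <- voi_statistics(static_image(arr, 2), mk)
  # exhaustive loop oracle
  vals <- c(); d <- dim(arr)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (mk[i, j, k]) vals <- c(vals, arr[i, j, k])
  expect_equal(st$mean, mean(vals), tolerance = 1e-12)
  expect_identical(st$max, max(vals))
  expect_gte(st$max, st$mean)
})

test_that("VOI statistics reject empty masks and mismatched grids", {
  img <- static_image(array(1, dim = c(4, 4, 4)), 4.92)
  expect_error(voi_statistics(img, array(FALSE, dim = c(4, 4, 4))), "empty")
  expect_error(voi_statistics(img, array(TRUE, dim = c(5, 4, 4))), "grids differ")
})

test_that("largest 26-connected component selection works", {
  m <- array(FALSE, dim = c(10, 10, 3))
  m[1:2, 1:2, 1] <- TRUE                      # 4-voxel blob
  m[6:9, 6:9, 1:2] <- TRUE                    # 32-voxel blob
  out <- pypquant:::largest_component_26(m)
  expect_equal(sum(out), 32)
  expect_true(all(out[6:9, 6:9, 1:2]))
  # diagonal touch counts as connected under 26-connectivity
  m2 <- array(FALSE, dim = c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(sum(pypquant:::largest_component_26(m2)), 2)
})

test_that("blood-pool-threshold segmentation recovers the myocardium on late images", {
  s <- noiseless_subject("ATTR")
  geo <- test_geometry()
  late <- synthesize_static(s$image_dc, 150, 165)
  seg <- segment_myocardium(late, geo$labels$LA_bp, geo$labels$LV_myo, k = 1.0)
  truth <- geo$labels$LV_myo
  expect_gte(sum(seg$mask & truth) / sum(truth), 0.95)
  # Dice > 0.9 across k in [0.8, 1.2]
  for (k in c(0.8, 1.0, 1.2)) {
    sk <- segment_myocardium(late, geo$labels$LA_bp, geo$labels$LV_myo, k = k)
    dice <- 2 * sum(sk$mask & truth) / (sum(sk$mask) + sum(truth))
    expect_gt(dice, 0.9)
  }
})

test_that("segmentation is monotone in k and handles the threshold-off limit", {
  s <- noiseless_subject("ATTR")
  geo <- test_geometry()
  late <- synthesize_static(s$image_dc, 150, 165)
  # add deterministic pseudo-noise so thresholds actually cut
  set.seed(8)
  noisy <- late
  noisy$data <- late$data * array(1 + 0.1 * rnorm(length(late$data)),
                                  dim = dim(late$data))
  prev <- NULL
  for (k in c(0.6, 0.8, 1.0, 1.2, 1.4)) {
    seg <- segment_myocardium(noisy, geo$labels$LA_bp, geo$labels$LV_myo, k = k)
    if (!is.null(prev)) expect_true(all(seg$mask <= prev))
    prev <- seg$mask
  }
  # k = 0 on a strictly positive image: the largest component of the prior
  pos <- late; pos$data <- pos$data + 1
  seg0 <- segment_myocardium(pos, geo$labels$LA_bp, geo$labels$LV_myo, k = 0)
  expect_identical(seg0$mask,
                   pypquant:::largest_component_26(geo$labels$LV_myo))
})

test_that("a threshold excluding everything is a reported error", {
  s <- noiseless_subject("non-ATTR")
  geo <- test_geometry()
  late <- synthesize_static(s$image_dc, 150, 165)
  # non-ATTR myocardium is below blood pool at 150 min
  expect_error(segment_myocardium(late, geo$labels$LA_bp,
                                  geo$labels$LV_myo, k = 1.0),
               "empty segmentation.*threshold")
})

test_that("VOI transfer is identity on shared grids and errors otherwise", {
  s <- noiseless_subject("ATTR")
  geo <- test_geometry()
  late <- synthesize_static(s$image_dc, 150, 165)
  vm <- voi_mask("LS", geo$labels$LS, "late")
  tr <- transfer_vois(vm, late, "copy")
  expect_identical(voi_statistics(late, tr), voi_statistics(late, vm))
  # transfer onto a dynamic frame: stats follow that frame, mask unchanged
  fr <- image_frame(s$image_dc, 1)
  tr2 <- transfer_vois(vm, s$image_dc, "frame1")
  expect_identical(tr2$mask, vm$mask)
  expect_equal(voi_statistics(fr, tr2)$mean, mean(fr$data[vm$mask]))
  small <- static_image(array(1, dim = c(8, 8, 8)), 4.92)
  expect_error(transfer_vois(vm, small), "grid mismatch")
})
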