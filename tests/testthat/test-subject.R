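test_that("subject records enforce dose bookkeeping invariants", {
  expect_error(subject_record("s", "ATTR", -1, 900, -30, 10, 5), "weight")
  expect_error(subject_record("s", "ATTR", 80, 900, -30, 950, 5), "residual")
  expect_error(subject_record("s", "ATTR", 80, 900, 10, 10, 5),
               "assay_time_min")
})

test_that("noiseless filling round-trips the kinetics at every frame midpoint", {
  s <- noiseless_subject("ATTR")
  geo <- test_geometry()
  sch <- s$image$schedule
  myo_anchor <- make_tissue_tac(default_tissue_kinetics("ATTR")$myocardium)
  # 90-min static frame recovers the group curve to within 0.1%
  i90 <- which(sch$start == 90)
  st <- image_frame(s$image_dc, i90)
  got <- suv(voi_statistics(st, geo$labels$LV_myo)$mean, s$dose, s$record$weight_kg)
  expect_equal(got, myo_anchor(97.5), tolerance = 1e-3)
  # and a handful of other frames, all VOIs
  kin <- cv0_kinetics("ATTR")
  for (i in c(1, 25, 33)) {
    fr <- image_frame(s$image_dc, i)
    for (pair in list(c("LV_myo", "myocardium"), c("LA_bp", "blood"),
                      c("LS", "bone"))) {
      got <- suv(voi_statistics(fr, geo$labels[[pair[1]]])$mean, s$dose,
                 s$record$weight_kg)
      expect_equal(got, make_tissue_tac(kin[[pair[2]]])(sch$mid[i]),
                   tolerance = 1e-3)
    }
  }
})

test_that("generated subjects always satisfy their group's uptake ordering", {
  geo <- test_geometry()
  sch <- default_frame_schedule()
  for (seed in 1:12) {
    for (group in c("ATTR", "non-ATTR")) {
      set.seed(seed)
      kin <- default_tissue_kinetics(group)
      tacs <- lapply(kin, make_tissue_tac)
      m <- pypquant:::draw_subject_multipliers(kin, tacs, sch, group)
      myo <- tacs$myocardium(sch$mid) * m[["myocardium"]]
      bp <- tacs$blood(sch$mid) * m[["blood"]]
      bone <- tacs$bone(sch$mid) * m[["bone"]]
      if (group == "ATTR") {
        expect_true(all(myo[sch$start >= 10] >= bp[sch$start >= 10]))
      } else {
        expect_true(all(bp > myo))
      }
      # bone peaks at the 90-min window in every subject
      expect_true(all(bone[sch$start == 90] >= bone[sch$start < 90]))
    }
  }
})

test_that("accepted-population mean multiplier is 1 per tissue (selection-compensated)", {
  sch <- default_frame_schedule()
  for (group in c("ATTR", "non-ATTR")) {
    kin <- default_tissue_kinetics(group)
    tacs <- lapply(kin, make_tissue_tac)
    set.seed(99)
    draws <- replicate(4000, pypquant:::draw_subject_multipliers(kin, tacs, sch, group))
    mu <- rowMeans(draws)
    cvs <- vapply(kin, function(k) k$subject_cv, numeric(1))[rownames(draws)]
    # means within 4 standard errors of 1
    expect_true(all(abs(mu - 1) < 4 * cvs / sqrt(4000) + 1e-6),
                info = paste(group, paste(round(mu, 4), collapse = ",")))
  }
})

test_that("identical seeds and configs give bit-identical subjects", {
  geo <- test_geometry()
  a <- generate_subject("ATTR", geo, seed = 7)
  b <- generate_subject("ATTR", geo, seed = 7)
  expect_identical(a$record, b$record)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$multipliers, b$multipliers)
})

test_that("Poisson noise leaves the expected count statistics in a VOI", {
  # constant-activity phantom: uniform cylinder, 200 repeated frames
  acq <- acquisition_model(noise = TRUE)
  base <- simulate_uniform_cylinder(100, 1000, grid_shape = 32,
                                    acquisition = noiseless_acq(),
                                    duration_s = 30)
  core <- pypquant:::erode_mask(base$mask, 2L)
  rate_true <- 100e6 / 1000 * acq$sensitivity       # counts/voxel/s
  means <- vapply(1:200, function(i) {
    sim <- simulate_uniform_cylinder(100, 1000, grid_shape = 32,
                                     acquisition = acq, duration_s = 30,
                                     seed = 5000 + i)
    mean(sim$image$data[core])
  }, numeric(1))
  rel_sd <- sd(means) / mean(means)
  expected <- 1 / sqrt(rate_true * 30 * sum(core))  # 1/sqrt(total core counts)
  expect_lt(rel_sd / expected, 1.5)
  expect_gt(rel_sd / expected, 1 / 1.5)
})

test_that("cohorts have requested sizes, labels and deterministic seeds", {
  cfg <- cohort_config(grid_shape = 48, acquisition = noiseless_acq(),
                       kinetics = list(ATTR = cv0_kinetics("ATTR"),
                                       `non-ATTR` = cv0_kinetics("non-ATTR")),
                       schedule = frame_schedule(c(10, 150), c(15, 15)))
  co <- generate_cohort(0, 3, cfg, seed = 2)
  expect_length(co$subjects, 3)
  expect_true(all(vapply(co$subjects, function(s) s$record$group, "") == "non-ATTR"))
  co2 <- generate_cohort(0, 3, cfg, seed = 2)
  for (i in 1:3) {
    expect_identical(co$subjects[[i]]$record, co2$subjects[[i]]$record)
    expect_identical(co$subjects[[i]]$image$data, co2$subjects[[i]]$image$data)
  }
})

test_that("missing tissue kinetics is a configuration error", {
  geo <- test_geometry()
  kin <- default_tissue_kinetics("ATTR")
  kin$bone <- NULL
  expect_error(generate_subject("ATTR", geo, kinetics_set = kin, seed = 1),
               "missing tissue")
})
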