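test_that("voxel volumes are exact unit conversions", {
  lab <- array(0L, c(20, 10, 10))
  lab[1:10, 1:10, 1:10] <- 1L
  vol <- labeled_volume(lab, c(1, 1, 1))
  expect_equal(voxel_volume_mL(vol, 1), 1.0)
  expect_equal(voxel_volume_mL(vol, 2), 0.0)
  expect_error(voxel_volume_mL(vol, 5), "label")

  sph <- test_sphere(10, 0.5)
  expect_lt(abs(voxel_volume_mL(sph, 1) - 4.18879) / 4.18879, 0.01)
})

test_that("the ABC/2 formula and invariants hold", {
  m <- abc2_measurement(5, 4, 3)
  expect_equal(m$volume_mL, 30.0)
  # B <= A is enforced by swapping
  m2 <- abc2_measurement(4, 5, 3)
  expect_equal(m2$A_cm, 5)
  expect_equal(m2$B_cm, 4)
  expect_equal(m2$volume_mL, 30.0)
  expect_error(abc2_measurement(0, 1, 1), "positive")
})

test_that("ABC/2 on a digitized ellipsoid approaches the analytic limits", {
  ell <- make_ellipsoid_mask(c(30, 20, 10), c(0.5, 0.5, 0.5), c(132, 92, 52))
  true_v <- 4 / 3 * pi * 30 * 20 * 10 / 1000

  mf <- abc2_measure(ell, "full_extent")
  expect_lt(abs(mf$volume_mL / true_v - 3 / pi), 0.01)
  expect_equal(mf$volume_mL, mf$A_cm * mf$B_cm * mf$C_cm / 2)
  expect_lte(mf$B_cm, mf$A_cm)

  # Kothari weighting: fine-grid limit of the weighted C on an ellipsoid is
  # (1 + (sqrt(3) - 1)/2) * c = 1.366 c, giving ratio 2.732 / (4 pi / 3)
  mk <- abc2_measure(ell, "kothari_weighted")
  expect_lt(abs(mk$volume_mL / true_v - 0.6523), 0.02)
  expect_lt(mk$C_cm, mf$C_cm)

  expect_error(abc2_measure(labeled_volume(array(0L, c(8, 8, 8)), c(1, 1, 1))),
               "nonempty ICH")
})

test_that("voxel and ABC/2 errors shrink as the grid is refined", {
  true_v <- 4 / 3 * pi * 30 * 20 * 10 / 1000
  vox_err <- abc_err <- numeric(0)
  for (s in c(2, 1, 0.5)) {
    shp <- as.integer(ceiling((2 * c(30, 20, 10) + 12) / s))
    shp <- shp + shp %% 2L
    e <- make_ellipsoid_mask(c(30, 20, 10), rep(s, 3), shp)
    vox_err <- c(vox_err, abs(voxel_volume_mL(e, 1) - true_v) / true_v)
    abc_err <- c(abc_err,
                 abs(abc2_measure(e, "full_extent")$volume_mL / true_v - 3 / pi))
  }
  expect_true(all(diff(vox_err) < 0))
  expect_true(all(diff(abc_err) < 0))
})

test_that("IVH is excluded from the ICH volume by construction", {
  sph <- test_sphere(8, 1)
  before <- voxel_volume_mL(sph, 1)
  with_ivh <- add_ivh_component(sph, 1.5, seed = 4)
  expect_equal(voxel_volume_mL(with_ivh, 1), before)
  # and ABC/2, which reads label 1 only, is also unchanged
  expect_equal(abc2_measure(with_ivh)$volume_mL, abc2_measure(sph)$volume_mL)
})

test_that("ABC/2 error grows with shape irregularity at fixed volume", {
  # increasingly irregular phantoms of the same target volume: the ABC/2
  # overestimation (relative to the voxel reference) is nondecreasing
  semi <- c(14, 11, 9)
  ratios <- sapply(c(0, 0.3, 0.6, 0.9), function(irr) {
    err <- sapply(1:6, function(sd) {
      vol <- ichagree:::rasterize_deformed_ellipsoid(
        semi, c(1, 1, 1), c(72, 72, 72), irr, seed = sd)
      abc2_measure(vol, "kothari_weighted")$volume_mL / voxel_volume_mL(vol, 1)
    })
    mean(err)
  })
  expect_true(all(diff(ratios) > -0.005))  # monotone up to simulation noise
  expect_gt(ratios[4], ratios[1])
})

test_that("the auto-segmentation simulator honours its degenerate limits", {
  rec <- data.frame(case_id = "c1", true_ich_volume_mL = 50,
                    true_ivh_volume_mL = 8, ivh_present = TRUE)
  # near-step detection: intercept 0, huge slope => threshold at 1 mL
  steep <- auto_seg_error_model(detect_intercept = 0, detect_slope = 1e5,
                                p_ivh_include = 0, p_partial = 0,
                                p_distractor_include = 0,
                                multiplicative_noise_sd = 0)
  for (s in 1:20) {
    expect_false(simulate_auto_segmentation(NULL, rec, steep, seed = s)$missed)
  }
  small <- rec
  small$true_ich_volume_mL <- 0.1
  for (s in 1:20) {
    expect_true(simulate_auto_segmentation(NULL, small, steep, seed = s)$missed)
  }

  # exact IVH inclusion with an otherwise error-free model
  ivh_only <- auto_seg_error_model(detect_intercept = 1e6, detect_slope = 0,
                                   p_ivh_include = 1, p_partial = 0,
                                   p_distractor_include = 0,
                                   multiplicative_noise_sd = 0)
  m <- simulate_auto_segmentation(NULL, rec, ivh_only, seed = 1)
  expect_equal(m$volume_mL, 58)
  expect_true(m$ivh_included)

  # zeroed model reproduces the truth exactly
  zero <- auto_seg_error_model(zeroed = TRUE)
  expect_equal(simulate_auto_segmentation(NULL, rec, zero, seed = 1)$volume_mL, 50)

  # seed contract
  noisy <- auto_seg_error_model()
  m1 <- simulate_auto_segmentation(NULL, rec, noisy, seed = 5)
  m2 <- simulate_auto_segmentation(NULL, rec, noisy, seed = 5)
  expect_identical(m1, m2)
})

test_that("IVH inclusion biases the automated measurement upward", {
  cfg <- cohort_config(n_cases = 400L, seed = 31L)
  truth <- sample_cohort(cfg, masks = FALSE)$truth
  model <- auto_seg_error_model(detect_intercept = 1e6, detect_slope = 0,
                                p_partial = 0, p_distractor_include = 0)
  meas <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    simulate_auto_segmentation(NULL, truth[i, ], model, seed = 1000L + i)
  }))
  ivh <- truth$ivh_present
  bias <- meas$volume_mL - truth$true_ich_volume_mL
  expect_gt(mean(bias[ivh]), mean(bias[!ivh]))
  expect_gt(mean(bias[ivh]), 0)
})

test_that("the calibrated detection model reproduces the study's missingness pattern", {
  stats <- t(sapply(1:20, function(s) {
    truth <- sample_cohort(cohort_config(n_cases = 300L, seed = 100L + s),
                           masks = FALSE)$truth
    model <- auto_seg_error_model()
    missed <- sapply(seq_len(300L), function(i) {
      simulate_auto_segmentation(NULL, truth[i, ], model,
                                 seed = s * 1000L + i)$missed
    })
    c(det = mean(!missed),
      med_missed = median(truth$true_ich_volume_mL[missed]),
      med_det = median(truth$true_ich_volume_mL[!missed]))
  }))
  expect_gt(mean(stats[, "det"]), 0.78)
  expect_lt(mean(stats[, "det"]), 0.88)
  # the missed cases are the small haematomas
  expect_true(all(stats[, "med_missed"] < stats[, "med_det"]))
})

test_that("ABC/2 reader noise behaves as specified", {
  ideal <- abc2_measurement(5, 4, 3, thickness_cm = 0.1)
  expect_equal(simulate_abc2_reader(ideal, 0, seed = 1)$volume_mL,
               ideal$volume_mL)
  r1 <- simulate_abc2_reader(ideal, 0.05, seed = 9, case_id = "c1")
  r1b <- simulate_abc2_reader(ideal, 0.05, seed = 9, case_id = "c1")
  expect_identical(r1, r1b)
  expect_false(r1$volume_mL == ideal$volume_mL)

  # two readers over a volume-heterogeneous case mix: ICC stays high
  set.seed(4)
  vols <- rlnorm(200, log(26), 1.37)
  ratings <- do.call(rbind, lapply(seq_along(vols), function(i) {
    base <- abc2_measurement(2 * (vols[i] * 3 / (4 * pi))^(1 / 3),
                             1.8 * (vols[i] * 3 / (4 * pi))^(1 / 3),
                             1.5 * (vols[i] * 3 / (4 * pi))^(1 / 3),
                             thickness_cm = 0.1)
    rbind(simulate_abc2_reader(base, 0.05, seed = 2L * i, case_id = i,
                               reader_id = "r1"),
          simulate_abc2_reader(base, 0.05, seed = 2L * i + 1L, case_id = i,
                               reader_id = "r2"))
  }))
  expect_gt(icc_oneway(ratings)$icc, 0.9)
})

test_that("measurement records enforce the missingness and flag rules", {
  expect_error(measurement_record("c1", "auto_sim", volume_mL = 5,
                                  missed = TRUE),
               "missing volume")
  expect_error(measurement_record("c1", "reference_voxel", volume_mL = 5,
                                  partial = TRUE),
               "reference")
  rec <- measurement_record("c1", "auto_sim", missed = TRUE)
  expect_true(is.na(rec$volume_mL))
})

test_that("measurement tables round-trip through CSV with empty missing fields", {
  recs <- rbind(
    measurement_record("c1", "auto_sim", missed = TRUE),
    measurement_record("c1", "reference_voxel", volume_mL = 12.5),
    measurement_record("c2", "abc2", volume_mL = 30, reader_id = "reader_1"))
  path <- tempfile(fileext = ".csv")
  write_measurements(recs, path)
  raw <- readLines(path)
  expect_match(raw[2], ",,", fixed = TRUE)  # missing volume as empty field
  back <- read_measurements(path)
  expect_equal(back$volume_mL, recs$volume_mL)
  expect_equal(back$missed, recs$missed)
  unlink(path)
})
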