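test_that("spheroid detection recovers disc diameter and flags QC cases", {
  ph <- generate_spheroid_series(spheroid_phantom_params(
    doses_mM = 0, timepoints_h = 1, n_per_condition = 4, noise_sd = 0,
    seed = 21))
  for (i in seq_along(ph$wells)) {
    img <- ph$wells[[i]]
    det <- detect_spheroid(img$channels$brightfield, img$um_per_px)
    expect_true(det$qc_pass)
    true_d <- ph$truth$plate$true_diameter_um[i]
    expect_lt(abs(det$diameter_um - true_d) / true_d, 0.02)
  }
  blank <- detect_spheroid(matrix(45000, 120, 120), 5)
  expect_false(blank$qc_pass)
  expect_identical(blank$qc_flags, "blank_well")
})

test_that("two objects in a well select the larger with a warning flag", {
  bf <- matrix(45000, 160, 160)
  px <- rep(seq_len(160) - 0.5, each = 160)
  py <- rep(seq_len(160) - 0.5, times = 160)
  bf[matrix((px - 50)^2 + (py - 50)^2 <= 40^2, 160, 160)] <- 15000
  bf[matrix((px - 120)^2 + (py - 120)^2 <= 15^2, 160, 160)] <- 15000
  det <- detect_spheroid(bf, 5)
  expect_true(det$qc_pass)
  expect_true("multiple_objects" %in% det$qc_flags)
  expect_lt(abs(det$diameter_um - 2 * 40 * 5) / (2 * 40 * 5), 0.02)
})

test_that("masked mean intensity matches closed-form phantom geometry", {
  expect_equal(mean_red_intensity(matrix(50, 8, 8), matrix(TRUE, 8, 8)),
               50)
  half <- matrix(rep(c(0, 100), each = 32), 8, 8)
  expect_equal(mean_red_intensity(half, matrix(TRUE, 8, 8)), 50)
  expect_error(mean_red_intensity(half, matrix(FALSE, 8, 8)), "empty")
  # core multiplier 0.4: area-weighted mean over the spheroid mask
  p <- spheroid_phantom_params(doses_mM = c(0, 2.4), timepoints_h = 1,
                               n_per_condition = 2, noise_sd = 0,
                               seed = 3)
  ph <- generate_spheroid_series(p)
  i <- which(ph$truth$plate$dose_mM == 2.4)[1]
  img <- ph$wells[[i]]
  det <- detect_spheroid(img$channels$brightfield, img$um_per_px)
  mult <- ph$truth$plate$true_multiplier[i]
  w <- p$core_fraction^2            # core area fraction of the spheroid
  analytic <- w * (p$red_background + p$core_intensity * mult) +
    (1 - w) * p$red_background
  got <- mean_red_intensity(img$channels$red_hypoxia, det$mask)
  expect_lt(abs(got - analytic) / analytic, 0.02)
})

test_that("dose-time summary normalises to same-timepoint controls", {
  ph <- generate_spheroid_series(spheroid_phantom_params(
    doses_mM = c(0, 1.2, 9.6), timepoints_h = c(1, 24),
    n_per_condition = 4, noise_sd = 200, seed = 31))
  obs <- measure_spheroid_series(ph$wells, ph$truth$plate)
  summ <- dose_time_summary(obs)
  # control ratio exactly 1 at every timepoint
  expect_identical(summ$ratio_to_control[summ$dose_mM == 0], c(1, 1))
  # top dose at 1 h strongly reduced and significant
  top <- summ[summ$dose_mM == 9.6 & summ$timepoint_h == 1, ]
  expect_lt(top$ratio_to_control, 0.5)
  expect_lt(top$p, 0.05)
  # re-emergence: low-dose ratio at 24 h above its 1 h value
  low <- summ[summ$dose_mM == 1.2, ]
  expect_gt(low$ratio_to_control[low$timepoint_h == 24],
            low$ratio_to_control[low$timepoint_h == 1])
  # missing control cell errors with the timepoint named
  expect_error(dose_time_summary(obs[obs$dose_mM > 0 |
                                       obs$timepoint_h == 1, ]),
               "control at timepoint 24")
})

test_that("identical dose and control intensities give ratio 1 and p 1", {
  obs <- data.frame(dose_mM = rep(c(0, 2.4), each = 3), timepoint_h = 1,
                    mean_red_intensity = 500)
  summ <- dose_time_summary(obs)
  expect_equal(summ$ratio_to_control, c(1, 1))
  expect_equal(summ$p[summ$dose_mM == 2.4], 1)
})

test_that("paired testing across replicate experiments is used when keyed", {
  set.seed(4)
  obs <- expand.grid(dose_mM = c(0, 4.8), timepoint_h = 1,
                     experiment_id = c("e1", "e2", "e3"),
                     rep = 1:4)
  obs$mean_red_intensity <- ifelse(obs$dose_mM == 0, 1000, 400) +
    rnorm(nrow(obs), sd = 30)
  summ <- dose_time_summary(obs)
  expect_identical(summ$method[summ$dose_mM == 4.8], "paired t")
  expect_lt(summ$p[summ$dose_mM == 4.8], 0.05)
})
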