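test_that("section phantom realises requested category fractions", {
  ph <- generate_section_phantom(section_phantom_params(
    baseline_hypoxic_fraction = 0.30, reoxygenated_fraction = 0.5,
    seed = 7))
  tr <- ph$truth
  n_roi <- sum(tr$roi_mask)
  # reoxygenated category = 0.5 * 0.30 of ROI, within 2 pp
  meas <- sum(tr$true_cci_mask & !tr$true_pimo_mask) / n_roi
  expect_lt(abs(meas - 0.15), 0.02)
  # stored fractions recomputable from the masks exactly
  expect_identical(unname(tr$true_category_fractions["reoxygenated"]), meas)
  expect_identical(unname(tr$true_category_fractions["no_change"]),
                   sum(tr$true_cci_mask & tr$true_pimo_mask) / n_roi)
  # masks restricted to ROI
  expect_false(any(tr$true_cci_mask & !tr$roi_mask))
  expect_false(any(tr$true_pimo_mask & !tr$roi_mask))
})

test_that("section phantom degenerate mismatch settings", {
  eq <- generate_section_phantom(section_phantom_params(
    reoxygenated_fraction = 0, new_hypoxia_fraction = 0, seed = 2))
  expect_identical(eq$truth$true_cci_mask, eq$truth$true_pimo_mask)
  full <- generate_section_phantom(section_phantom_params(
    reoxygenated_fraction = 1, new_hypoxia_fraction = 0.1, seed = 2))
  expect_false(any(full$truth$true_cci_mask & full$truth$true_pimo_mask))
})

test_that("infeasible fraction combinations are rejected by name", {
  expect_error(section_phantom_params(baseline_hypoxic_fraction = 0.7,
                                      new_hypoxia_fraction = 0.4),
               "baseline_hypoxic_fraction")
})

test_that("phantoms are deterministic under seed and noiseless channels
          are two-level", {
  a <- generate_section_phantom(section_phantom_params(seed = 11,
                                                       noise_sd = 0))
  b <- generate_section_phantom(section_phantom_params(seed = 11,
                                                       noise_sd = 0))
  expect_identical(a, b)
  expect_length(unique(as.vector(a$image$channels$cci103f)), 2L)
  c <- generate_section_phantom(section_phantom_params(seed = 12,
                                                       noise_sd = 0))
  expect_false(identical(a$image, c$image))
})

test_that("foci phantom ground truth matches its count distribution", {
  z <- generate_foci_phantom(foci_phantom_params(
    n_nuclei = 20, foci_count_distribution = list(name = "poisson",
                                                  lambda = 0),
    seed = 1))
  expect_true(all(z$truth$nuclei$true_foci_count == 0L))
  allpos <- generate_foci_phantom(foci_phantom_params(
    n_nuclei = 20, fraction_cci_positive = 1, seed = 1))
  expect_true(all(allpos$truth$nuclei$cci_positive))
  # Poisson(6) tail: fraction with > 5 foci near closed form 1 - F(5; 6)
  ph <- generate_foci_phantom(foci_phantom_params(
    n_nuclei = 200, image_height_px = 560, image_width_px = 560,
    foci_count_distribution = list(name = "poisson", lambda = 6),
    seed = 3))
  frac <- mean(ph$truth$nuclei$true_foci_count > 5L)
  expect_lt(abs(frac - (1 - ppois(5, 6))), 0.05)
})

test_that("foci phantom nuclei are non-overlapping and capacity-checked", {
  ph <- generate_foci_phantom(foci_phantom_params(n_nuclei = 15, seed = 5))
  d <- as.matrix(dist(ph$truth$nuclei[, c("cx", "cy")]))
  diag(d) <- Inf
  expect_gt(min(d), 2 * 10)  # default radius 10
  expect_error(generate_foci_phantom(foci_phantom_params(
    n_nuclei = 500, image_height_px = 100, image_width_px = 100)),
    "infeasible")
})

test_that("spheroid clearance model obeys its invariants", {
  tps <- c(1, 6, 24)
  expect_equal(core_clearance_multiplier(0, tps), rep(1, 3))
  doses <- c(0, 0.6, 1.2, 2.4, 4.8, 9.6)
  for (tp in tps)
    expect_true(all(diff(core_clearance_multiplier(doses, tp)) <= 0))
  # top dose at 1 h strictly below control
  expect_lt(core_clearance_multiplier(9.6, 1), 1)
  # re-emergence: low-dose multiplier relaxes back toward 1 by 24 h
  expect_gt(core_clearance_multiplier(1.2, 24),
            core_clearance_multiplier(1.2, 1))
})

test_that("spheroid phantoms have the requested geometry", {
  ph <- generate_spheroid_series(spheroid_phantom_params(
    doses_mM = c(0, 2.4), timepoints_h = 1, n_per_condition = 3,
    noise_sd = 0, seed = 9))
  expect_length(ph$wells, 6L)
  for (i in seq_along(ph$wells)) {
    img <- ph$wells[[i]]
    # disc diameter from pixel count within 1 px of requested
    a <- sum(img$channels$brightfield <
               spheroid_phantom_params()$bf_background)
    d_px <- 2 * sqrt(a / pi)
    expect_lt(abs(d_px - ph$truth$plate$true_diameter_um[i] /
                    img$um_per_px), 1)
  }
})
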