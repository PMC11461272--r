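test_that("preset threshold applies the >= rule inside the ROI", {
  roi <- rand_mask(16, 16, 0.8)
  u100 <- matrix(100, 16, 16)
  expect_identical(preset_threshold(u100, roi, 50)$mask, roi)
  expect_false(any(preset_threshold(u100, roi, 101)$mask))
  expect_true(all(preset_threshold(u100, roi, 100)$mask == roi))
  expect_error(preset_threshold(u100, roi & FALSE, 50), "empty ROI")
})

test_that("preset threshold recovers a two-level phantom's true mask", {
  ph <- tiny_section(f_reox = 0.3, noise_sd = 0)
  ch8 <- to_8bit(ph$image$channels$cci103f, 16L)
  # levels 40000 -> 156, 6000 -> 23 on the 8-bit scale
  mm <- preset_threshold(ch8, ph$truth$roi_mask, 110)
  expect_identical(mm$mask, ph$truth$true_cci_mask)
})

test_that("Otsu matches an exhaustive between-class-variance search", {
  set.seed(101)
  for (k in 1:25) {
    # mixture histograms of varying separation and weight
    n <- 400
    mu <- sort(sample(20:230, 2))
    v <- c(pmin(pmax(round(rnorm(n * runif(1, 0.2, 0.8), mu[1], 12)), 0),
                255),
           pmin(pmax(round(rnorm(n, mu[2], 18)), 0), 255))
    ch <- matrix(v[seq_len(144)], 12, 12)
    roi <- matrix(TRUE, 12, 12)
    got <- otsu_threshold(ch, roi, bit_depth = 8L)$threshold_value
    expect_identical(got, otsu_bruteforce(ch[roi]))
  }
})

test_that("Otsu separates a two-value histogram exactly and recovers the
          phantom mask", {
  ch <- matrix(c(rep(40L, 60), rep(180L, 40)), 10, 10)
  roi <- matrix(TRUE, 10, 10)
  mm <- otsu_threshold(ch, roi, bit_depth = 8L)
  expect_true(mm$threshold_value > 40 && mm$threshold_value <= 180)
  expect_identical(mm$mask, ch >= 180L)
  ph <- tiny_section(f_reox = 0.4, noise_sd = 0)
  got <- otsu_threshold(ph$image$channels$cci103f, ph$truth$roi_mask,
                        bit_depth = 16L)
  expect_identical(got$mask, ph$truth$true_cci_mask)
  expect_error(otsu_threshold(matrix(7L, 4, 4), matrix(TRUE, 4, 4),
                              bit_depth = 8L), "no threshold")
})

test_that("category arithmetic matches the per-pixel truth table", {
  set.seed(77)
  for (k in 1:10) {
    roi <- rand_mask(8, 8, 0.9)
    cci <- rand_mask(8, 8) & roi
    pim <- rand_mask(8, 8) & roi
    cmap <- classify_categories(cci, pim, roi)
    expect_identical(cmap$labels, classify_bruteforce(cci, pim, roi))
  }
  expect_error(classify_categories(rand_mask(4, 4), rand_mask(5, 5),
                                   rand_mask(4, 4)), "shape mismatch")
})

test_that("category degenerate cases behave per the set algebra", {
  roi <- matrix(TRUE, 6, 6)
  m <- rand_mask(6, 6)
  same <- classify_categories(m, m, roi)
  expect_false(any(same$labels %in% c("reoxygenated", "new_hypoxia")))
  expect_identical(category_mask(same, "no_change"), m)
  a <- m; b <- !m
  disj <- classify_categories(a, b, roi)
  expect_identical(category_mask(disj, "reoxygenated"), a)
  expect_identical(category_mask(disj, "new_hypoxia"), b)
  expect_false(any(category_mask(disj, "no_change")))
})

test_that("partition, symmetry and monotonicity invariants hold", {
  set.seed(5)
  for (k in 1:20) {
    roi <- rand_mask(12, 12, 0.85)
    cci <- rand_mask(12, 12) & roi
    pim <- rand_mask(12, 12) & roi
    cmap <- classify_categories(cci, pim, roi)
    # partition identity
    un <- sum(cci | pim)
    parts <- sum(category_mask(cmap, "reoxygenated")) +
      sum(category_mask(cmap, "new_hypoxia")) +
      sum(category_mask(cmap, "no_change"))
    expect_identical(parts, un)
    # swapping markers swaps reoxygenated and new hypoxia
    sw <- classify_categories(pim, cci, roi)
    expect_identical(category_mask(sw, "reoxygenated"),
                     category_mask(cmap, "new_hypoxia"))
    expect_identical(category_mask(sw, "no_change"),
                     category_mask(cmap, "no_change"))
    # growing pimonidazole never grows the reoxygenated area
    pim2 <- (pim | rand_mask(12, 12)) & roi
    cm2 <- classify_categories(cci, pim2, roi)
    expect_lte(sum(category_mask(cm2, "reoxygenated")),
               sum(category_mask(cmap, "reoxygenated")))
  }
})

test_that("optional post-filters clean small objects and holes", {
  roi <- matrix(TRUE, 12, 12)
  cci <- matrix(FALSE, 12, 12)
  cci[3:8, 3:8] <- TRUE; cci[5, 5] <- FALSE   # hole
  cci[11, 11] <- TRUE                          # 1-px speck
  pim <- matrix(FALSE, 12, 12)
  raw <- classify_categories(cci, pim, roi)
  expect_equal(sum(category_mask(raw, "reoxygenated")), 36L - 1L + 1L)
  filt <- classify_categories(cci, pim, roi, min_object_px = 4L,
                              fill_holes = TRUE)
  expect_equal(sum(category_mask(filt, "reoxygenated")), 36L)
})

test_that("percent area and integrated density match brute-force sums", {
  roi <- rand_mask(8, 8, 0.9)
  expect_equal(percent_area(roi, roi), 100)
  expect_equal(percent_area(roi & FALSE, roi), 0)
  set.seed(8)
  ch <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  m <- rand_mask(8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) if (m[i, j]) acc <- acc + ch[i, j]
  expect_equal(integrated_density(ch, m), acc)
  expect_equal(integrated_density(ch, m & FALSE), 0)
  u <- matrix(10, 10, 10)
  expect_equal(integrated_density(u, u > 0), 1000)
})

test_that("phantom percent areas track the generator ground truth", {
  ph <- tiny_section(f_reox = 0, noise_sd = 0, seed = 4)
  mm <- otsu_threshold(ph$image$channels$cci103f, ph$truth$roi_mask)
  expect_lt(abs(percent_area(mm, ph$truth$roi_mask) - 30), 2)
})
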