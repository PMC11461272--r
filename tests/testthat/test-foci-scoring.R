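test_that("region selection is seeded, qualifying and non-overlapping", {
  # build a category map with known reoxygenated tiles
  roi <- matrix(TRUE, 96, 96)
  cci <- matrix(FALSE, 96, 96)
  # 9 tiles of the 32-px grid fully reoxygenated
  for (b in 0:8) {
    y0 <- (b %/% 3) * 32; x0 <- (b %% 3) * 32
    cci[(y0 + 1):(y0 + 32), (x0 + 1):(x0 + 32)] <- TRUE
  }
  cmap <- classify_categories(cci, matrix(FALSE, 96, 96), roi)
  sel <- select_reoxygenated_regions(cmap, n_regions = 6,
                                     region_size_px = 32, seed = 5)
  expect_equal(nrow(sel), 6L)
  expect_identical(sel, select_reoxygenated_regions(
    cmap, n_regions = 6, region_size_px = 32, seed = 5))
  # windows from the grid never overlap
  expect_false(anyDuplicated(sel[, c("x0", "y0")]) > 0)
  # zero reoxygenated pixels -> error reporting the candidate count
  empty <- classify_categories(matrix(FALSE, 96, 96),
                               matrix(FALSE, 96, 96), roi)
  expect_error(select_reoxygenated_regions(empty, 6, 32, 1), "found 0")
})

test_that("nuclei segmentation counts well-separated and touching nuclei", {
  ph <- generate_foci_phantom(foci_phantom_params(n_nuclei = 12, seed = 2))
  labs <- segment_nuclei(ph$image$channels$nuclei)
  expect_equal(max(labs), 12L)
  expect_equal(max(segment_nuclei(matrix(1000, 64, 64))), 0L)
  # two touching discs with distinct centres split by the watershed
  m <- matrix(2000, 80, 80)
  for (cx in c(30, 49)) {
    px <- rep(seq_len(80) - 0.5, each = 80)
    py <- rep(seq_len(80) - 0.5, times = 80)
    m[matrix((px - cx)^2 + (py - 40)^2 <= 100, 80, 80)] <- 30000
  }
  expect_equal(max(segment_nuclei(m)), 2L)
})

test_that("foci counting is exact on noiseless phantoms for 0-10 foci", {
  ph <- generate_foci_phantom(foci_phantom_params(
    n_nuclei = 22, image_height_px = 200, image_width_px = 280,
    foci_count_distribution = list(name = "fixed", counts = 0:10),
    noise_sd = 0, seed = 3))
  cells <- score_field(ph$image, cci_mask = ph$truth$cci_mask)
  tr <- ph$truth$nuclei
  truth <- vapply(seq_len(nrow(cells)), function(i) {
    j <- which.min((tr$cx - cells$cx[i])^2 + (tr$cy - cells$cy[i])^2)
    tr$true_foci_count[j]
  }, 0L)
  expect_identical(cells$foci_count, truth)
})

test_that("foci below the prominence threshold are not counted", {
  ph <- generate_foci_phantom(foci_phantom_params(
    n_nuclei = 4, foci_count_distribution = list(name = "fixed",
                                                 counts = 3),
    noise_sd = 0, seed = 6))
  labs <- segment_nuclei(ph$image$channels$nuclei)
  n1 <- labs == 1
  expect_equal(count_foci(ph$image$channels$phospho_atm, n1), 3L)
  expect_equal(count_foci(ph$image$channels$phospho_atm, n1,
                          min_prominence = 0.9), 0L)
  expect_error(count_foci(ph$image$channels$phospho_atm,
                          labs == 99), "empty nucleus")
})

test_that("cell scoring applies the majority CCI rule and class bounds", {
  labs <- matrix(0L, 10, 10)
  labs[2:4, 2:4] <- 1L; labs[7:9, 7:9] <- 2L
  cci <- matrix(FALSE, 10, 10); cci[1:5, 1:5] <- TRUE
  cells <- score_cells(labs, c(6L, 5L), cci)
  expect_identical(cells$cci_status, c("positive", "negative"))
  # the >5 boundary: 6 is high, 5 is low
  expect_identical(cells$foci_class, c("high", "low"))
  expect_identical(score_cells(labs, c(0L, 1L), cci)$foci_class,
                   c("none", "low"))
  expect_error(score_cells(labs, c(1L), cci), "length")
})

test_that("stratified aggregation enforces QC and is order-invariant", {
  set.seed(9)
  cells <- data.frame(
    nucleus_id = 1:160, cx = 0, cy = 0, area_px = 50L,
    cci_status = rep(c("negative", "positive"), c(100, 60)),
    foci_count = c(rep(c(7L, 0L), c(41, 59)),      # 41% high in negatives
                   rep(c(6L, 1L), c(21, 39))),
    foci_class = NA, field_id = 1L, region_id = 1L)
  small <- data.frame(nucleus_id = 1:10, cx = 0, cy = 0, area_px = 50L,
                      cci_status = "negative", foci_count = 9L,
                      foci_class = NA, field_id = 2L, region_id = 1L)
  rep1 <- aggregate_foci(rbind(cells, small), min_fields_per_region = 1L)
  neg <- rep1$strata[rep1$strata$cci_status == "negative", ]
  pos <- rep1$strata[rep1$strata$cci_status == "positive", ]
  expect_equal(neg$pct_high_foci, 41)
  expect_equal(pos$pct_high_foci, 35)
  expect_false(rep1$fields$retained[rep1$fields$n_cells == 10L])
  # permuting rows does not change the stratified percentages
  perm <- rbind(cells, small)[sample(170), ]
  rep2 <- aggregate_foci(perm, min_fields_per_region = 1L)
  expect_equal(rep2$strata[order(rep2$strata$cci_status), ],
               rep1$strata[order(rep1$strata$cci_status), ],
               ignore_attr = TRUE)
  # all fields under the minimum -> error; absent stratum -> no row
  expect_error(aggregate_foci(small), "all fields excluded")
  only_neg <- aggregate_foci(cells[cells$cci_status == "negative", ],
                             min_fields_per_region = 1L)
  expect_false("positive" %in% only_neg$strata$cci_status)
})

test_that("empirical high-foci fraction approaches the Poisson tail", {
  ph <- generate_foci_phantom(foci_phantom_params(
    n_nuclei = 250, image_height_px = 620, image_width_px = 620,
    foci_count_distribution = list(name = "poisson", lambda = 2),
    seed = 13))
  frac <- mean(ph$truth$nuclei$true_foci_count > 5L)
  expect_lt(abs(frac - (1 - ppois(5, 2))), 0.05)
})
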