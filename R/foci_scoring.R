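#' @title Phospho-ATM foci scoring stratified by baseline hypoxia
#' @name foci_scoring
#' @description Detects nuclei and punctate phospho-ATM foci, classifies
#'   each cell by foci burden (none / 1-5 / >5) and CCI-103F status, and
#'   aggregates per high-power field and region with the study's sampling
#'   scheme (6 random reoxygenated regions, >= 5 fields each, >= 50 cells
#'   per field).
NULL

#' Select random reoxygenated regions from a category map
#'
#' Candidate windows are the non-overlapping tiles of a regular grid whose
#' reoxygenated-category fraction exceeds `min_reox_frac`; `n_regions` of
#' them are sampled uniformly without replacement. Deterministic under
#' `seed`.
#'
#' @param cmap a `CategoryMap`.
#' @param n_regions regions to select (default 6).
#' @param region_size_px window side length in pixels.
#' @param seed integer seed.
#' @param min_reox_frac minimum reoxygenated fraction of a window
#'   (default 0.2).
#' @return data.frame of `FieldSpec` regions: `region_id`, `x0`, `y0`,
#'   `x1`, `y1` (0-based, half-open pixel bounds).
#' @export
select_reoxygenated_regions <- function(cmap, n_regions = 6L,
                                        region_size_px = 64L, seed = 1L,
                                        min_reox_frac = 0.2) {
  .assert(inherits(cmap, "CategoryMap"), "cmap must be a CategoryMap")
  reox <- category_mask(cmap, "reoxygenated")
  h <- nrow(reox); w <- ncol(reox); s <- as.integer(region_size_px)
  .assert(s >= 1L && s <= min(h, w), "region_size_px out of range")
  ys <- seq(0L, h - s, by = s); xs <- seq(0L, w - s, by = s)
  cand <- list()
  for (y0 in ys) for (x0 in xs) {
    frac <- mean(reox[(y0 + 1L):(y0 + s), (x0 + 1L):(x0 + s)])
    if (frac > min_reox_frac)
      cand[[length(cand) + 1L]] <- c(x0 = x0, y0 = y0)
  }
  .assert(length(cand) >= n_regions,
          "insufficient candidate regions: found %d, need %d",
          length(cand), n_regions)
  set.seed(seed)
  pick <- sample(length(cand), n_regions)
  sel <- do.call(rbind, cand[pick])
  data.frame(region_id = seq_len(n_regions),
             x0 = sel[, "x0"], y0 = sel[, "y0"],
             x1 = sel[, "x0"] + s, y1 = sel[, "y0"] + s)
}

#' Segment nuclei in a field
#'
#' Otsu threshold on the (8-bit converted) nuclei channel, hole filling, a
#' minimum-area filter, and a distance-map watershed to split touching
#' nuclei. An empty field yields zero labels, not an error.
#'
#' @param nuclei numeric nuclei-channel matrix (the field crop).
#' @param bit_depth depth of the channel.
#' @param min_area_px minimum nucleus area kept (default 30).
#' @return integer label matrix (0 = background, 1..n = nuclei).
#' @export
segment_nuclei <- function(nuclei, bit_depth = 16L, min_area_px = 30L) {
  n8 <- to_8bit(nuclei, bit_depth)
  if (length(unique(as.vector(n8))) < 2L)
    return(matrix(0L, nrow(n8), ncol(n8)))
  roi_all <- matrix(TRUE, nrow(n8), ncol(n8))
  mm <- otsu_threshold(n8, roi_all, bit_depth = 8L, marker = "nuclei")
  mask <- .mat(EBImage::fillHull(mm$mask)) > 0
  if (!any(mask)) return(matrix(0L, nrow(n8), ncol(n8)))
  dm <- .mat(EBImage::distmap(mask))
  lab <- .mat(EBImage::watershed(EBImage::as.Image(dm)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  out <- matrix(match(lab, keep, nomatch = 0L), nrow(lab), ncol(lab))
  storage.mode(out) <- "integer"
  out
}

# scale-normalised difference-of-Gaussians response, calibrated so a
# Gaussian spot of sd `sigma` and amplitude A peaks at ~A
.dog_response <- function(x, sigma) {
  s2 <- 1.6 * sigma
  dog <- .gblur(x, sigma) - .gblur(x, s2)
  gain <- sigma^2 / (sigma^2 + sigma^2) - sigma^2 / (sigma^2 + s2^2)
  dog / gain
}

#' Count punctate foci inside one nucleus
#'
#' Blob detection: a scale-matched difference-of-Gaussians (Laplacian of
#' Gaussian approximation) response is computed over the channel, local
#' maxima (3x3 plateau-aware) above an absolute prominence threshold are
#' found, and those inside the nucleus mask are counted. Deterministic.
#'
#' @param patm phospho-ATM channel matrix (native depth).
#' @param nucleus_mask logical matrix selecting one nucleus.
#' @param foci_sigma_px expected focus scale (Gaussian sd) in pixels.
#' @param min_prominence detection threshold as a fraction of the channel
#'   dynamic range (`2^bit_depth - 1`); spots whose calibrated response
#'   falls below it are not counted.
#' @param bit_depth channel depth.
#' @return nonnegative integer count.
#' @export
count_foci <- function(patm, nucleus_mask, foci_sigma_px = 1,
                       min_prominence = 0.1, bit_depth = 16L) {
  .assert(any(nucleus_mask), "empty nucleus mask")
  .assert(identical(dim(patm), dim(nucleus_mask)), "shape mismatch")
  # work on a padded bounding box of the nucleus for speed
  rr <- range(which(rowSums(nucleus_mask) > 0))
  cc <- range(which(colSums(nucleus_mask) > 0))
  pad <- ceiling(6 * foci_sigma_px) + 2L
  r0 <- max(1L, rr[1] - pad); r1 <- min(nrow(patm), rr[2] + pad)
  c0 <- max(1L, cc[1] - pad); c1 <- min(ncol(patm), cc[2] + pad)
  x <- patm[r0:r1, c0:c1, drop = FALSE]
  m <- nucleus_mask[r0:r1, c0:c1, drop = FALSE]
  resp <- .dog_response(x, foci_sigma_px)
  thr <- min_prominence * (2^bit_depth - 1)
  peaks <- (resp >= .max3(resp)) & (resp > thr)
  if (!any(peaks & m)) return(0L)
  # plateau-aware: count connected peak components touching the nucleus
  lab <- .mat(EBImage::bwlabel(peaks))
  length(unique(lab[lab > 0L & m]))
}

#' Score cells by foci burden and CCI-103F status
#'
#' A cell is CCI-positive when at least `cci_min_frac` of its nucleus
#' pixels fall inside the CCI-103F mask (majority rule by default). Foci
#' class is `none` (0), `low` (1-5) or `high` (> 5, i.e. >= 6).
#'
#' @param nuclei_labels integer label matrix from [segment_nuclei()].
#' @param foci_counts integer vector, one count per label `1..max(labels)`.
#' @param cci_mask logical baseline-hypoxia mask, same shape.
#' @param cci_min_frac nucleus fraction required for positivity.
#' @return data.frame of `CellFociScore`: `nucleus_id`, `cx`, `cy`,
#'   `area_px`, `cci_status`, `foci_count`, `foci_class`.
#' @export
score_cells <- function(nuclei_labels, foci_counts, cci_mask,
                        cci_min_frac = 0.5) {
  n <- max(nuclei_labels)
  .assert(length(foci_counts) == n,
          "foci_counts length (%d) != number of labels (%d)",
          length(foci_counts), n)
  if (n == 0L)
    return(data.frame(nucleus_id = integer(), cx = numeric(),
                      cy = numeric(), area_px = integer(),
                      cci_status = character(), foci_count = integer(),
                      foci_class = character()))
  .assert(identical(dim(nuclei_labels), dim(cci_mask)), "shape mismatch")
  idx <- which(nuclei_labels > 0L)
  lab <- nuclei_labels[idx]
  rows <- (idx - 1L) %% nrow(nuclei_labels) + 1L
  cols <- (idx - 1L) %/% nrow(nuclei_labels) + 1L
  area <- tabulate(lab, nbins = n)
  in_cci <- tapply(cci_mask[idx], lab, sum)
  cx <- tapply(cols - 0.5, lab, mean)
  cy <- tapply(rows - 0.5, lab, mean)
  counts <- as.integer(foci_counts)
  data.frame(nucleus_id = seq_len(n),
             cx = as.numeric(cx), cy = as.numeric(cy), area_px = area,
             cci_status = ifelse(as.numeric(in_cci) / area >= cci_min_frac,
                                 "positive", "negative"),
             foci_count = counts,
             foci_class = ifelse(counts == 0L, "none",
                                 ifelse(counts <= 5L, "low", "high")),
             stringsAsFactors = FALSE)
}

#' Score all nuclei of a field
#'
#' Convenience wrapper: segments nuclei, counts foci per nucleus, and
#' scores cells.
#'
#' @param img `SectionImage` with `nuclei`, `phospho_atm` and (optionally)
#'   `cci103f` channels; when `cci_mask` is not given, the `cci103f`
#'   channel is Otsu-thresholded over the full frame.
#' @param cci_mask optional logical baseline-hypoxia mask.
#' @param ... passed to [count_foci()].
#' @return data.frame of cell scores (see [score_cells()]).
#' @export
score_field <- function(img, cci_mask = NULL, ...) {
  .assert(inherits(img, "SectionImage"), "img must be a SectionImage")
  labs <- segment_nuclei(img$channels$nuclei, img$bit_depth)
  n <- max(labs)
  if (is.null(cci_mask)) {
    roi_all <- matrix(TRUE, nrow(labs), ncol(labs))
    cci_mask <- otsu_threshold(img$channels$cci103f, roi_all,
                               bit_depth = img$bit_depth,
                               marker = "cci103f")$mask
  }
  counts <- vapply(seq_len(n), function(i)
    count_foci(img$channels$phospho_atm, labs == i,
               bit_depth = img$bit_depth, ...), 0L)
  score_cells(labs, counts, cci_mask)
}

#' Aggregate cell scores into a stratified foci report
#'
#' Fields with fewer than `min_cells_per_field` scored cells are flagged
#' and excluded from the percentages (quality control mirroring manual
#' exclusion of artefact regions); regions retaining fewer than
#' `min_fields_per_region` fields are flagged. Percentages of cells with
#' any foci and with > 5 foci are reported per CCI-103F stratum, both
#' pooled over retained cells and as per-field means. A stratum with no
#' retained cells is reported as absent (no row), not as 0%.
#'
#' @param cells data.frame of cell scores with added `field_id` and
#'   `region_id` columns.
#' @param min_cells_per_field minimum scored cells per high-power field.
#' @param min_fields_per_region minimum retained fields per region.
#' @return list (`FociReport`): `strata` (per `cci_status`: `n_cells`,
#'   `pct_any_foci`, `pct_high_foci`, `pct_any_foci_fieldmean`,
#'   `pct_high_foci_fieldmean`), `fields` (per-field QC: `n_cells`,
#'   `retained`), `regions` (fields retained per region, flag).
#' @export
aggregate_foci <- function(cells, min_cells_per_field = 50L,
                           min_fields_per_region = 5L) {
  .assert(all(c("field_id", "region_id") %in% names(cells)),
          "cells must carry field_id and region_id")
  fid <- interaction(cells$region_id, cells$field_id, drop = TRUE)
  ncf <- tapply(seq_len(nrow(cells)), fid, length)
  fields <- data.frame(field = names(ncf), n_cells = as.integer(ncf),
                       retained = as.integer(ncf) >= min_cells_per_field)
  .assert(any(fields$retained),
          "all fields excluded by the %d-cell minimum", min_cells_per_field)
  keep <- cells[fid %in% fields$field[fields$retained], , drop = FALSE]
  kfid <- interaction(keep$region_id, keep$field_id, drop = TRUE)
  strata <- do.call(rbind, lapply(split(seq_len(nrow(keep)),
                                        keep$cci_status), function(ix) {
    s <- keep[ix, ]
    per_field_any <- tapply(s$foci_count > 0L, kfid[ix], mean)
    per_field_high <- tapply(s$foci_count >= 6L, kfid[ix], mean)
    data.frame(cci_status = s$cci_status[1L], n_cells = nrow(s),
               pct_any_foci = 100 * mean(s$foci_count > 0L),
               pct_high_foci = 100 * mean(s$foci_count >= 6L),
               pct_any_foci_fieldmean =
                 100 * mean(per_field_any, na.rm = TRUE),
               pct_high_foci_fieldmean =
                 100 * mean(per_field_high, na.rm = TRUE))
  }))
  rownames(strata) <- NULL
  rf <- table(unique(data.frame(r = keep$region_id,
                                f = keep$field_id))$r)
  regions <- data.frame(region_id = names(rf),
                        fields_retained = as.integer(rf),
                        sufficient = as.integer(rf) >=
                          min_fields_per_region)
  list(strata = strata, fields = fields, regions = regions)
}
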