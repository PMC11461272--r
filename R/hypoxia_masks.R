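#' @title Marker thresholding and category mask arithmetic
#' @name hypoxia_masks
#' @description Thresholds each hypoxia-marker channel within the tumour
#'   ROI (global preset value or Otsu on the ROI-restricted 8-bit
#'   histogram) and combines the two marker masks into the three mismatch
#'   categories: reoxygenated (CCI-103F minus overlap), new hypoxia
#'   (pimonidazole minus CCI-103F) and no change (overlap).
NULL

.marker_mask <- function(mask, marker, method, threshold_value, roi) {
  structure(list(mask = mask, marker = marker, method = method,
                 threshold_value = threshold_value,
                 roi_area_px = sum(roi)),
            class = "MarkerMask")
}

#' @export
print.MarkerMask <- function(x, ...) {
  cat(sprintf("MarkerMask [%s, %s @ %g]: %d / %d ROI px positive (%.1f%%)\n",
              x$marker, x$method, x$threshold_value, sum(x$mask),
              x$roi_area_px, 100 * sum(x$mask) / x$roi_area_px))
  invisible(x)
}

#' Threshold a marker channel at a global preset intensity
#'
#' A pixel is marker-positive iff its intensity is at least
#' `threshold_value` and it lies inside the ROI.
#'
#' @param channel numeric intensity matrix.
#' @param roi logical ROI mask, same shape.
#' @param threshold_value preset global intensity threshold.
#' @param marker channel-role label carried into the result.
#' @return a `MarkerMask`.
#' @export
preset_threshold <- function(channel, roi, threshold_value,
                             marker = "cci103f") {
  .assert(identical(dim(channel), dim(roi)), "channel/ROI shape mismatch")
  .assert(sum(roi) > 0L, "empty ROI")
  .assert(is.finite(threshold_value), "threshold must be finite")
  .marker_mask(channel >= threshold_value & roi, marker, "preset",
               threshold_value, roi)
}

# Otsu threshold on an 8-bit histogram (counts over values 0..255).
# Positivity rule is intensity >= t, so classes are {v < t} vs {v >= t};
# candidate thresholds t = 1..255; ties broken toward the lower t.
.otsu_from_hist <- function(counts) {
  counts <- as.numeric(counts)      # avoid integer overflow on large ROIs
  n <- sum(counts)
  v <- 0:255
  w0 <- cumsum(counts)[1:255]                  # |{v < t}| for t = 1..255
  w1 <- n - w0
  s0 <- cumsum(counts * v)[1:255]
  m0 <- ifelse(w0 > 0, s0 / w0, 0)
  m1 <- ifelse(w1 > 0, (sum(counts * v) - s0) / w1, 0)
  bcv <- w0 * w1 * (m0 - m1)^2                 # n^2 * sigma_B^2, same argmax
  valid <- w0 > 0 & w1 > 0
  .assert(any(valid), "no threshold exists: constant image within ROI")
  bcv[!valid] <- -Inf
  which.max(bcv)                               # first max -> lowest t
}

#' Otsu-threshold a marker channel within the ROI
#'
#' The threshold maximises the between-class variance of the 8-bit
#' histogram restricted to ROI pixels (the channel is converted with
#' [to_8bit()] first when 16-bit). Ties are broken toward the lower
#' threshold; positivity is intensity >= threshold on the 8-bit scale.
#'
#' @inheritParams preset_threshold
#' @param bit_depth depth of `channel` (8 or 16).
#' @return a `MarkerMask`; `threshold_value` is on the 8-bit scale.
#' @export
otsu_threshold <- function(channel, roi, bit_depth = 16L,
                           marker = "cci103f") {
  .assert(identical(dim(channel), dim(roi)), "channel/ROI shape mismatch")
  .assert(sum(roi) > 0L, "empty ROI")
  ch8 <- to_8bit(channel, bit_depth)
  vals <- ch8[roi]
  .assert(length(unique(vals)) >= 2L,
          "no threshold exists: constant image within ROI")
  counts <- tabulate(vals + 1L, nbins = 256L)
  t8 <- .otsu_from_hist(counts)
  .marker_mask(ch8 >= t8 & roi, marker, "otsu", t8, roi)
}

.as_mask <- function(x) if (inherits(x, "MarkerMask")) x$mask else x

#' Classify pixels into mismatch categories
#'
#' Implements the mask arithmetic on the thresholded marker images:
#' reoxygenated = CCI \\ Pimo, new hypoxia = Pimo \\ CCI, no change =
#' CCI AND Pimo, background = ROI minus their union; pixels outside the
#' ROI are labelled `outside_roi`. Categories are pairwise disjoint and,
#' with `background` and `outside_roi`, partition the image.
#'
#' Optional post-filters (both off by default, preserving the raw
#' arithmetic): `min_object_px` removes connected components of CCI or
#' pimonidazole smaller than the given size before classification;
#' `fill_holes` fills enclosed holes in each marker mask.
#'
#' @param cci,pimo `MarkerMask` objects (or logical matrices) for CCI-103F
#'   and pimonidazole.
#' @param roi logical ROI mask.
#' @param min_object_px minimum connected-component size kept (0 = off).
#' @param fill_holes fill enclosed holes in marker masks first.
#' @return a `CategoryMap`: list with `labels` (character matrix over
#'   `outside_roi`, `background`, `reoxygenated`, `new_hypoxia`,
#'   `no_change`), the two post-filter settings, and `roi`.
#' @export
classify_categories <- function(cci, pimo, roi, min_object_px = 0L,
                                fill_holes = FALSE) {
  cm <- .as_mask(cci); pm <- .as_mask(pimo)
  .assert(identical(dim(cm), dim(pm)) && identical(dim(cm), dim(roi)),
          "mask shape mismatch")
  post <- function(m) {
    if (fill_holes) m <- .mat(EBImage::fillHull(m)) > 0
    if (min_object_px > 0L) {
      lab <- .mat(EBImage::bwlabel(m))
      keep <- which(tabulate(lab[lab > 0L]) >= min_object_px)
      m <- matrix(lab %in% keep, nrow(m), ncol(m))
    }
    m & roi
  }
  cm <- post(cm); pm <- post(pm)
  labels <- matrix("outside_roi", nrow(cm), ncol(cm))
  labels[roi] <- "background"
  labels[cm & !pm] <- "reoxygenated"
  labels[pm & !cm] <- "new_hypoxia"
  labels[cm & pm] <- "no_change"
  structure(list(labels = labels, roi = roi,
                 min_object_px = min_object_px, fill_holes = fill_holes),
            class = "CategoryMap")
}

#' Category mask accessor
#'
#' @param cmap a `CategoryMap`.
#' @param category one of `reoxygenated`, `new_hypoxia`, `no_change`,
#'   `background`, `outside_roi`.
#' @return logical matrix for that category.
#' @export
category_mask <- function(cmap, category) {
  .assert(inherits(cmap, "CategoryMap"), "not a CategoryMap")
  .assert(category %in% c("reoxygenated", "new_hypoxia", "no_change",
                          "background", "outside_roi"),
          "unknown category '%s'", category)
  cmap$labels == category
}

#' Percent area of a mask within the ROI
#'
#' @param mask a `MarkerMask`, logical matrix, or `CategoryMap` category
#'   mask.
#' @param roi logical ROI mask.
#' @return `100 * |mask| / |ROI|`, a real in `[0, 100]`.
#' @export
percent_area <- function(mask, roi) {
  m <- .as_mask(mask)
  .assert(sum(roi) > 0L, "empty ROI")
  100 * sum(m & roi) / sum(roi)
}

#' Integrated density over a mask
#'
#' Sum of channel intensities over the mask pixels (area times mean
#' intensity). Empty masks give 0.
#'
#' @param channel numeric intensity matrix.
#' @param mask logical matrix (or `MarkerMask`), same shape.
#' @return nonnegative real.
#' @export
integrated_density <- function(channel, mask) {
  m <- .as_mask(mask)
  .assert(identical(dim(channel), dim(m)), "channel/mask shape mismatch")
  sum(as.numeric(channel[m]))
}

#' Per-category pixel counts and percent areas
#'
#' @param cmap a `CategoryMap`.
#' @return data.frame with one row per category (`reoxygenated`,
#'   `new_hypoxia`, `no_change`, `background`): `pixels`, `pct_of_roi`.
#' @export
category_table <- function(cmap) {
  cats <- c("reoxygenated", "new_hypoxia", "no_change", "background")
  n_roi <- sum(cmap$roi)
  px <- vapply(cats, function(k) sum(cmap$labels == k), 0L)
  data.frame(category = cats, pixels = px,
             pct_of_roi = 100 * px / n_roi, row.names = NULL)
}
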