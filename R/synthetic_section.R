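#' @title Paired-marker tumour-section phantoms
#' @name synthetic_section
#' @description Generates two-channel (CCI-103F / pimonidazole) section
#'   phantoms with patchy hypoxia geometry and exactly known ground truth,
#'   standing in for the study's undeposited microscopy.
NULL

#' Parameters for a paired-marker section phantom
#'
#' Hypoxic geometry is a union of smoothed random blobs (a thresholded
#' low-pass Gaussian random field with correlation length `blob_scale_px`),
#' mimicking patchy perfusion-limited hypoxia. Reoxygenation is carved out
#' of the baseline (CCI-103F) mask by removing whole blobs and then eroding
#' the boundary of one more blob until the target pixel count is met
#' exactly; new hypoxia is drawn from an independent field outside the
#' baseline mask.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param roi_polygon an [roi_polygon()] or n x 2 vertex matrix; default an
#'   octagonal inset covering most of the frame.
#' @param baseline_hypoxic_fraction fraction of the ROI positive for
#'   CCI-103F at baseline, in `[0, 1]`.
#' @param reoxygenated_fraction fraction of baseline hypoxia that is NOT
#'   pimonidazole-positive post-treatment, in `[0, 1]`.
#' @param new_hypoxia_fraction fraction of the ROI pimonidazole-positive
#'   but CCI-negative, in `[0, 1]`.
#' @param foreground_intensity_mean,background_intensity_mean channel
#'   intensity levels (16-bit range); foreground must exceed background.
#' @param noise_sd additive Gaussian per-pixel noise SD (0 = noiseless).
#' @param blob_scale_px correlation length of the hypoxic patches.
#' @param um_per_px physical pixel size.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return a validated `SectionPhantomParams` list.
#' @export
section_phantom_params <- function(image_height_px = 256L,
                                   image_width_px = 256L,
                                   roi_polygon = NULL,
                                   baseline_hypoxic_fraction = 0.3,
                                   reoxygenated_fraction = 0,
                                   new_hypoxia_fraction = 0,
                                   foreground_intensity_mean = 40000,
                                   background_intensity_mean = 6000,
                                   noise_sd = 0,
                                   blob_scale_px = 18,
                                   um_per_px = 1,
                                   seed = 1L) {
  h <- as.integer(image_height_px); w <- as.integer(image_width_px)
  .assert(h > 0 && w > 0, "image size must be positive")
  if (is.null(roi_polygon)) {
    # octagon inset ~6% from each edge
    mx <- 0.06 * w; my <- 0.06 * h
    cx <- c(0.30 * w, 0.70 * w, w - mx, w - mx, 0.70 * w, 0.30 * w, mx, mx)
    cy <- c(my, my, 0.30 * h, 0.70 * h, h - my, h - my, 0.70 * h, 0.30 * h)
    roi_polygon <- roi_polygon(cbind(cx, cy))
  }
  if (!inherits(roi_polygon, "RoiPolygon"))
    roi_polygon <- roi_polygon(roi_polygon)
  v <- roi_polygon$vertices
  .assert(all(v[, 1L] >= 0 & v[, 1L] <= w & v[, 2L] >= 0 & v[, 2L] <= h),
          "roi polygon lies outside image bounds")
  for (f in c(baseline_hypoxic_fraction, reoxygenated_fraction,
              new_hypoxia_fraction))
    .assert(is.numeric(f) && f >= 0 && f <= 1, "fractions must be in [0,1]")
  .assert(baseline_hypoxic_fraction + new_hypoxia_fraction <= 1,
          paste("infeasible fractions: baseline_hypoxic_fraction +",
                "new_hypoxia_fraction = %.3f exceeds 1"),
          baseline_hypoxic_fraction + new_hypoxia_fraction)
  .assert(foreground_intensity_mean > background_intensity_mean,
          "foreground_intensity_mean must exceed background_intensity_mean")
  .assert(noise_sd >= 0, "noise_sd must be nonnegative")
  .assert(blob_scale_px > 0, "blob_scale_px must be positive")
  structure(list(image_height_px = h, image_width_px = w,
                 roi_polygon = roi_polygon,
                 baseline_hypoxic_fraction = baseline_hypoxic_fraction,
                 reoxygenated_fraction = reoxygenated_fraction,
                 new_hypoxia_fraction = new_hypoxia_fraction,
                 foreground_intensity_mean = foreground_intensity_mean,
                 background_intensity_mean = background_intensity_mean,
                 noise_sd = noise_sd, blob_scale_px = blob_scale_px,
                 um_per_px = um_per_px, seed = as.integer(seed)),
            class = "SectionPhantomParams")
}

# low-pass Gaussian random field, standardised
.random_field <- function(h, w, scale) {
  f <- .gblur(matrix(rnorm(h * w), h, w), sigma = scale)
  (f - mean(f)) / sd(f)
}

# select exactly k pixels from `pool` (logical) with the highest `field`
# values; deterministic tie-break by linear index
.top_k_mask <- function(field, pool, k) {
  out <- matrix(FALSE, nrow(field), ncol(field))
  if (k <= 0L) return(out)
  idx <- which(pool)
  ord <- idx[order(field[idx], idx, decreasing = c(TRUE, FALSE),
                   method = "radix")]
  out[ord[seq_len(min(k, length(ord)))]] <- TRUE
  out
}

# carve `k` pixels out of `mask`: drop whole connected blobs (seeded random
# order), then peel the final blob boundary-first via its distance map
.carve_mask <- function(mask, k) {
  if (k <= 0L) return(mask)
  if (k >= sum(mask)) return(mask & FALSE)
  lab <- .mat(EBImage::bwlabel(mask))
  sizes <- tabulate(lab[lab > 0L])
  ord <- sample(seq_along(sizes))       # seeded caller RNG
  removed <- 0L
  out <- mask
  for (b in ord) {
    if (removed + sizes[b] <= k) {
      out[lab == b] <- FALSE
      removed <- removed + sizes[b]
      if (removed == k) return(out)
    } else {
      # partial: erode this blob from its boundary inward, exact count
      need <- k - removed
      blob <- lab == b
      dm <- .mat(EBImage::distmap(blob))
      idx <- which(blob)
      peel <- idx[order(dm[idx], idx, method = "radix")][seq_len(need)]
      out[peel] <- FALSE
      return(out)
    }
  }
  out
}

.render_channel <- function(mask, fg, bg, noise_sd) {
  ch <- matrix(bg, nrow(mask), ncol(mask))
  ch[mask] <- fg
  if (noise_sd > 0)
    ch <- ch + rnorm(length(ch), sd = noise_sd)
  ch <- pmin(pmax(floor(ch + 0.5), 0), 65535)
  storage.mode(ch) <- "integer"
  ch
}

#' Generate a paired-marker section phantom
#'
#' Produces a two-channel 16-bit `SectionImage` (roles `cci103f`,
#' `pimonidazole`) plus exact ground truth. The true masks realise the
#' requested category fractions up to blob-count rounding (within 2
#' percentage points; in practice exact to one pixel). At `noise_sd = 0`
#' each channel takes exactly the two configured intensity levels.
#'
#' @param params a [section_phantom_params()].
#' @return list with elements `image` (a `SectionImage`) and `truth` (class
#'   `SectionGroundTruth`: `roi_mask`, `true_cci_mask`, `true_pimo_mask`,
#'   `true_category_fractions` (reoxygenated / new_hypoxia / no_change, as
#'   fractions of the ROI), and `seed`).
#' @export
generate_section_phantom <- function(params) {
  .assert(inherits(params, "SectionPhantomParams"),
          "params must come from section_phantom_params()")
  p <- params
  set.seed(p$seed)
  h <- p$image_height_px; w <- p$image_width_px
  roi <- rasterize_roi(p$roi_polygon, c(h, w))
  n_roi <- sum(roi)
  .assert(n_roi > 0L, "ROI rasterises to an empty mask")

  f1 <- .random_field(h, w, p$blob_scale_px)
  k_cci <- round(p$baseline_hypoxic_fraction * n_roi)
  cci <- .top_k_mask(f1, roi, k_cci)

  k_reox <- round(p$reoxygenated_fraction * sum(cci))
  kept <- .carve_mask(cci, k_reox)      # pimonidazole-positive part of cci

  f2 <- .random_field(h, w, p$blob_scale_px)
  k_new <- round(p$new_hypoxia_fraction * n_roi)
  newh <- .top_k_mask(f2, roi & !cci, k_new)

  pimo <- kept | newh
  fracs <- c(reoxygenated = sum(cci & !pimo) / n_roi,
             new_hypoxia = sum(pimo & !cci) / n_roi,
             no_change = sum(cci & pimo) / n_roi)

  img <- section_image(
    list(cci103f = .render_channel(cci, p$foreground_intensity_mean,
                                   p$background_intensity_mean, p$noise_sd),
         pimonidazole = .render_channel(pimo, p$foreground_intensity_mean,
                                        p$background_intensity_mean,
                                        p$noise_sd)),
    um_per_px = p$um_per_px, bit_depth = 16L,
    provenance = sprintf("section phantom seed=%d", p$seed))
  truth <- structure(list(roi_mask = roi, true_cci_mask = cci,
                          true_pimo_mask = pimo,
                          true_category_fractions = fracs,
                          seed = p$seed),
                     class = "SectionGroundTruth")
  list(image = img, truth = truth)
}
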