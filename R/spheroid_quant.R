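#' @title Spheroid diameter and hypoxia-reporter quantification
#' @name spheroid_quant
#' @description Segments one spheroid per brightfield well image,
#'   measures its equivalent-circle diameter and the masked mean red
#'   (hypoxia reporter) fluorescence, and summarises intensity relative
#'   to same-timepoint untreated controls over a dose-by-time grid.
NULL

#' Detect the spheroid in a brightfield well image
#'
#' Otsu threshold on the inverted (8-bit converted) brightfield selects
#' dark objects; the largest hole-filled connected component above
#' `min_area_px` is the spheroid. Diameter is the equivalent-circle
#' diameter from the component area. A circularity check
#' (`4*pi*A / P^2`) flags disaggregated spheroids rather than silently
#' excluding them; a second large component yields a QC warning flag.
#'
#' @param brightfield numeric matrix.
#' @param um_per_px pixel size.
#' @param bit_depth channel depth.
#' @param min_area_px minimum component area (default 200).
#' @param min_circularity QC threshold on `4*pi*A/P^2` (default 0.6).
#' @return list (`SpheroidObservation` geometry): `mask` (logical),
#'   `diameter_um`, `qc_pass`, `qc_flags` (character vector).
#' @export
detect_spheroid <- function(brightfield, um_per_px, bit_depth = 16L,
                            min_area_px = 200L, min_circularity = 0.6) {
  inv <- (2^bit_depth - 1) - brightfield
  flags <- character()
  roi_all <- matrix(TRUE, nrow(inv), ncol(inv))
  if (length(unique(as.vector(to_8bit(inv, bit_depth)))) < 2L)
    return(list(mask = matrix(FALSE, nrow(inv), ncol(inv)),
                diameter_um = NA_real_, qc_pass = FALSE,
                qc_flags = "blank_well"))
  mm <- otsu_threshold(inv, roi_all, bit_depth = bit_depth,
                       marker = "brightfield")
  mask <- .mat(EBImage::fillHull(mm$mask)) > 0
  lab <- .mat(EBImage::bwlabel(mask))
  sizes <- tabulate(lab[lab > 0L])
  big <- which(sizes >= min_area_px)
  if (length(big) == 0L)
    return(list(mask = matrix(FALSE, nrow(inv), ncol(inv)),
                diameter_um = NA_real_, qc_pass = FALSE,
                qc_flags = "no_object"))
  if (length(big) > 1L) flags <- c(flags, "multiple_objects")
  best <- big[which.max(sizes[big])]
  sph <- lab == best
  area <- sum(sph)
  feat <- EBImage::computeFeatures.shape(
    EBImage::as.Image((lab == best) * 1))
  per <- feat[1L, "s.perimeter"]
  circ <- 4 * pi * area / per^2
  if (is.finite(circ) && circ < min_circularity)
    flags <- c(flags, "low_circularity")
  list(mask = sph, diameter_um = 2 * sqrt(area / pi) * um_per_px,
       qc_pass = TRUE, qc_flags = flags)
}

#' Masked mean reporter intensity
#'
#' Arithmetic mean of the red-channel intensities over the spheroid mask.
#'
#' @param red numeric red-channel matrix.
#' @param mask logical spheroid mask.
#' @return real.
#' @export
mean_red_intensity <- function(red, mask) {
  .assert(identical(dim(red), dim(mask)), "shape mismatch")
  .assert(any(mask), "empty spheroid mask")
  mean(red[mask])
}

#' Measure a generated or acquired well series
#'
#' Runs [detect_spheroid()] and [mean_red_intensity()] over a list of
#' two-channel well images with a plate map.
#'
#' @param wells list of `SectionImage` (roles `brightfield`,
#'   `red_hypoxia`).
#' @param plate data.frame with `well_id`, `dose_mM`, `timepoint_h` (and
#'   optionally `experiment_id`), one row per well in order.
#' @return data.frame of `SpheroidObservation`: plate columns plus
#'   `diameter_um`, `mean_red_intensity`, `qc_pass`, `qc_flags`.
#' @export
measure_spheroid_series <- function(wells, plate) {
  .assert(length(wells) == nrow(plate), "wells/plate length mismatch")
  res <- lapply(seq_along(wells), function(i) {
    img <- wells[[i]]
    det <- detect_spheroid(img$channels$brightfield, img$um_per_px,
                           img$bit_depth)
    red <- img$channels$red_hypoxia
    mri <- if (det$qc_pass) mean_red_intensity(red, det$mask) else NA_real_
    # well background: median red signal outside the spheroid, used for
    # background-corrected reporter ratios
    bg <- if (det$qc_pass) stats::median(red[!det$mask])
          else stats::median(red)
    data.frame(diameter_um = det$diameter_um, mean_red_intensity = mri,
               background_red = bg, qc_pass = det$qc_pass,
               qc_flags = paste(det$qc_flags, collapse = ";"))
  })
  cbind(plate, do.call(rbind, res))
}

#' Dose-by-time summary relative to untreated controls
#'
#' For every (dose, time) cell: n, mean and SD of reporter intensity, the
#' ratio of the cell mean to the same-timepoint dose-0 control mean (1 by
#' construction at dose 0), and a two-sided t test against control --
#' paired across replicate experiments when `experiment_id` is present
#' (per-experiment means), otherwise Welch's unpaired t on the spheroid
#' intensities.
#'
#' @param obs data.frame from [measure_spheroid_series()] (QC failures are
#'   dropped with a message).
#' @return data.frame (`DoseTimeSummary`): `dose_mM`, `timepoint_h`, `n`,
#'   `mean_intensity`, `sd_intensity`, `ratio_to_control`,
#'   `ratio_bgcorr` (well-background-corrected ratio, the estimator used
#'   to recover core-clearance multipliers; NA when no `background_red`
#'   column is present), `t`, `p`, `method` (`p` is NA for the control
#'   cell itself).
#' @export
dose_time_summary <- function(obs) {
  .assert(all(c("dose_mM", "timepoint_h", "mean_red_intensity") %in%
                names(obs)), "missing required columns")
  if ("qc_pass" %in% names(obs)) {
    n_bad <- sum(!obs$qc_pass)
    if (n_bad > 0) message(n_bad, " QC-failed wells dropped")
    obs <- obs[obs$qc_pass, , drop = FALSE]
  }
  has_exp <- "experiment_id" %in% names(obs) &&
    length(unique(obs$experiment_id)) >= 2L
  out <- list()
  for (tp in sort(unique(obs$timepoint_h))) {
    at_t <- obs[obs$timepoint_h == tp, , drop = FALSE]
    ctrl <- at_t[at_t$dose_mM == 0, , drop = FALSE]
    .assert(nrow(ctrl) >= 2L,
            "missing or insufficient dose-0 control at timepoint %g h", tp)
    for (d in sort(unique(at_t$dose_mM))) {
      cell <- at_t[at_t$dose_mM == d, , drop = FALSE]
      .assert(nrow(cell) >= 2L,
              "fewer than 2 observations at dose %g, %g h", d, tp)
      if (d == 0) {
        tt <- list(statistic = NA_real_, p.value = NA_real_,
                   method = "control")
      } else if (has_exp) {
        xe <- tapply(cell$mean_red_intensity, cell$experiment_id, mean)
        ye <- tapply(ctrl$mean_red_intensity, ctrl$experiment_id, mean)
        common <- intersect(names(xe), names(ye))
        tt <- if (length(common) >= 2L)
          .safe_t_test(as.numeric(xe[common]), as.numeric(ye[common]),
                       paired = TRUE)
        else .safe_t_test(cell$mean_red_intensity,
                          ctrl$mean_red_intensity)
      } else {
        tt <- .safe_t_test(cell$mean_red_intensity,
                           ctrl$mean_red_intensity)
      }
      ratio_bg <- if ("background_red" %in% names(obs))
        mean(cell$mean_red_intensity - cell$background_red) /
          mean(ctrl$mean_red_intensity - ctrl$background_red)
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        dose_mM = d, timepoint_h = tp, n = nrow(cell),
        mean_intensity = mean(cell$mean_red_intensity),
        sd_intensity = sd(cell$mean_red_intensity),
        ratio_to_control = mean(cell$mean_red_intensity) /
          mean(ctrl$mean_red_intensity),
        ratio_bgcorr = ratio_bg,
        t = tt$statistic, p = tt$p.value, method = tt$method)
    }
  }
  do.call(rbind, out)
}
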