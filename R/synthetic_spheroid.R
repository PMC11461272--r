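#' @title Spheroid dose-by-time phantom series
#' @name synthetic_spheroid
#' @description Well-plate image pairs (brightfield + red hypoxia
#'   reporter) for tumour spheroids across an H2O2 dose and time grid,
#'   with a parametric hypoxic-core clearance model as ground truth.
NULL

#' Hypoxic-core clearance multiplier
#'
#' Maps (dose, time) to the fluorescence multiplier of the hypoxic core in
#' `[0, 1]`: `m(d, t) = 1 - c(d) * exp(-t / tau(d))` with saturating
#' clearance `c(d) = d / (d + half_max_mM)` and dose-dependent persistence
#' `tau(d) = tau0_h * (1 + d / dose_ref_mM)`. By construction `m(0, t) = 1`
#' at all times, `m` is non-increasing in dose at any fixed time, and at
#' late times the multiplier relaxes back toward 1 (re-emergence of
#' hypoxia), fastest at low dose.
#'
#' @param dose_mM H2O2 dose in mM (vectorised).
#' @param time_h time post-treatment in hours (vectorised).
#' @param half_max_mM dose of half-maximal clearance (default 1.2 mM, the
#'   lowest dose at which reporter loss is clearly resolvable).
#' @param tau0_h persistence time scale at dose 0+ (default 6 h).
#' @param dose_ref_mM dose scale for persistence growth (default 4.8 mM).
#' @return numeric multiplier in `[0, 1]`.
#' @export
core_clearance_multiplier <- function(dose_mM, time_h, half_max_mM = 1.2,
                                      tau0_h = 6, dose_ref_mM = 4.8) {
  .assert(all(dose_mM >= 0) && all(time_h >= 0),
          "dose and time must be nonnegative")
  cl <- dose_mM / (dose_mM + half_max_mM)
  tau <- tau0_h * (1 + dose_mM / dose_ref_mM)
  1 - cl * exp(-time_h / tau)
}

#' Parameters for a spheroid phantom series
#'
#' @param doses_mM H2O2 doses (default the experimental ladder
#'   0, 0.6, 1.2, 2.4, 4.8, 9.6 mM).
#' @param timepoints_h imaging times post-treatment (default 1, 6, 24 h).
#' @param n_per_condition spheroids per (dose, time) cell (default 14).
#' @param diameter_range_um min/max spheroid diameter (default 400-700 um).
#' @param um_per_px pixel size of the well imager (default 5 um/px).
#' @param core_fraction hypoxic-core diameter as a fraction of the
#'   spheroid diameter.
#' @param core_intensity red-reporter core amplitude at multiplier 1.
#' @param red_background red-channel background level.
#' @param bf_background,bf_spheroid brightfield background / spheroid
#'   levels (spheroid darker).
#' @param clearance_params list passed to [core_clearance_multiplier()].
#' @param noise_sd additive Gaussian noise SD on both channels.
#' @param seed integer seed.
#' @return a validated `SpheroidPhantomParams` list.
#' @export
spheroid_phantom_params <- function(doses_mM = c(0, 0.6, 1.2, 2.4, 4.8, 9.6),
                                    timepoints_h = c(1, 6, 24),
                                    n_per_condition = 14L,
                                    diameter_range_um = c(400, 700),
                                    um_per_px = 5,
                                    core_fraction = 0.6,
                                    core_intensity = 20000,
                                    red_background = 300,
                                    bf_background = 45000,
                                    bf_spheroid = 15000,
                                    clearance_params = list(),
                                    noise_sd = 0,
                                    seed = 1L) {
  .assert(all(doses_mM >= 0), "doses must be nonnegative")
  .assert(all(timepoints_h >= 0), "timepoints must be nonnegative")
  .assert(n_per_condition >= 1L, "n_per_condition must be positive")
  .assert(diameter_range_um[1] > 0 &&
            diameter_range_um[2] >= diameter_range_um[1],
          "invalid diameter range")
  .assert(um_per_px > 0, "um_per_px must be positive")
  .assert(core_fraction > 0 && core_fraction <= 1,
          "core_fraction must be in (0,1]")
  .assert(bf_background > bf_spheroid,
          "brightfield spheroid must be darker than background")
  .assert(noise_sd >= 0, "noise_sd must be nonnegative")
  structure(list(doses_mM = doses_mM, timepoints_h = timepoints_h,
                 n_per_condition = as.integer(n_per_condition),
                 diameter_range_um = diameter_range_um,
                 um_per_px = um_per_px, core_fraction = core_fraction,
                 core_intensity = core_intensity,
                 red_background = red_background,
                 bf_background = bf_background, bf_spheroid = bf_spheroid,
                 clearance_params = clearance_params,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "SpheroidPhantomParams")
}

#' Generate a spheroid dose-by-time image series
#'
#' For every (dose, time, replicate) one two-channel well image is built:
#' brightfield (dark disc on bright background) and red hypoxia reporter
#' (core disc at `core_intensity * multiplier`). True diameters and
#' multipliers are recorded.
#'
#' @param params a [spheroid_phantom_params()].
#' @return list with `wells` (list of `SectionImage`, one per well, roles
#'   `brightfield` and `red_hypoxia`) and `truth` (class
#'   `SectionGroundTruth`: data.frame `plate` with `well_id`, `dose_mM`,
#'   `timepoint_h`, `true_diameter_um`, `true_multiplier`,
#'   `true_core_mean`; plus `seed`).
#' @export
generate_spheroid_series <- function(params) {
  .assert(inherits(params, "SpheroidPhantomParams"),
          "params must come from spheroid_phantom_params()")
  p <- params
  set.seed(p$seed)
  grid <- expand.grid(rep = seq_len(p$n_per_condition),
                      dose_mM = p$doses_mM, timepoint_h = p$timepoints_h,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  dia <- runif(n, p$diameter_range_um[1], p$diameter_range_um[2])
  mult <- do.call(core_clearance_multiplier,
                  c(list(dose_mM = grid$dose_mM,
                         time_h = grid$timepoint_h), p$clearance_params))
  side <- ceiling(p$diameter_range_um[2] / p$um_per_px * 1.5)
  wells <- vector("list", n)
  for (i in seq_len(n)) {
    r_px <- dia[i] / 2 / p$um_per_px
    cx <- side / 2 + runif(1, -3, 3)
    cy <- side / 2 + runif(1, -3, 3)
    sph <- .disc_mask(side, side, cx, cy, r_px)
    core <- .disc_mask(side, side, cx, cy, r_px * p$core_fraction)
    bf <- matrix(p$bf_background, side, side)
    bf[sph] <- p$bf_spheroid
    red <- matrix(p$red_background, side, side)
    red[core] <- p$red_background + p$core_intensity * mult[i]
    if (p$noise_sd > 0) {
      bf <- bf + rnorm(length(bf), sd = p$noise_sd)
      red <- red + rnorm(length(red), sd = p$noise_sd)
    }
    clip <- function(x) {
      x <- pmin(pmax(floor(x + 0.5), 0), 65535)
      storage.mode(x) <- "integer"
      x
    }
    wells[[i]] <- section_image(
      list(brightfield = clip(bf), red_hypoxia = clip(red)),
      um_per_px = p$um_per_px, bit_depth = 16L,
      provenance = sprintf("spheroid phantom well %d seed=%d", i, p$seed))
  }
  plate <- data.frame(well_id = sprintf("W%04d", seq_len(n)),
                      dose_mM = grid$dose_mM,
                      timepoint_h = grid$timepoint_h,
                      replicate = grid$rep,
                      true_diameter_um = dia,
                      true_multiplier = mult,
                      true_core_mean = p$red_background +
                        p$core_intensity * mult)
  truth <- structure(list(plate = plate, seed = p$seed),
                     class = "SectionGroundTruth")
  list(wells = wells, truth = truth)
}
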