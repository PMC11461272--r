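#' @title Reproducible end-to-end pipeline runs
#' @name pipeline
#' @description Orchestrates simulate -> quantify -> foci -> spheroid ->
#'   report as one seeded, manifest-tracked run. Identical configuration
#'   and seeds reproduce byte-identical outputs.
NULL

#' Default pipeline configuration
#'
#' One nested list with a block per stage. The simulated study emulates
#' the animal design: three groups (non-injected, vehicle, KORTUC) of
#' section phantoms whose mean reoxygenated fractions differ, a foci
#' phantom with a higher focus burden in the treated group, and a
#' spheroid dose-by-time series.
#'
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @return a `RunConfig` list.
#' @export
default_run_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    sections = list(
      n_per_group = 3L,
      groups = list(
        non_injected = list(reox_mean = 0.03, reox_sd = 0.02),
        vehicle = list(reox_mean = 0.08, reox_sd = 0.05),
        kortuc = list(reox_mean = 0.55, reox_sd = 0.15)),
      baseline_hypoxic_fraction = 0.3,
      new_hypoxia_fraction = 0.03,
      noise_sd = 1500,
      image_px = 256L,
      threshold_method = "otsu",
      seed = seed + 101L),
    foci = list(
      n_nuclei = 120L,
      lambda = c(positive = 6, negative = 6),
      fraction_cci_positive = 0.4,
      noise_sd = 800,
      seed = seed + 202L),
    spheroid = list(
      n_per_condition = 14L,
      noise_sd = 400,
      seed = seed + 303L)
  )
}

.write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  write.csv(df, path, row.names = FALSE)
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order and writes per-stage
#' CSV outputs plus a JSON manifest (config, seeds, package version,
#' output paths) under `out_dir`. Every stochastic stage draws only from
#' its explicit stage seed, so a rerun from the same config is
#' numerically identical. A stage failure halts the run, names the stage,
#' and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param config a [default_run_config()]-shaped list.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("sections", "foci", "spheroid")`.
#' @return the manifest, invisibly; outputs on disk:
#'   `sections_report.csv`, `section_group_tests.csv`, `foci_cells.csv`,
#'   `foci_strata.csv`, `spheroid_observations.csv`,
#'   `spheroid_summary.csv`, `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("reoxmap_run_"),
                         stages = c("sections", "foci", "spheroid")) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (st in stages)
    .assert(!is.null(config[[st]]$seed),
            "config stage '%s' has no explicit seed", st)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("reoxmap")),
                   config = config, stages = stages, outputs = list())
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if ("sections" %in% stages) run_stage("sections", function() {
    sc <- config$sections
    set.seed(sc$seed)
    rows <- list()
    for (g in names(sc$groups)) {
      gp <- sc$groups[[g]]
      for (i in seq_len(sc$n_per_group)) {
        f <- min(max(rnorm(1, gp$reox_mean, gp$reox_sd), 0), 0.95)
        ph_seed <- sample.int(.Machine$integer.max, 1L)
        ph <- generate_section_phantom(section_phantom_params(
          image_height_px = sc$image_px, image_width_px = sc$image_px,
          baseline_hypoxic_fraction = sc$baseline_hypoxic_fraction,
          reoxygenated_fraction = f,
          new_hypoxia_fraction = sc$new_hypoxia_fraction,
          noise_sd = sc$noise_sd, seed = ph_seed))
        rows[[length(rows) + 1L]] <- cbind(
          score_section(ph$image, ph$truth$roi_mask,
                        tumour_id = sprintf("%s_%02d", g, i), group = g,
                        threshold_method = sc$threshold_method),
          true_reox_fraction = f, phantom_seed = ph_seed)
      }
    }
    rep <- do.call(rbind, rows)
    .write_csv_stable(rep, file.path(out_dir, "sections_report.csv"))
    gs <- group_summary(rep$reox_log2fc, rep$group)
    .write_csv_stable(gs$tests,
                      file.path(out_dir, "section_group_tests.csv"))
    manifest$outputs$sections <<- c("sections_report.csv",
                                    "section_group_tests.csv")
  })

  if ("foci" %in% stages) run_stage("foci", function() {
    fc <- config$foci
    ph <- generate_foci_phantom(foci_phantom_params(
      n_nuclei = fc$n_nuclei, image_height_px = 360L,
      image_width_px = 360L,
      foci_count_distribution = list(name = "poisson",
                                     lambda = fc$lambda),
      fraction_cci_positive = fc$fraction_cci_positive,
      noise_sd = fc$noise_sd, seed = fc$seed))
    cells <- score_field(ph$image, cci_mask = ph$truth$cci_mask)
    cells$field_id <- 1L
    cells$region_id <- 1L
    .write_csv_stable(cells, file.path(out_dir, "foci_cells.csv"))
    rep <- aggregate_foci(cells, min_cells_per_field = 50L,
                          min_fields_per_region = 1L)
    .write_csv_stable(rep$strata, file.path(out_dir, "foci_strata.csv"))
    manifest$outputs$foci <<- c("foci_cells.csv", "foci_strata.csv")
  })

  if ("spheroid" %in% stages) run_stage("spheroid", function() {
    sp <- config$spheroid
    ph <- generate_spheroid_series(spheroid_phantom_params(
      n_per_condition = sp$n_per_condition, noise_sd = sp$noise_sd,
      seed = sp$seed))
    obs <- measure_spheroid_series(ph$wells, ph$truth$plate)
    .write_csv_stable(obs, file.path(out_dir,
                                     "spheroid_observations.csv"))
    summ <- dose_time_summary(obs)
    .write_csv_stable(summ, file.path(out_dir, "spheroid_summary.csv"))
    manifest$outputs$spheroid <<- c("spheroid_observations.csv",
                                    "spheroid_summary.csv")
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
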