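#!/usr/bin/env Rscript
# Simulate the study's imaging inputs: three groups of dual-marker section
# phantoms (non-injected, vehicle, KORTUC), one foci-bearing nuclei field,
# and a spheroid dose-by-time well series. Ground truth goes to
# results/simulated/; the phantoms themselves are regenerated on demand by
# the later scripts from the seeds recorded here, so nothing binary needs
# to persist.

library(reoxmap)

seed <- 20260926L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# --- section cohort: per-group mean reoxygenated fractions --------------
groups <- list(non_injected = list(mean = 0.03, sd = 0.02),
               vehicle = list(mean = 0.08, sd = 0.05),
               kortuc = list(mean = 0.55, sd = 0.15))
n_per_group <- 6L
set.seed(seed)
cohort <- do.call(rbind, lapply(names(groups), function(g) {
  f <- pmin(pmax(rnorm(n_per_group, groups[[g]]$mean, groups[[g]]$sd),
                 0), 0.95)
  data.frame(tumour_id = sprintf("%s_%02d", g, seq_len(n_per_group)),
             group = g, reox_fraction = f,
             phantom_seed = sample.int(2^31 - 1, n_per_group))
}))
write.csv(cohort, file.path(out, "section_cohort.csv"), row.names = FALSE)
cat(sprintf("section cohort: %d tumours, KORTUC mean true reox fraction %.2f\n",
            nrow(cohort),
            mean(cohort$reox_fraction[cohort$group == "kortuc"])))

# one phantom written out as a TIFF to show the on-disk interchange format
ph <- generate_section_phantom(section_phantom_params(
  baseline_hypoxic_fraction = 0.3, reoxygenated_fraction = 0.5,
  new_hypoxia_fraction = 0.03, noise_sd = 1500,
  seed = cohort$phantom_seed[cohort$group == "kortuc"][1]))
write_section(ph$image, file.path(out, "example_kortuc_section.tif"))

# --- foci field and spheroid series: record the generating seeds --------
sim_manifest <- list(seed = seed,
                     foci = list(n_nuclei = 150L,
                                 lambda = list(positive = 6, negative = 6),
                                 fraction_cci_positive = 0.4,
                                 noise_sd = 800, seed = seed + 1L),
                     spheroid = list(n_per_condition = 14L,
                                     noise_sd = 1000, seed = seed + 2L))
jsonlite::write_json(sim_manifest, file.path(out, "sim_manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("wrote", file.path(out, "sim_manifest.json"), "\n")
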