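#!/usr/bin/env Rscript
# Collate the per-stage outputs into one run summary.

report <- read.csv("results/sections_report.csv")
strata <- read.csv("results/foci_strata.csv")
summ <- read.csv("results/spheroid_summary.csv")

lines <- c(
  "reoxmap analysis run summary",
  "============================",
  "",
  sprintf("Sections: %d tumours in %d groups", nrow(report),
          length(unique(report$group))),
  vapply(unique(report$group), function(g)
    sprintf("  %-13s mean reox log2Fc %+.2f; %d/%d called reoxygenated",
            g, mean(report$reox_log2fc[report$group == g]),
            sum(report$group == g & report$call == "reoxygenated"),
            sum(report$group == g)), ""),
  "",
  vapply(seq_len(nrow(strata)), function(i)
    sprintf("Foci: CCI-103F %s stratum, %.0f%% of %d cells with >5 foci",
            strata$cci_status[i], strata$pct_high_foci[i],
            strata$n_cells[i]), ""),
  "",
  sprintf("Spheroids: %d (dose, time) cells; min ratio-to-control %.2f",
          nrow(summ), min(summ$ratio_to_control)),
  sprintf("  significant at 1 h for doses >= %.1f mM",
          min(summ$dose_mM[summ$timepoint_h == 1 & summ$dose_mM > 0 &
                             summ$p < 0.05])))

writeLines(lines, "results/run_summary.txt")
writeLines(lines)
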