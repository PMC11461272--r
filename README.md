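# reoxmap

Quantifies tumour reoxygenation from **dual 2-nitroimidazole
hypoxia-marker** immunofluorescence. In the dual-marker design the first
marker (CCI-103F) is administered before an intervention and the second
(pimonidazole) after it, so each tumour serves as its own hypoxia
control: tissue staining for the baseline marker but not the second one
must have reoxygenated in between. The package is aimed at radiobiology
and tumour-microenvironment labs analysing such paired stains — for
example after intratumoural hydrogen peroxide (KORTUC) radiosensitiser
injection — together with the two companion assays of the same design:
phospho-ATM focus scoring and spheroid hypoxia-reporter imaging.

## What it computes

Within a tumour region of interest (ROI), each marker channel is
thresholded (Otsu on the ROI-restricted 8-bit histogram, or a global
preset value) and the masks are combined by set algebra into three
categories:

| category | definition |
|---|---|
| reoxygenated | CCI \ Pimo |
| new hypoxia  | Pimo \ CCI |
| no change    | CCI ∩ Pimo |

Each tumour is then scored with

```
log2Fc = log2( ID(CCI) / ID(CCI ∩ Pimo) )
```

where ID is integrated density (sum of pixel intensities) on the CCI
channel. `log2Fc < 0` is called *absent* reoxygenation, `log2Fc > 1`
*reoxygenated*, and `[0, 1]` *indeterminate*. If a fraction *f* of the
baseline-hypoxic area reoxygenates, the score equals `-log2(1 - f)`,
which is the calibration the tests verify. An area-based statistic
`log2(pct_cci / pct_pimo)` is reported alongside, and groups are
compared with Student's t tests (Welch or paired).

Also included: per-cell phospho-ATM focus counting
(difference-of-Gaussians blob detection; cells classified 0 / 1–5 / >5
foci and stratified by CCI-103F status), spheroid segmentation and
reporter quantification over an H2O2 dose × time grid, and a synthetic
phantom generator (sections, nuclei fields, spheroid series) with exact
ground truth that stands in for the study's undeposited microscopy.

## Worked example

```r
library(reoxmap)

# a section phantom: 30% of the ROI hypoxic at baseline, half of it
# reoxygenated, exact ground truth returned alongside
ph <- generate_section_phantom(section_phantom_params(
  baseline_hypoxic_fraction = 0.3, reoxygenated_fraction = 0.5,
  new_hypoxia_fraction = 0.05, seed = 7))

score_section(ph$image, ph$truth$roi_mask, threshold_method = "otsu")
#>   pct_cci pct_pimo pct_reox area_log2fc reox_log2fc         call
#> 1    30.0     20.0     15.0       0.585     1.00011 reoxygenated
```

30% of the ROI is CCI-positive and 20% pimonidazole-positive; the 15
percentage-point mismatch is the reoxygenated category. The
integrated-density score is 1.000 — exactly `-log2(1 - 0.5)` for a half
reoxygenated baseline — and, being above 1, the tumour is called
reoxygenated.

The `analysis/` scripts chain the full workflow on a simulated
three-group cohort (non-injected, vehicle, KORTUC; run them in order):

```sh
Rscript analysis/01_simulate.R          # cohort design + seeds
Rscript analysis/02_quantify_sections.R # per-tumour scores and calls
Rscript analysis/03_foci.R              # stratified foci percentages
Rscript analysis/04_spheroids.R         # dose x time reporter ratios
Rscript analysis/05_report.R            # collated run summary
```

`02_quantify_sections.R` prints, for the default simulated cohort:

```
non_injected: 0/6 tumours called reoxygenated (log2Fc > 1)
vehicle:      0/6 tumours called reoxygenated (log2Fc > 1)
kortuc:       3/6 tumours called reoxygenated (log2Fc > 1)
KORTUC vs vehicle p = 0.0077
```

i.e. only the treated group produces scores above the reoxygenation
threshold, and `04_spheroids.R` shows the dose-dependent loss of
hypoxia-reporter signal at 1 h (ratio 0.21 at 9.6 mM) with re-emergence
by 24 h (1.2 mM: 0.59 → 0.98). Outputs land in `results/`.

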