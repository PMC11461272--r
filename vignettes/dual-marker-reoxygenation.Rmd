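---
title: "Quantifying tumour reoxygenation with dual hypoxia markers"
author: "reoxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour reoxygenation with dual hypoxia markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reoxmap)
```

## The measurement problem

2-nitroimidazole compounds such as CCI-103F and pimonidazole are
bioreduced and covalently bound in cells below roughly 10 mmHg of oxygen,
and can later be detected on sections with adduct-specific antibodies.
Giving CCI-103F *before* an intervention and pimonidazole *after* it makes
each tumour its own hypoxia control: wherever the baseline marker stains
but the second one does not, tissue that was hypoxic has become
oxygenated. reoxmap turns that qualitative idea into numbers:

* each marker channel is thresholded inside the outlined tumour region of
  interest (ROI);
* binary mask arithmetic splits the ROI into **reoxygenated**
  (CCI \\ Pimo), **new hypoxia** (Pimo \\ CCI) and **no change**
  (CCI AND Pimo);
* a per-tumour score is computed as
  `log2Fc = log2( ID(CCI) / ID(CCI AND Pimo) )`, the log2 ratio of the
  integrated density (sum of pixel intensities) of the whole
  baseline-hypoxic region to that of the overlap region, on the CCI
  channel. A score below 0 is called *absent* reoxygenation, above 1
  *reoxygenated*, and the closed interval `[0, 1]` -- boundaries included
  -- *indeterminate*, because the defining inequalities are strict;
* a second, coarser statistic, `log2(pct_cci / pct_pimo)` on percent
  areas, is reported alongside.

If a fraction $f$ of the baseline-hypoxic area reoxygenates uniformly,
the integrated-density ratio is $1/(1-f)$, so the score should equal
$-\log_2(1-f)$: 0 at $f=0$, 1 at $f=0.5$, 2 at $f=0.75$. That closed form
is the calibration target used throughout the tests.

Two companion assays from the same study design are covered: per-cell
phospho-ATM (s1981) focus counting stratified by baseline CCI-103F
status (reoxygenation and H2O2-derived reactive oxygen species both drive
ATM autophosphorylation), and spheroid hypoxia-reporter quantification
over an H2O2 dose-by-time grid.

## Thresholding choices

The acquisition software's description of its thresholding ("a global
preset intensity using an adaptive threshold") is internally ambiguous,
so the package exposes both things it could mean and does not guess
further:

* `preset_threshold()` -- one fixed global intensity, applied inside the
  ROI;
* `otsu_threshold()` -- Otsu's criterion (maximum between-class variance)
  computed on the histogram of the 8-bit converted channel restricted to
  ROI pixels.

Conventions are fixed and documented rather than inherited from any one
tool: positivity is `intensity >= threshold`; Otsu ties break toward the
lower threshold so results are deterministic; 16-bit images are mapped to
8-bit by fixed nominal-range scaling (`v * 255 / 65535`, rounded half
up), **not** per-image min--max, because per-image scaling would silently
change what a "global preset" means from section to section. Local or
per-tile adaptive thresholding is deliberately out of scope.

`classify_categories()` performs the raw set algebra by default. Two
post-filters (minimum object size, hole filling) exist for noisy real
sections but are off by default, so the partition identity
`area(reox) + area(new) + area(no change) = area(CCI OR Pimo)` holds
exactly on every input.

## Edge cases and regularisation

Empty masks make both log2 ratios undefined. Rather than failing or
returning infinities silently, both statistics add a small documented
epsilon -- 0.01 percentage points for the area ratio, 1 intensity unit
for the integrated-density ratio -- and **flag** its activation in the
output (`eps_used`), so a reviewer can see which tumours were scored on
a regularised denominator. Call thresholds (0 and 1) are visible
function arguments, not buried constants.

`group_summary()` compares groups with two-sided t tests: Welch's
unequal-variance form for unpaired comparisons, an exact paired t when a
pairing key is supplied. Degenerate comparisons (identical groups) return
t = 0, p = 1 instead of erroring. Multi-way ANOVA post-hoc machinery is
intentionally not reimplemented here.

## Foci scoring

The study scored foci by eye; reoxmap substitutes a documented detector
so the procedure is reproducible: nuclei are segmented by Otsu +
hole-fill + distance-map watershed (minimum area 30 px), and foci are
counted per nucleus as local maxima of a scale-matched
difference-of-Gaussians (Laplacian-of-Gaussian approximation) response,
calibrated so a matched Gaussian spot of amplitude $A$ yields response
$\approx A$. The detection threshold `min_prominence` is expressed as a
fraction of the channel's dynamic range (default 0.1); maxima are
plateau-aware (connected equal-valued peaks count once). "More than 5
foci" is interpreted strictly as >= 6, and the boundary is tested.

CCI-103F status per cell uses a majority-pixel rule (>= 50% of nucleus
pixels inside the CCI mask, configurable), mirroring visual scoring.
Sampling follows the study's scheme: random non-overlapping regions
whose reoxygenated fraction exceeds 20%, at least 5 fields per region,
and fields with fewer than 50 scored cells are flagged and excluded from
percentages (the quality-control mirror of manual artefact exclusion).
Because the source text is ambiguous about whether the stratified
percentages are pooled or per-field means, `aggregate_foci()` emits
both. A stratum with no retained cells is reported as absent, not 0%.
The phospho-ATM slide is assumed pre-registered with the dual-marker
slide (shared pixel coordinates); no registration is attempted.

## Spheroid quantification

The well imager's proprietary spheroid segmentation is replaced by a
documented equivalent: Otsu on the inverted brightfield, hole filling,
largest component, equivalent-circle diameter from area. Disaggregated
spheroids (a known effect of cytotoxic H2O2 doses) are flagged by a
circularity check ($4\pi A/P^2 < 0.6$) rather than silently dropped;
a second large object yields a `multiple_objects` flag. Reporter
intensity is the masked mean (whole-well means would dilute the signal
with background; the choice is documented since the original software
does not state it). Ratios are taken to the same-timepoint untreated
control, so the control ratio is exactly 1 by construction. For
recovering the generator's core-clearance multipliers the
background-corrected ratio (`ratio_bgcorr`, well background estimated as
the median red signal outside the spheroid mask) is the right estimator:
the raw ratio carries a small positive bias from background fluorescence
under the mask.

## What the phantoms emulate -- and what they do not

The study's raw microscopy is not deposited, so every quantitative claim
here is validated against synthetic phantoms with exact ground truth.

**Sections.** Hypoxia is patchy and perfusion-limited, so the CCI mask
is a thresholded low-pass Gaussian random field (correlation length
`blob_scale_px`), not a disc -- this exercises multi-component mask
handling. Reoxygenation is carved from the baseline mask by removing
whole blobs in seeded random order and then peeling the last blob
boundary-first via its distance transform until the target pixel count
is met exactly; new hypoxia comes from an independent field outside the
baseline mask. Channels are two-level (foreground/background) 16-bit
images plus clipped additive Gaussian noise; at `noise_sd = 0` exactly
two intensity values occur. Stored category fractions are recomputed
from the emitted masks, so ground truth is self-consistent by
construction.

**Foci.** Nuclei are non-overlapping discs; foci are Gaussian spots
(`sigma` = half the focus radius) whose centres stay inside the parent
nucleus. Spot centres keep a minimum spacing of **two** focus radii
(four sigma): at one radius (two sigma) two spots can merge into a
single intensity maximum and the true count would be ill-defined even
without noise, which would corrupt the ground truth itself. When
crowding prevents placing a drawn Poisson count, the number actually
rendered is recorded as truth.

**Spheroids.** A dark disc on bright background (brightfield) and a
hypoxic core at 60% of the spheroid diameter whose intensity is scaled
by the clearance model
$m(d,t) = 1 - \frac{d}{d + K}\,e^{-t/\tau(d)}$, with half-max dose
$K = 1.2$ mM and persistence $\tau(d) = 6\,(1 + d/4.8)$ h. This
reproduces the qualitative biology the assay shows: no effect at dose 0,
monotone dose response, sustained clearance at high dose, re-emergence
of hypoxia at 24 h that is fastest at low dose. Default study conditions
follow the experimental design: doses 0, 0.6, 1.2, 2.4, 4.8, 9.6 mM;
1, 6, 24 h; 14 spheroids per condition; diameters uniform in
400--700 um at 5 um/px.

The phantoms deliberately omit optics (no point-spread function),
stitching artefacts, illumination gradients, antibody
penetration/staining variability and real tissue texture. Passing tests
therefore demonstrate that the *measurement pipeline* is correct and
calibrated on images whose truth is known -- not that any biological
conclusion transfers to real sections. One consequence worth noting:
phantom group comparisons are far better powered than real experiments
(t tests on phantom spheroids reach significance even at the lowest
dose), so p-values from simulated runs characterise the machinery, not
the assay's sensitivity.

## Numerical choices

* ROI polygons rasterise by the even-odd rule on 0-based pixel centres
  (`(x + 0.5, y + 0.5)`); an axis-aligned rectangle of width $w$ covers
  exactly $w$ pixel columns.
* Otsu's criterion is computed in double precision from the 256-bin
  histogram; the first argmax (lowest threshold) is taken on ties; a
  constant ROI raises "no threshold exists".
* Exact-count mask carving breaks ties deterministically by linear pixel
  index, so phantoms are bit-identical under a fixed seed.
* Every stochastic stage takes an explicit integer seed; the pipeline
  refuses configs with a missing stage seed, and two runs from one
  config produce byte-identical CSVs (numeric columns written at 12
  significant digits).

## Problem sizes

The shipped tests and the validation script use deliberately small
phantoms chosen to keep the whole suite quick on a laptop while leaving
the statistical checks well-powered: 160--256 px sections, 1,000 nuclei
(5 fields of 200) for the Poisson-tail check, 252 spheroid wells per
seed. All sizes are ordinary function arguments, so larger studies are a
parameter change, not a code change.

## Known limitations

* No image registration: serial sections are assumed aligned; the
  study's manual three-way region mapping is approximated by shared
  coordinates.
* The "global preset" of the original acquisition software cannot be
  reverse-engineered; the preset pathway requires the user to supply the
  value.
* The supplementary normalised-image ("delta-score") cross-check used
  for region selection is not defined in the available methods text and
  is not implemented.
* Foci scoring is 2-D; overlapping foci along z in thick sections will
  undercount relative to confocal stacks.
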