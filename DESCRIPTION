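Package: reoxmap
Title: Dual Hypoxia-Marker Mismatch Analysis of Tumour Reoxygenation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies tumour reoxygenation from registered dual
    2-nitroimidazole hypoxia-marker immunofluorescence sections
    (CCI-103F given before treatment, pimonidazole after). Thresholds
    each marker channel within a tumour region of interest (global
    preset or Otsu), classifies every pixel as reoxygenated, new
    hypoxia or no change by binary mask arithmetic, and scores each
    tumour with log2 fold-change statistics on percent areas and
    integrated densities, with explicit call thresholds. Also scores
    phospho-ATM nuclear foci per cell stratified by baseline-hypoxia
    (CCI-103F) status, and quantifies hypoxia-reporter fluorescence in
    tumour spheroids across a hydrogen peroxide dose by time grid.
    Ships a synthetic phantom generator (paired-marker sections,
    foci-bearing nuclei, spheroid well series) with exact ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
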