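#' @title Reoxygenation log2 fold-change statistics and calls
#' @name reox_stats
#' @description The two per-tumour log2 fold-change statistics (percent
#'   areas of the two markers; integrated density of the CCI-103F region
#'   versus the marker-overlap region), the categorical reoxygenation
#'   call, and group summaries with Student's t tests.
NULL

#' Area log2 fold change between the two markers
#'
#' `log2((pct_cci + eps) / (pct_pimo + eps))`. The small `eps` (in
#' percentage points) regularises empty masks; its activation (either
#' percent area below `eps`) is flagged rather than silent.
#'
#' @param pct_cci,pct_pimo percent areas in `[0, 100]`.
#' @param eps regularisation in percentage points (default 0.01).
#' @return numeric log2 fold change, with attribute `eps_used` (logical).
#' @export
area_log2fc <- function(pct_cci, pct_pimo, eps = 0.01) {
  .assert(pct_cci >= 0 && pct_pimo >= 0, "percent areas must be >= 0")
  .assert(pct_cci <= 100 && pct_pimo <= 100, "percent areas must be <= 100")
  out <- log2((pct_cci + eps) / (pct_pimo + eps))
  attr(out, "eps_used") <- (pct_cci < eps) || (pct_pimo < eps)
  out
}

#' Integrated-density reoxygenation log2 fold change
#'
#' The per-tumour reoxygenation score: the log2 ratio of the integrated
#' density of the CCI-103F-stained region to that of the region where the
#' two markers overlap, on the CCI-103F channel. A large score means most
#' of the baseline-hypoxic signal no longer stains for pimonidazole.
#'
#' With `numerator = "cci_full"` (default) the numerator is the integrated
#' density over the whole CCI mask; `"cci_only"` restricts it to the
#' CCI-minus-overlap (reoxygenated) region.
#'
#' @param channel CCI-103F intensity matrix (8-bit analysis range in the
#'   standard pathway).
#' @param cci_mask logical CCI-103F-positive mask (or `MarkerMask`).
#' @param overlap_mask logical overlap (no-change) mask, must be a subset
#'   of `cci_mask`.
#' @param eps regularisation in intensity units (default 1) for empty
#'   overlap regions; activation flagged.
#' @param numerator `"cci_full"` or `"cci_only"`.
#' @return numeric log2 fold change with attribute `eps_used`.
#' @export
reox_log2fc <- function(channel, cci_mask, overlap_mask, eps = 1,
                        numerator = c("cci_full", "cci_only")) {
  numerator <- match.arg(numerator)
  cm <- .as_mask(cci_mask); om <- .as_mask(overlap_mask)
  .assert(!any(om & !cm), "overlap mask is not a subset of the CCI mask")
  num_mask <- if (numerator == "cci_full") cm else (cm & !om)
  id_num <- integrated_density(channel, num_mask)
  id_den <- integrated_density(channel, om)
  out <- log2((id_num + eps) / (id_den + eps))
  attr(out, "eps_used") <- (id_num < eps) || (id_den < eps)
  out
}

#' Categorical reoxygenation call from the log2 fold change
#'
#' Strict thresholds: a score below `lower` (default 0) calls `absent`, a
#' score above `upper` (default 1) calls `reoxygenated`, anything in the
#' closed interval `[lower, upper]` -- including the boundaries -- is
#' `indeterminate`.
#'
#' @param log2fc numeric score(s); must be finite.
#' @param lower,upper call thresholds.
#' @return character vector in `{absent, indeterminate, reoxygenated}`.
#' @export
call_reoxygenation <- function(log2fc, lower = 0, upper = 1) {
  x <- as.numeric(log2fc)
  .assert(all(is.finite(x)), "log2fc must be finite")
  ifelse(x < lower, "absent",
         ifelse(x > upper, "reoxygenated", "indeterminate"))
}

#' Score one tumour section end to end
#'
#' Runs the standard Fiji-style pathway on a two-marker `SectionImage`:
#' 8-bit conversion, thresholding (Otsu by default, or a global preset
#' value), category arithmetic, percent areas, both log2 fold-change
#' statistics and the reoxygenation call.
#'
#' @param img `SectionImage` with `cci103f` and `pimonidazole` channels.
#' @param roi logical ROI mask.
#' @param tumour_id,group identifiers carried into the report.
#' @param threshold_method `"otsu"` or `"preset"`.
#' @param preset_value global preset intensity (8-bit scale) when
#'   `threshold_method = "preset"`.
#' @param eps_area,eps_id regularisation constants for the two statistics.
#' @return one-row data.frame (a `ReoxygenationReport`): `tumour_id`,
#'   `group`, `pct_cci`, `pct_pimo`, `pct_reox`, `pct_new_hypoxia`,
#'   `pct_no_change`, `area_log2fc`, `id_cci_total`, `id_overlap`,
#'   `id_cci_only`, `reox_log2fc`, `call`, `eps_used`, `threshold_cci`,
#'   `threshold_pimo`.
#' @export
score_section <- function(img, roi, tumour_id = "t1", group = NA_character_,
                          threshold_method = c("otsu", "preset"),
                          preset_value = 128, eps_area = 0.01, eps_id = 1) {
  threshold_method <- match.arg(threshold_method)
  .assert(inherits(img, "SectionImage"), "img must be a SectionImage")
  .assert(all(c("cci103f", "pimonidazole") %in% names(img$channels)),
          "img must contain cci103f and pimonidazole channels")
  cci8 <- to_8bit(img$channels$cci103f, img$bit_depth)
  pim8 <- to_8bit(img$channels$pimonidazole, img$bit_depth)
  th <- function(ch, marker) {
    if (threshold_method == "otsu")
      otsu_threshold(ch, roi, bit_depth = 8L, marker = marker)
    else preset_threshold(ch, roi, preset_value, marker = marker)
  }
  cci_m <- th(cci8, "cci103f")
  pim_m <- th(pim8, "pimonidazole")
  cmap <- classify_categories(cci_m, pim_m, roi)
  overlap <- category_mask(cmap, "no_change")
  pct_cci <- percent_area(cci_m, roi)
  pct_pimo <- percent_area(pim_m, roi)
  afc <- area_log2fc(pct_cci, pct_pimo, eps = eps_area)
  rfc <- reox_log2fc(cci8, cci_m, overlap, eps = eps_id)
  data.frame(tumour_id = tumour_id, group = group,
             pct_cci = pct_cci, pct_pimo = pct_pimo,
             pct_reox = percent_area(category_mask(cmap, "reoxygenated"),
                                     roi),
             pct_new_hypoxia = percent_area(
               category_mask(cmap, "new_hypoxia"), roi),
             pct_no_change = percent_area(overlap, roi),
             area_log2fc = as.numeric(afc),
             id_cci_total = integrated_density(cci8, cci_m),
             id_overlap = integrated_density(cci8, overlap),
             id_cci_only = integrated_density(cci8, cci_m$mask & !overlap),
             reox_log2fc = as.numeric(rfc),
             call = call_reoxygenation(as.numeric(rfc)),
             eps_used = attr(afc, "eps_used") || attr(rfc, "eps_used"),
             threshold_cci = cci_m$threshold_value,
             threshold_pimo = pim_m$threshold_value,
             stringsAsFactors = FALSE)
}

# t test robust to the degenerate all-equal case (t = 0, p = 1)
.safe_t_test <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    if (sd(d) == 0) {                 # constant differences: t.test errors
      if (d[1] == 0)
        return(list(statistic = 0, p.value = 1, method = "paired t"))
      return(list(statistic = sign(d[1]) * Inf, p.value = 0,
                  method = "paired t"))
    }
    tt <- t.test(x, y, paired = TRUE)
  } else {
    if (sd(x) == 0 && sd(y) == 0) {
      if (mean(x) == mean(y))
        return(list(statistic = 0, p.value = 1, method = "Welch t"))
      return(list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0,
                  method = "Welch t"))
    }
    tt <- t.test(x, y, var.equal = FALSE)
  }
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       method = if (paired) "paired t" else "Welch t")
}

#' Group summaries with Student's t tests
#'
#' Per-group mean, SD and n, plus two-sided t tests for each pair of
#' groups: Welch's unequal-variance t for unpaired comparisons, or an
#' exact paired t when a pairing key is supplied (subjects matched across
#' groups by key). Significance is conventionally read at the 5% level.
#'
#' @param values numeric vector of per-tumour scores.
#' @param groups factor/character of group labels, same length.
#' @param pair_id optional pairing key; when given, each pairwise test
#'   uses only keys present in both groups, paired.
#' @return list with `groups` (data.frame group/n/mean/sd) and `tests`
#'   (data.frame group1/group2/method/t/p).
#' @export
group_summary <- function(values, groups, pair_id = NULL) {
  .assert(length(values) == length(groups), "values/groups length mismatch")
  groups <- as.character(groups)
  gl <- unique(groups)
  gs <- do.call(rbind, lapply(gl, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v))
  }))
  small <- gs$group[gs$n < 2L]
  .assert(length(small) == 0L,
          "insufficient n (< 2) in group(s): %s",
          paste(small, collapse = ", "))
  pairs <- if (length(gl) >= 2L) utils::combn(gl, 2L, simplify = FALSE)
           else list()
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    x <- values[groups == pr[1L]]; y <- values[groups == pr[2L]]
    if (!is.null(pair_id)) {
      kx <- pair_id[groups == pr[1L]]; ky <- pair_id[groups == pr[2L]]
      common <- intersect(kx, ky)
      .assert(length(common) >= 2L,
              "insufficient paired n between %s and %s", pr[1L], pr[2L])
      x <- x[match(common, kx)]; y <- y[match(common, ky)]
      tt <- .safe_t_test(x, y, paired = TRUE)
    } else {
      tt <- .safe_t_test(x, y, paired = FALSE)
    }
    data.frame(group1 = pr[1L], group2 = pr[2L], method = tt$method,
               t = tt$statistic, p = tt$p.value)
  }))
  list(groups = gs, tests = tests)
}
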