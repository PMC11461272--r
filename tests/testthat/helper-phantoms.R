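# shared fixtures, all generated in code

# random logical mask of given shape
rand_mask <- function(h, w, p = 0.5) matrix(runif(h * w) < p, h, w)

# brute-force exhaustive Otsu: try every threshold t in 1..255, classes
# {v < t} vs {v >= t}, maximise between-class variance; lowest t on ties
otsu_bruteforce <- function(vals) {
  best_t <- NA_integer_; best_v <- -Inf
  n <- length(vals)
  for (t in 1:255) {
    lo <- vals[vals < t]; hi <- vals[vals >= t]
    if (length(lo) == 0L || length(hi) == 0L) next
    v <- (length(lo) / n) * (length(hi) / n) *
      (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# per-pixel truth-table category classifier (independent of the mask
# arithmetic implementation)
classify_bruteforce <- function(cci, pimo, roi) {
  out <- matrix("outside_roi", nrow(roi), ncol(roi))
  for (i in seq_len(nrow(roi))) for (j in seq_len(ncol(roi))) {
    if (!roi[i, j]) next
    c1 <- cci[i, j]; p1 <- pimo[i, j]
    out[i, j] <- if (c1 && !p1) "reoxygenated"
      else if (!c1 && p1) "new_hypoxia"
      else if (c1 && p1) "no_change" else "background"
  }
  out
}

# small noiseless two-marker phantom used across tests
tiny_section <- function(f_reox = 0.5, noise_sd = 0, seed = 7,
                         size = 160L) {
  generate_section_phantom(section_phantom_params(
    image_height_px = size, image_width_px = size,
    baseline_hypoxic_fraction = 0.3, reoxygenated_fraction = f_reox,
    new_hypoxia_fraction = 0.05, blob_scale_px = 12,
    noise_sd = noise_sd, seed = seed))
}
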