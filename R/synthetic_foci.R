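#' @title Foci-bearing nuclei phantoms
#' @name synthetic_foci
#' @description Nuclei fields with punctate phospho-ATM-like foci and a
#'   per-nucleus baseline-hypoxia (CCI-103F) status, with known per-nucleus
#'   foci counts.
NULL

#' Parameters for a foci-bearing nuclei phantom
#'
#' Nuclei are rendered as non-overlapping discs; foci as 2-D Gaussian spots
#' (`sigma = foci_radius_px / 2`) whose centres lie inside their parent
#' nucleus with a minimum centre-to-centre spacing of two foci radii so
#' that counts stay well-defined at zero noise.
#'
#' @param n_nuclei number of nuclei to place.
#' @param image_height_px,image_width_px field size in pixels.
#' @param nucleus_radius_px nucleus disc radius.
#' @param foci_count_distribution list describing the per-nucleus foci
#'   count law: `list(name = "poisson", lambda = x)` (optionally
#'   `lambda = c(positive = a, negative = b)` for per-stratum means), or
#'   `list(name = "fixed", counts = v)` with `v` recycled over nuclei.
#' @param foci_radius_px focus radius (spot `sigma` is half this).
#' @param foci_intensity peak spot amplitude above background (16-bit).
#' @param fraction_cci_positive fraction of nuclei inside baseline-hypoxic
#'   (CCI-103F positive) tissue.
#' @param nucleus_intensity,background_intensity nuclei-channel levels.
#' @param noise_sd additive Gaussian noise SD on intensity channels.
#' @param seed integer seed.
#' @return a validated `FociPhantomParams` list.
#' @export
foci_phantom_params <- function(n_nuclei = 50L,
                                image_height_px = 256L,
                                image_width_px = 256L,
                                nucleus_radius_px = 10,
                                foci_count_distribution =
                                  list(name = "poisson", lambda = 3),
                                foci_radius_px = 2,
                                foci_intensity = 28000,
                                fraction_cci_positive = 0.5,
                                nucleus_intensity = 30000,
                                background_intensity = 2000,
                                noise_sd = 0,
                                seed = 1L) {
  .assert(n_nuclei >= 1L, "n_nuclei must be positive")
  .assert(nucleus_radius_px > 0 && foci_radius_px > 0,
          "radii must be positive")
  .assert(foci_radius_px < nucleus_radius_px,
          "foci_radius_px must be smaller than nucleus_radius_px")
  .assert(is.list(foci_count_distribution) &&
            foci_count_distribution$name %in% c("poisson", "fixed"),
          "foci_count_distribution must be poisson or fixed")
  .assert(fraction_cci_positive >= 0 && fraction_cci_positive <= 1,
          "fraction_cci_positive must be in [0,1]")
  .assert(noise_sd >= 0, "noise_sd must be nonnegative")
  structure(list(n_nuclei = as.integer(n_nuclei),
                 image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 nucleus_radius_px = nucleus_radius_px,
                 foci_count_distribution = foci_count_distribution,
                 foci_radius_px = foci_radius_px,
                 foci_intensity = foci_intensity,
                 fraction_cci_positive = fraction_cci_positive,
                 nucleus_intensity = nucleus_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "FociPhantomParams")
}

# place n points in [lo, hi] box with pairwise distance >= min_d
.place_points <- function(n, xlo, xhi, ylo, yhi, min_d, max_tries = 4000L) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1L
    x <- runif(1, xlo, xhi); y <- runif(1, ylo, yhi)
    if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_d^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n) return(NULL)
  cbind(x = xs, y = ys)
}

.disc_mask <- function(h, w, cx, cy, r) {
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  matrix((px - cx)^2 + (py - cy)^2 <= r^2, h, w)
}

#' Generate a foci-bearing nuclei phantom
#'
#' Returns a three-channel 16-bit `SectionImage` (`nuclei`, `phospho_atm`,
#' `cci103f`) and ground truth with true per-nucleus foci counts, centres
#' and CCI status. Nuclei are non-overlapping by construction; every focus
#' centre lies inside its parent nucleus. When crowding prevents placing a
#' drawn count, the number actually rendered is recorded as truth.
#'
#' @param params a [foci_phantom_params()].
#' @return list with `image` (a `SectionImage`) and `truth` (class
#'   `SectionGroundTruth`: data.frame `nuclei` with columns `nucleus_id`,
#'   `cx`, `cy`, `cci_positive`, `true_foci_count`; plus `seed`).
#' @export
generate_foci_phantom <- function(params) {
  .assert(inherits(params, "FociPhantomParams"),
          "params must come from foci_phantom_params()")
  p <- params
  set.seed(p$seed)
  h <- p$image_height_px; w <- p$image_width_px
  r <- p$nucleus_radius_px
  m <- r + 2                             # margin from image edge
  .assert(w - 2 * m > 0 && h - 2 * m > 0, "image too small for nuclei")
  centres <- .place_points(p$n_nuclei, m, w - m, m, h - m, 2 * r + 2,
                           max_tries = max(4000L, 400L * p$n_nuclei))
  .assert(!is.null(centres),
          "n_nuclei = %d infeasible for a %d x %d image at radius %.1f",
          p$n_nuclei, h, w, r)

  dist <- p$foci_count_distribution
  cci_pos <- runif(p$n_nuclei) < p$fraction_cci_positive
  counts <- switch(dist$name,
    poisson = {
      lam <- dist$lambda
      if (length(lam) > 1L)
        rpois(p$n_nuclei, ifelse(cci_pos, lam[["positive"]],
                                 lam[["negative"]]))
      else rpois(p$n_nuclei, lam)
    },
    fixed = rep_len(as.integer(dist$counts), p$n_nuclei))

  nuc <- matrix(0, h, w)
  cci <- matrix(FALSE, h, w)
  patm <- matrix(0, h, w)
  placed <- integer(p$n_nuclei)
  sig <- p$foci_radius_px / 2
  for (i in seq_len(p$n_nuclei)) {
    cx <- centres[i, 1L]; cy <- centres[i, 2L]
    d <- .disc_mask(h, w, cx, cy, r)
    nuc[d] <- 1
    if (cci_pos[i]) cci <- cci | .disc_mask(h, w, cx, cy, r + 1)
    if (counts[i] > 0L) {
      rr <- max(r - p$foci_radius_px - 1, 1)
      fc <- .place_points(counts[i], cx - rr, cx + rr, cy - rr, cy + rr,
                          2 * p$foci_radius_px)
      if (!is.null(fc)) {
        keep <- (fc[, 1L] - cx)^2 + (fc[, 2L] - cy)^2 <= rr^2
        # re-draw inside the disc until enough fit, bounded effort
        tries <- 0L
        while (sum(keep) < counts[i] && tries < 200L) {
          tries <- tries + 1L
          cand <- c(runif(1, cx - rr, cx + rr), runif(1, cy - rr, cy + rr))
          if ((cand[1] - cx)^2 + (cand[2] - cy)^2 > rr^2) next
          ok <- all((fc[keep, 1L] - cand[1])^2 +
                      (fc[keep, 2L] - cand[2])^2 >=
                      (2 * p$foci_radius_px)^2)
          if (ok) { fc <- rbind(fc, cand); keep <- c(keep, TRUE) }
        }
        fc <- fc[keep, , drop = FALSE]
        fc <- fc[seq_len(min(nrow(fc), counts[i])), , drop = FALSE]
        half <- ceiling(5 * sig)
        for (k in seq_len(nrow(fc))) {
          # render each spot only on its local window (+/- 5 sigma)
          x0 <- fc[k, 1L]; y0 <- fc[k, 2L]
          cs <- max(1L, floor(x0 - half)):min(w, ceiling(x0 + half))
          rs <- max(1L, floor(y0 - half)):min(h, ceiling(y0 + half))
          gx <- exp(-((cs - 0.5) - x0)^2 / (2 * sig^2))
          gy <- exp(-((rs - 0.5) - y0)^2 / (2 * sig^2))
          patm[rs, cs] <- patm[rs, cs] + p$foci_intensity * outer(gy, gx)
        }
        placed[i] <- nrow(fc)
      }
    }
  }

  mk <- function(base) {
    x <- base
    if (p$noise_sd > 0) x <- x + rnorm(length(x), sd = p$noise_sd)
    x <- pmin(pmax(floor(x + 0.5), 0), 65535)
    storage.mode(x) <- "integer"
    x
  }
  img <- section_image(
    list(nuclei = mk(p$background_intensity +
                       nuc * (p$nucleus_intensity - p$background_intensity)),
         phospho_atm = mk(p$background_intensity + patm),
         cci103f = mk(p$background_intensity +
                        cci * (p$nucleus_intensity -
                                 p$background_intensity))),
    um_per_px = 0.1, bit_depth = 16L,
    provenance = sprintf("foci phantom seed=%d", p$seed))
  truth <- structure(
    list(nuclei = data.frame(nucleus_id = seq_len(p$n_nuclei),
                             cx = centres[, 1L], cy = centres[, 2L],
                             cci_positive = cci_pos,
                             true_foci_count = placed),
         cci_mask = cci, seed = p$seed),
    class = "SectionGroundTruth")
  list(image = img, truth = truth)
}
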