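#' @title Multi-channel section images and ROI polygons
#' @name image_io
#' @description Readers/writers for the raster formats the pipeline
#'   consumes, polygon ROI rasterisation, and acquisition-range (16-bit)
#'   to analysis-range (8-bit) conversion.
NULL

.channel_roles <- c("cci103f", "pimonidazole", "nuclei", "phospho_atm",
                    "brightfield", "red_hypoxia")

#' Construct a SectionImage
#'
#' A registered multi-channel 2-D intensity raster. Channels are integer
#' matrices sharing one shape, keyed by role.
#'
#' @param channels named list of numeric matrices; names are channel roles,
#'   one of `cci103f`, `pimonidazole`, `nuclei`, `phospho_atm`,
#'   `brightfield`, `red_hypoxia`.
#' @param um_per_px physical pixel size in micrometres per pixel.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @param provenance free-text source path or metadata.
#' @return an object of class `SectionImage`.
#' @export
section_image <- function(channels, um_per_px = 1, bit_depth = 16,
                          provenance = "") {
  .assert(is.list(channels) && length(channels) >= 1L,
          "channels must be a non-empty named list of matrices")
  roles <- names(channels)
  .assert(!is.null(roles) && !anyDuplicated(roles),
          "channel roles must be unique and named")
  bad <- setdiff(roles, .channel_roles)
  .assert(length(bad) == 0L, "unknown channel role(s): %s",
          paste(bad, collapse = ", "))
  .assert(bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  shp <- dim(channels[[1L]])
  for (r in roles) {
    ch <- channels[[r]]
    .assert(is.matrix(ch), "channel '%s' is not a matrix", r)
    .assert(identical(dim(ch), shp),
            "channel '%s' shape (%s) differs from first channel (%s)",
            r, paste(dim(ch), collapse = "x"), paste(shp, collapse = "x"))
    rng <- range(ch)
    .assert(rng[1] >= 0 && rng[2] <= 2^bit_depth - 1,
            "channel '%s' intensities outside %d-bit range", r, bit_depth)
  }
  .assert(is.numeric(um_per_px) && um_per_px > 0, "um_per_px must be > 0")
  structure(list(channels = channels, um_per_px = um_per_px,
                 bit_depth = as.integer(bit_depth),
                 provenance = provenance),
            class = "SectionImage")
}

#' @export
print.SectionImage <- function(x, ...) {
  shp <- dim(x$channels[[1L]])
  cat(sprintf("SectionImage: %d x %d px, %d-bit, %.3g um/px\n",
              shp[1], shp[2], x$bit_depth, x$um_per_px))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Read a multi-page TIFF as a SectionImage
#'
#' Each TIFF page is assigned a channel role through `channel_map`.
#'
#' @param path path to a (multi-page) TIFF file.
#' @param channel_map named integer vector mapping role -> 1-based page
#'   index, e.g. `c(cci103f = 1, pimonidazole = 2)`.
#' @param um_per_px physical pixel size (not stored by plain TIFF).
#' @return a [section_image()].
#' @export
read_section <- function(path, channel_map, um_per_px = 1) {
  .assert(file.exists(path), "file not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("unreadable TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  .assert(!is.null(names(channel_map)), "channel_map must be named by role")
  bad <- setdiff(names(channel_map), .channel_roles)
  .assert(length(bad) == 0L, "unknown channel role(s): %s",
          paste(bad, collapse = ", "))
  idx <- as.integer(channel_map)
  .assert(all(idx >= 1L & idx <= length(pages)),
          "channel_map references page(s) %s but file has %d page(s)",
          paste(idx[idx < 1L | idx > length(pages)], collapse = ", "),
          length(pages))
  chans <- lapply(idx, function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # grey stored as RGB
    storage.mode(p) <- "integer"
    p
  })
  names(chans) <- names(channel_map)
  depth <- if (max(vapply(chans, max, 0)) > 255) 16L else 8L
  section_image(chans, um_per_px = um_per_px, bit_depth = depth,
                provenance = path)
}

#' Write a SectionImage as a multi-page TIFF
#'
#' Channels are written in the order given (default: as stored), one page
#' per channel, at the image's declared bit depth. Lossless; a write/read
#' round trip preserves pixel values exactly.
#'
#' @param img a `SectionImage`.
#' @param path output path.
#' @param roles channel roles to write, in page order.
#' @return `path`, invisibly; attribute `"roles"` records the page order.
#' @export
write_section <- function(img, path, roles = names(img$channels)) {
  .assert(inherits(img, "SectionImage"), "img must be a SectionImage")
  .assert(all(roles %in% names(img$channels)), "unknown role in 'roles'")
  mx <- 2^img$bit_depth - 1
  pages <- lapply(img$channels[roles], function(ch) ch / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = img$bit_depth,
                  compression = "none")
  attr(path, "roles") <- roles
  invisible(path)
}

#' Construct an ROI polygon
#'
#' The tumour-bearing region outline, excluding skin and normal tissue.
#' Vertices are 0-based pixel coordinates, x right, y down; the polygon is
#' implicitly closed.
#'
#' @param vertices n x 2 numeric matrix (or data.frame) of (x, y) vertices.
#' @return an object of class `RoiPolygon`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  .assert(is.numeric(v) && ncol(v) == 2L && nrow(v) >= 3L,
          "vertices must be an n x 2 numeric matrix with n >= 3")
  .assert(all(is.finite(v)), "vertices must be finite")
  # reject zero-area degenerate polygons
  x <- v[, 1L]; y <- v[, 2L]
  a <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
  .assert(abs(a) > 0, "degenerate polygon: zero signed area")
  structure(list(vertices = v), class = "RoiPolygon")
}

#' Rasterise an ROI polygon to a binary mask
#'
#' A pixel is inside iff its centre `(x + 0.5, y + 0.5)` falls inside the
#' polygon under the even-odd (crossing-number) rule. Deterministic.
#'
#' @param roi a [roi_polygon()] (or an n x 2 vertex matrix).
#' @param shape integer vector `c(height, width)` in pixels.
#' @return logical matrix of dimension `shape`.
#' @export
rasterize_roi <- function(roi, shape) {
  if (!inherits(roi, "RoiPolygon")) roi <- roi_polygon(roi)
  v <- roi$vertices
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  .assert(h >= 1L && w >= 1L, "shape must be positive")
  .assert(all(v[, 1L] >= 0 & v[, 1L] <= w & v[, 2L] >= 0 & v[, 2L] <= h),
          "polygon extends outside image bounds")
  px <- rep(seq_len(w) - 0.5, each = h)   # column-major to match matrix()
  py <- rep(seq_len(h) - 0.5, times = w)
  inside <- rep(FALSE, h * w)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < xi + (py - yi) * (xj - xi) / (yj - yi))
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  matrix(inside, nrow = h, ncol = w)
}

#' Convert a channel to the 8-bit analysis range
#'
#' 8-bit input is returned unchanged. 16-bit input is mapped by fixed
#' nominal-range scaling `round_half_up(v * 255 / 65535)` -- not per-image
#' min-max -- so preset thresholds stay comparable across sections. The
#' mapping is monotone non-decreasing.
#'
#' @param x numeric matrix of intensities.
#' @param bit_depth 8 or 16, the depth of `x`.
#' @return integer matrix in `[0, 255]`.
#' @export
to_8bit <- function(x, bit_depth) {
  .assert(bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  if (bit_depth == 8L) {
    storage.mode(x) <- "integer"
    return(x)
  }
  out <- floor(x * 255 / 65535 + 0.5)  # round half up, ties away from zero
  storage.mode(out) <- "integer"
  out
}
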