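#' Segmentation configuration
#'
#' Parameters controlling root- and canopy-image segmentation. The adaptive
#' threshold compares each pixel's grey value to the mean of its local
#' neighbourhood, which cancels slowly varying illumination; `offset` sets
#' how far below the local mean a pixel must fall to be called root.
#'
#' @param window Odd integer, side of the square local-mean neighbourhood
#'   (px). Must comfortably exceed the root stroke width so the local mean
#'   reflects background, not root.
#' @param offset Threshold offset in grey levels (0--255 scale). Larger
#'   values reject more noise but erode faint roots.
#' @param min_component Minimum 8-connected component size (px) kept by
#'   [remove_small_components()].
#' @param hue_lo,hue_hi Canopy hue band endpoints in degrees `[0, 360)`;
#'   the band may wrap across 360.
#' @param sat_min Saturation floor for canopy pixels; hue is undefined for
#'   achromatic pixels, so pixels with saturation below this never match.
#' @param crop Optional `c(row0, row1, col0, col1)` window (1-based,
#'   inclusive) restricting segmentation to a sub-frame; `NULL` = full frame.
#' @return A `seg_config` list.
#' @export
seg_config <- function(window = 51L, offset = 10, min_component = 100L,
                       hue_lo = 60, hue_hi = 180, sat_min = 0.15,
                       crop = NULL) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    abort("`window` must be an odd integer >= 3.", class = "rhizoquant_config_error")
  if (min_component < 1L)
    abort("`min_component` must be >= 1.", class = "rhizoquant_config_error")
  if (isTRUE(all.equal(hue_lo, hue_hi)))
    abort("`hue_lo` and `hue_hi` must differ.", class = "rhizoquant_config_error")
  structure(list(window = window, offset = offset,
                 min_component = as.integer(min_component),
                 hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
                 crop = crop),
            class = "seg_config")
}

# ITU-R 601 luma from an rows x cols x 3 array on the 0-255 scale
luma <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Exact local mean over a (2h+1)^2 window clipped to the image, via an
# integral image; border windows are normalised by their true area.
local_mean <- function(x, window) {
  h <- (window - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  # integral image with a zero top row / left col
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / area
}

#' Segment roots by adaptive mean thresholding
#'
#' Converts the RGB rhizotron image to greyscale (ITU-R 601 luma) and marks
#' as root every pixel darker than the mean of its local neighbourhood by
#' more than `cfg$offset` grey levels. Local-mean thresholding corrects for
#' uneven illumination: adding a constant, or any gradient flat at the
#' window scale, to the whole frame leaves the mask unchanged.
#'
#' @param img RGB array from [read_plant_image()] (or a grey matrix),
#'   values 0--255.
#' @param cfg A [seg_config()].
#' @return Logical matrix, `TRUE` = root; same shape as the (cropped) frame.
#' @export
binarize_roots <- function(img, cfg = seg_config()) {
  stopifnot(inherits(cfg, "seg_config"))
  g <- luma(img)
  if (!is.null(cfg$crop)) {
    cr <- cfg$crop
    g <- g[cr[1]:cr[2], cr[3]:cr[4], drop = FALSE]
  }
  g < local_mean(g, cfg$window) - cfg$offset
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the label pairs.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # SE
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))   # NE
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0L) {
    for (q in seq_len(nrow(pairs))) {
      a <- find(pairs[q, 1L]); b <- find(pairs[q, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Remove small connected components from a mask
#'
#' Drops every 8-connected component with fewer than `min_component`
#' pixels. Idempotent, and never adds pixels.
#'
#' @param mask Logical matrix.
#' @param min_component Minimum surviving component size (px).
#' @return Logical matrix of the same shape.
#' @export
remove_small_components <- function(mask, min_component = 100L) {
  stopifnot(min_component >= 1L)
  if (min_component == 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Full root segmentation pipeline
#'
#' [binarize_roots()] followed by [remove_small_components()], with an
#' optional exclusion mask (pixels to force to background, standing in for
#' the manual clean-up step of interactive workflows).
#'
#' @inheritParams binarize_roots
#' @param exclude Optional logical matrix; `TRUE` pixels are removed.
#' @return Logical root mask.
#' @export
segment_roots <- function(img, cfg = seg_config(), exclude = NULL) {
  mask <- binarize_roots(img, cfg)
  if (!is.null(exclude)) mask <- mask & !exclude
  remove_small_components(mask, cfg$min_component)
}

# Per-pixel HSV hue (degrees) and saturation from an RGB array (0-255)
pixel_hsv <- function(img) {
  rgb <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
               as.vector(img[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  list(h = hsv[1L, ] * 360, s = hsv[2L, ], v = hsv[3L, ])
}

#' Canopy mask by hue-band thresholding
#'
#' Converts the canopy photograph to HSV and selects pixels whose hue falls
#' in the configured band (wrapping across 360 degrees allowed) and whose
#' saturation is at least `cfg$sat_min` — achromatic background has no
#' defined hue and is never selected.
#'
#' @inheritParams binarize_roots
#' @return Logical matrix, `TRUE` = canopy.
#' @export
canopy_mask <- function(img, cfg = seg_config()) {
  stopifnot(length(dim(img)) == 3L)
  hs <- pixel_hsv(img)
  inband <- if (cfg$hue_lo <= cfg$hue_hi) {
    hs$h >= cfg$hue_lo & hs$h <= cfg$hue_hi
  } else {
    hs$h >= cfg$hue_lo | hs$h <= cfg$hue_hi
  }
  matrix(inband & hs$s >= cfg$sat_min, dim(img)[1L], dim(img)[2L])
}

#' Canopy area in pixels
#'
#' @inheritParams canopy_mask
#' @return Integer pixel count of the canopy mask.
#' @export
canopy_area <- function(img, cfg = seg_config()) {
  sum(canopy_mask(img, cfg))
}
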