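#' Count orthogonal and diagonal skeleton pixel pairs
#'
#' Counts unordered pairs of skeleton pixels that are orthogonally adjacent
#' (sharing an edge) or diagonally adjacent (sharing only a corner). These
#' counts feed the orientation-robust Kimura length estimator.
#'
#' @param sk A `root_skeleton` or a logical matrix of skeleton pixels.
#' @return List with integer `N_o` and `N_d`.
#' @export
count_pairs <- function(sk) {
  px <- if (inherits(sk, "root_skeleton")) sk$pixels else sk
  nr <- nrow(px); nc <- ncol(px)
  N_o <- sum(px[-nr, ] & px[-1L, ]) + sum(px[, -nc] & px[, -1L])
  N_d <- sum(px[-nr, -nc] & px[-1L, -1L]) + sum(px[-1L, -nc] & px[-nr, -1L])
  list(N_o = as.integer(N_o), N_d = as.integer(N_d))
}

#' Kimura skeleton length estimator
#'
#' Combines orthogonal (`N_o`) and diagonal (`N_d`) adjacent-pair counts
#' into a length estimate that is nearly invariant to line orientation:
#' \deqn{L = \sqrt{N_d^2 + (N_d + N_o/2)^2} + N_o/2.}
#' An axis-aligned n-pixel line gives exactly n - 1; a diagonal line gives
#' (n - 1) * sqrt(2).
#'
#' @param N_o,N_d Pair counts from [count_pairs()]; alternatively `N_o` may
#'   be the list returned by [count_pairs()].
#' @return Length in pixels.
#' @export
kimura_length <- function(N_o, N_d = NULL) {
  if (is.list(N_o)) { N_d <- N_o$N_d; N_o <- N_o$N_o }
  sqrt(N_d^2 + (N_d + N_o / 2)^2) + N_o / 2
}

# Kimura length of the skeleton pixels whose row lies in [r1, r2], with
# adjacent pairs straddling a band edge assigned to the band of their
# deeper (larger-row) pixel.
band_length <- function(px, r1, r2) {
  N_o <- 0L; N_d <- 0L
  nr <- nrow(px); nc <- ncol(px)
  # vertical pairs: deeper pixel is the lower one
  v <- px[-nr, ] & px[-1L, ]
  vr <- ((which(v) - 1L) %% (nr - 1L)) + 2L        # row of deeper pixel
  N_o <- N_o + sum(vr >= r1 & vr <= r2)
  # horizontal pairs: both pixels share a row
  h <- px[, -nc] & px[, -1L]
  hr <- ((which(h) - 1L) %% nr) + 1L
  N_o <- N_o + sum(hr >= r1 & hr <= r2)
  # diagonal pairs: deeper pixel has the larger row
  d1 <- px[-nr, -nc] & px[-1L, -1L]
  d1r <- ((which(d1) - 1L) %% (nr - 1L)) + 2L
  d2 <- px[-1L, -nc] & px[-nr, -1L]
  d2r <- ((which(d2) - 1L) %% (nr - 1L)) + 2L
  N_d <- sum(d1r >= r1 & d1r <= r2) + sum(d2r >= r1 & d2r <= r2)
  kimura_length(as.integer(N_o), as.integer(N_d))
}

#' Vertical length distribution of the root system
#'
#' Splits the root system's own vertical extent (topmost to bottommost mask
#' row) into an upper third and lower two-thirds, computes the Kimura length
#' of the skeleton within each band (pairs straddling the boundary count in
#' the band of their deeper pixel), and returns the upper:lower ratio. High
#' values indicate a shallow, surface-foraging architecture.
#'
#' @param sk A `root_skeleton` from [skeletonize()].
#' @return List with `ratio` (NA when the lower band is empty), `upper` and
#'   `lower` lengths (px), and the boundary row.
#' @export
length_distribution <- function(sk) {
  stopifnot(inherits(sk, "root_skeleton"))
  top <- sk$extent[1L]; bottom <- sk$extent[2L]
  H <- bottom - top + 1L
  # first row of the lower band; upper band spans [top, boundary - 1]
  boundary <- top + ceiling(H / 3)
  upper <- band_length(sk$pixels, top, boundary - 1L)
  lower <- band_length(sk$pixels, boundary, bottom)
  ratio <- if (lower > 0) upper / lower else NA_real_
  if (lower == 0)
    warn("Lower two-thirds contains no skeleton length; ratio undefined.")
  list(ratio = ratio, upper = upper, lower = lower, boundary = boundary)
}

# closed arc length of an ocontour point chain (unit/sqrt(2) steps)
contour_arc_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  sum(sqrt(rowSums((pts - nxt)^2)))
}

#' Boundary-following perimeter of a mask
#'
#' Sum of outer and inner (hole) boundary arc lengths by 8-connected
#' boundary following: orthogonal steps count 1, diagonal steps sqrt(2).
#'
#' @param mask Logical matrix.
#' @return Perimeter in pixels.
#' @export
mask_perimeter <- function(mask) {
  lab <- label_components(mask)
  per <- sum(vapply(EBImage::ocontour(lab), contour_arc_length, numeric(1)))
  holes <- matrix(as.logical(EBImage::fillHull(mask * 1)), nrow(mask)) & !mask
  if (any(holes)) {
    hlab <- label_components(holes)
    per <- per + sum(vapply(EBImage::ocontour(hlab), contour_arc_length,
                            numeric(1)))
  }
  per
}

# Rasterized convex hull area: number of pixel centres inside or on the
# convex hull polygon of the root pixel centres (scanline on the convex
# polygon; exact up to floating-point at the boundary).
convex_hull_area <- function(mask) {
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(0L)
  if (nrow(coords) <= 2L) return(nrow(coords))
  hull_idx <- grDevices::chull(coords[, 2L], coords[, 1L])  # x = col, y = row
  hull <- coords[hull_idx, , drop = FALSE]
  if (nrow(hull) <= 2L) {
    # collinear point set: hull degenerates to a segment of pixels
    return(nrow(unique(coords)))
  }
  rows <- seq(min(hull[, 1L]), max(hull[, 1L]))
  eps <- 1e-9
  total <- 0L
  vx <- hull[, 2L]; vy <- hull[, 1L]
  k <- length(vx)
  nxt <- c(2:k, 1L)
  for (r in rows) {
    xs <- numeric(0)
    for (i in seq_len(k)) {
      y1 <- vy[i]; y2 <- vy[nxt[i]]
      x1 <- vx[i]; x2 <- vx[nxt[i]]
      if (y1 == y2) {
        if (y1 == r) xs <- c(xs, x1, x2)
      } else if (r >= min(y1, y2) && r <= max(y1, y2)) {
        xs <- c(xs, x1 + (r - y1) * (x2 - x1) / (y2 - y1))
      }
    }
    if (length(xs) > 0L)
      total <- total + max(0L, floor(max(xs) + eps) - ceiling(min(xs) - eps) + 1L)
  }
  total
}

#' Binary-image geometry traits
#'
#' Computes the mask-level traits: total area `A` (root pixel count),
#' perimeter `P` (boundary following), convex area `CA` (rasterised convex
#' hull), solidity `S = A / CA` (thoroughness of soil exploration within
#' the explored envelope), depth `D` (inclusive row extent) and `medR`
#' (median over mask-intersecting rows of the number of maximal horizontal
#' root runs — a proxy for root number).
#'
#' @param mask Logical matrix, non-empty.
#' @return List with `total_area`, `perimeter`, `convex_area`, `solidity`,
#'   `depth`, `medr`.
#' @export
geometry_traits <- function(mask) {
  if (!any(mask)) abort("Empty mask.", class = "rhizoquant_empty_mask")
  A <- sum(mask)
  CA <- convex_hull_area(mask)
  rows <- which(rowSums(mask) > 0L)
  runs <- row_run_counts(mask)[rows]
  list(total_area = A,
       perimeter = mask_perimeter(mask),
       convex_area = CA,
       solidity = A / CA,
       depth = max(rows) - min(rows) + 1L,
       medr = median(runs))
}

# number of maximal TRUE runs in every row
row_run_counts <- function(mask) {
  nc <- ncol(mask)
  starts <- mask & !cbind(FALSE, mask[, -nc, drop = FALSE])
  rowSums(starts)
}

#' Radius-derived traits
#'
#' Average diameter, volume and specific root length from the skeleton's
#' distance-transform radii: `d = mean(2 r_i)`, `V = sum(pi r_i^2)` (each
#' skeleton pixel contributes a unit-length cylinder slice), and
#' `SRL = L / A` (length per unit projected area), with `L / V` available
#' as a radius-weighted alternative.
#'
#' @param sk A `root_skeleton`.
#' @param L Total root length (px), e.g. `kimura_length(count_pairs(sk))`.
#' @param A Total root area (px).
#' @param srl_method `"length_area"` (default) or `"length_volume"`.
#' @return List with `average_diameter`, `volume`, `srl`.
#' @export
radius_traits <- function(sk, L, A, srl_method = c("length_area", "length_volume")) {
  srl_method <- match.arg(srl_method)
  r <- sk$radius[sk$pixels]
  V <- sum(pi * r^2)
  list(average_diameter = mean(2 * r),
       volume = V,
       srl = if (srl_method == "length_area") L / A else L / V)
}

#' All root-architecture traits from a mask
#'
#' Runs skeletonization and assembles the full trait record: total length
#' (Kimura estimator), total area, average diameter, perimeter, convex
#' area, volume, SRL, solidity, medR, depth and length distribution.
#' Deterministic given the mask.
#'
#' @param mask Logical root mask (row 1 = top of the rhizotron).
#' @param plant_id,time_point Identifiers carried into the output.
#' @param srl_method Passed to [radius_traits()].
#' @return A one-row tibble with columns `plant_id`, `time_point`,
#'   `total_length`, `total_area`, `average_diameter`, `perimeter`,
#'   `convex_area`, `volume`, `srl`, `solidity`, `medr`, `depth`,
#'   `length_distribution`.
#' @export
all_traits <- function(mask, plant_id = NA_character_,
                       time_point = NA_integer_,
                       srl_method = "length_area") {
  sk <- skeletonize(mask, plant_id = plant_id)
  L <- kimura_length(count_pairs(sk))
  geo <- geometry_traits(mask)
  rad <- radius_traits(sk, L, geo$total_area, srl_method)
  ld <- length_distribution(sk)
  tibble(plant_id = plant_id,
         time_point = time_point,
         total_length = L,
         total_area = geo$total_area,
         average_diameter = rad$average_diameter,
         perimeter = geo$perimeter,
         convex_area = geo$convex_area,
         volume = rad$volume,
         srl = rad$srl,
         solidity = geo$solidity,
         medr = geo$medr,
         depth = geo$depth,
         length_distribution = ld$ratio)
}
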