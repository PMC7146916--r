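#' Synthetic rhizotron scene specification
#'
#' Describes a fake rhizotron front: dark root-like strokes (downward-biased
#' random walks, optionally branching) rasterized at a fixed stroke width
#' over an unevenly illuminated background with additive Gaussian pixel
#' noise. The generator records exact analytic ground truth (polyline arc
#' lengths before rasterization), which trait-recovery tests compare
#' against.
#'
#' @param rows,cols Image size in pixels.
#' @param n_primary Number of primary strokes.
#' @param branch_prob Per-step probability that a stroke spawns a lateral.
#' @param stroke_width Stroke width in px (>= 1).
#' @param depth_bias Downward drift in `[0, 1]`; 1 gives perfectly vertical
#'   strokes (started at well-separated columns, so per-row run counts are
#'   exact).
#' @param illum_amplitude Peak-to-centre amplitude (grey levels) of a linear
#'   illumination gradient across the frame.
#' @param illum_direction `"horizontal"` or `"vertical"`.
#' @param noise_sd Additive Gaussian noise SD (grey levels).
#' @param background Mean background grey level.
#' @param contrast How much darker root strokes are than the local
#'   background (grey levels).
#' @param seed Integer seed; fixes the scene exactly.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(rows = 1200L, cols = 1000L, n_primary = 3L,
                       branch_prob = 0.003, stroke_width = 5L,
                       depth_bias = 0.9, illum_amplitude = 40,
                       illum_direction = c("horizontal", "vertical"),
                       noise_sd = 5, background = 180, contrast = 90,
                       seed = 1L) {
  illum_direction <- match.arg(illum_direction)
  if (rows < 10L || cols < 10L)
    abort("Scene must be at least 10 x 10 px.", class = "rhizoquant_config_error")
  stopifnot(stroke_width >= 1L, branch_prob >= 0, branch_prob <= 1,
            depth_bias >= 0, depth_bias <= 1)
  structure(as.list(environment()), class = "scene_spec")
}

# one random-walk polyline: (row, col) vertices at unit steps, plus the
# heading (angle from straight-down) at every vertex so laterals can be
# spawned at a divergent angle
walk_polyline <- function(start, heading, depth_bias, rows, cols, max_steps,
                          target = 0) {
  pts <- matrix(NA_real_, max_steps + 1L, 2L)
  phis <- numeric(max_steps + 1L)
  pts[1L, ] <- start
  phi <- heading
  phis[1L] <- phi
  wobble <- (1 - depth_bias) * 0.45 + 0.02
  n <- 1L
  for (s in seq_len(max_steps)) {
    # mean-revert to the growth-direction setpoint (vertical for primaries,
    # the emergence angle for laterals) with small angular noise
    phi <- target + 0.97 * (phi - target) + rnorm(1L, 0, wobble)
    phi <- max(min(phi, 1.3), -1.3)   # never walk upward
    step <- c(cos(phi), sin(phi))     # (d_row, d_col), unit length
    nxt <- pts[n, ] + step
    if (nxt[1L] > rows - 2 || nxt[2L] < 2 || nxt[2L] > cols - 1) break
    n <- n + 1L
    pts[n, ] <- nxt
    phis[n] <- phi
  }
  list(pts = pts[seq_len(n), , drop = FALSE], phis = phis[seq_len(n)])
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# arc length of the polyline falling in rows [r1, r2] (analytic clipping)
polyline_band_length <- function(pts, r1, r2) {
  if (nrow(pts) < 2L) return(0)
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(a))) {
    y1 <- a[i, 1L]; y2 <- b[i, 1L]
    len <- sqrt(sum((b[i, ] - a[i, ])^2))
    if (len == 0) next
    lo <- min(y1, y2); hi <- max(y1, y2)
    if (hi < r1 || lo > r2) next
    if (y1 == y2) { tot <- tot + len; next }
    f <- (min(hi, r2) - max(lo, r1)) / (hi - lo)
    tot <- tot + len * max(0, f)
  }
  tot
}

# exact rasterization of a constant-width tube around the polyline: a pixel
# centre is stroke iff its Euclidean distance to the polyline is <= width/2
rasterize_polyline <- function(mask, pts, width) {
  rad <- width / 2
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(max(nrow(pts) - 1L, 1L))) {
    a <- pts[i, ]
    b <- if (nrow(pts) > 1L) pts[i + 1L, ] else a
    r1 <- max(1L, floor(min(a[1L], b[1L]) - rad))
    r2 <- min(nr, ceiling(max(a[1L], b[1L]) + rad))
    c1 <- max(1L, floor(min(a[2L], b[2L]) - rad))
    c2 <- min(nc, ceiling(max(a[2L], b[2L]) + rad))
    if (r1 > r2 || c1 > c2) next
    rr <- matrix(rep(r1:r2, times = c2 - c1 + 1L), nrow = r2 - r1 + 1L)
    cc <- matrix(rep(c1:c2, each = r2 - r1 + 1L), nrow = r2 - r1 + 1L)
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else
      pmin(pmax(((rr - a[1L]) * ab[1L] + (cc - a[2L]) * ab[2L]) / len2, 0), 1)
    d2 <- (rr - (a[1L] + t * ab[1L]))^2 + (cc - (a[2L] + t * ab[2L]))^2
    hit <- d2 <= rad^2
    if (any(hit)) {
      blk <- mask[r1:r2, c1:c2]
      blk[hit] <- TRUE
      mask[r1:r2, c1:c2] <- blk
    }
  }
  mask
}

#' Render a synthetic rhizotron scene
#'
#' Draws the strokes described by a [scene_spec()], rasterizes them at the
#' configured width, composes the unevenly illuminated noisy image (roots
#' darker than background, as against peat), and returns exact ground
#' truth. Identical seeds give bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (rows x cols x 3 array, 0--255), `mask` (the
#'   true stroke raster) and `truth`: `drawn_length` (summed analytic
#'   polyline arc length), `upper_length`/`lower_length` (split at the
#'   upper-third boundary of the polyline vertical extent), `stroke_width`,
#'   `depth` (row extent of the raster), `row_runs` (per-row maximal-run
#'   counts of the raster), `n_polylines`, and the `polylines` themselves.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  rows <- spec$rows; cols <- spec$cols
  polys <- list()
  if (spec$depth_bias >= 1) {
    # perfectly vertical, non-overlapping strokes at well-separated columns
    gap <- max(2L * spec$stroke_width + 2L, 4L)
    avail <- seq(spec$stroke_width + 2L, cols - spec$stroke_width - 2L, by = gap)
    start_cols <- sample(avail, min(spec$n_primary, length(avail)))
    for (c0 in start_cols) {
      r0 <- runif(1, 3, rows * 0.15)
      r1 <- runif(1, rows * 0.6, rows - 3)
      polys[[length(polys) + 1L]] <- cbind(c(r0, r1), c(c0, c0))
    }
  } else {
    for (i in seq_len(spec$n_primary)) {
      start <- c(runif(1, 2, rows * 0.1), runif(1, cols * 0.1, cols * 0.9))
      main <- walk_polyline(start, rnorm(1, 0, 0.2), spec$depth_bias,
                            rows, cols, max_steps = rows)
      polys[[length(polys) + 1L]] <- main$pts
      if (spec$branch_prob > 0 && nrow(main$pts) > 10L) {
        spawn <- which(runif(nrow(main$pts)) < spec$branch_prob)
        for (s in spawn) {
          # laterals leave the parent corridor immediately: emergence angle
          # 0.5--1.0 rad off the parent's local heading, random side
          emerge <- main$phis[s] + sample(c(-1, 1), 1L) * runif(1, 0.5, 1.0)
          emerge <- max(min(emerge, 1.25), -1.25)
          br <- walk_polyline(main$pts[s, ], emerge,
                              spec$depth_bias, rows, cols,
                              max_steps = ceiling(rows / 4), target = emerge)
          if (nrow(br$pts) > 5L) polys[[length(polys) + 1L]] <- br$pts
        }
      }
    }
  }
  polys <- polys[vapply(polys, nrow, integer(1)) >= 2L]

  mask <- matrix(FALSE, rows, cols)
  for (p in polys) mask <- rasterize_polyline(mask, p, spec$stroke_width)

  lens <- vapply(polys, polyline_length, numeric(1))
  allr <- unlist(lapply(polys, function(p) p[, 1L]))
  top <- min(allr); bottom <- max(allr)
  boundary <- top + (bottom - top) / 3
  upper <- sum(vapply(polys, polyline_band_length, numeric(1),
                      r1 = top, r2 = boundary))
  lower <- sum(vapply(polys, polyline_band_length, numeric(1),
                      r1 = boundary, r2 = bottom))

  grad <- if (spec$illum_direction == "horizontal") {
    matrix(rep(seq(-1, 1, length.out = cols), each = rows), rows, cols)
  } else {
    matrix(rep(seq(-1, 1, length.out = rows), times = cols), rows, cols)
  }
  bg <- spec$background + spec$illum_amplitude * grad
  grey <- bg - spec$contrast * mask
  grey <- grey + rnorm(rows * cols, 0, spec$noise_sd)
  grey <- pmin(pmax(grey, 0), 255)
  img <- array(rep(grey, 3L), dim = c(rows, cols, 3L))

  mrows <- which(rowSums(mask) > 0L)
  truth <- list(drawn_length = sum(lens),
                upper_length = upper,
                lower_length = lower,
                stroke_width = spec$stroke_width,
                depth = if (length(mrows)) max(mrows) - min(mrows) + 1L else 0L,
                row_runs = row_run_counts(mask),
                n_polylines = length(polys),
                polylines = polys)
  list(image = img, mask = mask, truth = truth)
}

#' Render a synthetic canopy scene
#'
#' White background with `n_leaves` painted leaf-green elliptical blobs;
#' the exact painted pixel count is recorded as ground truth for canopy
#' area extraction.
#'
#' @param rows,cols Image size.
#' @param n_leaves Number of leaf blobs.
#' @param leaf_hue Leaf hue in degrees (default 120, pure green).
#' @param seed Integer seed.
#' @return List with `image` (rows x cols x 3, 0--255) and
#'   `truth$painted_pixels`.
#' @export
render_canopy <- function(rows = 400L, cols = 400L, n_leaves = 5L,
                          leaf_hue = 120, seed = 1L) {
  set.seed(seed)
  painted <- matrix(FALSE, rows, cols)
  for (i in seq_len(n_leaves)) {
    cr <- runif(1, rows * 0.2, rows * 0.8)
    cc <- runif(1, cols * 0.2, cols * 0.8)
    a <- runif(1, 8, rows / 8); b <- runif(1, 8, cols / 8)
    rr <- matrix(rep(seq_len(rows), cols), rows, cols)
    ccm <- matrix(rep(seq_len(cols), each = rows), rows, cols)
    painted <- painted | ((rr - cr)^2 / a^2 + (ccm - cc)^2 / b^2 <= 1)
  }
  col <- grDevices::hsv(leaf_hue / 360, s = 0.8, v = 0.7)
  rgbv <- grDevices::col2rgb(col)
  img <- array(255, dim = c(rows, cols, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[painted] <- rgbv[ch]
    img[, , ch] <- plane
  }
  list(image = img, truth = list(painted_pixels = sum(painted)))
}

#' Genetic simulation specification
#'
#' Describes a clonally replicated F1 mapping population: genotype effects
#' drawn from `N(0, var_g)`, replicate errors from `N(0, var_e)`, biallelic
#' markers segregating 1:1, and an optional causal marker whose effect is
#' scaled so that it explains a chosen fraction of the genotype-mean
#' phenotypic variance.
#'
#' @param n_genotypes Number of F1 genotypes.
#' @param n_reps Clonal replicates per genotype.
#' @param var_g Genetic (genotype-effect) variance.
#' @param var_e Environmental (replicate-error) variance.
#' @param n_markers Number of markers.
#' @param causal_marker Index of the causal marker (`NA` = none).
#' @param effect_size Fraction of genotype-mean variance explained by the
#'   causal marker, in `[0, 1)`.
#' @param n_linkage_groups Markers are assigned round-robin to this many
#'   linkage groups.
#' @param seed Integer seed.
#' @return A `gsim_spec` list.
#' @export
gsim_spec <- function(n_genotypes = 168L, n_reps = 3L, var_g = 1,
                      var_e = 3, n_markers = 24L, causal_marker = NA_integer_,
                      effect_size = 0, n_linkage_groups = 4L, seed = 1L) {
  stopifnot(var_g >= 0, var_e >= 0, effect_size >= 0, effect_size < 1,
            n_genotypes >= 2L, n_reps >= 1L)
  if (!is.na(causal_marker) && causal_marker > n_markers)
    abort("`causal_marker` exceeds `n_markers`.", class = "rhizoquant_config_error")
  structure(as.list(environment()), class = "gsim_spec")
}

#' Simulate a clonally replicated mapping population
#'
#' Generates phenotype and marker tables under a [gsim_spec()]. The causal
#' marker contributes an additive effect `a` on one allele class, with `a`
#' chosen so that its marginal variance `a^2/4` equals `effect_size` of the
#' total genotype-mean variance `var_g + var_e/n_reps + a^2/4`.
#'
#' @param g A [gsim_spec()].
#' @param trait_name Name of the simulated trait column.
#' @return List with `phenotypes` (tibble: `genotype_id`, `replicate_id`,
#'   `experiment_id`, trait), `markers` (tibble: `genotype_id` + one
#'   `"A"`/`"B"` column per marker), `map` (tibble: `marker`,
#'   `linkage_group`) and `truth` (the planted parameters, including the
#'   realised heritability `var_g / (var_g + var_e)` and causal effect `a`).
#' @export
simulate_population <- function(g, trait_name = "trait") {
  stopifnot(inherits(g, "gsim_spec"))
  set.seed(g$seed)
  ids <- sprintf("G%03d", seq_len(g$n_genotypes))
  geno_eff <- rnorm(g$n_genotypes, 0, sqrt(g$var_g))
  marker_mat <- matrix(sample(c("A", "B"), g$n_genotypes * g$n_markers,
                              replace = TRUE),
                       g$n_genotypes, g$n_markers)
  a <- 0
  if (!is.na(g$causal_marker) && g$effect_size > 0) {
    v_base <- g$var_g + g$var_e / g$n_reps
    a <- 2 * sqrt(g$effect_size / (1 - g$effect_size) * v_base)
    geno_eff <- geno_eff + a * (marker_mat[, g$causal_marker] == "B")
  }
  pheno <- tidyr::expand_grid(genotype_id = ids,
                              replicate_id = seq_len(g$n_reps)) %>%
    mutate(experiment_id = 1L,
           value = 10 + geno_eff[match(.data$genotype_id, ids)] +
             rnorm(dplyr::n(), 0, sqrt(g$var_e)))
  names(pheno)[names(pheno) == "value"] <- trait_name
  markers <- as_tibble(as.data.frame(marker_mat,
                                     stringsAsFactors = FALSE))
  mnames <- sprintf("M%03d", seq_len(g$n_markers))
  names(markers) <- mnames
  markers <- dplyr::bind_cols(tibble(genotype_id = ids), markers)
  map <- tibble(marker = mnames,
                linkage_group = sprintf(
                  "LG%d", ((seq_len(g$n_markers) - 1L) %% g$n_linkage_groups) + 1L))
  list(phenotypes = pheno, markers = markers, map = map,
       truth = list(H2 = if (g$var_g + g$var_e > 0)
                      g$var_g / (g$var_g + g$var_e) else 0,
                    causal_effect = a,
                    causal_marker = if (!is.na(g$causal_marker))
                      mnames[g$causal_marker] else NA_character_))
}
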