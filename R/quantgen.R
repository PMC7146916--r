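#' Genotype trait means
#'
#' Arithmetic mean over replicates for each genotype; missing values are
#' skipped, and genotypes with no non-missing observation are omitted.
#'
#' @param pheno Data frame with `genotype_id` and trait columns.
#' @param trait Trait column name.
#' @return Tibble with `genotype_id` and `mean_value`.
#' @export
genotype_means <- function(pheno, trait) {
  if (!trait %in% names(pheno))
    abort(sprintf("Trait '%s' not found.", trait),
          class = "rhizoquant_missing_trait")
  pheno %>%
    group_by(.data$genotype_id) %>%
    summarise(mean_value = mean(.data[[trait]], na.rm = TRUE),
              n = sum(!is.na(.data[[trait]])), .groups = "drop") %>%
    filter(.data$n > 0L) %>%
    select("genotype_id", "mean_value")
}

#' Broad-sense heritability from clonal replicates
#'
#' One-way random-effects genotype model estimated by the ANOVA method of
#' moments: `var_e = MS_within`, `var_g = (MS_between - MS_within) / n0`
#' with `n0` the mean replicate number (used for unbalanced designs), and
#' negative `var_g` clamped to zero. Returns
#' `H2 = var_g / (var_g + var_e)`, the fraction of phenotypic variance
#' attributable to genotype.
#'
#' @param pheno Data frame with `genotype_id` and trait columns; replicate
#'   rows per genotype.
#' @param trait Trait column name.
#' @return One-row tibble: `trait`, `H2`, `var_g`, `var_e`,
#'   `n_genotypes`, `mean_reps`.
#' @export
heritability <- function(pheno, trait) {
  dat <- pheno[!is.na(pheno[[trait]]), c("genotype_id", trait)]
  names(dat) <- c("genotype_id", "y")
  sizes <- table(dat$genotype_id)
  sizes <- sizes[sizes > 0L]
  if (length(sizes) < 2L || !any(sizes >= 2L))
    abort("Heritability needs >= 2 genotypes and replication.",
          class = "rhizoquant_insufficient_data")
  fit <- aov(y ~ factor(genotype_id), data = dat)
  ss <- summary(fit)[[1L]]
  ms_b <- ss[["Mean Sq"]][1L]
  ms_w <- if (nrow(ss) > 1L) ss[["Mean Sq"]][2L] else 0
  if (is.na(ms_w)) ms_w <- 0
  n0 <- mean(sizes)
  var_g <- max((ms_b - ms_w) / n0, 0)
  var_e <- ms_w
  h2 <- if (var_g + var_e > 0) var_g / (var_g + var_e) else 0
  tibble(trait = trait, H2 = h2, var_g = var_g, var_e = var_e,
         n_genotypes = length(sizes), mean_reps = unname(n0))
}

# genotype x replicate wide matrix for one trait
rep_matrix <- function(pheno, trait) {
  wide <- pheno %>%
    select("genotype_id", "replicate_id", dplyr::all_of(trait)) %>%
    tidyr::pivot_wider(names_from = "replicate_id",
                       values_from = dplyr::all_of(trait))
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$genotype_id
  m
}

#' Genetic correlation via reciprocal replicates
#'
#' For every ordered pair of distinct replicate indices (i, j), correlates
#' trait X measured on replicate i with trait Y measured on replicate j
#' across genotypes, then averages the correlations. Because the two
#' replicates of a clone share only their genotype, each reciprocal
#' correlation is attenuated environmental-noise-free toward the genetic
#' covariance; with X = Y it estimates repeatability rather than unity.
#'
#' @param pheno Data frame with `genotype_id`, `replicate_id` and traits.
#' @param trait_x,trait_y Trait column names (may be equal).
#' @param min_pairs Minimum complete genotypes for a replicate pairing to
#'   count (default 3); pairings below it are skipped.
#' @param average `"mean"` (literal average of correlations, default) or
#'   `"fisher"` (average on the Fisher-z scale).
#' @return One-row tibble: `trait_x`, `trait_y`, `r_g`, `n_pairings`.
#' @export
genetic_correlation <- function(pheno, trait_x, trait_y, min_pairs = 3L,
                                average = c("mean", "fisher")) {
  average <- match.arg(average)
  mx <- rep_matrix(pheno, trait_x)
  my <- rep_matrix(pheno, trait_y)
  reps <- intersect(colnames(mx), colnames(my))
  if (length(reps) < 2L)
    abort("Need >= 2 replicates for reciprocal correlations.",
          class = "rhizoquant_insufficient_data")
  rs <- c()
  for (i in reps) for (j in reps) {
    if (i == j) next
    ok <- stats::complete.cases(mx[, i], my[, j])
    if (sum(ok) < min_pairs) next
    rs <- c(rs, cor(mx[ok, i], my[ok, j]))
  }
  if (length(rs) == 0L)
    abort("All replicate pairings had too few complete genotypes.",
          class = "rhizoquant_insufficient_data")
  r_g <- if (average == "mean") mean(rs) else tanh(mean(atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12))))
  tibble(trait_x = trait_x, trait_y = trait_y, r_g = r_g,
         n_pairings = length(rs))
}

#' Phenotypic correlations between traits
#'
#' Pairwise Pearson correlations of genotype means, with complete-pairs
#' handling and two-sided p-values.
#'
#' @param pheno Data frame with `genotype_id` and trait columns.
#' @param traits Character vector of trait columns; default all numeric
#'   columns except identifiers.
#' @return Tibble with `trait_x`, `trait_y`, `r`, `p`, `n`; includes the
#'   unit diagonal and both triangles (symmetric).
#' @export
phenotypic_correlation <- function(pheno, traits = NULL) {
  id_cols <- c("genotype_id", "replicate_id", "experiment_id", "plant_id",
               "time_point")
  if (is.null(traits))
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      id_cols)
  means <- pheno %>%
    group_by(.data$genotype_id) %>%
    summarise(dplyr::across(dplyr::all_of(traits),
                            ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  if (nrow(means) < 3L)
    abort("Need >= 3 genotypes.", class = "rhizoquant_insufficient_data")
  grid <- expand.grid(trait_x = traits, trait_y = traits,
                      stringsAsFactors = FALSE)
  out <- pmap(grid, function(trait_x, trait_y) {
    x <- means[[trait_x]]; y <- means[[trait_y]]
    ok <- stats::complete.cases(x, y)
    if (trait_x == trait_y) {
      tibble(trait_x = trait_x, trait_y = trait_y, r = 1, p = 0, n = sum(ok))
    } else {
      ct <- suppressWarnings(cor.test(x[ok], y[ok]))
      tibble(trait_x = trait_x, trait_y = trait_y,
             r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  })
  bind_rows(out)
}

#' Kruskal--Wallis single-marker scan
#'
#' For each marker, runs a tie-corrected Kruskal--Wallis test of genotype
#' mean trait values across the marker's segregating classes (chi-square
#' p-value, df = classes - 1). Markers with fewer than two classes of at
#' least `min_class` genotypes are flagged unscanned. Within each linkage
#' group the most significant marker is reported as the focal SNP. An
#' optional Benjamini--Hochberg q-value column is included for reference;
#' no threshold is imposed.
#'
#' @param markers Data frame: `genotype_id` plus one column per marker
#'   (class labels as strings; `NA`/empty = missing).
#' @param pheno Data frame with `genotype_id` and the trait (replicate rows
#'   allowed; genotype means are taken first).
#' @param trait Trait column name.
#' @param map Optional data frame `marker`, `linkage_group`; when `NULL`
#'   all markers form one group.
#' @param min_class Minimum genotypes per class for a marker to be scanned.
#' @return A `kw_scan` object; see [tidy.kw_scan()] and [glance.kw_scan()].
#' @export
kw_scan <- function(markers, pheno, trait, map = NULL, min_class = 2L) {
  means <- genotype_means(pheno, trait)
  dat <- left_join(markers, means, by = "genotype_id")
  marker_cols <- setdiff(names(markers), "genotype_id")
  rows <- lapply(marker_cols, function(mc) {
    cls <- dat[[mc]]
    cls[!is.na(cls) & cls == ""] <- NA
    ok <- !is.na(cls) & !is.na(dat$mean_value)
    y <- dat$mean_value[ok]; gcls <- factor(cls[ok])
    counts <- table(gcls)
    if (sum(counts >= min_class) < 2L) {
      return(tibble(marker = mc, H = NA_real_, p = NA_real_,
                    df = NA_integer_, n = sum(ok), scanned = FALSE,
                    class_medians = list(NULL)))
    }
    meds <- tapply(y, gcls, median)
    if (length(unique(y)) == 1L) {
      H <- 0; p <- 1; df <- nlevels(gcls) - 1L
    } else {
      kt <- kruskal.test(y, gcls)
      H <- unname(kt$statistic); p <- kt$p.value
      df <- unname(kt$parameter)
    }
    tibble(marker = mc, H = H, p = p, df = as.integer(df), n = sum(ok),
           scanned = TRUE, class_medians = list(meds))
  })
  res <- bind_rows(rows)
  if (is.null(map)) map <- tibble(marker = marker_cols, linkage_group = "LG1")
  res <- left_join(res, map, by = "marker")
  res$q <- NA_real_
  res$q[res$scanned] <- stats::p.adjust(res$p[res$scanned], method = "BH")
  focal <- res %>%
    filter(.data$scanned) %>%
    group_by(.data$linkage_group) %>%
    slice_min(.data$p, n = 1L, with_ties = FALSE) %>%
    ungroup()
  structure(list(result = res, focal = focal, trait = trait),
            class = "kw_scan")
}

#' @describeIn kw_scan Per-marker scan table.
#' @param x A `kw_scan` object.
#' @param ... Unused.
#' @export
tidy.kw_scan <- function(x, ...) {
  select(x$result, "marker", "linkage_group", "H", "df", "p", "q", "n",
         "scanned")
}

#' @describeIn kw_scan One row per linkage group with its focal SNP.
#' @export
glance.kw_scan <- function(x, ...) {
  select(x$focal, "linkage_group", focal_marker = "marker", "H", "p")
}

#' @export
print.kw_scan <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis scan of '%s': %d markers (%d scanned), %d linkage groups\n",
              x$trait, nrow(x$result), sum(x$result$scanned),
              length(unique(x$result$linkage_group))))
  print(glance(x))
  invisible(x)
}

r_squared <- function(fit) summary(fit)$r.squared

#' Stepwise focal-SNP model
#'
#' Combines the focal SNPs of a [kw_scan()] into a multiple-QTL model by
#' forward--backward stepwise ordinary least squares on genotype means,
#' selecting by AIC (entry/exit by p-value available via `criterion`).
#' Reports the retained markers, each retained marker's partial R-squared
#' (the drop in model R-squared when it is removed, i.e. its effect size as
#' percent variance explained), and the full-model R-squared.
#'
#' @param scan A `kw_scan` object (its focal markers seed the model).
#' @param markers,pheno,trait As in [kw_scan()].
#' @param criterion `"AIC"` (default) or `"p"` (entry/exit at `alpha`).
#' @param alpha Entry/exit p-value when `criterion = "p"`.
#' @return A `qtl_model` object; see [tidy.qtl_model()] and
#'   [glance.qtl_model()].
#' @export
stepwise_qtl <- function(scan, markers, pheno, trait,
                         criterion = c("AIC", "p"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(scan, "kw_scan"))
  focal <- scan$focal$marker
  if (length(focal) == 0L)
    abort("Scan has no focal markers.", class = "rhizoquant_insufficient_data")
  means <- genotype_means(pheno, trait)
  dat <- left_join(means, markers, by = "genotype_id")
  dat <- dat[stats::complete.cases(dat[, c("mean_value", focal)]), ]
  for (f in focal) dat[[f]] <- factor(dat[[f]])
  null_fit <- lm(mean_value ~ 1, data = dat)
  scope <- as.formula(paste("~", paste(focal, collapse = " + ")))
  if (criterion == "AIC") {
    fit <- step(null_fit, scope = list(lower = ~1, upper = scope),
                direction = "both", trace = 0)
  } else {
    fit <- step_by_p(dat, focal, alpha)
  }
  terms_kept <- attr(stats::terms(fit), "term.labels")
  # drop aliased (collinear) markers, later-entering one first
  alias_na <- names(coef(fit))[is.na(coef(fit))]
  if (length(alias_na) > 0L) {
    bad <- terms_kept[vapply(terms_kept, function(tm)
      any(startsWith(alias_na, tm)), logical(1))]
    if (length(bad) > 0L) {
      warn(sprintf("Dropping collinear marker(s): %s",
                   paste(bad, collapse = ", ")))
      terms_kept <- setdiff(terms_kept, bad)
      fit <- lm(reformulate_terms(terms_kept), data = dat)
    }
  }
  full_r2 <- if (length(terms_kept)) r_squared(fit) else 0
  partial <- map_dbl(terms_kept, function(tm) {
    reduced <- lm(reformulate_terms(setdiff(terms_kept, tm)), data = dat)
    full_r2 - r_squared(reduced)
  })
  structure(list(model = fit, retained = terms_kept,
                 partial_r2 = setNames(partial, terms_kept),
                 r2 = full_r2, n = nrow(dat), trait = trait),
            class = "qtl_model")
}

reformulate_terms <- function(terms_kept) {
  if (length(terms_kept) == 0L) return(mean_value ~ 1)
  as.formula(paste("mean_value ~", paste(terms_kept, collapse = " + ")))
}

# p-value driven forward-backward selection
step_by_p <- function(dat, candidates, alpha) {
  current <- character(0)
  repeat {
    changed <- FALSE
    # forward
    remaining <- setdiff(candidates, current)
    if (length(remaining) > 0L) {
      base_fit <- lm(reformulate_terms(current), data = dat)
      pvals <- map_dbl(remaining, function(tm) {
        f2 <- lm(reformulate_terms(c(current, tm)), data = dat)
        an <- stats::anova(base_fit, f2)
        an$`Pr(>F)`[2L]
      })
      if (min(pvals) < alpha) {
        current <- c(current, remaining[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward
    if (length(current) > 0L) {
      full_fit <- lm(reformulate_terms(current), data = dat)
      pvals <- map_dbl(current, function(tm) {
        f0 <- lm(reformulate_terms(setdiff(current, tm)), data = dat)
        an <- stats::anova(f0, full_fit)
        an$`Pr(>F)`[2L]
      })
      if (max(pvals) >= alpha) {
        current <- setdiff(current, current[which.max(pvals)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lm(reformulate_terms(current), data = dat)
}

#' @describeIn stepwise_qtl Retained markers with partial R-squared.
#' @param x A `qtl_model` object.
#' @param ... Unused.
#' @export
tidy.qtl_model <- function(x, ...) {
  tibble(marker = x$retained,
         partial_r2 = unname(x$partial_r2[x$retained]),
         pct_variance = 100 * unname(x$partial_r2[x$retained]))
}

#' @describeIn stepwise_qtl Model-level summary.
#' @export
glance.qtl_model <- function(x, ...) {
  tibble(r2 = x$r2, n_markers = length(x$retained), n = x$n,
         aic = if (length(x$retained)) AIC(x$model) else NA_real_)
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("Stepwise QTL model for '%s': %d marker(s), R2 = %.3f\n",
              x$trait, length(x$retained), x$r2))
  if (length(x$retained)) print(tidy(x))
  invisible(x)
}

#' Low phosphate tolerance index
#'
#' Per-genotype ratio of mean dry biomass under low phosphate to mean dry
#' biomass under optimal phosphate (`mode = "ratio"`, default; 1 = fully
#' tolerant). `mode = "relative_difference"` returns
#' `(optimal - low) / optimal` instead.
#'
#' @param optimal,low Data frames with `genotype_id` and the trait, one per
#'   fertigation treatment.
#' @param trait Biomass column name.
#' @param mode `"ratio"` or `"relative_difference"`.
#' @return Tibble with `genotype_id`, `tolerance`, `mean_low`,
#'   `mean_optimal`; genotypes with zero optimal-treatment mean get `NA`
#'   with a warning.
#' @export
tolerance_index <- function(optimal, low, trait = "biomass",
                            mode = c("ratio", "relative_difference")) {
  mode <- match.arg(mode)
  mo <- genotype_means(optimal, trait) %>% rename(mean_optimal = "mean_value")
  ml <- genotype_means(low, trait) %>% rename(mean_low = "mean_value")
  joined <- dplyr::inner_join(mo, ml, by = "genotype_id")
  zero <- joined$mean_optimal == 0
  if (any(zero))
    warn(sprintf("%d genotype(s) with zero optimal-P mean; tolerance set NA.",
                 sum(zero)))
  tol <- if (mode == "ratio") joined$mean_low / joined$mean_optimal
         else (joined$mean_optimal - joined$mean_low) / joined$mean_optimal
  tol[zero] <- NA_real_
  tibble(genotype_id = joined$genotype_id, tolerance = tol,
         mean_low = joined$mean_low, mean_optimal = joined$mean_optimal)
}
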