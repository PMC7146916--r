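test_that("genotype means skip missing values and match a hand group-by", {
  ph <- tibble::tibble(genotype_id = c("a", "a", "b", "b", "b", "c"),
                       replicate_id = c(1, 2, 1, 2, 3, 1),
                       y = c(2, 4, 1, NA, 7, NA))
  gm <- genotype_means(ph, "y")
  expect_equal(gm$mean_value[gm$genotype_id == "a"], 3)
  expect_equal(gm$mean_value[gm$genotype_id == "b"], 4)
  expect_false("c" %in% gm$genotype_id)  # no observations left
  expect_error(genotype_means(ph, "nope"), class = "rhizoquant_missing_trait")
})

test_that("heritability hits its degenerate endpoints and affine invariance", {
  ph <- tibble::tibble(genotype_id = rep(c("a", "b", "c"), each = 3),
                       replicate_id = rep(1:3, 3),
                       y = rep(c(1, 5, 9), each = 3))
  expect_equal(heritability(ph, "y")$H2, 1)

  flat <- ph; flat$y <- 4
  expect_equal(heritability(flat, "y")$H2, 0)

  set.seed(2)
  ph$y <- ph$y + rnorm(9)
  h1 <- heritability(ph, "y")$H2
  ph$z <- 100 + 7 * ph$y
  expect_equal(heritability(ph, "z")$H2, h1, tolerance = 1e-12)

  expect_error(heritability(ph[c(1, 4), ], "y"),
               class = "rhizoquant_insufficient_data")
})

test_that("heritability recovers planted variance ratios in simulation", {
  set.seed(0)
  h25 <- vapply(1:60, function(s) {
    pop <- simulate_population(gsim_spec(n_genotypes = 200, n_reps = 3,
                                         var_g = 1, var_e = 3, seed = s))
    heritability(pop$phenotypes, "trait")$H2
  }, numeric(1))
  expect_lt(abs(mean(h25) - 0.25), 0.03)
})

test_that("genetic correlation: duplicated trait gives 1, independent effects give ~0", {
  set.seed(5)
  n <- 120
  g <- rnorm(n)
  ph <- tibble::tibble(genotype_id = rep(sprintf("g%03d", 1:n), each = 2),
                       replicate_id = rep(1:2, n),
                       x = rep(g, each = 2),
                       y = rep(g, each = 2))
  expect_equal(genetic_correlation(ph, "x", "y")$r_g, 1)

  # independent genotype effects: near-zero reciprocal correlation
  set.seed(6)
  ph$y <- rep(rnorm(n), each = 2) + rnorm(2 * n, 0, 0.1)
  expect_lt(abs(genetic_correlation(ph, "x", "y")$r_g), 0.2)
})

test_that("reciprocal self-correlation is attenuated by noise and approaches 1 as noise vanishes", {
  set.seed(9)
  n <- 200
  g <- rnorm(n, 0, 1)
  make_ph <- function(sd_e) tibble::tibble(
    genotype_id = rep(sprintf("g%03d", 1:n), each = 3),
    replicate_id = rep(1:3, n),
    x = rep(g, each = 3) + rnorm(3 * n, 0, sd_e))
  r_noisy <- genetic_correlation(make_ph(1), "x", "x")$r_g
  r_clean <- genetic_correlation(make_ph(1e-6), "x", "x")$r_g
  expect_lt(r_noisy, 0.75)       # attenuation: expect ~ H2 = 0.5
  expect_gt(r_noisy, 0.25)
  expect_equal(r_clean, 1, tolerance = 1e-6)
})

test_that("genetic correlation recovers rho * H2 for a shared genotype effect", {
  # traits X and Y share a genotype effect with cross-trait correlation
  # rho = 0.6 and per-trait H2 = 0.5: reciprocal-replicate correlation
  # estimates rho * H2 = 0.3
  set.seed(31)
  n <- 300
  rhats <- vapply(1:20, function(i) {
    gx <- rnorm(n); gy <- 0.6 * gx + sqrt(1 - 0.36) * rnorm(n)
    ph <- tibble::tibble(
      genotype_id = rep(sprintf("g%03d", 1:n), each = 2),
      replicate_id = rep(1:2, n),
      x = rep(gx, each = 2) + rnorm(2 * n, 0, 1),
      y = rep(gy, each = 2) + rnorm(2 * n, 0, 1))
    genetic_correlation(ph, "x", "y")$r_g
  }, numeric(1))
  se <- sd(rhats) / sqrt(length(rhats))
  expect_lt(abs(mean(rhats) - 0.3), 3 * se + 0.02)
})

test_that("phenotypic correlations match the textbook formula and structure", {
  set.seed(12)
  ph <- tibble::tibble(genotype_id = sprintf("g%02d", 1:30),
                       a = rnorm(30), b = rnorm(30))
  ph$c <- -ph$a
  pc <- phenotypic_correlation(ph, traits = c("a", "b", "c"))
  expect_equal(pc$r[pc$trait_x == "a" & pc$trait_y == "a"], 1)
  expect_equal(pc$r[pc$trait_x == "a" & pc$trait_y == "c"], -1)
  r_ab <- pc$r[pc$trait_x == "a" & pc$trait_y == "b"]
  manual <- sum((ph$a - mean(ph$a)) * (ph$b - mean(ph$b))) /
    sqrt(sum((ph$a - mean(ph$a))^2) * sum((ph$b - mean(ph$b))^2))
  expect_equal(r_ab, manual, tolerance = 1e-12)
  # symmetry
  expect_equal(r_ab, pc$r[pc$trait_x == "b" & pc$trait_y == "a"])
})

test_that("KW scan H matches the independent rank oracle and handles degenerate ties", {
  mk <- tibble::tibble(genotype_id = sprintf("g%d", 1:6),
                       M1 = c("A", "A", "A", "B", "B", "B"))
  ph <- tibble::tibble(genotype_id = sprintf("g%d", 1:6),
                       y = c(1, 2, 3, 10, 11, 12))
  sc <- kw_scan(mk, ph, "y")
  res <- tidy(sc)
  expect_equal(res$H, kw_H_oracle(ph$y, mk$M1), tolerance = 1e-9)
  expect_equal(res$H, 3.857, tolerance = 1e-3)

  # all trait values equal: H defined as 0, p = 1
  ph0 <- ph; ph0$y <- 5
  res0 <- tidy(kw_scan(mk, ph0, "y"))
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)

  # marker with a single observed class is flagged, not scanned
  mk$M2 <- "A"
  res2 <- tidy(kw_scan(mk, ph, "y"))
  expect_false(res2$scanned[res2$marker == "M2"])
})

test_that("KW scan agrees with the rank oracle across random populations", {
  for (s in 1:3) {
    pop <- simulate_population(gsim_spec(n_genotypes = 60, n_markers = 6,
                                         causal_marker = 2L,
                                         effect_size = 0.15, seed = s))
    res <- tidy(kw_scan(pop$markers, pop$phenotypes, "trait", map = pop$map))
    means <- genotype_means(pop$phenotypes, "trait")
    dat <- merge(pop$markers, means)
    for (m in res$marker) {
      expect_equal(res$H[res$marker == m],
                   kw_H_oracle(dat$mean_value, dat[[m]]), tolerance = 1e-9)
    }
    # focal marker per linkage group is the argmin p
    fo <- glance(kw_scan(pop$markers, pop$phenotypes, "trait", map = pop$map))
    for (lg in fo$linkage_group) {
      sub <- res[res$linkage_group == lg & res$scanned, ]
      expect_equal(fo$focal_marker[fo$linkage_group == lg],
                   sub$marker[which.min(sub$p)])
    }
  }
})

test_that("stepwise model selects the causal marker and its partial R2 matches all-subsets", {
  hits <- 0; spurious <- 0
  for (s in 1:25) {
    pop <- simulate_population(gsim_spec(n_genotypes = 168, n_markers = 10,
                                         n_linkage_groups = 10,
                                         causal_marker = 4L,
                                         effect_size = 0.2, seed = 100 + s))
    sc <- kw_scan(pop$markers, pop$phenotypes, "trait", map = pop$map)
    qm <- stepwise_qtl(sc, pop$markers, pop$phenotypes, "trait")
    if ("M004" %in% qm$retained) hits <- hits + 1
    spurious <- spurious + length(setdiff(qm$retained, "M004"))
  }
  expect_gte(hits / 25, 0.9)        # the causal marker is (almost) always kept
  expect_lt(spurious / 25, 2.5)     # AIC admits only a few null markers

  # partial R2 against an explicit projection oracle on the retained set
  pop <- simulate_population(gsim_spec(n_genotypes = 168, n_markers = 8,
                                       n_linkage_groups = 8,
                                       causal_marker = 3L,
                                       effect_size = 0.15, seed = 77))
  sc <- kw_scan(pop$markers, pop$phenotypes, "trait", map = pop$map)
  qm <- stepwise_qtl(sc, pop$markers, pop$phenotypes, "trait")
  means <- genotype_means(pop$phenotypes, "trait")
  dat <- merge(means, pop$markers)
  full_r2 <- r2_oracle(dat$mean_value, marker_design(dat, qm$retained))
  expect_equal(qm$r2, full_r2, tolerance = 1e-9)
  for (m in qm$retained) {
    red <- r2_oracle(dat$mean_value, marker_design(dat, setdiff(qm$retained, m)))
    expect_equal(unname(qm$partial_r2[m]), full_r2 - red, tolerance = 1e-9)
  }
  # invariants: partial R2 sums below model R2 (markers near-orthogonal)
  expect_lte(sum(qm$partial_r2), qm$r2 + 1e-9)
})

test_that("stepwise handles no-signal populations and p-value criterion", {
  pop <- simulate_population(gsim_spec(n_genotypes = 100, n_markers = 6,
                                       n_linkage_groups = 6,
                                       effect_size = 0, var_g = 0.01,
                                       var_e = 4, seed = 13))
  sc <- kw_scan(pop$markers, pop$phenotypes, "trait", map = pop$map)
  qm <- stepwise_qtl(sc, pop$markers, pop$phenotypes, "trait",
                     criterion = "p", alpha = 1e-6)
  expect_equal(length(qm$retained), 0L)
  expect_equal(qm$r2, 0)

  # collinear focal markers: the later-entering duplicate is dropped
  pop2 <- simulate_population(gsim_spec(n_genotypes = 120, n_markers = 4,
                                        n_linkage_groups = 4,
                                        causal_marker = 1L,
                                        effect_size = 0.3, seed = 19))
  pop2$markers$M002 <- pop2$markers$M001
  sc2 <- kw_scan(pop2$markers, pop2$phenotypes, "trait", map = pop2$map)
  # the duplicate never improves the model, so at most one copy is retained
  qm2 <- stepwise_qtl(sc2, pop2$markers, pop2$phenotypes, "trait")
  expect_false(all(c("M001", "M002") %in% qm2$retained))
  expect_true(any(c("M001", "M002") %in% qm2$retained))
})

test_that("tolerance index is the low:optimal ratio with sensible edge cases", {
  opt <- tibble::tibble(genotype_id = c("a", "a", "b", "b", "c"),
                        biomass = c(2, 4, 5, 5, 0))
  low <- tibble::tibble(genotype_id = c("a", "b", "b", "c"),
                        biomass = c(3, 0, 0, 1))
  expect_warning(ti <- tolerance_index(opt, low), "zero optimal")
  expect_equal(ti$tolerance[ti$genotype_id == "a"], 1)
  expect_equal(ti$tolerance[ti$genotype_id == "b"], 0)
  expect_true(is.na(ti$tolerance[ti$genotype_id == "c"]))

  ti2 <- suppressWarnings(tolerance_index(opt, low, mode = "relative_difference"))
  expect_equal(ti2$tolerance[ti2$genotype_id == "a"], 0)
  expect_equal(ti2$tolerance[ti2$genotype_id == "b"], 1)
})
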