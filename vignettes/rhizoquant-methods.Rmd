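---
title: "Methods: rhizotron root phenotyping and downstream genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhizotron root phenotyping and downstream genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and algorithmic choices behind
`rhizoquant`, in the spirit of a methods supplement: what each stage
assumes, which tunable parameters matter, what the synthetic generator
does and does not emulate, and where the design was genuinely open.

## Segmentation

Rhizotron photographs show dark roots pressed against a peat background
whose brightness varies smoothly across the frame (lighting geometry,
acrylic reflections). A single global grey threshold cannot separate the
two everywhere, so the package thresholds against a *local mean*: pixel
$p$ is root iff

$$\mathrm{grey}(p) < \overline{\mathrm{grey}}_{w \times w}(p) - \delta .$$

Because the local mean follows any additive, slowly varying illumination
field, the rule is exactly invariant to constant shifts and nearly
invariant to linear gradients that are flat at the window scale.

Parameters, with units and defaults:

* `window` ($w$, px; default 51) — must exceed the root stroke width by
  roughly an order of magnitude so that the window mean reflects
  background. At a typical rhizotron resolution of ~230 µm/px a 2 mm root
  is ~9 px wide, making 51 px a comfortable default.
* `offset` ($\delta$, grey levels on 0–255; default 10) — the noise
  rejection margin. With sensor noise of SD $\sigma \approx 5$ grey
  levels, $\delta = 2\sigma$ keeps the per-pixel false-positive rate
  around 2%, and the component-size filter removes the survivors.
* `min_component` (px; default 100) — 8-connected components smaller than
  this are treated as noise. The choice mirrors the deselection threshold
  used in practice: genuine root fragments at this resolution are larger,
  though disconnected fine laterals can fall below it (the motivation for
  the optional exclusion/inclusion mask input in interactive workflows).

The local mean is computed exactly via an integral image, with border
windows renormalised by their true clipped area; greyscale conversion is
ITU-R 601 luma, a fixed testable convention.

Canopy photographs are thresholded on HSV hue inside a configurable band
(default 60–180°, wrapping allowed) with a saturation floor (default
0.15): hue is undefined for achromatic pixels, so white background can
never match a hue band regardless of numerical noise in the conversion.

## Skeleton and length estimation

Traits derive from a one-pixel-wide, 8-connected skeleton obtained by
Guo–Hall thinning. Thinning algorithm choice matters more than is usually
appreciated: Zhang–Suen output retains staircase residue — pixels with
redundant orthogonal *and* diagonal connections to the same neighbour run
— which inflates adjacent-pair counts by 8–15% on curved strokes. Guo–Hall
deletes those pixels, and on rendered test tubes brings length errors
under 2%, so it is the package's thinning pass.

Total root length uses the Kimura pair-count estimator,

$$L = \sqrt{N_d^2 + \left(N_d + N_o/2\right)^2} + N_o/2,$$

with $N_o$ and $N_d$ the unordered orthogonal and diagonal adjacent
skeleton pixel pairs. It is exact for axis-aligned lines ($n-1$) and
diagonal lines ($(n-1)\sqrt2$), and its residual orientation bias is below
2% — the property the estimator exists for.

The per-pixel radius convention is $r_i = \mathrm{EDT}(i) - 0.5$, where
EDT is the Euclidean distance from a skeleton pixel centre to the nearest
background pixel centre. A single-pixel line then has diameter exactly 1
and a 5-px bar diameter exactly 5; on oblique or wiggly strokes the
skeleton rides slightly off the true centreline and the convention
under-reads width by a fraction of a pixel (observed ~0.5 px on width-5
random walks), an accepted bias documented in the trait-recovery tests.
Average diameter is $\overline{2r_i}$; volume is $\sum_i \pi r_i^2$, each
skeleton pixel contributing a unit-length cylindrical slice.

Other conventions worth stating:

* **Perimeter** follows 8-connected boundaries (outer contours plus hole
  contours), orthogonal steps counting 1 and diagonal steps $\sqrt2$ —
  less resolution-biased than counting boundary pixels.
* **Convex area** is the number of pixel centres inside or on the convex
  hull of the root pixel centres, rasterised by scanline; solidity is
  $A/CA$ and is therefore bounded by 1 (the area-over-hull reading; the
  inverted ratio that sometimes appears in trait tables is not bounded and
  is not used).
* **Depth** is the inclusive row extent of the mask, independent of where
  the frame was cropped above the soil line.
* **medR** is the median over mask-intersecting rows of the number of
  maximal horizontal root runs — horizontal slices of the network.
* **Length distribution** splits the *root system's own* vertical extent
  (not the frame's) at one third; Kimura length is computed per band with
  boundary-straddling pairs assigned to the band of their deeper pixel,
  which conserves the total pair count and reproduces the closed-form
  value $29/60$ for a 90-row vertical line. SRL defaults to $L/A$ (the
  trait-table convention); a radius-weighted alternative $L/V$ is exposed
  as `srl_method = "length_volume"` for users who prefer a volume-specific
  length.

Degenerate inputs: an empty mask raises a typed error carrying the plant
id; a lower band with no skeleton length makes the length-distribution
ratio a missing value (never $\infty$), which propagates as `NA` through
`all_traits()`.

## Growth kinetics

Root expansion between early imaging sessions is close to exponential, so
the growth rate is the slope $k$ of an ordinary least-squares fit of
$\log(\text{value})$ against session index, restricted to sessions 2–5
(the first session is still establishment; later sessions saturate as
roots hit rhizotron walls). The log-linear fit is closed-form and
deterministic; the window indices refer to the session column of the
trait table, not calendar days. Zero values inside the window are excluded
with a warning, and fewer than three positive points is a typed error.
The estimator is exactly invariant to rescaling the trait and to shifting
the time axis (with the window shifted along).

## Synthetic scenes: what they emulate, and what they do not

`render_scene()` draws root-like strokes as downward-biased random walks:
the heading mean-reverts to a growth-direction setpoint (vertical for
primaries; the emergence angle, 0.5–1.0 rad off the parent heading, for
laterals) with small angular noise per unit step. Strokes are rasterised
as exact constant-width tubes (a pixel is stroke iff its centre lies
within width/2 of the polyline), composed over a linear illumination
gradient with additive Gaussian noise, roots darker than background.

Ground truth is *analytic*: the summed arc length of the generating
polylines before rasterisation, per-band lengths from exact segment
clipping, plus the stroke width, raster depth extent and per-row run
counts. That truth contract has one important consequence: it is only an
unbiased length oracle while strokes rarely overlap, because overlapping
tubes merge in the raster while the summed polyline length counts them
twice. The generator is therefore sparse by design — defaults of 3
primaries and a per-step branching probability of 0.003 on a 1200×1000 px
frame keep expected overlap well under 1% of total length, while still
exercising branching, curvature and crossings. A denser scene is easy to
request, but its recorded "truth" stops being one; the methods tests keep
to the sparse regime for exactly that reason. With `depth_bias = 1` the
generator switches to perfectly vertical, column-separated strokes, the
regime in which per-row run counts (and hence medR) are exactly
predictable.

What the scenes deliberately do not emulate: soil texture, root hairs,
blur, specular reflections, water droplets, or growth dynamics (scenes
are static; kinetic fixtures are built by scaling drawn lengths
analytically). Passing the recovery tests therefore demonstrates that the
measurement chain is correct on images whose difficulty lies in uneven
illumination, noise, curvature and moderate overlap — not that
segmentation is robust to every glasshouse artefact; real deployments
still need the exclusion-mask path for manual clean-up.

`simulate_population()` plants a clonally replicated F1 population:
genotype effects $\sim N(0, \sigma^2_g)$, replicate errors
$\sim N(0, \sigma^2_e)$, biallelic markers segregating 1:1, and an
optional causal marker whose additive effect $a$ satisfies
$a^2/4 = e \cdot (\sigma^2_g + \sigma^2_e/r + a^2/4)$ so that it explains
the requested fraction $e$ of genotype-mean variance — the scale on which
the scan operates. Defaults (168 genotypes, 3 replicates, 24 markers in 4
linkage groups) mirror a realistic single-experiment mapping design at
desk scale.

## Quantitative genetics

**Heritability.** Broad-sense $H^2$ uses the one-way random-effects ANOVA
method of moments: $\hat\sigma^2_e = MS_W$,
$\hat\sigma^2_g = (MS_B - MS_W)/\bar n$ with $\bar n$ the mean replicate
number for unbalanced designs, negative estimates clamped at zero, and
$H^2 = \hat\sigma^2_g/(\hat\sigma^2_g + \hat\sigma^2_e)$. The estimator is
closed-form, invariant to affine trait transformations, and recovers
planted ratios of 0.25 and 0.10 within ±0.03 in the package's parameter
recovery simulations. The mean-replicate coefficient (rather than the
unbiased $n_0$ adjustment) is the declared convention; at the package's
replication levels the difference is far below the simulation tolerance.

**Genetic correlation.** For every ordered pair of distinct replicate
indices $(i, j)$, the Pearson correlation across genotypes between trait
X on replicate $i$ and trait Y on replicate $j$; the estimate is the
plain average over pairings (Fisher-z averaging is an option). Because
reciprocal replicates share only genotype, the expectation is the genetic
covariance over the phenotypic variance — for equal-heritability traits,
$\rho_g H^2$ — so the self-correlation is an attenuated repeatability,
not 1. Pairings with fewer than three complete genotypes are skipped.

**Kruskal–Wallis scan.** Markers are tested one at a time on genotype
means with the tie-corrected Kruskal–Wallis statistic
($\chi^2$ p-values, df = classes − 1). The all-values-tied degenerate
case is defined as $H = 0$, $p = 1$. Within each linkage group the
smallest-p marker is the focal SNP. No multiple-testing threshold is
imposed — focal SNPs feed the next stage rather than a declaration of
significance — but Benjamini–Hochberg q-values are included for
reference. Null calibration (pooled p-values uniform by Kolmogorov–
Smirnov across 200 seeded populations) and power at the 168-genotype
design are exercised in the acceptance tests.

**Stepwise focal-SNP model.** Focal SNPs are combined by forward–backward
stepwise OLS on genotype means under AIC (entry/exit by p-value is an
exposed alternative). Each retained marker's effect size is its partial
$R^2$ — the drop in model $R^2$ on removal — which matches an all-subsets
projection oracle to numerical precision. AIC is deliberately liberal:
with ten candidate markers, one or two null markers with small partial
$R^2$ typically enter alongside a genuine signal; the selection test
asserts causal-marker retention and bounded spurious admission rather
than exact-set recovery, which no AIC-based rule can promise.

**Tolerance index.** The low:optimal ratio of genotype-mean dry biomass
(bounded below by 0, 1 = fully tolerant), with the signed relative
difference available behind a flag; a zero optimal-phosphate mean yields
a missing value with a warning.

## Problem sizes and determinism

The validation suite uses 1200×1000 px scenes (20 seeds) for trait
recovery, 200 replicate fits for kinetics noise, 100 simulations per
heritability level, and 200 seeded populations each for scan calibration
and power — sizes at which every Monte-Carlo tolerance in the tests is
several standard errors wide. All stochastic stages are seeded; identical
seeds and configurations give bit-identical masks, trait tables and CSV
output, which the acceptance script verifies by hashing.

## Known limitations

* Traits are 2-D projections; volume assumes circular cross-sections.
* No topology reconstruction: primary and lateral roots are not
  distinguished, so branching-hierarchy traits are out of reach.
* The Kimura estimator corrects orientation, not overlap: heavily
  overlapping root mats are under-measured, in the package as in the
  imaging practice it models.
* The adaptive threshold assumes roots darker than background; reversed-
  contrast imaging would need an inverted comparison.
* Heritability uses a single-experiment one-way model; genotype×experiment
  interaction variance is not separated (the genetic-correlation module is
  the cross-experiment consistency check instead).
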