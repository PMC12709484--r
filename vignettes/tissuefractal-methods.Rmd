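---
title: "Quantifying structural complexity and disorder in tissue micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structural complexity and disorder in tissue micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(tissuefractal)
library(dplyr)
```

## The problem

Bright-field transmission micrographs of thin tissue sections encode local
mass density: denser material transmits differently, so the grayscale
intensity field I(x, y) is a proxy for the spatial organisation of tissue
mass. Degenerative disease reorganises that mass — diffuse matrix gives way
to compact deposits, heterogeneity grows across scales — and the change is
often too subtle for visual histopathology. `tissuefractal` quantifies it
with four complementary, physics-inspired statistics computed from a plain
grayscale image:

1. **Threshold-dependent box-counting fractal dimension.** Binarize at a
   grayscale level g, tile into square regions, and estimate each region's
   dimension Df as the least-squares slope of ln N(r) against ln(1/r),
   where N(r) counts occupied grid boxes of side r. Sweeping g traces a
   *trajectory* of the pooled MeanDf and STDDf; the threshold maximizing a
   between-group difference is the *optimal threshold*.
2. **Multifractal spectrum.** The intensity mass measure P(ε, i) (box
   intensity over total intensity) is probed with Q-warped weights
   μ_i = P_i^Q / Σ P_i^Q. Regressing Σ μ ln P and Σ μ ln μ on ln ε gives
   α(Q) and f(Q) directly — the singularity spectrum without a Legendre
   transform. Its bandwidth Δα = αmax − αmin measures heterogeneity.
3. **Fractal functional transformation.** Dtf = Df / (Dfmax − Df) with
   Dfmax = 2 for planar images. The map diverges as regions approach
   plane-filling, stretching the compressed upper tail of the Df
   distribution; ln Dtf is approximately Gaussian, so its mean and
   standard deviation are clean parametric summaries. Gaussianity is
   scored by a chi-square fit (below).
4. **Inverse participation ratio (IPR).** Each L×L window becomes a
   tight-binding optical lattice: site potentials ε_i = (I_i − Ī)/Ī (the
   relative intensity fluctuation, a stand-in for refractive-index
   fluctuation), unit hopping between 4-neighbours, open boundaries. For
   every unit-normalized eigenfunction E_k, IPR_k = Σ E_k⁴ ∈ [1/L², 1];
   the mean over all L² states measures localization, hence structural
   disorder. Scanning L shows how disorder accumulates with length scale.

## Conventions that matter

* **Percent thresholds divide by 256.** A grayscale level g maps to
  100·g/256 percent of full scale, so 110 ↔ 42.96875%, 95 ↔ 37.109375%,
  80 ↔ 31.25%. This is the only divisor consistent with all those pairs
  simultaneously; `percent_of()` / `gray_of()` implement it exactly, and
  any 4-decimal display rounding is cosmetic.
* **Pixels equal to the threshold are foreground.** The ≥ rule makes
  foreground monotonically non-increasing in the level, with level 0
  all-foreground.
* **Grid-anchored box counting, ragged edges included.** Boxes are
  anchored at the top-left; partial edge boxes count. This keeps N(r)
  exact on self-similar fixtures whose construction scales divide the box
  sizes, which is what the oracle tests rely on.
* **Region tiles are 1-based, row-major.** Tile (1, 5) of a 480×480 image
  at size 60 covers pixel rows 1–60 and columns 241–300. Remainder margins
  are dropped, never padded — padding would inject artificial structure
  into Df.
* **Empty regions are excluded, not zeroed.** ln N is undefined on an
  empty mask, so the region's Df is NA and the exclusion is counted;
  setting it to 0 would fabricate spurious optima in the trajectories.
  Likewise `transform_field()` *excludes* regions within δ = 1e-9 of the
  Dfmax pole rather than clipping them, because a clipped value would
  become an extreme outlier in ln Dtf.
* **Aggregation pools regions across images.** MeanDf / STDDf (and the
  lnDtf analogues) at each threshold are computed over the pooled
  per-region values of all images in a group, matching pooled
  distribution summaries; the standard deviation is the sample (ddof 1)
  estimate.
* **Contrast conventions.** `optimal_threshold()` maximizes the absolute
  between-group difference over jointly defined grid entries, breaking
  ties toward the lowest threshold, and reports percent change relative
  to the control group. Percent changes are therefore antisymmetric under
  a group swap only up to the change of denominator.

## Estimator details and numerical choices

**α(Q) estimator.** The spectrum uses the companion estimator
α(Q) = slope of Σ μ ln P versus ln ε, regressed over the box-side list
(default ε ∈ {2, 4, 6, 10, 12}, mirroring the box-counting scales on
60×60 regions for comparability). Zero-mass boxes are dropped before the
μ weights are formed because 0^Q diverges for Q < 0, and the weights are
computed in log-space so |Q| = 10 on masses spanning hundreds of orders
of magnitude stays finite. With a single ε the estimator degrades to the
single-scale quotient with a warning. Estimated f values above the
support dimension (2) are reported as-is and flagged
(`f_exceeds_dimension`), never clamped: a finite-scale regression can
legitimately yield them, and clamping would hide the diagnostic.

**Gaussianity score.** The score of a sample is 100 times the p-value of
a Pearson chi-square test on bins of equal expected probability under a
normal fitted by moments (df = bins − 3). A well-fitting Gaussian scores
high; scores above 90 mean no detectable departure at the 0.1 level. The
definition (p-value rather than an R² of a density fit) is a package
choice, exposed through `gaussian_fit()` with configurable bin count.

**IPR solver.** Windows are non-overlapping (overlap would correlate
supposedly independent lattice statistics), boundaries open by default
(periodic available), all L² eigenstates enter the mean with no energy
filtering, and group STD is taken across windows pooled over the group's
images. Dense symmetric eigendecomposition (LAPACK via `eigen`) is exact
at the sizes used (L ≤ 32 gives 1024×1024 operators); numerically
degenerate eigenvalues — certain on the ordered lattice — are flagged
because individual IPRs within a degenerate subspace are basis-dependent,
while their mean is not. Windows whose mean intensity is zero carry no
optical medium and are skipped (counted, reported as NA). A
`disorder_scale` multiplier on the potentials is exposed because the
physical constant linking relative intensity to refractive-index
fluctuation is sample-dependent and not identifiable from images alone.

## Synthetic ground truth

Every estimator is validated against generators whose answers are known
in closed form:

* `make_carpet()` — Sierpinski-type carpets. Deterministic variants have
  exact occupied-box counts m^(k−j) at scale b^j and dimension
  ln m / ln b; random variants retain m of b² cells independently per
  cell, with the same dimension in expectation.
* `make_cascade()` — binomial multiplicative cascades with exact box
  masses; the analytic spectrum (τ(Q) = −log_b Σ w^Q and its companion
  α, f) is provided by `cascade_spectrum()`. The raw float measure is
  kept: 8-bit quantization would destroy deep-level mass ratios, so
  grayscale export is explicit (`measure_to_gray()`).
* `make_anderson()` — i.i.d. Uniform(−W/2, W/2) site disorder, the
  textbook lattice whose mean IPR grows monotonically with W.
* `make_pseudo_tissue()` — the study-condition emulator, described next.

## What the pseudo-tissue generator emulates

`make_pseudo_tissue()` composes three layers on a `size²` grid
(default 480, the native micrograph size; tests use smaller sizes for
speed and state them explicitly):

* a constant transmission **floor** (default 40 grayscale units) — the
  minimum optical signal of a mounted section; thresholds at or below the
  floor give exactly full binary masks in *both* groups, so the
  informative sweep range starts above it;
* a **diffuse matrix**: a one-sided spatially correlated field
  (spectral synthesis, power-law exponent 3) scaled to 25 units — tissue
  mass only ever adds signal;
* **deposits**: Poisson-scattered Gaussian clumps (density 1.2e-2 per
  pixel, σ = 2.5 px) with lognormal amplitudes (log-mean log 110,
  log-sd 0.25) — the long-tailed mass hot-spots.

The `severity` knob emulates progressive, *focal* mass accumulation
with five coupled effects, each chosen for the direction disease moves
the corresponding statistic: deposits become more numerous (+90% at
severity 1) and slightly brighter and more variable in amplitude
(log-mean +0.1, log-sd +0.2), which raises MeanDf and Mean(lnDtf) at
every threshold above the floor; deposit placement clusters into
image-scale hot zones (placement weights `exp(0.8·severity·zones)` on a
long-range correlated zone field), so some analysis regions saturate
while others stay control-like — the regional bimodality that raises
STDDf and STD(lnDtf) against the variance-compressing ceiling at
Df → 2; deposits become more compact (σ −0.6, aggregate-like); and
pixel-scale lognormal speckle on the deposits (log-sd 0.6) supplies the
nanoscale granularity that raises the mean IPR at every window size.
These couplings were chosen once, as the generator's definition of a
control-like versus disease-like cohort, and the direction claims are
verified by simulation in the test suite.

One direction is deliberately *not* claimed: the image-level
multifractal bandwidth Δα at the default box scales. Severity
mechanisms that raise coverage (required for the MeanDf and Mean(lnDtf)
directions — box counting sits near Df ≈ 1.95 for any well-connected
mask, so even a hairline coverage deficit at one threshold flips those
contrasts violently) also stack deposits and saturate the 8-bit range,
which flattens the densest boxes and tends to *narrow* the measured
spectrum. The bandwidth-broadening mechanism itself (greater weight
disparity widens f(α)) is validated on cascade measures, where the
spectrum is known in closed form.

What the generator does **not** emulate: optics (point-spread function,
shading, staining chemistry), anisotropic or oriented structures, and
any quantitative correspondence to real cohorts. A passing direction
test therefore shows the *pipeline* responds correctly to a known
heterogeneity contrast — it says nothing about effect sizes in real
tissue, and the headline numbers of any real study depend on its
specific images.

## Worked example

```{r example}
ctrl <- lapply(1:4, function(s) make_pseudo_tissue(96, severity = 0, seed = s))
dis <- lapply(5:8, function(s) make_pseudo_tissue(96, severity = 1, seed = s))

report <- run_group_comparison(ctrl, dis, region_size = 48,
                               ipr_sizes = c(4, 8, 16),
                               eps_list = c(2, 4, 8, 16))
tidy(report)
```

```{r plots}
plot_contrast(report$trajectories$control, report$trajectories$disease)
autoplot(group_spectrum(dis, eps_list = c(2, 4, 8, 16)))
```

## Known limitations

* Df from ordinary least squares over a handful of box sizes carries
  finite-size bias on non-self-similar masks; the per-fit R² is reported
  so poorly scaling regions can be screened.
* The multifractal regression shares scales with the box counting by
  default; very small regions (below ~32 px) leave too few distinct ε
  for a stable spectrum.
* The IPR eigenproblem is dense: cost grows as L⁶ per window, which is
  why the scan caps at L = 32 by default.
* The chi-square Gaussianity score is a function of sample size; scores
  are comparable within a study design, not across very different n.
* Image selection (which micrographs enter a group) is the caller's
  responsibility; no automatic quality filter is applied.

The test suite exercises the full pipeline on compact study designs —
10-image cohorts of 96–120 px images with 40–48 px regions, IPR windows
up to 32 px, and 500-lattice disorder simulations at L = 16 — sizes
chosen so every region still contains many deposits and every sweep has
at least nine regions per image. The 480 px generator default matches
the native micrograph format for interactive use.
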