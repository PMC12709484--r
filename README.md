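# tissuefractal

Multiparametric quantification of structural complexity and disorder in
grayscale tissue micrographs, for image-analysis researchers and
quantitative pathologists working with bright-field transmission images
where intensity tracks local mass density.

The package computes four complementary statistics from a plain 2D
grayscale image (PNG/TIFF, 0–255):

* **Threshold-dependent box-counting fractal dimension.** Binarize at
  grayscale level *g* (foreground where I ≥ g), tile into square regions,
  and fit each region's dimension as the least-squares slope
  *Df = ln N(r) / ln(1/r)* over box sizes *r* (default {2, 4, 6, 10, 12}).
  Sweeping *g* over a grid (default levels 25–155, i.e. ~10–60% of full
  scale with the 100·g/256 percent convention) traces MeanDf and STDDf
  trajectories; `optimal_threshold()` locates the threshold where two
  groups differ most.
* **Multifractal singularity spectrum** f(α) vs α by the direct μ-measure
  method: μᵢ(Q) = Pᵢ^Q / Σ Pᵢ^Q over box mass fractions Pᵢ, with α(Q) and
  f(Q) obtained as regressions of Σ μ ln P and Σ μ ln μ on ln ε. Spectrum
  parameters (αmin, αmax, Δα, fmin, fmax, Δf) summarize heterogeneity.
* **Fractal functional transformation** Dtf = Df / (2 − Df), whose natural
  log is approximately Gaussian; Mean(lnDtf) and STD(lnDtf) trajectories
  and a chi-square Gaussianity score (`gaussian_fit()`).
* **Inverse participation ratio (IPR)** of intensity-derived tight-binding
  optical lattices: site potentials εᵢ = (Iᵢ − Ī)/Ī, unit nearest-neighbour
  hopping, open boundaries; IPR = Σ E⁴ per unit-normalized eigenstate,
  averaged over all L² states per L×L window and scanned over window sizes
  (default {2, 4, 8, 16, 32}).

Synthetic generators with analytic ground truth (Sierpinski-type carpets,
binomial multiplicative cascades, Anderson lattices, and a pseudo-tissue
cohort emulator with a disease-severity knob) validate every estimator.

## Worked example

```r
library(tissuefractal)

ctrl <- lapply(1:4, function(s) make_pseudo_tissue(96, severity = 0, seed = s))
dis  <- lapply(5:8, function(s) make_pseudo_tissue(96, severity = 1, seed = s))

report <- run_group_comparison(ctrl, dis, region_size = 48,
                               ipr_sizes = c(4, 8, 16),
                               eps_list = c(2, 4, 8, 16))
tidy(report)
```

```
# A tibble: 7 × 4
  metric      value_control value_disease percent_change
  <chr>               <dbl>         <dbl>          <dbl>
1 mean_df          1.08          1.37              27.0
2 std_df           0.135         0.191             40.9
3 mean_ln_dtf      0.155         0.809            420.
4 std_ln_dtf       0.287         0.492             71.4
5 mean_ipr         0.0117        0.0123             5.20
6 std_ipr          0.000582      0.000913          57.0
7 delta_alpha      0.431         0.304            -29.5
```

Each row contrasts the two groups: the fractal statistics
(`mean_df`/`std_df`) and transformed statistics (`mean_ln_dtf`/
`std_ln_dtf`) are evaluated at their own optimal thresholds (the sweep
thresholds where the groups differ most), `mean_ipr`/`std_ipr` at the
largest IPR window, and `delta_alpha` is the multifractal bandwidth of
each group's average spectrum. Positive percent change means the value is
higher in the second ("disease") group — the trajectory and IPR metrics
all move in the direction expected for rising structural disorder. The
image-level `delta_alpha` of the synthetic cohorts is the exception: the
severity knob concentrates mass but 8-bit saturation flattens the densest
boxes, so the bandwidth can shrink (see the methods vignette); spectrum
bandwidth behaviour is validated on cascade measures instead, where the
answer is known in closed form. (Exact numbers depend on seeds and cohort
sizes; regenerate with the code above.)

Single-image building blocks compose with the pipe:

```r
img <- read_gray("core.png")
img |> df_field(gray_level = 110, region_size = 60) |> glance()
img |> mf_spectrum() |> spectrum_params()
img |> ipr_scan(sizes = c(8, 16)) |> glance()
```

`autoplot()` methods draw every result type (trajectories, spectra, IPR
scans, distributions), and `inst/scripts/tissuefractal` is a small CLI
over the same functions.

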