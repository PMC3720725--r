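# lacoquant

Quantitative analysis of targeted chromatin array experiments.

Tethering a protein to an integrated lac-operator (lacO) repeat array via
a lac-repressor (lacR) fusion creates a microscopically visible chromatin
domain. Whether that domain stays compact or unfolds into a fibrillar
structure, which factors accumulate at it or are displaced from it, and
how fast those factors exchange, together report on what the tethered
protein does to chromatin. `lacoquant` implements the quantitative
pipeline such experiments need, for cell biologists and imaging analysts:

- **Synthetic ground truth** — simulation of 3D confocal stacks of nuclei
  carrying a compact (spheroidal) or unfolded (fibrillar) array domain,
  with anisotropic PSF blur, noise, per-cell expression variability and
  exactly known geometry; and simulation of FLIP/FRAP intensity series
  from a two-pool exchange model.
- **3D morphometry** — segmentation of the array domain, volume, mesh
  surface area, and the **surface factor**, the sphericity-type shape
  statistic

  SF = π^(1/3) · (6V)^(2/3) / S,

  i.e. the surface of an equal-volume sphere divided by the measured
  surface: 1 for a perfect sphere, lower for furrowed or fibrillar
  domains. Cohorts are classified as decondensed against a control
  quantile threshold.
- **Photobleaching kinetics** — background correction and normalization
  of FLIP/FRAP series (value 1 at the pre-bleach reference), and bounded
  nonlinear least-squares decomposition into

  v(t) = N₁·e^(−λ₁t) + N₂·e^(−λ₂t),   λ₁ > λ₂ ≥ 0,

  mapping the fast component to the freely diffusing pool and the slow
  component to the transiently chromatin-bound pool (fractions
  Nᵢ/(N₁+N₂), half-times ln 2/λᵢ).
- **Statistics** — Shapiro–Wilk normality gate with a Levene-type
  variance check, Wilcoxon rank-sum comparisons against control with
  Bonferroni correction (cutoff α/m, e.g. 0.05/7 ≈ 0.007), Pearson
  correlation of expression versus shape, chi-square independence on 2×2
  tables, comparative-Ct (ΔΔCt) fold changes and reporter-repression
  percentages.

## Worked example

Simulate one FLIP curve from a two-pool model with 37% bound molecules
(half-time 52 s) and a freely diffusing pool (half-time 3 s), normalize
it, and decompose it again:

```r
library(lacoquant)

spec  <- kinetics_spec(f_bound = 0.37, thalf_fast = 3, thalf_slow = 52,
                       noise_sigma = 0.02, seed = 42)
curve <- normalize_bleach(simulate_bleach_curve(spec, "FLIP"))
fit   <- fit_biexponential(curve)
fit
#> Bi-exponential decay fit (FLIP)
#>   fast pool:  65.9%  t1/2 = 3.18 s  (lambda = 0.2181 /s)
#>   slow pool:  34.1%  t1/2 = 55.3 s  (lambda = 0.01252 /s)
#>   rss 0.03214 over 81 points
pool_summary(fit)
#> 66% freely diffusing (t1/2 = 3.18 s), 34% chromatin-bound (t1/2 = 55.3 s)
```

A single noisy 160 s curve recovers the generating decomposition to a few
points; averaging 50 replicate fits (see `fit_cohort()` and
`simulate_flip_cohort()`) recovers it to a fraction of a point. The fit
object supports `coef()`, `predict()`, `residuals()`, `plot()` and
`simulate()`.

On the imaging side:

```r
gs <- generate_array_stack(scene_spec("sphere"))   # compact 1 um domain
dm <- measure_domain(gs$stack)
dm
#> domain_morphology: V 4.34 um^3, S 12.8 um^2, surface factor 1.003
```

A digitized sphere measures a surface factor of 1.00 (the defining
value); the default fibrillar domain of equal volume measures ≈ 0.54.
Whole-experiment drivers (`run_morphology_experiment()`,
`run_kinetics_experiment()`) take a config list or YAML file, write
CSV/JSON reports with reproducibility manifests, and are demonstrated in
the vignette (`vignettes/array-morphometry-and-kinetics.Rmd`).

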