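---
title: "Estimating rapeseed yield from six-band UAV imagery with spectral mixture analysis"
author: "rapemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rapeseed yield from six-band UAV imagery with spectral mixture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapemix)
```

## The problem

Flowering rapeseed canopies are a hard target for vegetation-index (VI) yield
regression. During bloom, bright yellow flowers sit on top of the canopy for
weeks, so every image pixel mixes flower, leaf and soil signals with very
different spectra. A VI computed from such mixed reflectance carries
information about components that are weakly related to yield, and indices
built on green reflectance degrade most. The remedy implemented here is
spectral mixture analysis: estimate, per pixel, the fractional abundance of
each scene component, and regress yield not on the VI alone but on the
product of the VI and the abundance of the component that actually drives
yield formation — the short-stalk leaves.

The package implements the full chain for six-band imagery (bands centred at
490, 550, 670, 720, 800 and 900 nm, 10 nm width):

1. **Empirical-line calibration** of raw digital numbers (DN) to surface
   reflectance using four in-scene panels of known reflectance.
2. **Fully constrained least-squares (FCLS) unmixing** of each pixel against
   a five-endmember library: flower (FL), sessile leaf (SE-LF), short-stalk
   leaf (SS-LF), wet soil (W-soil), dry soil (D-soil).
3. **Vegetation indices** (ten standard formulas) from plot-mean reflectance.
4. **Plot aggregation** over rectangular regions of interest.
5. **Yield regression** of four predictor families with averaged
   leave-one-out cross-validation (LOOCV).

A synthetic-scene generator with complete ground truth makes every stage
verifiable without field data.

## Radiometric calibration

The sensor is assumed linear per band:
$$\rho(\lambda) = \mathrm{DN}(\lambda)\, G_\lambda + B_\lambda .$$
Per band, $(B_\lambda, G_\lambda)$ is the ordinary-least-squares solution of
reflectance on DN over the calibration panels (nominal reflectances 0.06,
0.24, 0.48, 1.00), solved through the explicit normal equations. With two
panels the line interpolates exactly; with all four, the residual sum of
squares per band is kept as a diagnostic. Design choices:

* **Direct, not inverse, regression.** Reflectance is the response, DN the
  regressor, matching the normal-equations form of the calibration model.
* **No clipping.** Calibrated reflectance below 0 or above 1 passes through
  and is only counted (`attr(refl, "outOfRange")`). Clipping would bias the
  unmixing residuals of marginal pixels.
* **Panel statistic.** Panel DN is the plain arithmetic mean over the panel
  rectangle; nothing in the method requires a robust statistic on synthetic
  panels, and the mean keeps the estimator linear.

```{r calibration}
sc <- synthesizeScene(sceneConfig(noiseSigma = 0, width = 200L,
                                  height = 140L, plotWidth = 40L,
                                  plotHeight = 18L))
model <- fitEmpiricalLine(sc$panels)
model
```

## The linear mixing model and the FCLS solver

A pixel's reflectance is modelled as a convex combination of the endmember
spectra:
$$\rho(\lambda) = \sum_{i=1}^{5} \mathrm{Abd}_i\, \rho_i(\lambda), \qquad
0 \le \mathrm{Abd}_i \le 1, \qquad \sum_i \mathrm{Abd}_i = 1 .$$
Inversion is the fully constrained least-squares problem
$\min_a \|r - Ma\|^2$ subject to $a \ge 0$, $\mathbf{1}^\top a = 1$, where
$M$ is the 6-band × 5-endmember library matrix. The constraints are taken as
exact (not "solve unconstrained, then clip"): the model states them as hard
physical conditions, so the solver enforces them.

Numerical scheme (C++, per pixel):

* Lawson–Hanson active-set NNLS on the augmented system
  $[M;\ \delta\mathbf{1}^\top]\,a \approx [r;\ \delta]$ with $\delta = 10^3$,
  which makes the sum-to-one constraint effectively hard while keeping the
  problem an NNLS.
* The solution is renormalised to the simplex; if its sum deviates from 1 by
  more than $10^{-8}$, an exact equality-constrained refinement (KKT system
  on the positive support) replaces it.
* Gradient ties during active-set selection break toward the smallest
  endmember index, so collinear cases are deterministic.
* Pixels are strictly independent: no spatial regularisation, and results
  cannot depend on visiting order.

Feasibility is guaranteed for arbitrary input, including out-of-gamut
reflectance: components stay within $[0,1]$ to $10^{-9}$ and sums within
$10^{-6}$. The test suite also checks the solver against an exhaustive
0.01-step enumeration of the whole simplex (4.6 million candidate vectors),
which it must never lose to.

The built-in endmember library encodes the qualitative relations observed in
flowering rapeseed: flower blue reflectance (0.03) below half the leaf value
(0.08) but far above leaf in green, red and NIR; sessile leaf darker in
green and slightly brighter in NIR than short-stalk leaf; wet soil below dry
soil everywhere. Field spectra at 1 nm resolution can be substituted via
`resampleLibrary()`, which averages over the closed 10 nm band-pass window —
the resampling rule is this package's convention, as instrument-level
band-pass weighting is rarely published.

```{r unmix}
lib <- defaultEndmemberLibrary()
unmixPixel(0.4 * spectra(lib)[, "FL"] + 0.6 * spectra(lib)[, "SS-LF"], lib)
```

## Vegetation indices

Ten indices are evaluated literally from their standard formulas on 0–1
scale reflectance (`viNames`). Conventions worth stating:

* **SAVI** uses $L = 0.5$ by default (the canonical soil-adjustment value);
  $L$ is configurable per call.
* **TVI** is implemented as
  $0.5\,[\,120(\rho_{800}-\rho_{550}) - 200(\rho_{670}-\rho_{550})\,]$; a
  stray parenthesis that sometimes appears in printed versions of the
  formula is treated as a typo.
* **RDVI** is $\sqrt{\mathrm{NDVI} \cdot (\rho_{800}-\rho_{670})/2}$. The
  radicand equals $(\rho_{800}-\rho_{670})^2 / (2(\rho_{800}+\rho_{670}))$
  and can only go negative for out-of-gamut input with
  $\rho_{800}+\rho_{670} < 0$; such pixels yield a flagged `NA` rather than
  a complex number.
* **Degenerate denominators** (magnitude below $10^{-12}$) yield flagged
  `NA`s; `viImage()` aggregates flags to counts.
* **Scale.** The additive constants in EVI and SAVI fix the reflectance
  scale at 0–1 for the whole pipeline; percent-scale input would change EVI
  non-linearly, and a guard test asserts this.

## Plot aggregation

Plot values are unweighted arithmetic means over explicit, axis-aligned
rectangles in 0-based half-open pixel coordinates (x = column, y = row).
Explicit ROIs keep runs reproducible; `inscribeMaxRectangle()` is available
for users who want the "largest fitted rectangle in a plot mask" behaviour.
Plot-level VI follows the **VI-of-mean** convention (index of the mean
reflectance); mean-of-VI is available behind the `viStat` flag for
sensitivity checks. No ridge-pixel masking is applied inside ROIs. Mean
abundances of simplex-valued pixels remain on the simplex, which the table
builder checks to $10^{-6}$.

## Yield models and cross-validation

Four linear predictor families are fitted against yield over the plots:
yield ~ VI, yield ~ VI·Abd\_FL, yield ~ VI·(Abd\_SE-LF + Abd\_SS-LF) and
yield ~ VI·Abd\_SS-LF — 40 full-sample fits for the ten indices. The
leave-one-out procedure fits each fold on $K-1$ plots and reports
$$\mathrm{Coef} = \tfrac{1}{K}\sum_i \mathrm{Coef}_i, \quad
R^2 = \tfrac{1}{K}\sum_i R_i^2, \quad
\mathrm{RMSE} = \sqrt{\tfrac{1}{K}\sum_i E_i^2},$$
with $E_i$ the held-out error of fold $i$. Conventions:

* Slope and intercept are averaged independently across folds.
* $R_i^2$ is the *training* $R^2$ of fold $i$ (the fold's calibration
  accuracy), while RMSE comes from the held-out errors — so the averaged
  $R^2$ is optimistic relative to a purely predictive $R^2$, and the two
  metrics deliberately answer different questions.
* CV is defined as $100 \cdot \mathrm{RMSE} / \overline{y}$, the relative
  RMSE conventional in yield-estimation work (the quantity is often
  reported without a definition).
* Full-sample and cross-validated metrics are labelled separately in the
  output (`fits.csv` vs `loocv.csv`); where published tables are ambiguous
  about which was reported, this package computes both.
* No multiple-testing correction is applied across the 40 fits; the
  $R^2$ values are descriptive, not inferential.
* Predicted yields are not clipped at zero.

## The synthetic world

The generator's defaults are a stated world, fixed once:

| Parameter | Default | Why |
|---|---|---|
| Image | 480 × 320 px | desk-scale stand-in for ~30,000-pixel field plots |
| Plots | 24 (8 N rates × 3 replicates), 100 × 40 px | the targeted trial design: N = 0, 45, 90, 135, 180, 225, 270, 360 kg/ha |
| Panels | 4, at 0.06 / 0.24 / 0.48 / 1.00 | the standard calibration target set |
| Gains $G_\lambda$ | 4.2–5.2 × 10⁻⁴ refl/DN | puts the 100 % panel near DN 2000 (10–11-bit range) |
| Biases $B_\lambda$ | 0.005–0.012 | small positive dark offsets |
| Reflectance noise | σ = 0.005 | the noise level at which abundance recovery is specified |
| Pixel Dirichlet concentration | 60 | visible within-plot texture, clear between-plot contrast |
| Plot-mean Dirichlet concentration | 300 | mild replicate-to-replicate field heterogeneity |
| Yield model | 6500 · (NDVI × Abd_SS-LF) + 1000, σ = 150 kg/ha | see below |

Abundance fields are Dirichlet draws around a nitrogen-group mean (the
short-stalk-leaf mean abundance rises linearly from 0.12 at N = 0 to 0.59
at N = 360, the sessile leaf tracks it at 30 %, flower cover is flat at
0.20 — flowering canopies look alike from above — and soil takes the
remainder), Gaussian-smoothed within each plot and re-projected to the
simplex. Ridge pixels between plots are 97 % soil by construction. The
generative model is this package's own: real abundance maps were measured,
not simulated, in the motivating field study, and no within-plot variance
was published to calibrate against.

The yield coefficients were calibrated once, before the acceptance suite was
written, to the stated target that noiseless yields span roughly 1000–3500
kg/ha: the realized noiseless NDVI × Abd_SS-LF predictor spans ≈ 0.021–0.395
across seeds, giving $a = 6500$, $b = 1000$; σ = 150 kg/ha yield noise
leaves realized yields inside [800, 3800] at the probed seeds.

What the generator deliberately does **not** emulate: BRDF and
radiative-transfer effects, band-to-band mis-registration, vignetting,
atmospheric variation, quantization (off by default so round-trip oracles
are exact; a 10-bit flag exists), or spatially correlated sensor noise. A
green test suite therefore establishes that the *algorithms* are correct and
self-consistent under the linear model's own assumptions — it does not
establish that accuracies observed on synthetic scenes transfer to any real
scene.

## Numerical choices

* Reflectance is clipped to [0, 1.2] (not 1.0) at render time: the 100 %
  panel plus noise may legitimately exceed 1, and clipping at exactly 1
  would bias the panel regression.
* DN is rendered as floating point by default for exact inverse-composition
  oracles.
* All generator randomness flows through the config seed (abundance field:
  seed; reflectance noise: seed + 1; yield noise: seed + 2); the caller's
  RNG state is saved and restored.
* LOOCV contains no randomness and is bit-reproducible.
* Abundance feasibility tolerances: components within $10^{-9}$ of $[0,1]$,
  sums within $10^{-6}$ of 1.

## Limitations

* Endmembers must be supplied; there is no endmember extraction from the
  image (no N-FINDR/PPI) and no shade endmember or per-pixel endmember
  selection (MESMA).
* Aggregation is pixel-space only: no georeferencing, no sub-pixel ROI
  weighting.
* The synthetic scene shares the pipeline's linear-mixing assumption, so
  unmixing tests cannot detect model error in that assumption itself; they
  detect solver and plumbing error.
* The yield model is linear by design — the approach's appeal is that a
  simple linear fit works once the abundance product is used — and no
  machine-learning regressors are provided.
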