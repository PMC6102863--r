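# rapemix

Spectral mixture analysis pipeline for estimating rapeseed yield from
six-band UAV imagery.

## The problem

During bloom, a rapeseed canopy viewed from above is a mixture of bright
yellow flowers, green leaves and soil — components with very different
spectra — inside every image pixel. Vegetation indices (VIs) computed from
such mixed reflectance correlate weakly with yield, because much of the
signal comes from components that do not drive yield formation. The approach
implemented here unmixes each pixel into fractional **abundances** of five
endmembers — flower (FL), sessile leaf (SE-LF), short-stalk leaf (SS-LF),
wet soil (W-soil), dry soil (D-soil) — and regresses yield on the product of
a VI and the short-stalk-leaf abundance, the component most relevant to
yield.

The chain, for imagery with bands centred at 490/550/670/720/800/900 nm:

1. **Empirical-line calibration**: per band,
   ρ(λ) = DN(λ)·G<sub>λ</sub> + B<sub>λ</sub>, with (B, G) fitted by
   ordinary least squares over four in-scene panels of nominal reflectance
   0.06, 0.24, 0.48, 1.00.
2. **Fully constrained least-squares unmixing**: per pixel, minimise
   ‖r − M·Abd‖² subject to Abd ≥ 0 and ΣAbd = 1, where M is the 6×5
   endmember matrix (Lawson–Hanson NNLS on a sum-to-one-augmented system,
   with exact KKT refinement; implemented in C++).
3. **Vegetation indices**: NDVI, CI<sub>rededge</sub>, CI<sub>green</sub>,
   VARI, RVI, DVI, RDVI, EVI, TVI, SAVI, evaluated literally from their
   standard formulas on 0–1 reflectance.
4. **Plot aggregation**: unweighted means over rectangular ROIs (0-based,
   half-open pixel coordinates); VI-of-mean convention.
5. **Yield regression**: four predictor families (VI, VI·Abd_FL,
   VI·(Abd_SE-LF+Abd_SS-LF), VI·Abd_SS-LF) fitted by OLS, with averaged
   leave-one-out cross-validation: Coef = ΣCoef_i/K, R² = ΣR²_i/K,
   RMSE = √(ΣE²_i/K), CV = 100·RMSE/mean(y).

A synthetic-scene generator with complete ground truth (true abundances,
true sensor gain/bias, true yields) makes every stage testable offline; see
the vignette in `vignettes/` for the model and all numerical conventions.

## Worked example

```r
library(rapemix)

sc    <- synthesizeScene(sceneConfig(seed = 1))        # 480 x 320 px, 24 plots
model <- fitEmpiricalLine(sc$panels)                   # per-band (G, B)
refl  <- applyCalibration(sc$image, model)             # DN -> reflectance
am    <- unmixImage(refl, sc$library)                  # per-pixel abundances
tab   <- buildPlotTable(refl, am, sc$rois, sc$yields)  # 24-row analysis table
rep   <- evaluateAll(tab)
```

The plot table (one row per plot):

```
  plot_id n_rate  ndvi abd_fl abd_ss_lf yield_kg_ha
1     P01     45 0.283  0.207    0.1534        1194
2     P02     90 0.360  0.142    0.2507        1615
3     P03      0 0.235  0.175    0.0981        1234
4     P04      0 0.234  0.138    0.1026        1043
```

NDVI rises with nitrogen rate, short-stalk-leaf abundance rises faster, and
yields (generated as 6500·(NDVI×Abd_SS-LF) + 1000 + noise in this synthetic
world) track the product. The four predictor families for NDVI:

```
    vi  family slope intercept    r2 rmse    cv
1 NDVI      VI  6068    -491.4 0.952  165  8.07
2 NDVI   VIxFL 25152     -32.3 0.809  331 16.13
3 NDVI VIxLEAF  5226     915.2 0.977  115  5.61
4 NDVI   VIxSS  6908     963.0 0.977  114  5.56
```

Multiplying by flower abundance *hurts* (R² 0.95 → 0.81), multiplying by
leaf-related abundance helps, and the short-stalk-leaf product is best —
the qualitative structure the method predicts. The cross-validated
shortlist:

```
         vi family  slope intercept     r2  rmse    cv  k
1      NDVI  VIxSS 6907.1     963.1 0.9773 127.1 6.198 24
2 CIrededge  VIxSS 7891.1     940.8 0.9772 127.7 6.230 24
3       TVI  VIxSS  165.3    1047.4 0.9758 131.9 6.431 24
4      SAVI  VIxSS 8089.5     973.0 0.9773 127.6 6.221 24
```

Averaged LOOCV slope/intercept (6907, 963) recover the generating model
(6500, 1000) up to the abundance shrinkage introduced by unmixing noisy
pixels; RMSE ≈ 127 kg/ha and CV ≈ 6.2 % on yields spanning ≈ 1000–3600
kg/ha.

`runPipeline(config = sceneConfig(seed = 1), outDir = "out")` runs the same
chain end to end and writes `refl.bsq/.hdr`, `abund.bsq/.hdr`,
`plot_table.csv`, `fits.csv`, `loocv.csv` and a reproducibility manifest. A
thin command-line wrapper with per-stage subcommands lives at
`inst/scripts/rapemix.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline's headline quantities from scratch: it synthesizes
the default scene at the given seed, runs calibration, unmixing, aggregation
and cross-validated yield regression through the installed package, logs the
run summary, and writes the JSON target report to `--out`.
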