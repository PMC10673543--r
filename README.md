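# acidocest

Ratiometric CEST-MRI tumor pH imaging, with a digital-phantom validation
loop and the cohort statistics of a preclinical treatment-efficacy study.

## The problem

Solid tumors acidify their extracellular space (pHe ~6.5–6.8 versus ~7.4
in normal tissue), and drugs that inhibit proton transporters are expected
to raise tumor pHe. CEST (chemical exchange saturation transfer) MRI can
measure pHe in vivo: after injecting iopamidol, a contrast agent with two
pH-sensitive amide resonances, the saturation-transfer effect `ST = 1 −
S(offset)/S0` is measured at 4.2 and 5.5 ppm from water, the pre-contrast
contribution is subtracted to remove the endogenous background, and the
ratio of the two contrast differences,

    R(pH) = ΔST(4.2 ppm) / ΔST(5.5 ppm),

cancels the unknown agent concentration to first order and is inverted
through a monotone calibration curve into a pixel-wise pHe map. Per-tumor
summaries are the mean pHe and an acidity score (mean of a 1–3 per-voxel
acidosis class; 3 = most acidic).

This package is for imaging scientists who want to build, stress-test, or
teach that pipeline end to end without scanner data. It implements:

- an N-pool **Bloch–McConnell simulator** for CW saturation (exact
  matrix-exponential propagation; no steady-state approximation);
- the **ratiometric calibration** between the ΔST ratio and pH, built from
  the same forward physics and measurement operator as the data;
- a **digital phantom generator**: mouse-tumor cohorts with known
  ground-truth pH fields, endogenous background CEST, B0 inhomogeneity and
  Rician noise, written as NIfTI + JSON sidecars;
- the **Z-spectrum processing pipeline**: cubic smoothing splines,
  per-voxel B0 correction, ST / ΔST maps, reliability masking, ratio
  inversion, pHe and acidity maps;
- the **cohort statistics** of a two-arm study: caliper tumor volume
  (`V = A·B²/2`), pooled Student t-tests recomputable from printed
  `mean ± SD` and n, one-/two-way ANOVA with Bonferroni correction,
  Shapiro–Wilk checks, and Kaplan–Meier survival with the log-rank test.

Because published calibration constants are not available, the package
*self-calibrates*: the same forward model generates both the phantoms and
the calibration curve, so pH recovery is a closed, testable loop. See
`vignettes/tumor-ph-imaging.Rmd` for the model, defaults, and what that
loop does and does not demonstrate about real scans.

## Worked example

The `analysis/` scripts run a complete in-silico study — simulate a
6 + 6 cohort (treated arm: +0.12 pH, slower growth), process every animal,
and test the readouts:

```sh
Rscript analysis/01_simulate.R     # phantoms + cohort table -> results/sim/
Rscript analysis/02_process.R     # pHe + acidity maps       -> results/proc/
Rscript analysis/03_stats.R       # group statistics         -> results/stats/
```

Step 2 prints one line per animal, e.g.

```
  m02: pHe 6.779 (truth 6.770), score 2.08 (truth 2.12), coverage 0.92 [0.2s]
  ...
Done: 12 animals; mean |pHe error| 0.014; summary at results/proc/summary.tsv
```

— recovered mean pHe against the generator's truth, the acidity score, and
the fraction of tumor voxels with a defined pH. Step 3 then reproduces the
published summary comparisons from their printed statistics and tests the
simulated arms:

```
  tumor_weight_g t =  5.88 (df 10), p = 1.55e-04  [p < 0.001]
  pHe_week1      t =  4.76 (df 10), p = 7.74e-04  [p < 0.001]
  pHe_week2      t =  5.20 (df 10), p = 4.04e-04  [p < 0.001]
  mean_pHe       control 6.771 +- 0.017, treated 6.883 +- 0.021, t = -10.19, p = 1.33e-06
  acidity_score  control 2.130 +- 0.076, treated 1.635 +- 0.092, t = 10.15, p = 1.38e-06
  survival log-rank p = 0.0006112
```

The pooled t for the tumor-weight comparison (1.16 ± 0.15 g vs
0.74 ± 0.09 g, n = 6/group) is 5.88 on 10 df — the printed `p < 0.001`
claims are exactly recomputable from the printed summaries alone.

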