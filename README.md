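# penumbra

Analysis of myelin-sensitive susceptibility metrics around white-matter
lesions in cerebral small vessel disease.

## The problem

In small vessel disease (including its monogenic form, CADASIL), macroscopic
white-matter hyperintensities (WMH) are surrounded by a *penumbra* of
normal-appearing white matter (NAWM) whose microstructure is already
degraded. χ separation decomposes the MR susceptibility signal into a
diamagnetic component (χ⁻, myelin-sensitive; a lower |χ⁻| means less myelin)
and a paramagnetic component (χ⁺, iron-sensitive), giving a myelin readout
that diffusion metrics (MD, RD, free water) lack. The analytical questions
this package answers, given co-registered metric maps and lesion masks:

1. How far beyond the WMH border does the myelin deficit extend, in 2-mm
   distance rings?
2. Is the χ⁻ deficit separable from iron and diffusion changes?
3. Does it explain cognitive slowing over and above the other metrics?

## What the package computes

- **Mask geometry** — WM masks from probability maps (`prob > 0.5`, 1-mm ball
  erosion), NAWM = WM − WMH − lacunes, penumbra rings from an exact
  anisotropic Euclidean distance transform binned `(2(k−1), 2k]` mm, and
  voxelwise lesion-frequency maps in percent.
- **Spatially matched difference scores** — per subject and ROI,
  `diff = mean(subject map over ROI) − mean(control-mean map over the same
  ROI)`, so that anatomy is held fixed; covariate adjustment keeps the
  group-mean prediction and individual residuals:
  `adjusted_i = ŷ(x̄) + ε_i − ȳ_CN,i`.
- **Inference** — one-sample t tests with Cohen's `d = t/√n` and
  normal-approximation CIs; Welch/pooled two-sample tests; Pearson
  correlations; Benjamini–Hochberg FDR with cluster extent thresholding for
  voxelwise maps; ridge regression `β̂ = (X′X + λI)⁻¹X′y` with effective
  residual degrees of freedom `edf = n − tr(2H − HH′)`,
  `H = X(X′X + λI)⁻¹X′`, t-distribution p-values at `edf`, partial
  `R² = t²/(t² + edf)`, and GCV-selected λ.
- **Cognition** — a processing-speed compound from Trail-Making-Test A/B
  times: age-by-education stratification against a normative table, Box–Cox
  power transform, negation (higher = faster), z-scaling to controls.
- **Synthetic cohorts** — a seeded generator planting lesion effects that
  decay exponentially with distance from the WMH boundary, with
  group-dependent lesion burden, subject random intercepts, and a cognition
  outcome coupled to the planted myelin deficit; every pipeline stage is
  testable without patient data.

## Worked example

```r
library(penumbra)
cohort <- simulate_cohort(simulation_config(seed = 1))   # 60 cases, 20 controls
res <- analyze_cohort(cohort, voxelwise = FALSE)
subset(res$penumbra_table, metric == "chi_neg",
       select = c(roi, t, df, p, d))
```

```
    roi       t df        p       d
  wmh   -15.74  59 8.7e-23  -2.03
  nawm   -0.81  59 0.42     -0.11
  ring1  -6.73  59 7.9e-09  -0.87
  ring2  -3.92  59 2.4e-04  -0.51
  ring3  -1.44  59 0.16     -0.19
  ring4  -0.28  59 0.78     -0.04
  ring5   0.32  59 0.75      0.04
```

The planted WMH myelin deficit (population effect size −2.5; this seed
recovers −2.03, within the sampling error of a d estimate at n = 60) decays
through the penumbra: significantly reduced |χ⁻| in the first two or three
rings (up to ~6 mm from the lesion border) and nothing beyond — the spatial
gradient the pipeline is designed to detect. The ridge model for the WMH ROI
(`res$ridge_models`) recovers the planted positive myelin–cognition
coupling:

```
 predictor  estimate_scaled      t    df        p  partial_r2
 chi_neg             0.466   6.28  51.3  7.4e-08       0.43
 chi_pos             0.025   0.33  51.3  0.74         <0.01
 ...
```

i.e. a lower myelin difference score predicts lower processing speed,
controlled for iron, diffusion, lesion volume and demographics, with
p-values from a t distribution with `edf = 51.3` effective degrees of
freedom.

## Command line

```sh
Rscript inst/cli/penumbra simulate --seed=7 --out=cohort_dir
Rscript inst/cli/penumbra all --in=cohort_dir --out=results_dir
```

Subcommands: `simulate`, `masks`, `diffscores`, `penumbra`, `correlate`,
`ridge`, `voxelwise`, `report`, `all`. A JSON config (`--config=...`) can
override any `simulation_config()` field.

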