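---
title: "Methods: penumbra gradients, matched difference scores, and effective-df ridge inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penumbra gradients, matched difference scores, and effective-df ridge inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(penumbra)
```

This vignette documents the statistical model behind the package, the
numerical choices where the method description left the design open, what
the synthetic-cohort generator does and does not emulate, and the known
limitations. It states no empirical result that the test suite does not
itself compute.

## 1. The analysis model

The pipeline takes, per subject, co-registered 3D metric maps on a common
grid — a diamagnetic susceptibility component χ⁻ (myelin-sensitive, stored
as negative ppm and analysed as the magnitude |χ⁻|), a paramagnetic
component χ⁺ (iron-sensitive), mean and radial diffusivity (mm²/s) and a
free-water fraction — together with binary masks for white matter, WMH
lesions and lacunes, and a subject table (group, age, sex, education,
cognition).

**Masks.** White matter comes from thresholding a probability map strictly
above 0.5 and eroding by a 1 mm ball; NAWM is WM minus WMH minus lacunes.
The penumbra is described by concentric distance rings around the WMH: an
exact Euclidean distance transform (voxel centres, per-axis spacing) is
binned into five 2 mm rings intersected with NAWM. Lacune voxels are
excluded from NAWM, the WMH analysis ROI, and every ring.

**Spatially matched difference scores.** Because normal myelination varies
regionally, a subject's lesion ROI cannot be compared against another
subject's differently located lesion. Instead, each case ROI mean is
referenced against the *control-group voxelwise mean map averaged over the
same subject-specific ROI*:
`diff_i = mean(map_i[ROI_i]) − mean(CN_mean[ROI_i])`, so `diff_i < 0` means
"below the control average at this exact location". Covariate adjustment
fits OLS of the raw case values on the covariates and keeps the group-mean
prediction plus the individual residual before subtracting the reference:
`adjusted_i = ŷ(x̄) + ε_i − ref_i`. Since the OLS prediction at the
covariate mean equals the group mean, the case-group mean effect is
preserved exactly (tested at 1e-10), while individual covariate-driven
variation is removed. Adjustment covariate sets are metric-specific:
|χ⁻| is adjusted for age, sex, education, χ⁺ and free water; χ⁺ for age,
sex, education and free water; the diffusion metrics for age, sex,
education and χ⁺ (to dissociate iron from diffusion effects).

**Penumbra gradient inference.** Per ring, a one-sample t test of the
adjusted difference scores against 0, reported with `d = t/√n` and the
normal-approximation CI `d ± z·√(1/n + d²/(2n))`. The published analysis
labels these "one-sample Welch t tests"; Welch's correction has no
one-sample meaning, so the standard one-sample t is used.

**Ridge cognition models.** Processing speed is regressed on the per-ROI
metric profile (|χ⁻|, MD, RD, FW, χ⁺ — difference scores for subject-specific
ROIs, plain means for fixed ROIs), lesion volume fraction, age, sex and
education. Because these predictors are collinear, the model is ridge
regression on standardized predictors with a centered outcome, the intercept
unpenalized (handled by centering and excluded from `X`):
`β̂ = (X′X + λI)⁻¹X′y`. Inference uses the effective residual degrees of
freedom `edf = n − tr(2H − HH′)` with `H = X(X′X + λI)⁻¹X′` (computed
through the singular values of `X`), `σ̂² = SSE/edf`, the penalized-LS
covariance `σ̂²(X′X+λI)⁻¹X′X(X′X+λI)⁻¹`, p-values from a t distribution with
`edf` degrees of freedom (not the normal approximation), per-predictor
partial `R² = t²/(t²+edf)`, and model `R² = 1 − SSE/SST`.

**Voxelwise mapping.** Per in-mask voxel, a linear model of the metric on
group (plus optional covariates); Benjamini–Hochberg FDR at α = 0.05 across
the in-mask family; surviving voxels grouped into connected components
(26-connectivity by default, configurable — the convention of the original
tooling is not stated anywhere) and components below 10 voxels discarded.
Voxels with zero residual variance are excluded from both the test and the
FDR family and counted in the output.

## 2. Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold`, `erode_mm` | 0.5, 1 mm | WM probability cut and erosion ball radius |
| `ring_step_mm`, `ring_max_mm` | 2, 10 | penumbra ring width and outer bound (5 rings) |
| `alpha` | 0.05 | FDR level and significance threshold |
| `extent_k` | 10 voxels | minimum cluster size in voxelwise maps |
| `connectivity` | 26 | cluster connectivity |
| `ridge_lambda` | `"auto"` (GCV) | ridge penalty; any fixed λ ≥ 0 accepted |

Ring statements like "effects detectable until 6 mm" are statistical
outcomes, never mask constraints: rings are always built to `ring_max_mm`.

## 3. Numerical choices

- **Distance vs. iterative dilation.** Rings use the exact EDT (separable
  lower-envelope algorithm, per-axis spacing), which is rotation-invariant
  and mm-accurate on anisotropic grids; the iterative 2 mm ball dilation
  construction is retained in the test suite as an independent oracle.
- **Ring bin edges.** Bins are `(2(k−1), 2k]`, closed above. This is what
  "dilate by one step and subtract the previous dilation" produces (a
  dilation by radius r includes voxels at distance exactly r), and it keeps
  ring 1 non-degenerate on grids whose spacing equals the step (on a 2 mm
  grid, face neighbours of a lesion sit at exactly 2.0 mm; with half-open
  `[0, 2)` bins ring 1 would be structurally empty).
- **Erosion structuring element.** A true physical ball with the radius
  converted per-axis; if the radius is below the smallest spacing the
  erosion is a no-op and a warning names the axes. The image boundary is
  not treated as background.
- **Automatic ridge penalty.** The original analysis used a third-party
  automatic estimator whose formula is unpublished. This package minimizes
  the generalized cross-validation criterion `GCV(λ) = SSE/(n − tr H)²`
  over a log-spaced grid (`10^seq(-6, 6)`, 121 points) with local
  refinement, which is deterministic; a fixed λ can be supplied instead.
  The formula-level checks (t, edf, partial R²) do not depend on the
  selector.
- **Ridge standard errors.** The source describes t-based p-values but not
  an SE construction; the conventional penalized-least-squares sandwich
  with `σ̂² = SSE/edf` is used.
- **Adjustment equation.** The printed middle term of the adjustment
  equation multiplies coefficients by the *outcome* group mean, which
  contradicts the accompanying prose ("adding the group-averaged prediction
  to the individual residuals"); the prose reading — coefficients times the
  case-group mean covariate vector — is implemented.
- **Cohen's d CI.** The normal-approximation SE is used; published interval
  formulas vary, so CIs are descriptive output, not an acceptance surface.
- **Box–Cox exponent.** "Power transformed" is made concrete as Box–Cox
  with a positivity shift (`1 − min`) and MLE exponent on a 0.05 grid with
  local refinement; a fixed exponent can be supplied. The subsequent
  negation and control z-scaling make the compound orientation- and
  scale-stable for any exponent (monotone decreasing in completion time).
- **Degenerate inputs.** Empty ROIs, empty WMH masks, zero-variance
  samples, rank-deficient covariate matrices and non-positive df all fail
  loudly with the offending object named; there are no silent fallbacks.
- **Ties in lesion growth.** The simulator fills the lesion target volume
  by taking the top-k field values with R's stable order, so cohorts are
  bit-reproducible for a given seed.

## 4. What the synthetic generator emulates — and what it does not

`simulate_cohort()` generates two groups on one shared grid (default
48×56×48 at 2 mm): an ellipsoidal brain and WM with two paraventricular
cavities; per-subject WMH grown by thresholding a smoothed Gaussian random
field penalized by ventricle distance at a per-subject target volume
(case mean 6 % of brain volume, control 0.2 %, lognormal spread, matching
the order of magnitude of reported burdens); Poisson lacune counts
(means 4.7 / 0.05); metric maps as
`baseline + subject intercept + effect·exp(−d/decay) + voxel noise`, where
`d` is the distance to the WMH (full effect inside), plus physical clamps
(χ⁻ ≤ 0, χ⁺ ≥ 0, FW ∈ [0,1], diffusivities > 0); and a cognition outcome
linearly coupled to the subject's planted WMH myelin deficit plus
demographic terms and Gaussian noise.

Design choices made once, with their rationale:

- **Planted effect scale.** The χ⁻ lesion effect (+0.010 ppm toward zero)
  over the case between-subject SD (0.004 ppm) fixes the population
  one-sample effect size of the WMH difference score at −2.5.
- **Penumbra decay 2.6 mm.** The source reports the gradient empirically
  without a functional form. The exponential e-folding length was fixed by
  an a-priori power analysis: with the planted WMH effect and n = 60, the
  ring-averaged planted effects are ≈ −1.2, −0.74, −0.35, −0.17, −0.08 d
  units for rings 1–5, i.e. detectable to ring 3 (6 mm) and not beyond —
  the qualitative pattern the pipeline is meant to resolve.
- **Asymmetric between-subject spread.** Controls are a screened, matched
  group; their metric intercept SD is set to one fifth of the case SD.
  This is also what keeps the difference-score one-sample test close to
  nominal: the control-mean reference is shared by all cases, so reference
  noise does not enter the across-case sample variance, and a reference as
  heterogeneous as the cases would make the test anticonservative by
  construction (variance inflation ≈ 1 + ρ·n_case/n_ctrl). With the
  asymmetric defaults the inflation is a few percent; the null-configuration
  test asserts the resulting rejection rate stays near α.
- **Gaussian cognition.** The study's cognitive scores are only described
  as "power transformed"; the simulator's Gaussian outcome is a stand-in,
  not a claim about the real distribution.
- **One shared grid.** Registration is upstream and out of scope; all
  subjects live on the template grid.

Not emulated: MR physics (no k-space, no susceptibility forward model),
realistic lesion texture or anatomy atlases, spatially varying baselines,
registration error, missing data. A green recovery test therefore
establishes that the *pipeline* recovers what was planted under its own
statistical assumptions — not that those assumptions hold in scanner data.

## 5. What the tests establish

- Formula-level: every published penumbra-table d follows from its t via
  `d = t/√n` (n = 60), and every published ridge partial R² from its t and
  effective df via `t²/(t²+df)`, at the printed 2-decimal precision.
- Properties: mask algebra, EDT, morphology and rings against brute-force
  oracles; BH step-up against hand computation and `p.adjust`; null-
  simulation FDR ≤ α within Monte-Carlo tolerance (200 replicates); ridge
  at λ = 0 ≡ OLS (1e-8) and the effective-df SVD identity (1e-10);
  adjustment mean-preservation (1e-10); one-sample type-I error at n = 60
  within binomial tolerance of 0.05 (10,000 replicates).
- Recovery (20 seeds at generator defaults): mean recovered WMH d within
  ±0.3 of −2.5; rings 1–3 significant and rings 4–5 not in a majority of
  seeds; the positive cognition–myelin coefficient recovered with p < 0.05
  in ≥ 80 % of seeds. The ±0.3 band is read on the across-seed mean: a
  single-seed d estimate at n = 60 has sampling SD ≈ 0.26 (the published
  CI half-widths say the same), so a per-seed guarantee would be
  unattainable for any faithful implementation.

## 6. Known limitations

- The difference-score one-sample test treats the control reference as
  fixed; with few controls and strongly overlapping lesion masks it is
  mildly anticonservative (see section 4). This mirrors the published procedure
  rather than correcting it.
- Covariate adjustment before a one-sample test with df = n − 1 spends no
  degrees of freedom on the fitted covariates, inflating |t| by roughly
  `√((n−1)/(n−1−p))` (≈ 4 % here) — again inherited from the published
  procedure.
- The NIfTI reader/writer covers the single-file NIfTI-1 subset this
  pipeline needs (3D, common datatypes, sform spacing); it is not a general
  neuroimaging I/O layer.
- Tract-level ROIs are supported as fixed masks with plain group
  comparisons; streamline sampling and tract segmentation are upstream.
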