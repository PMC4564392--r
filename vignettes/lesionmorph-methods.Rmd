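---
title: "Lesion-aware grey-matter morphometry: models, parameters and design notes"
author: "lesionmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-aware grey-matter morphometry: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In cerebral small-vessel disease (SVD), white-matter hyperintensities (WMH)
and lacunar infarcts (LI) have intensity profiles that confuse standard
tissue segmentation: WMH sits between grey matter (GM) and white matter
(WM) on T1-weighted images and is absorbed into the GM class, while the
gliotic cores of lacunes look like CSF. Those misclassifications propagate
into every downstream morphometric measure — cortical thickness, Jacobian-
modulated GM volume, and the deformations used to build group templates.
`lesionmorph` implements a lesion-aware analysis chain: two-channel
(T1 + FLAIR) tissue segmentation with population priors, an explicit tissue
*repair* step that reassigns lesion probability mass to its anatomically
correct class, diffeomorphic group-template construction with Jacobian
modulation, voxel-based cortical thickness (VBCT), voxel-wise regression
with random-field-theory (RFT) family-wise error (FWE) control, and
Gaussian-process regression (GPR) that predicts lesion load from grey-matter
maps. A synthetic brain-phantom generator with exact ground truth drives
all testing.

## The phantom generator

`phantom_spec()` describes a WM core (ball or slab) wrapped in a GM shell
of known cortical thickness inside CSF/background; `lesion_spec()` implants
spherical WMH and LI into the WM (LI with a CSF-like gliotic core holding a
configurable volume fraction); `intensity_model()` renders T1/FLAIR
intensities from per-class bivariate Gaussians; `cohort_spec()` +
`make_cohort()` generate cohorts in which the GM shell thins linearly with
WMH load.

Key defaults and the reasoning behind them:

* **Intensity means** (arbitrary units, `(T1, FLAIR)`): CSF (25, 20),
  GM (60, 60), WM (90, 50), WMH (70, 95), gliosis (32, 45); common
  within-class s.d. 5. No quantitative lesion intensity statistics exist
  for the motivating cohort, so these are free parameters chosen once to
  reproduce the qualitative contrast pattern that matters: WMH lies
  *between* GM and WM on T1 (closer to GM, so a T1-only segmentation
  absorbs it into GM) and is the brightest class on FLAIR; gliosis is
  CSF-like on T1.
* **Cohort association**: target WMH volume drawn uniformly on
  0–40,000 mm^3; GM thickness = base − 0.5 mm per 10,000 mm^3 of load
  (both configurable). The default phantom uses a 48^3 grid of 2 mm
  voxels with a 30 mm WM radius so that a 40,000 mm^3 load fits inside
  the WM compartment. Recorded `wmhv_mm3` always equals the realised
  truth-mask volume to the voxel.
* **Subject variability**: each subject receives a random smooth
  stationary-velocity warp (RMS amplitude 1.5 mm, ~6-voxel FWHM
  smoothness, edge-tapered), exponentiated by the registration module so
  that every subject deformation is a guaranteed diffeomorphism.
* **Sex** is coded 0/1, age in years.

What the phantoms deliberately do **not** emulate: MR physics (no
sequences, k-space or partial-volume model), skull/dura, microbleeds,
realistic cortical folding, or a separate CSF compartment — the CSF class
doubles as background, as in the label alphabet {0: background/CSF, 1: GM,
2: WM}. Two consequences are worth knowing: total intracranial volume is
constant across phantom subjects (the pipeline therefore drops constant
covariates from design matrices automatically, with a message), and
skull-stripping is trivially satisfied on phantoms. Passing tests on
phantoms therefore demonstrates the *algorithms* are correct at realistic
contrast and noise, not that the pipeline handles scanner artefacts,
bias-field extremes or complex gyral geometry.

## Segmentation

`fit_mixture()` is an expectation–maximisation fit of a multivariate
(typically two-channel) mixture of Gaussians over in-mask voxels. When a
set of prior tissue probability maps is supplied, the per-voxel prior
probabilities replace the global mixing weights in the E-step
(responsibilities `γ_vk ∝ π_vk N(x_v; μ_k, Σ_k)`), which is how
population-specific priors steer the per-subject re-segmentation. Details:

* initialisation by k-means on a ≤20,000-voxel subsample (seeded);
  classes are ordered by first-channel mean for reproducibility;
* covariance ridge `1e-6 · mean channel variance` guards degenerate
  classes;
* the log-likelihood is asserted non-decreasing at every iteration and
  convergence is declared at a relative change below `1e-6` (cap 200
  iterations).

The exact "modified" mixture algorithm cited by the motivating work is not
published in it; prior-weighted EM with these safeguards is this package's
documented interpretation. The WMH prior used in the pipeline's second
pass is a fixed fraction (0.25) of the WM prior — lesions live in white
matter and no lesion atlas exists for phantoms.

The per-subject WMH map is binarised at 0.5 by default (the motivating
analysis chose thresholds manually per subject; 0.5 is the neutral
default, overridable in `pipeline_config()`). Lacune masks can be grown
from seed points with `grow_lacune()` (6-connected, one accepted dilation
layer per iteration, default cap 500 iterations, intensity window supplied
by the user — on scanner-unit T1 images the field-standard window is
350–500).

## Tissue repair

Three deterministic, mass-conserving rules:

* `repair_wmh()`: inside the WMH mask, *all* GM probability joins WM
  (`wm' = wm + gm`, `gm' = 0`). The motivating description does not
  quantify the correction; the full-mass transfer is this package's
  documented choice and is what the acceptance property (every WMH voxel
  argmax-WM after repair) requires.
* `consensus_li_classes()`: each group-space voxel covered by any
  subject's LI mask is labelled by the tissue class that is the argmax of
  the most subjects' (lesion-free) posteriors; ties break WM > GM > CSF
  (lacunar damage lives in WM). A posterior-weighted vote was considered
  and rejected: the argmax vote is what "most likely tissue class over
  the subjects" states most directly, and it is robust to one subject's
  extreme posterior.
* `repair_li()`: within the subject's LI mask the full three-class mass
  moves to the consensus class; voxels with no consensus (label 0) fall
  back to the subject's own argmax and are counted.

Every rule leaves voxels outside the lesion masks bit-identical and
conserves the per-voxel tissue mass to 1e-6 — both are asserted in tests.
`compute_volumes()` reports WMHV/LIV as mask voxel counts × voxel volume
and TIV as the volume where GM+WM+CSF ≥ 0.2 (inclusive).
`reliability_metrics()` implements mean pairwise variability
(`|a−b|/mean × 100`), SEM (`sd(a−b)/√2`, or from a repeats matrix) and the
two-way absolute-agreement ICC(A,1).

## Registration and modulation

The group machinery uses a stationary-velocity diffeomorphic model — the
largest methodological substitution in the package relative to geodesic
shooting, chosen because it preserves every property the analysis consumes
(diffeomorphic warps, exact inverses via the negated field, positive
Jacobians, modulation) at a fraction of the complexity.

* `exp_velocity()` exponentiates by scaling-and-squaring. Compositions
  use cubic B-spline interpolation of the displacement components and the
  first step is bounded by 1/16 voxel; with the default cohort warps this
  keeps `exp(v) ∘ exp(−v)` within 0.1 voxel of the identity. (Trilinear
  composition plateaus near 0.2 voxel regardless of the number of
  squarings — the interpolation error, not the step size, is then the
  bottleneck.) Registration line searches use a cheap trilinear variant;
  all user-facing warps use the accurate one.
* `register_pair()` minimises multi-class SSD plus smoothing of the
  velocity updates (default 8-voxel FWHM) over a 3-level pyramid with
  backtracking step control; the objective trace per level is
  non-increasing by construction.
* `build_template()` iterates register-to-template / average / recentre
  (velocities to zero mean), starting from the voxel-wise average.
* `jacobian_det()` uses central differences (one-sided at the boundary);
  `modulate()` multiplies warped GM by it, conserving total GM volume to
  within 2% on phantom warps; `warped_weighted_smooth()` implements the
  ratio smoothing `smooth(w·t)/smooth(w)` with support threshold 1e-3.

Gaussian smoothing everywhere uses a truncated kernel renormalised at the
field-of-view edge (no mass leaks out of the grid), with σ = FWHM/2.355
per axis in mm.

## Voxel-based cortical thickness

`vbct()` composes three stages on the repaired segmentations, governed by
the standard parameter set (`sampling_resolution_mm = 0.5`,
`csf_smoothness_mm = 3`, `csf_thinness = 0.65`, `n_dilations = 1`,
`max_thickness_mm = 10`):

1. `extract_boundaries()` resamples the maps to the sampling grid,
   hard-labels voxels by argmax — after smoothing the CSF map by
   `csf_smoothness_mm` and forcing voxels whose smoothed CSF probability
   reaches `csf_thinness` to CSF, which reconstructs thin, partial-volumed
   sulcal CSF. The *core* GM set (argmax GM) is where thickness is
   measured; the Laplace domain is the core dilated `n_dilations` times,
   and the Dirichlet shells are the argmax-WM/CSF voxels adjacent to that
   domain. The original toolbox's parameter semantics are not published;
   these definitions are this package's, with the names kept.
2. `solve_laplace()` relaxes ψ (0 on the WM shell, 1 on the CSF shell) by
   SOR (ω = 1.9) until the largest update is below 1e-5 (error after 10^4
   sweeps); faces to voxels outside the domain are insulated.
3. `streamline_thickness()` traces RK4 streamlines along ±∇ψ/|∇ψ| (step =
   sampling/5) from every core voxel centre; each branch stops where the
   *interpolated core-GM indicator* crosses 0.5 — exactly the half-voxel
   tissue interface — with the crossing linearly interpolated. Thickness
   is the sum of both arc lengths, capped at `max_thickness_mm`.
   Vanishing-gradient voxels inherit the nearest valid neighbour and are
   counted. Dilation therefore stabilises the potential near the
   interfaces without inflating the measured thickness.

On a 4 mm flat slab the measured mean thickness is exact to well under
0.2 mm; on a 3 mm spherical shell it is within 7%. The discrete potential
matches the 1-D slab solution pointwise to 1e-3. For the spherical shell
the comparison uses the effective (mean) radii of the voxelised Dirichlet
shells and the *mean* absolute deviation (< 1e-2): the jagged voxel
boundary injects angular harmonics of amplitude ~h/2 relative to the
nominal sphere which do not vanish with finer sampling, so pointwise
agreement at 1e-2 is not attainable for any solver on this
discretisation — the mean deviation is the scale at which the solution can
be checked.

## Voxel-wise statistics

`fit_glm()` is voxel-wise OLS (one image per subject) with mean-centred
covariates (constant covariates are dropped with a message — see the TIV
note above); `t_contrast()` forms `t = c'β̂ / √(σ̂² c'(X'X)⁻¹c)`.
`estimate_smoothness()` estimates per-axis FWHM from one-sided spatial
differences of the normalised residual fields and converts the analysis
mask into resel counts via its point/edge/face/cube decomposition.
`rft_peak_fwe()` evaluates the expected Euler characteristic of the
t-field excursion above each voxel's value (EC densities of orders 0–3).
Two numerical guards matter: the EC sum is negative at low thresholds (the
order-3 density changes sign), so the corrected p is floored by the
uncorrected p — also giving the Bonferroni-like dominance property — and
the critical-threshold search runs on the decreasing tail of the EC curve.
`permutation_maxT()` provides the assumption-light cross-check
(Freedman–Lane residual permutation, max-statistic FWE).

RFT peak inference is known to be conservative at low degrees of freedom
and low smoothness. The calibration experiments therefore use 40 subjects
and 6-voxel-FWHM fields, where the empirical family-wise false-positive
rate sits near the nominal 0.05 and RFT and permutation thresholds agree
within 15%; at 12 subjects and 3-voxel smoothness the same code is
measurably conservative (rate ≈ 0.02) — that is a property of the method,
not a defect of the implementation.

## Gaussian-process prediction of lesion load

`build_linear_kernel()` forms `K = FF'/D` over the in-mask voxels of the
smoothed modulated GM (or warped-weighted thickness) maps, features
mean-centred across subjects; the centred features are retained so the
voxel-wise weight map `w = F'α/D` can be reconstructed (`θ_s·w` is the
effective primal predictor; the dual–primal identity is asserted to 1e-6).
`residualise_confounds()` applies `K' = RKR` with the residual-forming
projector of [intercept | confounds]; confound correction acts on the
kernel, not the targets, whose mean is an explicit offset.

`gpr_fit()` maximises the log marginal likelihood of
`Σ = θ_s K + θ_n I`. Because θ_s enters as a scale it is profiled out in
closed form on the eigenbasis of K, leaving a 1-D search over the
noise-to-signal ratio on a log grid — equivalent to, and far cheaper
than, a 2-D gradient ascent, and free of multi-start failures.
`loo_cv()` refits the confound projector, kernel eigenstructure and
hyperparameters inside every fold (no leakage; the held-out subject's
cross-covariance row is residualised using training-fold statistics only).
`permutation_significance()` permutes targets and reruns the entire LOO
analysis, re-using the per-fold eigendecompositions, which is what makes
1000 repetitions tractable.

A known behaviour worth stating: when the target is genuinely unrelated
to the kernel, the marginal likelihood correctly drives θ_s → 0, LOO
predictions collapse to the leave-one-out fold means, and the Pearson
correlation approaches −1 (the classic cross-validation negative-bias
artifact). The permutation test remains exact — it ranks the observed r
against the same statistic under permutation — but a strongly *negative*
LOO r should be read as "no signal", not as anti-prediction.

## Problem sizes used by the test-suite

All tests generate their data programmatically. The heavier experiments
run at sizes chosen to exercise the full chain comfortably on one CPU:
thickness oracles on 24^3–44^3 1 mm grids at the standard 0.5 mm sampling;
detection cohorts of 20 subjects on the default 48^3 (2 mm) phantom with
1 mm VBCT sampling; prediction cohorts of 60 subjects; FWE calibration
over 50 null cohorts of 40 subjects on 32^3 grids; permutation-uniformity
studies with 99 permutations × 200 runs. Cohort-level acceptance
experiments run the repair → VBCT → statistics chain on the deterministic
"corrupted-truth" segmentation mode (the exact misclassification pattern
the repair step addresses) with subjects analysed on their common grid:
EM segmentation and diffeomorphic registration are validated by their own
oracle experiments and run end-to-end in the pipeline smoke test.

## Known limitations

* No bias-field estimation (the phantom default amplitude is low); no
  DICOM import or inter-modality co-registration — phantoms are generated
  aligned, and an affine initialiser for real data is out of scope.
* Geodesic-shooting numerics are not reproduced; the stationary-velocity
  substitute preserves the analysis-relevant properties only.
* Cluster-extent inference, TFCE and anatomical labelling are not
  implemented (peak-level FWE only).
* The GP uses a linear kernel with an offset mean; alternative covariance
  functions and multi-kernel extensions are out of scope.
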