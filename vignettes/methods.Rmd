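---
title: "Methods: metrics, parametric change imaging, and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metrics, parametric change imaging, and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions they rest on, the parameters that matter,
and the choices made where the methods literature leaves the design
open.

## The problem

Serial FDG-PET quantifies the metabolic response of metastatic breast
cancer to therapy where morphological criteria struggle (bone lesions
in particular). Two analysis routes coexist: per-lesion *metric
changes* (how much did SUVmax, SUVpeak, SUVmean, MV, TLG, SAM drop
between scans?) thresholded into responder/non-responder calls, and
*parametric imaging*, which compares the registered scans voxel by
voxel and summarizes each lesion's evolution from a factor model. The
package implements both and evaluates them against a gold-standard
label with ROC/Youden machinery.

## Units and conventions

All images are dimensionless body-weight SUV
(`concentration [kBq/mL] × weight [kg] / injected activity [MBq]`);
lean-body-mass SUL is deliberately not implemented, matching the
body-weight normalization convention of the metrics being emulated.
Injected activity is assumed decay-corrected to scan start — phantom
data are generated directly in SUV, so no decay model is needed. Voxel
indices are 0-based; the physical position of voxel `(i,j,k)` is
`origin + (i,j,k)·spacing` (axis-aligned; no oblique affines). Volumes
are stored as float32 NIfTI-1 in RAS orientation.

## Segmentation

Lesions are delineated with a contrast-oriented adaptive threshold: in
a cubic working region of half-width `max_region` (default 20 mm)
around the seed,

```
T = coeff_a · mSUV70 + coeff_b · BG
```

where `mSUV70` is the mean of voxels at or above 70% of the regional
SUVmax (ties included: ≥, not >) and `BG` is the mean of a background
shell 10–20 mm outside the working region, excluding voxels above
`0.4·SUVmax` so a neighbouring lesion cannot inflate the background.
The mask is the 26-connected supra-threshold component containing the
seed. Defaults `coeff_a = 0.5`, `coeff_b = 1` are the generic
contrast-oriented form; scanner-specific coefficients are unknowable
without the original phantom calibration, so
`calibrate_coefficients()` reproduces that calibration on synthetic
sphere phantoms (grid search minimizing mean absolute relative volume
error).

Two failure modes are surfaced as typed conditions instead of being
papered over: *no focal uptake* (the 70%-isocontour mean does not
exceed background by `min_contrast`, default 0.5 SUV) and *empty mask*
(threshold above every voxel). No rescue heuristic is applied at the
segmentation level — adaptive thresholds are known to fail at poor
signal-to-noise, and silently guessing a contour would bias the
volume metrics.

## The six metrics

`suv_max` is the hottest masked voxel; `suv_mean`, `mv`, `tlg` follow
their definitions on the mask (`tlg = suv_mean × mv` holds exactly);
`suv_peak` is the maximum over mask-centred 1 cm³ spheres
(radius 6.204 mm, rasterized by voxel-centre inclusion — the
fixed-volume-sphere variant) of the in-sphere mean; `sam` integrates
the uptake excess over local background across the mask dilated by
8 mm (configurable). The dilation-based enlarged region is a stated
surrogate for the original CT-drawn two-contour construction, which
cannot be reproduced without CT. Note that for lesions smaller than
the peak sphere, `suv_peak` legitimately drops below `suv_mean`; the
usual `suv_mean ≤ suv_peak ≤ suv_max` ordering is asserted only for
lesions at or above the sphere scale.

## Registration

Serial scans are aligned with a rigid transform (3 rotations + 3
translations) estimated by iterated block matching: cubic blocks
(default 5³ voxels, stride 2) of the baseline scan with contrast above
1.5× the median block SD are displaced within a ±5-voxel search window
to maximize normalized cross-correlation, refined to sub-voxel
precision by parabolic interpolation of the score, and a rigid
transform is fitted to the displacement field with an iteratively
re-trimmed Kabsch solution (initial 20% quantile trim, then residuals
beyond 3× the median are dropped and the fit repeated). The estimate
is folded in, the moving scan resampled (trilinear), and the loop
repeats until the incremental motion of the volume corners falls
under 0.1 mm.

Robustness decisions worth knowing about:

* Matches with peak NCC below 0.5 are discarded — the maximum of
  pure-noise correlations over a full search window reaches ≈ 0.35, so
  weaker peaks carry no signal.
* If the surviving match field spans less than 30 mm, rotation is
  unidentifiable from it and a translation-only fit is used.
* If the final field is inconsistent with any rigid motion (median
  residual above 1.5× the mean voxel spacing), registration *fails*
  explicitly; the pipeline then proceeds unaligned with a warning.
  This happens, by construction, on pairs whose lesions resolved
  completely — there is nothing left to match, and a complete
  metabolic response is classified correctly even without alignment.

The original clinical procedure registers the CT channel and transfers
the transform to PET; the package registers whichever channel it is
given (phantoms have no CT, so the PET channel itself is used). Block
size, search radius, similarity measure and iteration counts are
package defaults, not values taken from any clinical protocol.

## Two-frame factor analysis and the parametric change image

With two frames, each voxel contributes a 2-vector
`S(v,·) = (S(v,1), S(v,2))`, modelled as
`Ib(v)·Cb + Ie(v)·Ce + e`. The background factor is fixed to the
constant vector `Cb = (1,1)` — so `Ib` carries the SUV of unchanged
voxels — and the evolution factor `Ce` has unit norm, which makes the
significance cut `|Ie| > 1` read as roughly one SUV of change. (The
normalization behind the published fixed cut is not stated anywhere;
this scale convention is the package's choice, and the threshold is a
parameter.)

Estimation alternates: (1) the *evolving set* is the voxels whose
residual under the constant factor alone — equivalently, whose frame
difference — exceeds `k_sigma` (default 4) times a robust MAD noise
scale estimated on the complement; (2) `Ce` is the dominant principal
direction (uncentred SVD) of the evolving voxels' two-frame profiles,
sign-fixed so the evolving set's summed `Ie` is non-negative. This is
an oblique rotation of the principal-component solution: `Ce` is not
forced orthogonal to `Cb`. Given the factors, `(Ib, Ie)` solve each
voxel's 2×2 system exactly, so reconstruction is exact wherever the
system is nonsingular, and the factor images equal independent
least-squares solutions by construction — a property the test suite
verifies against a naive oracle on hundreds of random models.

A pair with no real evolution must not hallucinate one. Three guards
flag a degenerate (all-stable) model with `Ie ≡ 0`: a rank-deficient
centred data matrix (second singular value below 10⁻³ of the first);
an evolving set no larger than twice its pure-noise expectation
(`2·Φ(−k)·N` voxels); and a sign-incoherent evolving set
(`|Σd|/Σ|d| < 0.15`, the signature of symmetric noise tails). Without
the latter two, the dominant direction fitted to noise voxels lies
nearly parallel to `Cb`, and the near-singular solve amplifies noise
far above any fixed cut.

Per lesion, the masked evolution image is summed over the lesion mask
(so large coherent changes dominate speckle — the aggregation rule for
heterogeneous lesions is a package decision; the published rule does
not define "main factor" when both signs occur within one lesion), and
the direction/sign rule is applied: responder iff the main factor
decreases and the lesion follows it, or increases and the lesion
opposes it. Lesions whose suprathreshold support covers under 5% of
the mask (noise speckle covers ≈ 1%) show no significant change and
are non-responders. A patient responds only if every lesion does.

## Response classification and evaluation

Percent change is `100·(m2 − m1)/m1` on the lesion level, and on the
patient level follows the hottest-lesion rule: the metric value of the
most intense target lesion *of each scan* (the two lesions may
differ), with targets capped at five per patient and two per organ,
ranked by baseline SUVmax. "Most intense" is judged by the metric
being evaluated (a flag switches to always-SUVmax ranking). A
responder is a decrease *strictly greater* than the threshold — a
decrease exactly at the threshold is a non-responder. New lesions do
not automatically trigger progression under the literal hottest-lesion
computation; a stricter flag is available.

ROC analysis sweeps cuts over midpoints of consecutive sorted unique
decrease values with sentinels past both ends; AUC uses the
Mann–Whitney rank formulation with midrank ties (identical to
trapezoidal integration of the empirical curve — asserted to 10⁻¹² in
the tests); the optimal threshold maximizes Youden's
`J = sens + spec − 1`, ties broken toward the smaller threshold
magnitude. Confusion ratios with zero denominators are undefined
(`NA`), never zero. The χ² association is Pearson's with 1 df and no
continuity correction (a flag enables Yates); a zero marginal leaves
the statistic undefined. Paired AUCs are compared with the DeLong test
(the method behind published AUC intercomparisons is typically
unstated; DeLong is the de-facto standard and is delegated to pROC),
and metrics are grouped by the transitive closure of non-significant
pairs.

## What the phantom generator emulates — and what it does not

`generate_pair()` builds each scan as a uniform liver-like background
(SUV 2) plus spherical lesions, convolved with an isotropic Gaussian
PSF (default FWHM 6 mm, typical clinical PET), plus additive Gaussian
noise in SUV units (default sigma 0.15 SUV). Partial-volume behaviour
arises from PSF and voxelization — precisely the effect SAM targets.
The follow-up scan's lesion spheres are displaced through the inverse
of a known rigid misalignment and rasterized analytically, so the
simulated scans carry no interpolation error and the misalignment is
exactly the transform registration should recover. The noise model is
additive Gaussian rather than Poisson-in-counts because every method
downstream operates on reconstructed SUV images; default grid 96³ at
2 mm keeps a cohort tractable on a laptop.

`generate_cohort()` draws organ labels from the frequency profile of a
typical metastatic breast-cancer lesion population
(node:bone:liver:breast:lung:peritoneum = 44:43:17:10:5:4), at most
two lesions per organ per patient, radii 6–14 mm, baseline SUV 5–12,
and a random misalignment (≤5 mm, ≤2°) per pair. True mean-SUV changes
come from a three-part mixture chosen to emulate a treated metastatic
population: clear responses U(−85, −40), boundary-straddling changes
U(−45, −12) (so threshold recovery is actually informative), and
stable/progressing disease (U(−5, +5) or U(+30, +80)). A lesion is a
ground-truth responder at or below −30% (the PERCIST convention,
configurable); a patient responds only if all lesions do, and every
non-responding patient carries at least one clearly stable or
progressing lesion, the usual clinical progression pattern.

What passing tests on these phantoms does *not* show: performance on
real anatomy (no organ texture, no respiratory motion, no
reconstruction artefacts), behaviour of the adaptive threshold at
clinical signal-to-noise (the published experience is that it fails on
faint lesions — the phantoms make that failure mode *visible* through
the typed conditions, not absent), or clinical values of the optimal
thresholds. The cohort studies validate *internal consistency*:
that the pipeline recovers the decision boundary it was fed and that
the parametric classification agrees with ground truth when the model
assumptions hold.

When a lesion shows no focal uptake at follow-up (complete metabolic
response), the pipeline measures the follow-up SUV statistics inside
the baseline mask transferred through the registration, and reports a
metabolic volume of 0 (hence TLG 0): a resolved lesion has no
measurable metabolically active volume, and the evolution is
quantified as a deep decrease rather than a hard error.

## Problem sizes and numerical settings

The shipped studies use 96³ voxel grids at 2 mm, cohorts of 57
patients (≈ 190–200 lesion evolutions; 2–5 lesions per patient), 20
registration recovery cases, and 500-instance oracle sweeps for the
factor-analysis and ROC equivalences; the end-to-end
boundary-recovery cohort uses noise sigma 0.05 SUV (a low-noise
setting, so the recovered thresholds reflect the boundary rather than
measurement noise). Convergence tolerances: 0.1 mm for registration,
10⁻⁶ for the evolution factor; factor iteration cap 20 (two to five
iterations suffice in practice). Ties: 70%-isocontour membership is
inclusive; Youden ties break toward the smaller threshold; target-
selection ties break by lesion id.

## Known limitations

* Rotation recovery requires spatially spread structure; a patient
  whose only matchable lesion cluster is compact gets a
  translation-only alignment.
* The factor model is strictly two-frame (the factor count equals the
  number of scans in a pair); longer series are analysed pairwise.
* SAM's enlarged region is dilation-based, not CT-drawn.
* The evaluation layer reports no confidence intervals for
  sensitivity/specificity — point estimates mirror the tabular
  convention of the clinical literature it follows.
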