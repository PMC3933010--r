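---
title: "Stacked-ellipse shape models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked-ellipse shape models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ellipstack)
```

## The model

`ellipstack` models a smooth organ — the motivating application is the
prostate in axial MR, as delineated for radiotherapy treatment planning — as
a stack of per-slice ellipses. Each contour slice is summarized by five
parameters $\rho = (\theta_1, \theta_2, \alpha_1, \alpha_2, \phi)$: the
in-plane center (mm), the two semi-axis lengths (mm) and the rotation of the
first axis (radians). The boundary is
$C(\rho) = \{\, R_\phi x + \theta \;:\; x_1^2/\alpha_1^2 + x_2^2/\alpha_2^2 = 1 \,\}$.

The package covers the full semiautomatic pipeline:

1. **Best-fitting ellipses (BFE).** Per slice, the ellipse minimizing the sum
   of squared *orthogonal* distances of the manual contour vertices to the
   boundary. This is a geometric (total least squares) fit, not an algebraic
   one: the residual is the actual point-to-curve distance.
2. **Correspondence.** Axis reordering between neighboring slices, rotation
   relaxation where slices are nearly circular, inter-slice rotation
   smoothing, and cubic resampling of each parameter to a common canonical
   slice count $L$.
3. **Registration.** A similarity-type transform derived from 18 boundary
   control points (6 each on the first, center and last organ slices) maps
   every case into a common sample space; a quadratic *center curve* through
   the three control-point group centroids absorbs the systematic
   through-stack drift of the slice centers.
4. **Shape statistics.** Per canonical slice, means and variances of the
   center offsets $\eta = \theta - \xi$ from the center curve, of
   $a = \log \alpha$, and of $\phi$ over the training population; the priors
   are Gaussian (offsets, rotation) and log-normal (axis lengths).
5. **Deformation.** For a new case, the 18 control points alone determine the
   transform and center curve; the mean shape is resampled to the case's
   spanned slice count and mapped back. This step is deterministic and is
   the method's primary output.
6. **Posterior refinement (optional).** An empirical-Bayes posterior — a
   two-class Gaussian gray-level likelihood whose parameters are estimated
   from the deformed template itself, times the shape prior re-centered on
   the template — sampled by slice-blocked random-walk Metropolis.

### Assumptions

* Organ cross sections are approximately elliptical and vary smoothly from
  slice to slice; slices are equidistant along the stack axis.
* The control points are placed reasonably accurately on the organ boundary
  of the first, center and last contour slices (the model is built to be
  "closest to the control points": the center curve interpolates their
  centroids exactly).
* Gray levels inside and outside the organ are each roughly homogeneous in a
  local band around the boundary (for the optional refinement only).

## Coordinate conventions

All modeling operates in continuous millimetres in the *de-rotated* patient
frame, where slice planes align with the voxel grid axes; `derotate()` maps
volumes, contours and control points there using the volume's direction
matrix (the standard image-to-patient orientation mapping). Voxel `(1,1,1)`
sits at the volume origin and pixel centers carry the geometry everywhere
(rasterization uses the pixel-center rule, with no partial-area weighting,
matching how clinical systems voxelize reference contours).

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `L` (canonical slices) | 11 | – | common slice count for statistics; near the typical contoured-slice count of the target acquisitions (about 10.5) |
| `circ_threshold` | 0.95 | ratio | circularity $\min\alpha/\max\alpha$ above which the rotation is blended towards the neighbors; a near-circular slice has no meaningful orientation |
| `window` | 3 | slices | centered moving-average window for rotation smoothing |
| `band_mm` | 5 | mm | width of the outside shell in the gray-level likelihood |
| `n_iter`, `burn_in` | 20000, 5000 | sweeps | refinement chain length (one sweep updates every slice block) |
| `proposal_scale` | 0.25 | × prior sd | pre-adaptation random-walk step |
| `cp_jitter_sd` | 1 | mm | phantom control-point placement error |

The canonical-slice interpolation uses the *normalized* slice position
$t \in [0,1]$ of each case's z span, not raw z, so cases with different
slice counts share one domain.

## Label correspondence across cases

Axis labels of an ellipse are arbitrary: $(\alpha_1,\alpha_2,\phi)$ and
$(\alpha_2,\alpha_1,\phi \pm \pi/2)$ describe the same boundary.
`reorder_axes()` makes labels *within* one stack consistent by chaining
outward from the center slice, choosing per slice the representation with
the smallest rotation step. That still leaves each case's overall labeling
arbitrary, and a population in which some cases carry labels rotated by
$90^\circ$ relative to others produces badly mixed axis-length and rotation
statistics. The registration resolves this: after mapping into the sample
space the dominant direction of the center control-point group lies on the
x-axis, so `canonicalize_labels()` relabels the center slice to the
representation with rotation nearest zero and re-chains. With that step the
population rotation means sit near zero and the two axis-length
distributions stay separated; without it they visibly collapse towards each
other.

A related convention: the principal direction of the center control-point
group is a *line*, so its sign is ambiguous. The sign is fixed towards the
group's first labeled point, which makes the de-rotation deterministic and
equivariant; the stored rotation therefore lies in $(-\pi, \pi]$. For
ellipse-shaped organs a $180^\circ$ ambiguity between cases is harmless
(an ellipse is symmetric under it), and labeled manual control points carry
the orientation in clinical use.

## Numerical choices

* **Orthogonal projection** onto an ellipse solves the orthogonality
  condition in the parametric angle by a clamped Newton iteration started
  from a 32-point coarse scan, with a dense-scan (4096 points) plus local
  refinement fallback for non-converged points. The query at the exact
  center of a circle deterministically returns the first-axis endpoint.
* **Fitting** is initialized by the direct algebraic least-squares conic fit
  constrained to ellipses (the numerically stable scatter-matrix
  decomposition, on centered and scaled coordinates) and refined by
  Levenberg–Marquardt (`minpack.lm::nls.lm`) on the signed orthogonal
  distances, with the semi-axes log-parametrized so positivity is
  structural. The refined fit never has a larger objective than the
  initializer; non-convergence returns the best iterate with a warning
  rather than failing, because clinical contours are benign and a hard
  failure would block whole-case pipelines.
* **Cubic resampling** uses interpolating splines with
  Forsythe–Malcolm–Moler end conditions (`stats::spline`, method `"fmm"`),
  which reproduce knots exactly and global cubic polynomials identically;
  stacks with fewer than 4 slices degrade to linear interpolation, and
  interpolated semi-axes are floored at $10^{-6}$ mm with a warning.
  Rotations are unwrapped (period $\pi$, which leaves the ellipse point set
  unchanged) before smoothing, averaging or interpolation.
* **Degenerate priors.** A slice with zero variance (for example the center
  offsets on the three control-point slices, which vanish identically when
  training uses exact automatic control points) is treated as a point mass:
  its log-density term contributes 0 at the mean and $-\infty$ elsewhere,
  never `NaN`. In the posterior such blocks are immovable and report an
  acceptance rate of 0 by construction.

## The refinement target

The likelihood scores voxels near the boundary under the inside/outside
gray-level models. One subtlety is essential: if the scored voxel set moves
with the current state ("current ellipse plus shell"), every log-density
term is negative and the sampler is rewarded for shrinking the region until
nothing is scored — the chain collapses the ellipses instead of refining
them. The refinement therefore scores a **fixed** voxel set per slice (the
*template* ellipse dilated by the shell width); the current state only
decides which class scores each voxel. The standalone `log_likelihood()`
keeps the per-stack voxel set for scoring a given delineation.

Proposal scales adapt during burn-in (stochastic approximation towards an
acceptance rate of 0.3, multiplicative updates every 25 sweeps, frozen when
burn-in ends so the summarized chain has a fixed kernel). This is needed
because the posterior's width varies by orders of magnitude between the
prior-dominated and the likelihood-dominated regime. The posterior summary
defaults to the parameter-wise posterior mean with semi-axes averaged on the
log scale; a MAP summary is available.

## What the phantom generator emulates — and what it does not

`phantom_spec()` defaults reproduce the target acquisition geometry:
0.559 mm in-plane spacing on a 288×288 grid, 3.3 mm slice distance, 7–14
contoured slices per case (mean 10.5). Shapes are stacked ellipses with
mid-slice semi-axes uniform on 15–30 mm, elliptic end-tapering
($\alpha(t) = \alpha_{\text{mid}}\sqrt{1-\lambda(2t-1)^2}$ with $\lambda$
uniform on 0.80–0.92), centers following a random quadratic curve (sd 4 mm
constant/linear, 6 mm quadratic terms) plus smoothed per-slice offsets
(sd 1 mm), and small smooth rotation profiles (case-level sd 0.25 rad,
wobble sd 0.04 rad). Gray levels are two-class (200 inside / 100 outside,
noise sd 10); contour vertices get 0.3 mm jitter and control points 1 mm —
the placement error budgeted for a clinician's clicks. `bumpy = TRUE` adds
low-order angular harmonics (orders 2–4, relative sd 0.02 each) so contours
are no longer exact ellipses, emulating the residual between real organ
outlines and their best-fitting ellipses.

The generator does **not** emulate MR texture, bias fields, neighboring
organs, partial-volume effects, or observer-dependent contouring styles.
Passing tests on phantoms therefore demonstrates the correctness and
stability of the estimation machinery under the model's own assumptions —
not clinical accuracy. The package's synthetic population results (deformed
mean-shape median Dice ≈ 0.93, mean Hausdorff ≈ 2 mm; per-slice fits
≈ 0.98 against bumpy contours) are analogues of, not substitutes for,
clinical evaluation.

## Problem sizes used in the checks

The test-suite and the acceptance script work at the study scale the
phantoms define: populations of 33 cases split 23/10, ten random re-splits
for the robustness check, twenty replicate populations of 23 sampled stacks
for the moment-recovery check, refinement chains of 700–4000 sweeps on
single phantom volumes, and a $10^5$-iteration chain on the one-slice toy
posterior that is compared against direct numerical integration on a
141×141 grid.

## Known limitations

* Ellipse cross sections cannot represent strongly non-convex or lobed
  outlines; the per-slice fit quality (not the deformation) bounds the
  achievable agreement.
* The deformed stack covers exactly the control-point span; organs visible
  outside the first/last control-point slices are not extrapolated.
* Slices are assumed equidistant; the canonical-slice mapping is exact only
  in that case.
* Curvature-type constraints between neighboring slices (beyond rotation
  smoothing) are not implemented.
* Volume I/O supports NIfTI; NIfTI-1 stores the affine in single precision,
  so geometry round-trips to about $10^{-7}$ relative. DICOM series and
  RT-structure input are out of scope here; contours are exchanged as JSON.

## A minimal end-to-end run

```{r example, eval = FALSE}
spec <- phantom_spec(n_cases = 33, with_volume = FALSE)
pop <- generate_population(spec)           # 23 train / 10 test
norm <- lapply(pop$cases[pop$train], function(cs)
  normalize_case(cs$contours, cp = cs$cp, L = 11))
model <- fit_shape_model(lapply(norm, `[[`, "stack"),
                         xi = lapply(norm, `[[`, "xi"))
cs <- pop$cases[[pop$test[1]]]
deformed <- predict(model, cs$cp, cs$truth$z)   # the semiautomatic output
```
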