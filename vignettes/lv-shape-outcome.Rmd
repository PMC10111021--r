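---
title: "From left-ventricle segmentations to outcome prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From left-ventricle segmentations to outcome prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvssm)
```

## The problem

Patients with severe aortic stenosis who undergo transcatheter aortic valve
replacement (TAVR) typically show *reverse remodelling*: the hypertrophied
left ventricle (LV) loses mass once the afterload is relieved. The
fractional change in LV mass index one year after the intervention,

$$\mathrm{LVMI_{regression}} = \frac{\mathrm{postLVMI} - \mathrm{preLVMI}}{\mathrm{preLVMI}},$$

correlates with survival, so predicting it from the *baseline* anatomy is
clinically useful. `lvssm` implements a statistical-shape-analysis (SSA)
pipeline that goes from a segmented LV label volume to that prediction:

1. **Label clean-up** (`close_label`, `median_smooth`, `largest_component`):
   morphological closing with a 5-voxel cube, majority filtering with a
   5-voxel ball, and isolation of the largest 26-connected component.
2. **Surface extraction** (`extract_surface`): iso-surfacing of the binary
   grid at level 0.5 followed by uniform Laplacian smoothing.
3. **Correspondence and alignment** (`build_cohort`): down-sampling each
   surface to N points, centring, selecting the reference shape whose
   surface area and volume are jointly closest to the cohort averages,
   rigid ICP with the scale fixed at 1 (ventricular size is itself a
   predictor and must not be normalized away), bijective point
   correspondence, the pointwise mean shape, one realignment pass against
   the mean, and per-subject deviation vectors
   $X^{(k)} - \bar X \in \mathbb{R}^{3N}$.
4. **Encoding** (`fit_pls`, `fit_pca`): supervised partial least squares
   (PLS1/NIPALS) or principal component analysis of the deviation matrix,
   giving shape modes $U_m$ and per-subject scores $a_{km}$ such that
   $X^{(k)} \approx \bar X + \sum_m a_{km} U_m$.
5. **Prediction** (`fit_svr`, `evaluate_prediction`): a linear-kernel
   epsilon-insensitive support vector regression from the leading scores to
   the outcome, evaluated on a held-out 15% split with RMSE on the
   normalized outcome scale and $R^2$; compared against the bivariate
   clinical baseline $y = p_0 + p_1\,\mathrm{preLVMI} + p_2\,\mathrm{LVEF}$.
6. **Localization** (`vip`): variable-importance-in-projection scores of
   the PLS model, aggregated per point, to map where on the anatomy the
   outcome signal lives.

Because cohorts of segmented clinical CT ventricles with one-year follow-up
are not publicly available, the package ships a parametric synthetic cohort
generator (`generate_cohort`) with known ground truth, and the whole
pipeline is validated end-to-end on it.

## The synthetic cohort generator

### Geometry

Each subject is a watertight truncated prolate-spheroid shell
(`generate_lv_mesh`): an epicardial half-ellipsoid with equatorial semi-axis
$a = 25\,\mathrm{mm} \times \texttt{size\_scale}$ and long semi-axis
$c = a \times \texttt{elongation}$, truncated by a flat basal plane at
$0.45\,c$; an endocardial ellipsoid with
$a_{\mathrm{endo}} = \texttt{chamber\_scale}\cdot a - (t - 7\,\mathrm{mm})$
and $c_{\mathrm{endo}} = \texttt{chamber\_scale}\cdot c$, where $t$ is the
wall thickness (a thicker wall shrinks the cavity at fixed epicardium); and
a flat basal annulus joining the two rims. Four fixed sites on the inner
wall carry Gaussian radial bumps (angular width 0.35 rad, amplitude in mm,
positive into the cavity) standing in for papillary-muscle and trabecular
structure. Bump amplitudes taper smoothly to zero at the basal rim because
the fibrous annulus carries no trabeculation. All sites, and the surface
parameterization, are shared across a cohort, so anatomical correspondence
across subjects is well defined.

### Population and outcome model

Latents are drawn independently normal with defaults chosen to match the
magnitude of inter-patient variation reported for adult aortic-stenosis
cohorts: linear dimensions vary by roughly 10–15% (size sd 0.12,
elongation sd 0.15), cavity scale by sd 0.07, wall thickness by sd 1.2 mm
around 7 mm, and local inner-wall structures by sd 3 mm — papillary-scale.
Hard clamps several sigma out keep every draw geometrically valid.

The outcome is linear in the latents plus noise:
$y = \beta_0 + \beta^\top z + \varepsilon$, with the default $\beta$
driving $y$ through exactly three latents — overall size, sphericity and
chamber scale — mirroring the anatomical interpretation of the three
leading shape modes in this application (volumetric size, chamber volume,
spherical-to-ovoidal conversion). Defaults: the intercept offsets the
driving betas at the latent means so the cohort mean outcome is $-0.25$ (a
typical 25% mass regression), each driving latent contributes an outcome
SD of 0.04–0.06, and the noise sd is 0.05.

The clinical covariates are generated as noisy functions of latents already
expressed in the shapes: preLVMI proportional to shell volume (myocardial
density 1.05 g/cm³ over a fixed body surface area, calibrated to a
120 g/m² template) and LVEF decreasing in chamber scale. This is what makes
the "adding covariates to the score vector changes little" property a
designed feature of the cohort rather than an accident.

What the generator does **not** emulate: real trabecular texture,
valve-plane anatomy, papillary muscle detachment, acquisition noise,
segmentation error correlated with image quality, and any nonlinearity in
the shape–outcome map. Passing the validation therefore shows the pipeline
recovers *linear* shape–outcome structure from *clean but sampled*
surfaces; it does not certify performance on clinical data.

## Numerical and design choices

**Iso-surfacing.** Surface extraction uses the tetrahedral decomposition
variant of marching cubes (six tetrahedra per cell, midpoint interpolation
at iso-level 0.5). It has no ambiguous cases, so the output is watertight
by construction; orientation is made globally outward per facet. On
analytic spheres the volume error is well under 2% at 10-voxel radius.

**Morphology.** Closing pads the grid by the element radius first, so it
behaves as on an unbounded background (a label touching the grid boundary
is not eroded). The median filter and erosion treat out-of-grid voxels as
background. Components use 26-connectivity; size ties break toward the
first component in raster order.

**Laplacian smoothing.** Uniform (umbrella) weights, default 20 iterations
at relaxation 0.1; on a 10-voxel sphere this shrinks volume by well under
5%, consistent with the requirement that smoothing leave intracavity
volume essentially unchanged.

**Down-sampling.** `downsample()` offers two deterministic uniform
strategies. Farthest-point sampling guarantees spatial uniformity but the
chosen subset responds *chaotically* to small shape changes; in a
correspondence-based model this injects tangential sampling jitter of
order half the sample spacing into every deviation vector, which we found
caps the recoverable signal well below the information actually present
(verified against a shared-parameterization oracle). The default for
cohort construction is therefore the evenly spaced pick along the source
vertex enumeration (`uniform_down_sample` in common mesh toolkits):
spatially stratified, equally unbiased, and smoothly varying across
similar shapes.

**ICP.** Fixed scale $s = 1$ throughout. Initialization screens identity
plus the four proper-rotation principal-axes pre-alignments and starts
from the lowest one-step error; this removes the azimuthal local minima of
a near-rotationally-symmetric ventricle and lets a 30° misalignment be
recovered to machine precision. Convergence is declared on relative error
change below 1e-8, on an absolute error floor, or when the incremental
transform moves no point more than ~1e-6 mm. Within `build_cohort` the
pose is estimated from the best-matching 90% of correspondences (trimmed
ICP): a localized wall bump should shift its neighbourhood, not tilt the
whole pose — untrimmed alignment was observed to leak localized signal
into the apex and rim through exactly this mechanism.

**Correspondence.** The row reordering against the template is a true
bijection. The default solves the linear assignment problem on squared
distances (with an optional surface-normal mismatch term) to
near-optimality with a forward auction with epsilon scaling; mutual-NN
plus greedy and pure greedy remain available. Assignment, unlike greedy
matching, spreads the unavoidable density mismatch between unequal-sized
shapes smoothly instead of concentrating it in a few distant matches, and
the matching metric is size-normalized (each cloud scaled to the
template's RMS radius *for the matching only*) so a pure size difference
does not force matches to migrate. Stored coordinates are never rescaled.
The auction's epsilon floor is set at ~5% of the typical best-candidate
cost — differences below the sampling jitter only reshuffle ties — and a
bid budget cuts degenerate price wars short, completing stragglers
greedily.

**Refinement.** After correspondence to the reference, the mean shape is
computed and every cloud is realigned and re-corresponded to it once
(`refine_passes = 1`). More passes were observed to erode localized
deformation signal (each re-assignment against an increasingly smooth mean
re-routes matches around local features), so iteration to convergence is
deliberately not the default. Deviations are computed after the final
pass, so their column means are numerically zero.

**PLS.** Univariate-response NIPALS (PLS1) with deflation of X and y;
weights, loadings, scores and per-component outcome sums of squares are
stored; modes are the loadings. Mode signs are fixed so the
largest-magnitude entry is positive. Explained outcome variance is the
incremental in-sample $R^2$ of the outcome on the leading scores (the
cross-validated alternative is deliberately not used here; the held-out
assessment happens in the prediction stage). New data are projected with
the standard rotation $W(P^\top W)^{-1}$.

**Prediction protocol.** `evaluate_prediction` refits the encoder on the
training subjects of every split — the supervised PLS encoder never sees
test outcomes; this leakage guard is structural, and the
fit-once-on-everything alternative is available only behind an explicit
flag that marks the report as leaky. Features are standardized and the
outcome z-scored with training statistics; RMSE is reported on that
normalized scale. SVR defaults C = 1, epsilon = 0.1. Because a 10-subject
test set is volatile, the analysis scripts report medians over repeated
splits.

**VIP.** Standard formula
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a}$
with unit-norm weight vectors; the mean squared VIP is exactly 1.
Per-point aggregation is the root mean square of the point's three
coordinate VIPs. The conventional importance threshold stays at 2.6 as a
configurable default, not a hard-coded rule, since it is specific to the
fit it came from.

## Validation experiments and their problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) validates the pipeline end to end at the study
scale: K = 66 subjects and N = 2000 points per shape for parameter
recovery (5 seeds; noise-free recovery demands test $R^2 \ge 0.9$, and
with outcome noise at 30% of the signal SD it must stay $\ge 0.5$);
20 permutation seeds for the null calibration (median test $R^2 \le 0.2$);
and 20 split seeds for the PLS-vs-PCA comparison, run on the noise-free
planted-outcome cohort where the encoder difference is not swamped by
irreducible outcome noise (under 30% outcome noise the two encoders'
split-level ranking becomes nearly a coin flip). The VIP localization
experiment plants the outcome on the mid-anterolateral inner-wall bump
site with the other bump sites quiet (sd 0.5 mm) and global nuisance
variation retained, uses N = 3000 points for spatial resolution, and
requires at least 70% of the top-decile per-point VIP mass to fall within
the bump's support region, approximated as the Euclidean ball of radius
20 mm (3 angular sigma of the planted deformation) around the site. These
sizes are the package's chosen validation conditions and are also what the
analysis scripts use.

## Known limitations

* Bijective sample matching has a noise floor of order the inter-point
  spacing; features whose geometric footprint is below it (e.g. millimetre
  bumps at N = 2000) are attenuated in the deviation matrix no matter how
  the matching is done. Global modes pass through essentially unscathed.
* The synthetic shape population is an assumption; no population statistics
  of the motivating cohort were available to fit it against.
* In-sample variance-explained curves overstate what a held-out assessment
  would show; use the prediction stage's split metrics for generalization.
* The clinical baseline comparison inherits whatever realism the covariate
  simulation has — it demonstrates the protocol, not clinical superiority.
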