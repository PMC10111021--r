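# lvssm — left-ventricle statistical shape modelling and outcome prediction

`lvssm` predicts one-year left-ventricular mass index (LVMI) regression
after transcatheter aortic valve replacement (TAVR) from the *baseline*
three-dimensional shape of the left ventricle, using a fully automatic
statistical-shape-analysis pipeline. It is aimed at cardiovascular imaging
researchers who have segmented LV label volumes (or surface meshes) plus a
per-subject outcome table, and want a reproducible shape-to-outcome
analysis.

The outcome is the fractional mass change

    LVMI_regression = (postLVMI − preLVMI) / preLVMI

and the pipeline is:

1. **Label clean-up** — morphological closing (5-voxel cube), ball median
   filter (5 voxels), largest 26-connected component.
2. **Surface extraction** — iso-surfacing of the binary volume at level
   0.5 plus uniform Laplacian smoothing (watertight output).
3. **Correspondence & alignment** — uniform down-sampling to N points per
   shape; centring; reference selection by joint surface-area/volume
   proximity to the cohort mean, `argmin (s−s̄)² + (v−v̄)²`; rigid ICP with
   the scale fixed at s = 1 (size is a clinical feature, never normalized
   away); bijective point assignment; mean shape `x̄_n = (1/K) Σ_k x_n(k)`;
   deviation vectors `X(k) − X̄ ∈ R^{3N}`.
4. **Supervised encoding** — PLS1 (NIPALS) of the deviation matrix against
   the outcome (PCA available for comparison), giving shape modes U_m and
   scores a_km with `X(k) ≈ X̄ + Σ_m a_km U_m`.
5. **Prediction** — linear-kernel support vector regression from the
   leading scores, evaluated on random 15% held-out splits (RMSE on the
   normalized outcome scale, R²), against the clinical baseline
   `y = p0 + p1·preLVMI + p2·LVEF`.
6. **Localization** — variable importance in projection (VIP) per
   anatomical point, flagging where on the ventricle the outcome signal
   lives.

Because clinical cohorts of this kind are not publicly shareable, the
package includes a parametric synthetic LV cohort generator
(truncated-spheroid shells with latent size / sphericity / chamber / wall /
inner-wall-bump parameters and a linear latent-to-outcome map) and
validates the entire pipeline against that ground truth.

## Worked example

```r
library(lvssm)

# a ground-truthed synthetic cohort emulating a 66-patient study
synth  <- generate_cohort(K = 66, truth = ground_truth(), seed = 7)
cohort <- build_cohort(synth$meshes, synth$outcomes, synth$covariates,
                       n_points = 2000, seed = 7)

evaluate_prediction(cohort, encoder = "pls", n_components = 5, seed = 1)
#> lv_eval (pls, nc=5): train RMSE 0.363 / R2 0.866; test RMSE 0.405 / R2 0.749
evaluate_prediction(cohort, encoder = "pca", n_components = 5, seed = 1)
#> lv_eval (pca, nc=5): train RMSE 0.511 / R2 0.734; test RMSE 0.463 / R2 0.672
evaluate_baseline(cohort, seed = 1)
#> lv_eval (baseline, nc=0): train RMSE 0.725 / R2 0.464; test RMSE 0.662 / R2 0.330
```

On this cohort (outcome noise SD 0.05 against a signal SD of ~0.09) the
supervised shape model explains most of the held-out outcome variance,
beats the unsupervised PCA encoding, and both shape models clearly beat
the two-number clinical baseline — the qualitative ordering the method is
designed to demonstrate. RMSE values are in z-scored outcome units.

The full analysis lives in `analysis/01_simulate.R` …
`analysis/06_vip_localization.R`, thin numbered drivers that write their
tables under `results/`. `run_pipeline(pipeline_config(...))` runs the
same chain as one call. The methods vignette
(`vignettes/lv-shape-outcome.Rmd`) documents the model, every tunable
parameter, and the design decisions.

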