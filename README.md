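# vesica

Automatic bladder-tumor segmentation on diffusion-weighted MRI (DWI) and
reproducibility analysis of the radiomics features extracted from the
resulting regions of interest — as a fully tested, self-contained R
package that runs on synthetic phantoms with known ground truth.

The package is aimed at quantitative-imaging researchers who want a
reference implementation of this workflow whose every stage is
verifiable: a DWI phantom generator, a from-scratch five-level U-Net, a
majority-vote ensemble, a complete 107-feature radiomics engine, and
ICC-based agreement statistics.

## What it implements

* **Phantom simulation** — aligned b0 / b1000 / ADC volumes obeying the
  mono-exponential diffusion decay `S(b) = S0·exp(−b·ADC)` (ADC in
  10⁻³ mm²/s), an ellipsoidal bladder with wall and urine-filled lumen,
  one or more tumors attached to the wall, Rician noise, and
  per-patient tissue variability (`synthesize_case()`,
  `generate_cohort()`).
* **Preprocessing** — resize to the model grid and the signal
  normalization `(SI − mean_SI)/(12·SD_SI)`; single-sequence
  (replicated) or multi-sequence (b0, b1000, ADC) three-channel inputs
  (`assemble_channels()`).
* **Segmentation** — a five-level U-Net (Conv–BatchNorm–ReLU blocks,
  max pooling, transposed-convolution decoder, skip connections,
  sigmoid head) trained with the soft Dice loss and Adam under
  five-fold patient-level cross-validation (`build_unet()`,
  `cross_validate()`). The engine (including backpropagation) is part
  of the package, with compiled convolution kernels and
  finite-difference gradient checks in the test suite.
* **Ensemble evaluation** — per-voxel majority vote over the five fold
  models (a voxel is tumor when ≥ 3 of 5 models agree) and Dice
  similarity coefficient `DSC = 2|T∩P|/(|T|+|P|)` reporting
  (`majority_vote()`, `dice_coefficient()`, `summarize_cv()`,
  `summarize_test()`).
* **Radiomics** — the standard 107 features (18 first-order, 14 shape,
  24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) on ADC maps with
  fixed bin width 0.005 and voxel array shift 1, all in 3D
  (`extract_all()`); cross-checked against an independent reference
  implementation and hand-enumerated matrices.
* **Reproducibility statistics** — per-feature ICC(2,1) (two-way
  random effects, absolute agreement) between manual and automatic
  masks, with F-tests, confidence intervals, agreement categories and
  per-family median/IQR summaries (`icc_2_1()`, `feature_icc()`,
  `feature_group_summary()`); plus a training-free mask-perturbation
  route calibrated to a target DSC (`perturb_mask()`,
  `calibrate_perturbation()`).

## Worked example

```r
library(vesica)

# the desk-scale phantom study: 50 cases, 40 in five-fold CV, 10 held out
res <- run_pipeline(pipeline_config(n_patients = 50, seed = 1))
res
#> <pipeline_result> CV val DSC 0.917 (0.889-0.945); test median DSC 0.95 (IQR 0.94-0.96)
#> # A tibble: 7 x 5
#>   family     n_features median_icc q1_icc q3_icc
#>   <chr>           <int>      <dbl>  <dbl>  <dbl>
#> 1 firstorder         18      0.677  0.374  0.965
#> 2 shape              14      0.994  0.990  0.998
#> 3 glcm               24      0.876  0.609  0.981
#> 4 glrlm              16      0.990  0.736  0.993
#> 5 glszm              16      0.977  0.725  0.990
#> 6 ngtdm               5      0.786  0.679  0.948
#> 7 gldm               14      0.979  0.628  0.995
```

The first line is the cross-validated segmentation accuracy (mean and
range of the five folds' validation Dice coefficients) and the held-out
test accuracy of the 3-of-5 ensemble (median and interquartile range
over test cases). The table reports, per feature family, the median and
IQR of the ICC(2,1) agreement between features computed under the
reference masks and under the ensemble's automatic masks — values near 1
mean the automatic segmentation preserves the radiomics phenotype.

`plot_case()`, `autoplot()` on models/DSC reports, and
`plot_icc_profile()` visualize phantoms, training curves, DSC
distributions and ICC profiles. A thin command-line wrapper ships at
`system.file("cli", "vesica", package = "vesica")`.

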