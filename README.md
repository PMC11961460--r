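# atypkd

Characterization of **atypical (Mayo Class 2) autosomal dominant polycystic
kidney disease** from T2-weighted abdominal MRI — for nephrology and medical
imaging researchers who need cyst volumetrics and cohort statistics for the
minority ADPKD phenotype (focal Class 2A: unilateral / lopsided /
asymmetric; atrophic Class 2B) where the usual volume-based prognostic tools
of typical disease fall short.

The package provides:

* **Automated total-cyst-volume segmentation.** Within a kidney mask, gray
  levels are histogrammed and the *progressive weighted curve*

  $$\mathrm{PWC}(k) = \frac{\sum_{i=0}^{k} w_i x_i}{\sum_{i=0}^{k} w_i}$$

  (prefix count-weighted mean of gray levels, with $w_i$ the histogram count
  of level $i$) is computed. Its inflection points are candidate thresholds;
  each candidate's objects are scored by slice circularity, internal
  intensity SD and mean border gradient, and the best-scoring threshold
  yields the cyst mask (`segment_cysts()`).
* **Volumetrics and Mayo classification**: TKV, htTKV (mL/m), TCV,
  RTV = TKV − TCV, their ratios, nephromegaly (TKV > 750 mL), Class 1A–1E
  from the htTKV growth model $\mathrm{htTKV}=150(1+r)^{\mathrm{age}}$, and
  Class 2A/2B from the imaging pattern (`derive_volumetrics()`,
  `classify_mayo()`).
* **Cohort statistics**: mean ± SD and median (IQR) summaries,
  normality-guided Student-t / Kruskal–Wallis comparisons, OLS eGFR slopes
  and progressor classification (`summarize_cohort()`, `compare_groups()`).
* **A packaged reference cohort** of 12 atypical-ADPKD patients (clinical +
  imaging tables, `load_cohort()`), so every cohort-level result is
  recomputable offline.
* **A synthetic phantom generator** — ellipsoidal kidneys with hyperintense
  spherical cysts, partial-volume blur, Gaussian/Rician noise, and the
  atypical spatial patterns — with exact ground-truth volumes for validating
  the segmentation (`generate_phantom()`).

## Worked example

Segment a lopsided phantom and derive its volumetrics:

```r
library(atypkd)

ph  <- generate_phantom(phantom_spec(pattern = "lopsided", seed = 1))
seg <- segment_cysts(ph$volume, ph$truth$kidney_mask)
seg
#> <cyst_segmentation> threshold 169.7168; TCV 25.87 mL; 6 candidate(s)
ph$truth$true_tcv           # ground truth: 25.86 mL

tkv <- compute_tkv(ph$truth$kidney_mask, ph$volume$spacing)
tkv$tkv_ml                  # 322 mL total (229.4 + 92.6 per kidney)
v <- derive_volumetrics(tkv$tkv_ml, seg$tcv_ml)
round(c(v$tcv_percent, v$rtv), 1)   # 8.0 % cystic, 296.1 mL residual tissue
```

The chosen threshold (169.7) sits between the parenchyma and cyst intensity
modes, and the estimated TCV is within 0.1% of truth for this phantom
(across 20 seeded phantoms the median |error| is ≈ 6%).

Reproduce the cohort characterization:

```r
rep <- summarize_cohort(load_cohort(), total_mri = 124)
round(rep$overall$httkv$mean, 1)    # 1893.2 mL/m mean htTKV
rep$progressors$n_progressors       # 4
rep$by_class$httkv$comparison       # 2A vs 2B: Kruskal-Wallis, p = 0.032
classify_mayo("lopsided")           # "2A"
classify_mayo(NULL, httkv = 600, age = 40)  # "1C"
```

The `analysis/` directory holds the narrative drivers
(`01_cohort_summary.R`, `02_group_comparisons.R`,
`03_phantom_validation.R`); each writes its tables under `results/`.

## Notes

The packaged cohort transcribes its source tables verbatim; two
typographically ambiguous/inconsistent cells and their handling are
documented in the methods vignette (`vignettes/atypkd-methods.Rmd`), along
with the segmentation's numerical design choices and the phantom's
limitations.
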