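# petadc

Quantitative correlation analysis of prostate PET and diffusion-MRI
lesion features, with a seeded digital phantom for validation.

## The problem

In prostate cancer, tumour tissue restricts water diffusion (low ADC on
DWI) and overexpresses PSMA (high SUV on ⁶⁸Ga-PSMA PET), so lesion-level
ADC and SUV are expected to be inversely coupled. Testing that coupling —
and how sensitive it is to the attenuation-correction (AC) method used to
reconstruct PET on hybrid PET-MR scanners — requires a reproducible chain
from voxels to statistics. `petadc` provides that chain for researchers
working with co-registered PET/DWI volumes:

* **ADC maps** from two-b-value DWI via the mono-exponential model
  ADC = ln(S₀/S_b)/b (reported in 10⁻³ mm²/s; non-physical voxels
  clamped and counted);
* **SUV maps** from activity volumes using body-weight SUV
  (SUV = C·W/A) with half-life decay correction (T₁/₂ = 4057.7 s);
* **lesion mask series** at 10–60 % of SUVmax (inclusive threshold,
  nested by construction, always derived from the reference PET);
* **six histogram features** per lesion (mean, max, min, median,
  population skewness g₁ = m₃/m₂^{3/2}, excess kurtosis m₄/m₂² − 3);
* **6×6 Spearman correlation grids** of ADC features × SUV features
  across a cohort, with per-cell two-sided p-values;
* **AC error reports**: per-feature average relative absolute error,
  avg.RAE = (1/N)·Σ|Pₓ − P_ref|/P_ref·100, with paired t and
  Mann–Whitney–Wilcoxon method comparisons;
* a **digital prostate phantom**: seeded cohorts of nested-ellipsoid
  subjects with a programmable Spearman coupling between lesion ADC and
  SUV (Gaussian copula), Rician DWI noise, and smooth multiplicative PET
  bias fields emulating Dixon-based and deep-learning-based μ-maps.

Everything is tabular and pipe-friendly: feature tables are tibbles,
fitted result objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(petadc)

cfg <- pipeline_config(output_dir = "petadc_run", master_seed = 1)
res <- run_pipeline(cfg)   # 27 synthetic subjects, 17 PZ / 10 TZ lesions

res$grids[["CT_reference_pct00"]]
#> <correlation_grid> CT_reference, threshold 0%, n = 27 subjects
#>           SUV
#> ADC         mean   max   min median kurtosis skewness
#>   mean     -0.59 -0.54 -0.52  -0.55    -0.07    -0.06
#>   max      -0.23 -0.16 -0.58  -0.21    -0.68    -0.54
#>   min      -0.59 -0.59 -0.21  -0.56     0.24     0.15
#>   median   -0.56 -0.51 -0.50  -0.56    -0.10    -0.03
#>   kurtosis -0.15 -0.18  0.03  -0.12    -0.05     0.00
#>   skewness -0.19 -0.20 -0.17  -0.14    -0.09    -0.17
```

The cohort was generated with a programmed lesion-level Spearman
coupling of −0.5 between ADC_mean and SUV_mean; the pipeline recovers
−0.59 on this seed (the sampling sd of Spearman's ρ at n = 27 is
≈ 1/√26 ≈ 0.2). The weaker kurtosis/skewness cells reflect the
homogeneous phantom lesions, whose shape statistics are
geometry-dominated.

```r
tidy(res$error_report)
#> # A tibble: 12 × 6
#>    feature  method_label mean_rae sd_rae n_used n_excluded
#>    <chr>    <chr>           <dbl>  <dbl>  <int>      <int>
#>  1 kurtosis DL_like          9.11   9.71     27          0
#>  2 kurtosis MRI_like        35.1   30.1      27          0
#>  3 max      DL_like          5.43   4.69     27          0
#>  4 max      MRI_like        15.8    9.82     27          0
#>  5 mean     DL_like          2.07   1.45     27          0
#>  6 mean     MRI_like         2.59   2.28     27          0
#>  ...
```

The per-feature avg.RAE against the CT-like reference reproduces the
expected pattern for MRI-based vs deep-learning-based attenuation
correction: mean-SUV errors of a few percent (≈ 2.6 % vs ≈ 2.1 %), an
order of magnitude larger for the shape statistics, and the DL-like
method strictly better throughout. `autoplot(res$error_report)` and
`autoplot(res$grids[[...]])` render the bar chart and annotated heatmap;
`render_heatmap()` writes the heatmap to file.

All run artifacts (feature tables, correlation grids, error report, run
manifest with seed and config hash) are written as CSV/JSON to
`output_dir`, and a rerun with the same seed is byte-identical.

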