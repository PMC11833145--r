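# ionmri

Quantitative sodium (²³Na) and potassium (³⁹K) MRI of skeletal muscle, as an
end-to-end simulatable and testable pipeline.

## The problem

X-nuclei MRI can measure the apparent tissue sodium concentration (aTSC) and
apparent tissue potassium concentration (aTPC) of muscle — volume-weighted
averages of the intra- and extracellular ion pools. In dystrophic muscle
(e.g. facio-scapulo-humeral muscular dystrophy), fatty replacement of muscle
tissue confounds these measures: fat contains ~7.9 mM sodium and essentially
no potassium, so the apparent concentrations of a partially fat-replaced
muscle drift toward the fat values even when the remaining muscle tissue is
unchanged. Quantification therefore chains several corrections:

1. **Region-based partial volume correction (PVC).** ³⁹K images have a
   nominal resolution of 8 × 8 × 32 mm³; the point spread mixes signal
   between neighbouring muscles, subcutaneous fat, and background. With
   segmentation masks, the observed region means obey
   `observed = M · true`, where `M[i, j]` is the mean over region *i* of
   the PSF-blurred indicator of region *j*; least-squares inversion
   recovers the unmixed region intensities.
2. **Relaxation-bias correction.** Spin-3/2 nuclei decay biexponentially
   (³⁹K in muscle: T2*short = 1.2 ms, T2*long = 8.1 ms); each region's
   intensity is divided by
   `w = (1 − e^(−TR/T1)) · Σᵢ fᵢ e^(−TE/T2*ᵢ)`.
3. **Calibration.** Five external reference compartments with known
   [Na⁺]/[K⁺] = 10/240, 20/210, 25/180, 30/150, 40/120 mM anchor a linear
   regression `intensity = slope · conc + intercept`, inverted to convert
   muscle intensities to mM.
4. **Fat correction.** With the region's fat fraction FF (from an extended
   phase graph water-T2/FF fit of a 32-echo MESE train),
   `aTSC_fc = (aTSC − 7.9 mM · FF) / (1 − FF)` and
   `aTPC_fc = aTPC / (1 − FF)` refer the concentrations to the remaining
   muscle tissue. Regions with median FF > 60% are excluded (the MESE fit
   destabilizes there).

No clinical data ship with the package. Instead, a digital lower-leg
phantom (seven muscles, subcutaneous fat, the five-compartment reference
holder) with known ground truth makes every stage verifiable by parameter
recovery, and a record-level cohort simulator supports the nonparametric
group statistics (Wilcoxon rank-sum, Kruskal–Wallis, Spearman, median/IQR
summaries by fat-fraction group).

## Worked example

Simulate a noiseless ³⁹K acquisition of the default leg phantom with a test
region at 240 mM K⁺ (the concentration of the first reference compartment),
then run the quantification chain:

```r
library(ionmri)

spec   <- leg_phantom_spec(test_region = list(na_mM = 40, k_mM = 240, ff = 0))
labels <- build_label_map(spec)
gt     <- ground_truth_maps(spec, labels)
acq    <- acq_preset("k39_da3drad")      # TR 40 ms, TE 0.4 ms, 8x8x32 mm3
sim    <- simulate_acquisition(gt$k, labels, spec, acq, noise_sigma = 0)
conc   <- quantify_regions(sim, labels, spec, acq)
dplyr::filter(conc, name %in% c("GM", "SOL", "REF1", "TEST"))
#> # A tibble: 4 × 3
#>   name  label_id conc_mM
#>   <chr>    <int>   <dbl>
#> 1 GM           1    81.3
#> 2 SOL          3    96.1
#> 3 REF1         9   240
#> 4 TEST        14   240.
glance(attr(conc, "calibration"))
#> # A tibble: 1 × 3
#>   r_squared nucleus n_refs
#>       <dbl> <chr>    <int>
#> 1         1 K39          5
```

The test region quantifies to exactly 240 mM; GM reads 81.3 mM because the
healthy phantom gives it a potassium tissue concentration of 84.7 mM at
FF = 0.04 (apparent value `(1 − 0.04) · 84.7 = 81.3`), which the fat
correction would restore.

Fit water T2 and fat fraction to a noiseless MESE train generated at
FF = 23.1 %, water T2 = 25 ms, B1 = 0.9:

```r
proto <- acq_preset("h1_mese")           # 32 echoes, 9.5 ms spacing
train <- two_pool_signal(100, ff = 0.231, water_t2_ms = 25, b1 = 0.9, proto)
fit_water_t2_ff(train, proto)
#> <mese_fit> water T2 = 25 ms, FF = 23.1%, B1 = 0.9
#>   residual norm 6.48e-05
```

Cohort statistics on a synthetic patient/control cohort show the
dystrophic signature — depressed fat-corrected aTPC in strongly
fat-replaced muscles:

```r
rec <- simulate_cohort_records(seed = 7)
cohort_group_summary(rec, "atpc_fc_mM")
#> # A tibble: 4 × 8
#>   ff_group     n median    q1    q3   iqr     p_vs_ctl significant
#>   <fct>    <int>  <dbl> <dbl> <dbl> <dbl>        <dbl> <lgl>
#> 1 CTL         77   82.3  73.5  96.2  22.7 NA           NA
#> 2 FF<10%      48   88.6  76.5  98.0  21.5  0.105       FALSE
#> 3 10-30%      23   92.6  72.4  97.1  24.8  0.544       FALSE
#> 4 30-60%      19   25.7  11.8  48.5  36.8  0.000000137 TRUE
```

`run_pipeline(pipeline_config(...))` chains all stages (phantom → ²³Na/³⁹K
simulation → MESE fitting → quantification → statistics) per subject and
writes CSV/JSON outputs with provenance.

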