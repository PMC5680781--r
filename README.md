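# trackdose

Simulated comparison of two respiratory motion-management strategies for
stereotactic body radiotherapy (SBRT) of pancreatic tumors:

* the **ITV concept**, which irradiates the internal target volume — the
  motion envelope of the gross tumor volume (GTV) over all breathing
  phases — plus a 5 mm margin, and
* **adaptive tumor tracking**, which irradiates the reference-phase GTV
  plus the same margin while the beam isocenter follows the tumor.

The package is aimed at medical-physics researchers who want a fully
scripted, deposit-free testbed for 4-D dosimetry methods. It provides the
whole chain:

1. **Synthetic 4-D phantoms** (`make_phantom()`): a water-equivalent
   abdomen with GTV, duodenum, stomach, bowel, liver, kidneys and spinal
   cord on a 2 mm voxel grid, breathing with a 10-phase cosine trace and
   known (rigid or rigid-plus-local) displacement fields — the stand-in
   for patient 4DCT scans and deformable registration.
2. **Structure geometry** (`build_structure_set()`, `union_envelope()`,
   `expand_margin()`, `motion_amplitudes()`): motion envelopes, isotropic
   margin expansion by Euclidean distance, centre-of-volume motion
   quantification with the 3-D motion magnitude
   `sqrt(AP² + SI² + LR²)`.
3. **A surrogate conformal-arc dose engine** (`plan_itv()`,
   `plan_track()`): two full arcs, conformal beam's-eye-view apertures,
   exponential depth attenuation with a Gaussian penumbra, prescription
   25 Gy / 5 fractions to the 60% isodose (D95 of the PTV normalized to
   25 Gy, 41.5 Gy ceiling), organ-at-risk constraints and a
   simultaneous-integrated-protection (SIP) style iterative aperture
   adjustment for PTV/OAR overlaps (25–27.5 Gy window).
4. **4-D dose accumulation** (`accumulate_4d()`): arcs are cut into
   angular segments assigned to breathing phases, per-phase sub-doses are
   computed (isocenter shifted with the tumor in tracking mode), warped
   to the reference phase along the ground-truth fields, and summed over
   two arcs and five fractions.
5. **DVH metrics** (`summarize_metrics()`): Dmean, Dmin, Dmax, D2, D95,
   D98 and D0.1cc by descending-sort rank interpolation, plus constraint
   reports.
6. **Cohort statistics** (`load_table1()`, `reproduce_table1_report()`,
   `wilcoxon_signed_rank()`, `spearman_rho()`, `linear_fit()`,
   `run_virtual_cohort()`): a bundled reference cohort of 12 pancreatic
   SBRT patients (PTV sizes for both concepts and per-axis motion
   amplitudes), exact paired Wilcoxon signed-rank by complete sign
   enumeration, Spearman rank correlation with midranks, ordinary least
   squares, and a virtual-cohort runner producing the two-arm comparison
   table for 3-D and 4-D dose.

## Worked example

```r
library(trackdose)

# the bundled reference cohort and everything derivable from it
print(reproduce_table1_report(), n = 19)
#> # A tibble: 19 × 2
#>    quantity                  value
#>    <chr>                     <dbl>
#>  1 ptv_itv_median_cc     131.
#>  2 ptv_itv_mean_cc       143.
#>  3 ptv_itv_sd_cc          71.2
#>  4 ptv_track_median_cc   109.
#>  5 ptv_track_mean_cc     122.
#>  6 reduction_mean_pct     16.8
#>  7 reduction_sd_pct        8.44
#>  8 reduction_min_pct       4.71
#>  9 reduction_max_pct      39.2
#> 10 motion3d_min_mm         1.34
#> 11 motion3d_max_mm        11.2
#> 12 motion3d_mean_mm        5.59
#> 13 motion3d_patient1_mm   11.2
#> 14 fit_slope              -2.29
#> 15 fit_intercept          -4.03
#> 16 fit_r_squared           0.543
#> 17 spearman_rho           -0.462
#> 18 spearman_p              0.131
#> 19 wilcoxon_ptv_p          0.000488
```

The tracking concept shrinks the PTV by 16.8% on average (up to 39.2%),
the reduction grows by ~2.3 percentage points per mm of 3-D tumor motion,
and the paired Wilcoxon test on the 12 PTV pairs is significant at
p = 2/4096 ≈ 0.0005.

A single virtual patient end to end:

```r
cfg <- phantom_config(motion_amplitude_mm = c(ap = 2.4, si = 10.4, lr = 3.3))
ph  <- make_phantom(cfg)

itv   <- plan_itv(ph)      # envelope arm: plan on the average anatomy + SIP
track <- plan_track(ph)    # tracking arm: plan on the reference phase + SIP

acc <- accumulate_4d(track, ph)          # 4-D accumulated tracking dose
summarize_metrics(acc$dose, track$structures, "4D", phantom = ph)

# DVH figure
gtv <- ph$phases[[ph$reference_phase]]$masks$gtv
autoplot(cumulative_dvh(track$dose, gtv),
         `GTV (4D)` = cumulative_dvh(acc$dose, gtv))
```

And the full 12-patient virtual cohort (about 5 minutes):

```r
vc  <- run_virtual_cohort(progress = TRUE)
summarize_virtual_cohort(vc)   # per-parameter two-arm comparison, 3D and 4D
```

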