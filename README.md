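# polytrans

Quantitative analysis of translation state from sucrose-gradient polysome
profiles, for labs studying how ribosome engagement changes in disease
models — here, the SMN-deficient (spinal muscular atrophy) mouse — and for
anyone who needs a tested, reproducible implementation of the polysome
profiling statistic stack rather than spreadsheet peak integration.

## What it computes

An A254 absorbance trace from a linear sucrose gradient shows, light to
heavy: free RNPs, the 40S and 60S ribosomal subunits, the 80S monosome,
and a train of polysome peaks. The package's central statistic is the
**fraction of ribosomes in polysomes**

    FRP = AUC(polysomes) / (AUC(polysomes) + AUC(80S))

computed after linear baseline subtraction, valley-based peak segmentation
and trapezoidal integration. Around it:

- **Cohort analysis** — Student's t tests on FRP between genotypes, Pearson
  and Spearman correlation of FRP with body weight and righting-reflex time,
  and hierarchical clustering of mice (variables standardised, Euclidean
  distances, Ward.D agglomeration).
- **Co-sedimentation** — per-lane normalised distribution of a protein's
  immunoblot signal across gradient fractions, polysome-association index,
  and signed shift statistics (toward lighter fractions = negative).
- **Translatome** — translation efficiency per transcript,
  log2TE = log2(POL/TOT) on CPM-normalised paired counts, with a
  label-permutation test for differential TE (joint permutation preserves
  POL/TOT pairing; exhaustive enumeration when feasible), and the qPCR
  delta-delta-Ct pathway: FC = 2^(−ΔΔCt) against the geometric mean of two
  reference genes, log2ΔTE = log2(FC_POL) − log2(FC_TOT).
- **Cell-level effects** — percent decrease in per-cell AHA fluorescence
  (de novo protein synthesis) and in per-axon ribosome density
  (count/area), with t tests at both pooled-cell and replicate-mean units.
- **Synthetic-data generators** for every input, with closed-form ground
  truth (Gaussian peak areas, planted FRP, planted TE shifts, planted
  effect sizes), so the whole pipeline is testable end to end.

## Worked example

```r
library(polytrans)

# one profile with known ground truth
sim <- simulate_profile(gradient_model(), seed = 42)
profile_frp(sim$profile)
#> # A tibble: 1 × 4
#>     frp area_polysomes area_80s qc
#>   <dbl>          <dbl>    <dbl> <chr>
#> 1 0.671           10.9     5.34 ""
sim$truth$frp
#> [1] 0.6716418

# a whole cohort: control vs SMA-like mice, FRP -> phenotype -> clustering
run <- run_pipeline(list(seed = 42), out = tempfile())
tidy(run$results$frp_test)
#> # A tibble: 1 × 7
#>   statistic    df   p_value mean_a mean_b alternative flag
#>       <dbl> <dbl>     <dbl>  <dbl>  <dbl> <chr>       <chr>
#> 1      7.56    10 0.0000194  0.738  0.579 two.sided   ""
run$results$correlations
#> # A tibble: 4 × 5
#>   method   estimate  p_value     n phenotype
#>   <chr>       <dbl>    <dbl> <int> <chr>
#> 1 pearson     0.861 0.000324    12 weight_g
#> 2 spearman    0.762 0.00590     12 weight_g
#> 3 pearson    -0.722 0.00807     12 righting_s
#> 4 spearman   -0.783 0.00412     12 righting_s
```

The FRP estimate (0.671) recovers the profile's analytic ground truth
(0.672). In the cohort run the control group's mean FRP (0.738) exceeds the
SMA group's (0.579, p ≈ 2e-5); FRP correlates positively with body weight
and negatively with righting time, and the Ward.D 2-cluster cut separates
the genotypes perfectly — the structure the generator planted.

Plots: `autoplot(profile)` (trace with shaded regions),
`autoplot(te_result)` (volcano), `plot_cosed(shares)`,
`plot(clustering)` (dendrogram).

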