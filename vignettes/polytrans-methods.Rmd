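---
title: "Methods: polysome-profile quantification and translation-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polysome-profile quantification and translation-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytrans)
```

## The measurement and the statistic

Polysome profiling separates cytoplasmic ribonucleoprotein complexes on a
linear sucrose gradient (typically 15–50%) and records absorbance at
254 nm while fractionating. The trace shows, light to heavy, the free RNP
pool, the 40S and 60S ribosomal subunits, the 80S monosome, and a series of
polysome peaks. The package's central statistic is the fraction of
ribosomes in polysomes,

$$\mathrm{FRP} = \frac{A_{\text{poly}}}{A_{\text{poly}} + A_{80S}},$$

the polysomal area under the curve over the polysomal plus 80S areas. The
subunit and RNP regions are excluded from the denominator on purpose: the
ratio contrasts assembled ribosomes that are engaged on mRNA with those
idling as monosomes. FRP is dimensionless, bounded in [0, 1], invariant to
rescaling the trace (lysate amount, detector gain), and strictly increasing
in polysomal mass. A polysome-to-monosome ratio
(`polysome_monosome_ratio()`) is provided as a conventional alternative but
is not used by any default.

## From trace to areas

**Baseline.** AUCs are computed on a baseline-subtracted trace by default.
The baseline model is a straight line through the median point of two
anchor windows, by default the first and last 2% of the trace, where
nothing sediments. This is the simplest model that exactly removes the
linear offset-plus-drift baseline the generator produces; raw-trace
integration remains available (`profile_frp(baseline = FALSE)`) because it
is unclear in general practice whether published AUCs are baseline
corrected. A rolling-ball or spline baseline could be swapped in behind the
same interface if real detector drift demanded it.

**Segmentation.** Local maxima are detected on a Savitzky–Golay-smoothed
copy of the trace (window 2% of the trace length, cubic order). Smoothing
exists solely so detector noise does not spawn spurious low-prominence
maxima; all integration uses the raw absorbance values. Peaks with
prominence below `min_prominence` (default 0.05 absorbance units) are
discarded; the first four surviving peaks, in position order, are assigned
to RNP, 40S, 60S and 80S, and region boundaries are placed at the valley
minima between adjacent assigned peaks. Everything beyond the valley that
follows the 80S peak is the POLYSOMES region. Where exactly "polysomes
start" is a genuine free choice — we document the minimum between the 80S
peak and the first polysomal peak as ours, and flag any boundary whose
valley depth is below the prominence threshold as ambiguous. Whether the
80S area should include shoulder overlap with the 60S peak is equally
undefined in the field; the valley boundary is our documented convention.

**Integration.** Trapezoidal rule per region on the raw (baseline-
corrected) samples. Negative net areas — noisy tails dipping below the
baseline — are clamped to zero with a QC flag rather than rejected, since
they are routine in real traces.

On noiseless synthetic profiles this stack recovers the closed-form
Gaussian region areas to better than 1% and FRP to within 0.005; with
additive trace noise at 2% of the tallest peak the mean absolute FRP error
stays under 0.02 (both properties are asserted in the test suite).

## Cohort statistics

Group comparisons of FRP use Student's (equal-variance) t tests, two-sided
by default; one-sided alternatives must be requested explicitly, mirroring
how directional hypotheses should be pre-declared. Two groups of identical
constants are reported as p = 1 with a `zero_variance` flag rather than an
error. FRP–phenotype association reports both Pearson's r and Spearman's ρ
with their test p-values.

Mouse clustering standardises each variable (FRP, relative weight,
relative righting time) to a common mean and standard deviation, computes
Euclidean distances, and agglomerates with **Ward.D** — the Lance–Williams
Ward update applied to unsquared distances. Ward.D2 (squared distances) is
the textbook criterion, but Ward.D is the named method we emulate, and the
test suite pins the tree to an independently coded Lance–Williams oracle on
6-point problems. Relative phenotypes divide each animal's value by the
mean of stage-matched controls, so pre-, early- and late-symptomatic
animals are comparable on one scale.

## Co-sedimentation

Immunoblot densitometry across fractions is normalised per lane (one
protein in one sample) to its total signal, because exposure differs
between blots; all comparisons use the resulting shares, which sum to 1.
The polysome-association index is the share summed over polysomal
fractions (optionally 80S + polysomal); it is bounded, and index plus
complement-index equals 1. Distribution shifts between conditions are
summarised by the signed change in association index and in the signal's
centre of mass in fraction-index units — fraction volume, not sucrose
percentage, being the reporting unit of gradient experiments. Negative
centre-of-mass shifts mean movement toward lighter fractions, the
signature of ribosome dissociation (e.g. EDTA). No published numeric index
exists for these curves, so the definitions are validated against the
synthetic generator's analytic expectations only.

## Translatome

Translation efficiency is the polysomal-to-total abundance ratio per
transcript: log2TE = log2((POL + c)/(TOT + c)) on CPM-normalised counts
(length-scaled, FPKM-like normalisation is available when gene lengths are
supplied). The pseudo-count c defaults to 0.5 normalised units — enough to
keep log-ratios finite at zero counts, small enough to be negligible at
moderate depth. How zero-expression transcripts were handled upstream in
published FPKM pipelines is never stated; this is our documented choice.

Differential TE is tested with a permutation scheme of our own design,
replacing (not reimplementing) the external tool used for the original
analysis: the statistic is the difference of group-mean log2TE, and the
null is built by permuting sample labels once per permutation, applied
jointly to both compartments so POL/TOT pairing is preserved. With at most
10,000 distinct case/control labelings the null is enumerated exhaustively
and p-values are exact (lattice-valued, with floor 2/K for K labelings);
otherwise random labelings are drawn and the add-one two-sided estimate is
used. BH-FDR is reported across genes, but gene selection at raw p < 0.05
is also emitted for comparability with the original pipeline's raw-p
thresholds. Results are comparable to the replaced tool in direction and
ranking, not in exact p-values.

The qPCR pathway implements delta-delta-Ct with two reference genes:
technical replicates are averaged per reaction; ΔCt subtracts the
arithmetic mean of the two reference Cts (equivalently, normalisation to
the geometric mean of reference expression); ΔΔCt contrasts case against
control means; FC = 2^(−ΔΔCt). log2ΔTE = log2(FC_POL) − log2(FC_TOT) is
the primary definition — "difference between the fold changes" read on the
log scale, consistent with calling the quantity log2ΔTE — with the raw
difference available as an option. On noiseless synthetic Ct tables the
composed pathway returns planted fold changes and log2ΔTE to machine
precision.

## Cell-level effect sizes

Percent decrease is defined on arithmetic means of raw intensities,
100·(1 − mean(case)/mean(control)), because mean fluorescence intensity is
the reported unit; it is invariant to common rescaling. The unit-of-
analysis question (cells pooled across preparations versus replicate
means) is a known pseudo-replication debate; published per-cell n suggests
pooled cells, so that is the default, but both analyses are always
reported side by side. Axonal ribosome density is count/area per axon
profile, compared with a two-tailed t test on per-axon densities.

## The synthetic generators: what they emulate and what they do not

The generators define the study conditions under which everything above is
validated:

- **Profiles** are sums of symmetric Gaussians over a linear baseline with
  additive Gaussian noise (a skew option exists but is off by default, as
  published profiles are near-symmetric schematics). Default geometry: 8
  peaks on a 0–100 coordinate, 12 equal-width fractions, 1000 sample
  points; true areas are amplitude·σ·√(2π). Detector sampling rate and
  gradient length are nowhere specified for the real instrument, so these
  units are arbitrary and configurable.
- **Cohorts** draw per-mouse FRP from group-specific normals truncated to
  (0, 1) (control mean 0.75 sd 0.03; SMA-like mean 0.55 sd 0.05 — values
  chosen once to produce clearly separated but overlapping groups of the
  kind the assay shows), with weight and righting time linear in FRP plus
  noise; righting is capped at 30 s after noise, the assay termination
  rule. Group sizes default to 6, inside the published 3–9 replicate range.
- **Counts** are negative binomial with shared dispersion (the field
  standard for count emulation; the original pipeline worked in FPKM and
  states no count model), with total-RNA means shared across groups and
  polysomal means scaled by 2^(log2ΔTE) for planted genes.
- **Ct tables** encode one cycle per expression doubling plus Gaussian
  cycle noise; reference genes are flat by construction.
- **Cell intensities** are lognormal (CV 0.4 by default) with the case
  mean scaled down by the planted percent decrease; **axon counts** are
  Poisson over lognormal areas (CV 0.3) attributed to 3 mice per genotype.

Noise is additive on traces (which may therefore go negative — handled by
baseline and clamping) but multiplicative lognormal on densitometry and
intensities, which are physically positive.

What the generators do *not* emulate: real detector artefacts, peak
asymmetry from diffusion, blot saturation, amplification-efficiency
differences between qPCR assays, within-mouse correlation of axon
profiles, or any transcript-level biological covariance structure. Passing
tests therefore demonstrate correctness of the estimators under the stated
generative models, not robustness to every pathology of real data. The
published tissue-level numbers (counts of altered-TE transcripts, DEG
overlap percentages, tissue FRP values) depend on unreleased animal data
and are not asserted anywhere; the property-based suites on synthetic
cohorts stand in for them.

## Numerical and design notes

- Exhaustive permutation enumeration is preferred whenever the labeling
  count is ≤ 10,000; sampled permutations use the add-one estimator and a
  caller-supplied seed. Comparisons of test statistics use a 1e-12
  absolute tie tolerance.
- Problem sizes in the test and acceptance suites — 1000-gene null
  simulations at 6 vs 6 samples, 20-seed FRP noise sweeps, 3-seed
  effect-size recoveries at the published per-group cell counts — were
  chosen as the smallest sizes at which the binomial/Monte-Carlo error of
  each check is well inside its assertion band.
- Fraction indices are 1-based, matching how fractions are numbered off a
  gradient; positions are continuous and arbitrary-unit.
- A single pipeline seed is fanned out to stages by fixed offsets, so any
  stage can be rerun in isolation and reproduce its part of a run;
  manifests record an MD5 checksum per artifact.
- The pipeline surface is the R functions themselves (`run_pipeline()`,
  `validate_inputs()`, and the per-module verbs); all I/O is plain text
  (TSV, YAML, JSON) for diffability.

## Known limitations

Overlapping polysome peaks are integrated as one region — no deconvolution
into per-n-some species. Valley segmentation assumes the four light-side
species peaks are detectable; heavily degraded profiles (no discernible
80S) are rejected rather than guessed at. The permutation ΔTE test has a
granular p-value floor at small sample sizes (2/70 at 4 vs 4), which caps
attainable significance; at least 6 samples per group are needed for
p < 0.001 claims. Lognormal intensity noise makes the pooled percent-
decrease estimator very slightly biased in small samples; the replicate-
mean analysis is co-reported partly for that reason.
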