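---
title: "Age-dependent rDNA methylation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-dependent rDNA methylation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaclock)
```

This vignette documents the scientific models behind `rdnaclock`, the
tunable parameters and their defaults, what the synthetic-data generators do
and do not emulate, and the numerical conventions a maintainer should know.

## The biological setting

Each haploid mammalian genome carries several hundred tandemly repeated
rDNA transcription units. Methylation of the rDNA promoter region silences
the unit, and the fraction of methylated units rises with age in somatic
tissues and — the focus of this package — in sperm. Two measurement layers
are modelled:

* **Bulk bisulfite pyrosequencing (BPS)** returns the mean methylation (β
  value, percent) of each CpG over millions of molecules. Four rDNA
  amplicons with 53 CpGs in total are tracked: upstream control element
  (UCE, 26 CpGs), core promoter (9), 18S (8), 28S (10).
* **Deep bisulfite sequencing (DBS)** returns the full methylation pattern
  of each individual molecule for two amplicons — region 1 in the external
  transcribed spacer (38 CpGs) and region 2 spanning UCE and core promoter
  (25 CpGs) — each containing an A/G variant that assigns every read to an
  allele class.

A molecule with more than half of its CpGs methylated is treated as an
epigenetically silenced unit ("epimutation"); the **epimutation rate** of a
read set is the percentage of such molecules. The threshold is strict: a
read at exactly 50% is not an epimutation.

## The single-molecule mixture model

DBS read sets are simulated from a two-component mixture. A molecule is
hypermethylated with probability $f_\mathrm{hyper}$, in which case each CpG
is methylated independently with probability $p_\mathrm{hyper}$; otherwise
each CpG is methylated with the background probability $p_\mathrm{bg}$.
Given a target sample mean methylation $m$ (as a fraction) and target
epimutation rate $e$, the parameters follow from

$$f_\mathrm{hyper} = e, \qquad
  p_\mathrm{bg} = \frac{m - f_\mathrm{hyper}\,p_\mathrm{hyper}}
                        {1 - f_\mathrm{hyper}},$$

so the mixture reconstructs $m$ exactly, and the expected epimutation rate
equals $f_\mathrm{hyper}$ up to the background tail probability
$P\{\mathrm{Bin}(n_\mathrm{CpG}, p_\mathrm{bg}) > n_\mathrm{CpG}/2\}$, which
`derive_mixture_preset()` reports. The default
$p_\mathrm{hyper} = 0.85$ keeps hypermethylated molecules unambiguously
above the 50% threshold while leaving that tail below $10^{-4}$ for every
built-in preset (the largest, for the heavily drifted old-donor region-2 A
cohort, is $8\times10^{-5}$).

Eight built-in presets parameterize the (region × variant × age class)
cohorts of the reference human sperm study; for example old-donor region-1
A alleles have mean 14.75% and ER 1.36%, young donors 7.92% and 0.32%. Two
dispersion modes exist:

* `"fixed"` — every sample of a cohort shares the cohort parameters. Used
  by the cohort-scale tests, because between-sample dispersion would make
  small-cohort ER ratios very noisy.
* `"dispersed"` — each sample re-derives its mixture from a mean-preserving
  Gaussian jitter of the target mean and ER, matched to the reported
  between-sample SDs; this emulates the epigenetic drift (wider scatter in
  old donors) visible in real cohorts.

Reads are simulated as single-end, full-length amplicons on the converted
top strand: PCR after bisulfite conversion fixes the strand, and the
paired-end chemistry of the real assay is a sequencing detail with no
analysis consequence here. Unmethylated and non-CpG cytosines convert C→T,
each failing independently with probability `conversion_failure` (default
0.005); substitution sequencing errors hit every base at rate `seq_error`
(default 0.001). PCR bias, chimeras, indels and paired-end overlap
artifacts are *not* simulated — so passing tests demonstrate correctness of
the analysis rules, not robustness to those artifacts.

Per-sample read depth defaults to a few thousand reads per allele
(2,000–5,000 in the shipped examples and tests); real per-sample DBS depth
is not published, and these values are chosen so that cohort-mean ER
estimates have standard errors well below the effects of interest.

## Read processing rules

* **Alignment.** Global Needleman–Wunsch (match +1, mismatch −1, linear gap
  −2) with the bisulfite asymmetry: read T opposite reference C scores as a
  match; the reverse (read C vs reference T) does not. Tie-breaking is
  deterministic (diagonal, then gap-in-reference, then gap-in-read). Global
  alignment is appropriate because amplicon reads span the reference.
  Reads scoring below `0.5 · L · match` are counted as unalignable. For
  speed, the batch caller first scores an equal-length read on the identity
  mapping and only falls back to the full dynamic program when ungapped
  bisulfite-aware identity drops below 90% — on amplicon data with
  substitution-dominated errors the two paths give identical calls, and
  the full DP remains the reference path for anything unusual.
* **Calling.** At a reference CpG cytosine: C → methylated, T →
  unmethylated, gap/other base → missing. At a non-CpG reference cytosine:
  T converted, C unconverted, gap/other excluded from the denominator
  (whether the original pipeline counted ambiguous bases in its conversion
  denominator is not documented; excluding them is the conservative
  choice). The conversion rate is the converted fraction of covered
  non-CpG cytosines, the standard proxy for bisulfite conversion
  completeness since mammalian non-CpG cytosines are essentially
  unmethylated.
* **QC.** A read passes if its conversion rate is **strictly** greater than
  0.95 (the strict ">95%" rule — a read at exactly 95% is rejected), at
  least 90% of reference CpGs received a call (`min_cpg_call_frac = 0.9`, a
  package choice: the conversion-rate rule says nothing about incomplete
  reads, and 90% keeps the per-read hypermethylation fraction
  meaningful), and the allele base is A or G. Rejection tallies partition
  the input by first matching reason (unaligned, no QC sites, low
  conversion, few CpG calls, undetermined allele).
* **Allele summaries.** The per-read methylation fraction uses called CpGs
  as its denominator (with ≥ 90% of CpGs called this is negligibly
  different from using all reference CpGs, and it matches the per-read
  logic elsewhere). Sample statistics are computed per sample; cohort
  statistics are unweighted means over samples, never over pooled reads.
  The ER denominator is the per-allele passing-read count; undetermined
  reads are tallied but excluded.

Quality strings are read but ignored: the processing rules reference only
conversion rate, so no quality trimming is applied.

## Cohort statistics

Partial correlations use the residual-regression form: correlate the OLS
residuals of $x$ and $y$ on the covariates, with $df = n - 2 - k$ for the
t-based p-value. (The precision-matrix form is algebraically identical and
serves as the independent oracle in the tests.) Confounders are adjusted
jointly by default. Missing values are handled pairwise-complete, with $n$
reported per result. No multiple-testing correction is applied — results
are raw per-amplicon p-values, mirroring how such cohort tables are
conventionally reported; apply `p.adjust` downstream if needed. The
parametric group test is Welch's unequal-variance t test; the
non-parametric one is the Mann–Whitney U.

Cross-species comparisons express age as a fraction of maximum life span:
human 80 years, bovine 20 years, marmoset 12 years, mouse 28 **months**
(mouse ages are supplied in months). Values above 1 simply mean a donor
beyond the nominal life span.

## The bulk cohort generator

$$\beta_{ij} = \mathrm{clip}\bigl(b_j + s_j\,\mathrm{age}_i + u_i +
  \varepsilon_{ij},\ 0,\ 100\bigr),\qquad
  u_i \sim N(0, \sigma_s^2),\ \varepsilon_{ij} \sim N(0, \sigma_c^2),$$

with cells masked missing completely at random. The shared offset $u_i$ is
the dominant noise term and is what limits any age predictor: it cannot be
averaged away across CpGs. Presets: `human_sperm` (n = 186, ages 25–66,
slope 0.33 %/yr for all rDNA regions) and `human_blood` (n = 188, ages
1–70, slope 0.06 %/yr), both with $\sigma_s = 2$, $\sigma_c = 1.5$
percentage points — moderate noise in the range of technical replicate
scatter for pyrosequencing. Baselines are region-level age-0 intercepts
chosen to put simulated values in realistic ranges (sperm rDNA low, ~2–20%;
blood higher, ~20–30%); they affect level, not slope. BMI and sperm
concentration are drawn independently of age, so they act as pure-noise
covariates unless the user constructs a confounded design explicitly (the
test suite does, as a positive control for the partial-correlation
adjustment).

With all noise at zero the generator is exactly linear in age — the
regression tests rely on this identity.

## The clock

The clock minimizes

$$\frac{1}{2n}\sum_i\Bigl(y_i - b_0 - \textstyle\sum_j x_{ij}b_j\Bigr)^2
 + \lambda\Bigl(\alpha\|b\|_1 + \tfrac{1-\alpha}{2}\|b\|_2^2\Bigr)$$

with $\alpha = 0.5$, predictors standardized internally (coefficients
reported on the original scale) and the response left in years. Fitting is
delegated to glmnet; note the convention that the penalty is applied on the
scale of predictors standardized to unit $1/n$ variance *and* of the
response scaled by its $1/n$ standard deviation, which is what makes
λ values comparable across cohorts — the test suite pins this down against
a hand-written coordinate-descent oracle. The λ path holds 100
log-spaced values descending four orders of magnitude from
$\lambda_{max} = \max_j |\langle x_{\cdot j}, y-\bar y\rangle|/(n\alpha)$.
Tenfold cross-validation (folds by seeded permutation, as equal as
possible, unstratified) selects the largest λ whose CV-MSE lies within one
standard error of the minimum — the conventional one-SE rule, which trades
a little training error for sparsity and stability. The chosen λ is
data-dependent and is not a reproducible constant.

Before fitting, samples with 10 or more missing values (of 53) are dropped
— the boundary is exact: 9 missing is kept, 10 dropped — and remaining gaps
are filled by KNN imputation with $k = 10$: distance is the root mean
squared difference over mutually observed CpGs, neighbour candidates are
restricted to samples with the target CpG observed, ties break by sample
order, and a sample sharing no observed CpG with any candidate falls back
to the CpG's overall mean (approximating the documented fallback of the
classical implementation). The procedure is fully deterministic.

Evaluation reports MSE (years²), MAD (median absolute difference, years) —
robust to the heavy-tailed errors typical of age prediction — and
Pearson's r between predicted and chronological age.

## Problem sizes and numerical choices

The cohort-scale tests and the acceptance script use the study-design
sizes: 23 samples per DBS cohort at 5,000 reads per allele (the full
eight-cohort run is ~1.8 million reads and takes well under a minute thanks
to the compiled batch caller), 186/188-sample bulk cohorts, and a
278-sample training cohort for the clock recovery check. Monte-Carlo
tolerances in the tests are derived from binomial standard errors at those
sizes plus the analytically known conversion-failure bias
(+`conversion_failure` · (100 − m) percentage points of apparent
methylation, ≈ +0.5 points at the default rate).

Other conventions: coordinates are 1-based throughout (idiomatic R);
generated β values are clipped to [0, 100]; all simulators accept a single
integer seed and are bit-reproducible given it; CSV outputs carry
`#`-prefixed provenance headers (package version, seed, thresholds) so
reruns are byte-identical.

## Known limitations

* The read simulator omits indels, PCR bias and chimeras; the aligner
  handles indels, but that path is exercised only by small synthetic cases.
* The mixture model treats CpGs within a molecule as independent given the
  component; real molecules show spatial correlation along the amplicon.
  Cohort-level means and ERs are insensitive to this, per-CpG co-methylation
  statistics would not be.
* The bulk generator's linear age model with Gaussian noise is a
  deliberately simple stand-in: it reproduces the regression structure
  (slopes, confounding, missingness) but not distributional quirks of real
  β values near their bounds.
* Clock performance on synthetic cohorts bounds what the pipeline can
  recover under the generator's assumptions; it is not an estimate of
  real-sperm prediction error.
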