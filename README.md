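# rdnaclock

DNA methylation of the ribosomal DNA (rDNA) transcription unit increases
with age in the mammalian male germline. `rdnaclock` packages the three
analysis layers needed to study this signal, together with a synthetic-data
generator that provides ground truth for every stage:

1. **Deep bisulfite sequencing (DBS) read processing.** Single-molecule
   amplicon reads are aligned to their reference with a bisulfite-aware
   Needleman–Wunsch aligner (a read `T` opposite a reference `C` scores as a
   match), CpGs are called per molecule, reads are filtered on a strict
   \>95% bisulfite conversion rate measured at non-CpG cytosines, and reads
   are split by the A/G variant inside the amplicon. Per allele the package
   reports mean methylation and the **epimutation rate (ER)**

   ER = 100 · #{reads with > 50% methylated CpGs} / #reads,

   i.e. the percentage of molecules dense enough in methylation to be
   considered epigenetically silenced. A read at exactly 50% does not count.

2. **Cohort statistics.** Regional means, Pearson/Spearman correlations,
   Pearson partial correlations (residual-regression form) to adjust
   age–methylation associations for confounders such as BMI and sperm
   concentration, Welch t / Mann–Whitney group comparisons, ER fold-changes,
   and cross-species life-span normalization (human 80 y, bovine 20 y,
   marmoset 12 y, mouse 28 mo).

3. **The sperm rDNA methylation clock.** An elastic-net age predictor
   (α = 0.5) over the 53 CpGs of the four bulk rDNA amplicons (UCE 26,
   promoter 9, 18S 8, 28S 10): samples with ≥ 10 missing values are
   dropped, the rest are completed by k-nearest-neighbour imputation
   (k = 10), and the penalty λ is chosen by tenfold cross-validation with
   the one-standard-error rule. Predicted age is the penalized linear
   predictor; performance is summarized as MSE, median absolute difference
   (MAD) and Pearson's r.

The simulators are first-class, tested code: single molecules are drawn from
a two-component mixture (background vs hypermethylated molecules) whose
parameters are derived from published cohort mean-methylation/ER pairs, then
pushed through bisulfite conversion with a configurable failure rate and
substitution sequencing errors; bulk cohorts follow a linear aging model
(sperm 0.33 %/yr, blood 0.06 %/yr presets) with sample- and CpG-level noise
and optional missingness.

## Worked example

```r
library(rdnaclock)

## 1. allele-specific methylation of one simulated old-donor sample
refs    <- builtin_amplicon_references()
presets <- dbs_presets("fixed")
simulate_dbs_sample(refs$region2,
                    preset_a = presets$region2_A_old,
                    preset_g = presets$region2_G_old,
                    n_reads_per_allele = 2000,
                    seed = 7, sample_id = "donor_57y")
#>   sample_id allele n_reads mean_methylation epimutation_rate n_hypermethylated
#> 1 donor_57y      A    1790             24.1             9.11               163
#> 2 donor_57y      G    1792             19.1             2.68                48
```

The A allele of rDNA region 2 is both more methylated (24.1% vs 19.1%) and
carries a ~3–4× higher epimutation rate than the G allele, as expected from
the old-donor presets; ~10% of reads were rejected by the conversion-rate
and allele QC.

```r
## 2. train and evaluate the methylation clock on synthetic cohorts
train <- simulate_bps_cohort(bps_cohort_preset("human_sperm", seed = 1,
                                               missing_rate = 0.02))
test  <- simulate_bps_cohort(bps_cohort_preset("human_sperm", seed = 2,
                                               n_samples = 100L,
                                               missing_rate = 0.02))
rownames(test$beta) <- paste0("T", rownames(test$beta))
res <- run_clock_pipeline(train$beta, train$meta$age,
                          test$beta, test$meta$age, seed = 3)
res$model
#> <clock_model> alpha=0.50 lambda=3.168, 24/53 features, intercept 12.67 years (n=186)
res$test_metrics
#> <clock_metrics> MSE 39.94, MAD 4.57 years, r 0.870
```

The one-SE rule keeps a sparse model (24 of 53 CpGs); on the held-out
cohort the clock predicts age with a median error of 4.6 years, close to
the noise floor implied by the generator's shared per-sample offset
(2 percentage points ÷ 0.33 %/yr ≈ 6 years of age-equivalent noise).

```r
## 3. confounder-adjusted age correlation
m  <- regional_mean(train$beta, rdna_regions()$promoter)
pc <- partial_corr(m, train$meta$age,
                   train$meta[, c("bmi", "sperm_concentration")])
#> partial r = 0.86 (df = 182, p = 6.14e-55)
relative_age(40, "human")
#> [1] 0.5
```

## Layout

- `R/` — simulators, reference/alignment/calling, allele summaries, cohort
  statistics, clock, pipeline drivers
- `src/align.cpp` — bisulfite-aware Needleman–Wunsch and the batch caller
- `vignettes/rdna-methylation-aging.Rmd` — model, assumptions, parameter
  choices and limitations
- `inst/extdata/` — the two synthetic amplicon references (FASTA + JSON)
- `tests/testthat/` — unit, property and cohort-scale tests with
  independent oracles
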