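#' Simulate and analyse one DBS sample
#'
#' Generates one heterozygous sample's reads (both alleles) from the given
#' presets, then runs alignment, methylation calling, QC filtering, allele
#' splitting and per-allele summarization.
#'
#' @param ref An [amplicon_reference()].
#' @param preset_a,preset_g Mixture presets for the two alleles.
#' @param n_reads_per_allele Reads per allele.
#' @param conversion_failure,seq_error Simulation error rates.
#' @param conv_threshold,min_cpg_call_frac QC thresholds.
#' @param seed Sample seed.
#' @param sample_id Sample label.
#' @return Data frame with one row per allele: `sample_id`, `allele`,
#'   `n_reads`, `mean_methylation`, `epimutation_rate`, plus QC counts.
#' @export
simulate_dbs_sample <- function(ref, preset_a, preset_g, n_reads_per_allele,
                                conversion_failure = 0.005,
                                seq_error = 0.001,
                                conv_threshold = 0.95,
                                min_cpg_call_frac = 0.9,
                                seed = NULL, sample_id = "sample") {
  ref <- prepare_reference(ref)
  sim <- simulate_dbs_reads(ref, preset_a, preset_g, n_reads_per_allele,
                            conversion_failure, seq_error, seed,
                            id_prefix = sample_id)
  if (length(sim$reads) == 0L) {
    stopf("sample '%s': no reads simulated", sample_id)
  }
  called <- call_reads(sim$reads, ref)
  smry <- summarize_sample(called, n_cpgs = length(ref$cpg_positions),
                           conv_threshold = conv_threshold,
                           min_cpg_call_frac = min_cpg_call_frac)
  rows <- lapply(smry$summaries, function(s) {
    data.frame(sample_id = sample_id, allele = s$allele, n_reads = s$n_reads,
               mean_methylation = s$mean_methylation,
               epimutation_rate = s$epimutation_rate,
               n_hypermethylated = s$n_hypermethylated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$n_rejected <- sum(smry$tally) - smry$tally[["passed"]]
  out
}

#' Run the full DBS simulation-and-analysis pipeline
#'
#' Simulates young- and old-donor cohorts for both rDNA DBS regions (each
#' sample heterozygous, carrying reads of the A and the G allele from the
#' region's allele-specific presets), processes every read set through the
#' calling/QC/allele-splitting pipeline, and reports per-sample allele
#' summaries plus a cohort-level report: per (region, variant, age class)
#' cohort means of methylation and epimutation rate, old/young epimutation
#' fold-changes per (region, variant), and the old-donor A/G epimutation
#' ratio in region 2.
#'
#' @param n_samples Samples per cohort (per region and age class).
#' @param n_reads_per_allele Reads simulated per allele per sample.
#' @param presets Preset list from [dbs_presets()].
#' @param references Reference list from [builtin_amplicon_references()].
#' @param conversion_failure,seq_error Simulation error rates.
#' @param conv_threshold,min_cpg_call_frac QC thresholds.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param out_dir Optional directory; when given, per-sample summaries and
#'   the cohort report are written as provenance-headed CSVs.
#' @return List with `samples` (per-sample per-allele data frame),
#'   `cohorts` (cohort-mean table), `er_old_young` (fold-change per
#'   region/variant), `er_region2_a_vs_g` (old-donor allele ratio) and
#'   `group_tests` (old-vs-young Mann-Whitney p per region/variant).
#' @export
run_dbs_pipeline <- function(n_samples = 23L, n_reads_per_allele = 5000L,
                             presets = dbs_presets("fixed"),
                             references = builtin_amplicon_references(),
                             conversion_failure = 0.005, seq_error = 0.001,
                             conv_threshold = 0.95, min_cpg_call_frac = 0.9,
                             seed = 1L, out_dir = NULL) {
  n_samples <- check_count(n_samples, "n_samples")
  seed <- as.integer(seed)
  rows <- list()
  sample_seed <- seed
  for (region in c("region1", "region2")) {
    ref <- references[[region]]
    for (age_class in c("young", "old")) {
      pa <- presets[[paste(region, "A", age_class, sep = "_")]]
      pg <- presets[[paste(region, "G", age_class, sep = "_")]]
      for (i in seq_len(n_samples)) {
        sample_seed <- sample_seed + 1L
        sid <- sprintf("%s_%s_%02d", region, age_class, i)
        r <- simulate_dbs_sample(ref, pa, pg, n_reads_per_allele,
                                 conversion_failure, seq_error,
                                 conv_threshold, min_cpg_call_frac,
                                 seed = sample_seed, sample_id = sid)
        r$region <- region
        r$age_class <- age_class
        rows[[sid]] <- r
      }
    }
  }
  samples <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  agg <- function(df) {
    data.frame(mean_methylation = mean(df$mean_methylation),
               mean_er = mean(df$epimutation_rate),
               n = nrow(df))
  }
  key <- interaction(samples$region, samples$allele, samples$age_class,
                     sep = "_", drop = TRUE)
  parts <- split(samples, key)
  cohorts <- do.call(rbind, lapply(names(parts), function(k) {
    cbind(data.frame(cohort = k, stringsAsFactors = FALSE), agg(parts[[k]]))
  }))

  cell <- function(region, allele, age_class) {
    samples[samples$region == region & samples$allele == allele &
              samples$age_class == age_class, ]
  }
  combos <- expand.grid(region = c("region1", "region2"),
                        allele = c("A", "G"), stringsAsFactors = FALSE)
  safe_ratio <- function(num, den) {
    tryCatch(er_ratio(num, den), error = function(cnd) NA_real_)
  }
  er_old_young <- vapply(seq_len(nrow(combos)), function(i) {
    safe_ratio(cell(combos$region[i], combos$allele[i], "old")$epimutation_rate,
               cell(combos$region[i], combos$allele[i], "young")$epimutation_rate)
  }, numeric(1))
  names(er_old_young) <- paste(combos$region, combos$allele, sep = "_")
  group_tests <- vapply(seq_len(nrow(combos)), function(i) {
    group_compare(cell(combos$region[i], combos$allele[i], "old")$epimutation_rate,
                  cell(combos$region[i], combos$allele[i], "young")$epimutation_rate,
                  test = "mannwhitney")$p
  }, numeric(1))
  names(group_tests) <- names(er_old_young)
  er_r2_ag <- safe_ratio(cell("region2", "A", "old")$epimutation_rate,
                         cell("region2", "G", "old")$epimutation_rate)

  result <- list(samples = samples, cohorts = cohorts,
                 er_old_young = er_old_young,
                 er_region2_a_vs_g = er_r2_ag,
                 group_tests = group_tests)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(seed = seed, n_samples = n_samples,
                 n_reads_per_allele = n_reads_per_allele,
                 conv_threshold = conv_threshold)
    write_table_with_provenance(samples, file.path(out_dir, "samples.csv"),
                                prov)
    write_table_with_provenance(cohorts, file.path(out_dir, "cohorts.csv"),
                                prov)
  }
  result
}

#' Run the clock training/evaluation pipeline
#'
#' Applies the sample-missingness QC and KNN imputation to the training
#' cohort, fits the elastic-net clock with cross-validated one-SE penalty
#' selection, then predicts and evaluates on both the training cohort and an
#' independent, non-overlapping test cohort.
#'
#' @param train_beta,test_beta Sample-by-CpG matrices (may contain `NA`).
#' @param train_ages,test_ages Chronological ages.
#' @param alpha,n_folds,seed,max_missing,k Clock hyperparameters, see
#'   [fit_clock()], [qc_filter_samples()], [knn_impute()].
#' @param lambda Optional penalty path override passed to [fit_clock()].
#' @param model_path Optional path; when given the fitted model is written
#'   as JSON.
#' @return List with `model`, `train_metrics`, `test_metrics`,
#'   `dropped_train` (QC-dropped sample ids) and `predictions` (data frame
#'   of cohort, sample id, age, predicted age).
#' @export
run_clock_pipeline <- function(train_beta, train_ages, test_beta, test_ages,
                               alpha = 0.5, n_folds = 10L, seed = 1L,
                               max_missing = 9L, k = 10L, lambda = NULL,
                               model_path = NULL) {
  overlap <- intersect(rownames(train_beta), rownames(test_beta))
  if (length(overlap)) {
    stopf("train/test leakage: shared sample id(s): %s",
          paste(overlap, collapse = ", "))
  }
  names(train_ages) <- rownames(train_beta)
  qc <- qc_filter_samples(train_beta, max_missing = max_missing)
  train_ages <- train_ages[rownames(qc$beta)]
  train_complete <- knn_impute(qc$beta, k = k)
  model <- fit_clock(train_complete, train_ages, alpha = alpha,
                     n_folds = n_folds, seed = seed, lambda = lambda)
  test_complete <- if (anyNA(test_beta)) knn_impute(test_beta, k = k)
                   else test_beta
  pred_train <- predict_age(model, train_complete)
  pred_test <- predict_age(model, test_complete)
  predictions <- rbind(
    data.frame(cohort = "train", sample_id = rownames(train_complete),
               age = unname(train_ages), predicted = unname(pred_train)),
    data.frame(cohort = "test", sample_id = rownames(test_complete),
               age = unname(test_ages), predicted = unname(pred_test)))
  if (!is.null(model_path)) write_clock_model(model, model_path)
  list(model = model,
       train_metrics = evaluate_clock(pred_train, train_ages),
       test_metrics = evaluate_clock(pred_test, test_ages),
       dropped_train = qc$dropped,
       predictions = predictions)
}
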