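#' Split passing read profiles by allele
#'
#' Partitions QC-passing reads by the base observed at the amplicon's A/G
#' variant. Partition sizes sum to the input size.
#'
#' @param profiles Profile data frame (QC-passing rows of [filter_reads()]).
#' @return Named list of row-index vectors, one per allele present.
#' @export
split_by_allele <- function(profiles) {
  if (nrow(profiles) == 0L) return(list())
  split(seq_len(nrow(profiles)), profiles$allele)
}

#' Per-read methylation fraction
#'
#' Fraction of called (non-missing) CpGs that are methylated. Missing calls
#' are excluded from the denominator; a read with zero called CpGs has no
#' defined fraction.
#'
#' @param calls Integer vector of CpG calls (1 methylated, 0 unmethylated,
#'   NA missing).
#' @return Fraction in `[0, 1]`.
#' @export
read_methylation_fraction <- function(calls) {
  n <- sum(!is.na(calls))
  if (n == 0L) stopf("methylation fraction undefined: no called CpGs")
  sum(calls == 1L, na.rm = TRUE) / n
}

#' Epimutation rate of a read set
#'
#' The percentage of reads whose methylated-CpG fraction strictly exceeds
#' 0.5; such hypermethylated molecules are treated as epigenetically
#' silenced rDNA units. A read at exactly 50% is not counted.
#'
#' @param meth_fraction Numeric vector of per-read methylation fractions.
#' @return Epimutation rate in percent.
#' @export
epimutation_rate <- function(meth_fraction) {
  if (length(meth_fraction) == 0L) stopf("epimutation rate undefined: no reads")
  if (anyNA(meth_fraction)) stopf("epimutation rate undefined: NA fractions")
  100 * sum(meth_fraction > 0.5) / length(meth_fraction)
}

#' Summarize one allele's reads
#'
#' Aggregates QC-passing reads of one allele into the allele summary used
#' throughout the cohort analyses: read count, mean methylation (mean over
#' reads of the per-read methylation fraction, in %), per-CpG mean
#' methylation (over non-missing calls; a CpG with no calls is reported
#' `NA`, not zero), hypermethylated-read count and epimutation rate.
#'
#' @param profiles Profile data frame rows for one allele.
#' @param calls Matching rows of the CpG call matrix.
#' @param allele Allele label stored in the summary.
#' @return List of class `allele_summary`: `allele`, `n_reads`,
#'   `mean_methylation`, `per_cpg_mean`, `n_hypermethylated`,
#'   `epimutation_rate`.
#' @export
allele_summary <- function(profiles, calls, allele = profiles$allele[1]) {
  if (nrow(profiles) == 0L) stopf("allele summary undefined: no reads")
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1L)
  stopifnot(nrow(calls) == nrow(profiles))
  fr <- profiles$meth_fraction
  n_hyper <- sum(fr > 0.5)
  n_called <- colSums(!is.na(calls))
  per_cpg <- ifelse(n_called > 0,
                    100 * colSums(calls == 1L, na.rm = TRUE) /
                      pmax(n_called, 1L),
                    NA_real_)
  structure(
    list(allele = allele,
         n_reads = nrow(profiles),
         mean_methylation = 100 * mean(fr),
         per_cpg_mean = per_cpg,
         n_hypermethylated = n_hyper,
         epimutation_rate = 100 * n_hyper / nrow(profiles)),
    class = "allele_summary")
}

#' @export
print.allele_summary <- function(x, ...) {
  cat(sprintf("<allele_summary> %s: %d reads, mean %.2f%%, ER %.2f%%\n",
              x$allele, x$n_reads, x$mean_methylation, x$epimutation_rate))
  invisible(x)
}

#' Summarize a sample's passing reads per allele
#'
#' Convenience wrapper: applies QC filtering, splits by allele and builds an
#' [allele_summary()] for each allele present.
#'
#' @param called Result of [call_reads()].
#' @param n_cpgs Number of reference CpGs.
#' @param conv_threshold,min_cpg_call_frac QC thresholds, see
#'   [filter_reads()].
#' @return List with `summaries` (named list of `allele_summary`), `tally`
#'   (QC tally) and `per_cpg` (matrix allele x CpG of per-CpG means, for
#'   heat-map export).
#' @export
summarize_sample <- function(called, n_cpgs, conv_threshold = 0.95,
                             min_cpg_call_frac = 0.9) {
  flt <- filter_reads(called$profiles, n_cpgs = n_cpgs,
                      conv_threshold = conv_threshold,
                      min_cpg_call_frac = min_cpg_call_frac)
  keep <- which(flt$passed)
  prof <- flt$profiles[keep, , drop = FALSE]
  calls <- called$calls[keep, , drop = FALSE]
  idx <- split_by_allele(prof)
  summaries <- lapply(names(idx), function(al) {
    allele_summary(prof[idx[[al]], , drop = FALSE],
                   calls[idx[[al]], , drop = FALSE], al)
  })
  names(summaries) <- names(idx)
  per_cpg <- do.call(rbind, lapply(summaries, function(s) s$per_cpg_mean))
  list(summaries = summaries, tally = flt$tally, per_cpg = per_cpg)
}
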