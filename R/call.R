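#' Bisulfite-aware global alignment of one read
#'
#' Needleman-Wunsch global alignment in which a read T opposite a reference C
#' scores as a match (the bisulfite asymmetry: unmethylated cytosines are
#' read as T), with standard match/mismatch/linear-gap scoring otherwise and
#' deterministic tie-breaking (diagonal, then gap-in-reference, then
#' gap-in-read).
#'
#' @param read Read sequence (non-empty A/C/G/T string).
#' @param ref An [amplicon_reference()] (or plain reference string).
#' @param match,mismatch,gap Alignment scores (defaults +1/-1/-2).
#' @param score_floor Minimum score below which the read is flagged
#'   unalignable; defaults to half the maximum attainable score.
#' @return List with `score`, `ref_to_read` (for each reference position,
#'   the 1-based read position aligned to it, `NA` where the reference base
#'   is deleted in the read) and `aligned` (whether `score >= score_floor`).
#' @export
align_read <- function(read, ref, match = 1, mismatch = -1, gap = -2,
                       score_floor = NULL) {
  if (!is.character(read) || length(read) != 1L || nchar(read) == 0L) {
    stopf("`read` must be a non-empty sequence string")
  }
  refseq <- if (inherits(ref, "amplicon_reference")) ref$sequence else ref
  if (is.null(score_floor)) score_floor <- 0.5 * nchar(refseq) * match
  aln <- nw_align_cpp(toupper(read), toupper(refseq), match, mismatch, gap)
  aln$aligned <- aln$score >= score_floor
  aln
}

#' Call a per-read methylation profile from an alignment
#'
#' At each reference CpG cytosine the aligned read base is interpreted as
#' C = methylated, T = unmethylated, gap or any other base = missing. At each
#' non-CpG reference cytosine, T counts as converted and C as unconverted
#' (gaps and other bases are excluded from the denominator); the read's
#' bisulfite conversion rate is `n_converted / n_noncpg_c_sites`. The allele
#' is the read base aligned to the variant position if it is A or G,
#' otherwise `undetermined`.
#'
#' @param alignment Result of [align_read()].
#' @param read The read sequence that was aligned.
#' @param ref A prepared [amplicon_reference()].
#' @param read_id Identifier stored in the profile.
#' @return A one-row data frame (class `read_profile` rows): `read_id`,
#'   `allele`, `n_called_cpgs`, `n_meth_cpgs`, `meth_fraction`,
#'   `n_noncpg_c_sites`, `n_converted`, `conversion_rate`, `aligned`, plus a
#'   `cpg_calls` attribute column stored as list (1 methylated,
#'   0 unmethylated, NA missing).
#' @export
call_read_profile <- function(alignment, read, ref, read_id = "read") {
  ref <- prepare_reference(ref)
  rd <- strsplit(toupper(read), "")[[1]]
  map <- alignment$ref_to_read
  base_at <- function(pos) {
    rp <- map[pos]
    if (is.na(rp)) NA_character_ else rd[rp]
  }
  cpg_b <- vapply(ref$cpg_positions, base_at, character(1))
  calls <- ifelse(is.na(cpg_b), NA_integer_,
                  ifelse(cpg_b == "C", 1L, ifelse(cpg_b == "T", 0L,
                                                  NA_integer_)))
  ncb <- vapply(ref$noncpg_c_positions, base_at, character(1))
  n_sites <- sum(ncb %in% c("C", "T"))
  n_conv <- sum(ncb %in% "T")
  vb <- base_at(ref$variant_position)
  allele <- if (!is.na(vb) && vb %in% c("A", "G")) vb else "undetermined"
  prof <- data.frame(
    read_id = read_id, allele = allele,
    n_called_cpgs = sum(!is.na(calls)),
    n_meth_cpgs = sum(calls == 1L, na.rm = TRUE),
    meth_fraction = if (sum(!is.na(calls)) > 0) {
      sum(calls == 1L, na.rm = TRUE) / sum(!is.na(calls))
    } else NA_real_,
    n_noncpg_c_sites = n_sites, n_converted = n_conv,
    conversion_rate = if (n_sites > 0) n_conv / n_sites else NA_real_,
    aligned = isTRUE(alignment$aligned),
    stringsAsFactors = FALSE)
  prof$cpg_calls <- list(calls)
  prof
}

#' Batch per-read methylation calling
#'
#' Aligns and calls every read against one amplicon reference. Equal-length
#' reads whose ungapped bisulfite-aware identity is at least
#' `fastpath_identity` are called on the identity mapping; all other reads go
#' through the full global alignment. Reads scoring below `score_floor` are
#' flagged unalignable and receive no calls.
#'
#' @param reads Named character vector of read sequences.
#' @param ref An [amplicon_reference()].
#' @param match,mismatch,gap,score_floor As in [align_read()].
#' @param fastpath_identity Minimum ungapped identity for the fast path.
#' @return List with `profiles` (data frame, one row per read: `read_id`,
#'   `allele`, `n_called_cpgs`, `n_meth_cpgs`, `meth_fraction`,
#'   `n_noncpg_c_sites`, `n_converted`, `conversion_rate`, `aligned`,
#'   `score`) and `calls` (integer matrix reads x CpGs; 1/0/NA).
#' @export
call_reads <- function(reads, ref, match = 1, mismatch = -1, gap = -2,
                       score_floor = NULL, fastpath_identity = 0.9) {
  ref <- prepare_reference(ref)
  if (length(reads) == 0L) {
    return(list(profiles = data.frame(), calls = matrix(integer(0), 0, 0)))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  res <- call_reads_cpp(unname(reads), ref$sequence, ref$cpg_positions,
                        ref$noncpg_c_positions, ref$variant_position,
                        match, mismatch, gap,
                        if (is.null(score_floor)) NA_real_ else score_floor,
                        fastpath_identity)
  calls <- res$calls
  rownames(calls) <- names(reads)
  colnames(calls) <- paste0("CpG", seq_along(ref$cpg_positions))
  n_called <- rowSums(!is.na(calls))
  n_meth <- rowSums(calls == 1L, na.rm = TRUE)
  profiles <- data.frame(
    read_id = names(reads),
    allele = res$allele,
    n_called_cpgs = n_called,
    n_meth_cpgs = n_meth,
    meth_fraction = ifelse(n_called > 0, n_meth / n_called, NA_real_),
    n_noncpg_c_sites = res$n_noncpg_c_sites,
    n_converted = res$n_converted,
    conversion_rate = ifelse(res$n_noncpg_c_sites > 0,
                             res$n_converted / res$n_noncpg_c_sites,
                             NA_real_),
    score = res$score,
    aligned = res$aligned,
    stringsAsFactors = FALSE)
  rownames(profiles) <- NULL
  list(profiles = profiles, calls = calls)
}

#' Filter read profiles by conversion and coverage QC
#'
#' Retains reads with a bisulfite conversion rate strictly above
#' `conv_threshold` (the standard rule for this assay: only reads with an overall
#' conversion rate of more than 95% are considered; a read at exactly the
#' threshold is rejected), a called-CpG fraction of at least
#' `min_cpg_call_frac`, and a determined (A or G) allele. Reads with no
#' conversion-QC sites fail with reason `no_qc_sites`.
#'
#' @param profiles Profile data frame from [call_reads()].
#' @param n_cpgs Number of reference CpGs (used for the call-fraction rule);
#'   inferred from the profiles when `NULL` via
#'   `max(n_called_cpgs)`.
#' @param conv_threshold Conversion-rate threshold (strict `>`).
#' @param min_cpg_call_frac Minimum fraction of reference CpGs with a call.
#' @return List with `passed` (logical vector), `profiles` (input plus
#'   `passed_qc` and `rejection_reason` columns) and `tally` (named counts:
#'   `passed`, `unaligned`, `no_qc_sites`, `low_conversion`, `few_cpg_calls`,
#'   `undetermined_allele`). Rejection reasons are assigned in that order and
#'   partition the input: `passed + rejected = total`.
#' @export
filter_reads <- function(profiles, n_cpgs = NULL, conv_threshold = 0.95,
                         min_cpg_call_frac = 0.9) {
  reasons <- c("unaligned", "no_qc_sites", "low_conversion",
               "few_cpg_calls", "undetermined_allele")
  if (nrow(profiles) == 0L) {
    tally <- setNames(integer(length(reasons) + 1L), c("passed", reasons))
    return(list(passed = logical(0),
                profiles = profiles, tally = tally))
  }
  if (is.null(n_cpgs)) n_cpgs <- max(profiles$n_called_cpgs)
  reason <- rep(NA_character_, nrow(profiles))
  reason[!profiles$aligned] <- "unaligned"
  no_qc <- is.na(reason) & profiles$n_noncpg_c_sites == 0L
  reason[no_qc] <- "no_qc_sites"
  low_conv <- is.na(reason) & profiles$conversion_rate <= conv_threshold
  reason[low_conv] <- "low_conversion"
  few <- is.na(reason) &
    profiles$n_called_cpgs < min_cpg_call_frac * n_cpgs
  reason[few] <- "few_cpg_calls"
  und <- is.na(reason) & profiles$allele == "undetermined"
  reason[und] <- "undetermined_allele"
  passed <- is.na(reason)
  tally <- c(passed = sum(passed),
             vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                    integer(1)))
  profiles$passed_qc <- passed
  profiles$rejection_reason <- reason
  list(passed = passed, profiles = profiles, tally = tally)
}
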