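#' Derive a two-component methylation mixture preset
#'
#' Single sperm DNA molecules are modelled as a two-component mixture: a
#' fraction `f_hyper` of molecules is hypermethylated (per-CpG methylation
#' probability `p_hyper`) and the remainder is background (per-CpG
#' probability `p_bg`). Given a target sample-level mean methylation and a
#' target epimutation rate (the percentage of molecules with >50% methylated
#' CpGs), the mixture parameters follow from
#' `f_hyper = target_er / 100` and
#' `p_bg = (target_mean_meth/100 - f_hyper * p_hyper) / (1 - f_hyper)`,
#' so that `f_hyper * p_hyper + (1 - f_hyper) * p_bg` reconstructs the
#' target mean exactly. The returned preset also reports the background tail
#' probability `P(Binomial(n_cpgs, p_bg) > n_cpgs / 2)`, i.e. the chance a
#' background molecule is miscounted as an epimutation; for sensible presets
#' this is negligible so the expected epimutation rate equals `f_hyper`.
#'
#' @param target_mean_meth Target mean methylation, percent.
#' @param target_er Target epimutation rate, percent, in `[0, 100)`.
#' @param p_hyper Per-CpG methylation probability of a hypermethylated
#'   molecule. Default 0.85 keeps hypermethylated molecules unambiguously
#'   above the 50% threshold while leaving the background tail negligible.
#' @param n_cpgs Number of CpGs on the molecule.
#' @return An object of class `mixture_preset`: list with `f_hyper`, `p_bg`,
#'   `p_hyper`, `n_cpgs`, `target_mean_meth`, `target_er`, `bg_tail_prob`.
#' @export
derive_mixture_preset <- function(target_mean_meth, target_er,
                                  p_hyper = 0.85, n_cpgs) {
  if (!is.numeric(p_hyper) || p_hyper <= 0 || p_hyper > 1) {
    stopf("`p_hyper` must be in (0, 1]")
  }
  if (!is.numeric(target_er) || target_er < 0 || target_er >= 100) {
    stopf("`target_er` must be in [0, 100), got %s", format(target_er))
  }
  n_cpgs <- check_count(n_cpgs, "n_cpgs")
  f_hyper <- target_er / 100
  p_bg <- (target_mean_meth / 100 - f_hyper * p_hyper) / (1 - f_hyper)
  if (p_bg < 0 || p_bg > p_hyper) {
    stopf(paste0("invalid preset: target mean %.3f%% is incompatible with ",
                 "target ER %.3f%% at p_hyper = %.3f (implied p_bg = %.5f)"),
          target_mean_meth, target_er, p_hyper, p_bg)
  }
  preset <- structure(
    list(f_hyper = f_hyper, p_bg = p_bg, p_hyper = p_hyper,
         n_cpgs = n_cpgs, target_mean_meth = target_mean_meth,
         target_er = target_er,
         bg_tail_prob = pbinom(floor(n_cpgs / 2), n_cpgs, p_bg,
                               lower.tail = FALSE)),
    class = "mixture_preset")
  stopifnot(abs(preset$f_hyper * preset$p_hyper +
                  (1 - preset$f_hyper) * preset$p_bg -
                  target_mean_meth / 100) < 1e-12)
  preset
}

#' @export
print.mixture_preset <- function(x, ...) {
  cat(sprintf(paste0("<mixture_preset> n_cpgs=%d f_hyper=%.4f p_bg=%.4f ",
                     "p_hyper=%.2f (mean %.2f%%, ER %.2f%%, bg tail %.2g)\n"),
              x$n_cpgs, x$f_hyper, x$p_bg, x$p_hyper, x$target_mean_meth,
              x$target_er, x$bg_tail_prob))
  invisible(x)
}

# Reference DBS cohort summary statistics for human sperm donors: mean
# methylation (%) and epimutation rate (%) with between-sample SDs, by rDNA
# region, A/G variant and donor age class (young 26-36 y, old 43-60 y,
# 23 informative samples per class).
dbs_reference_stats <- function() {
  data.frame(
    region    = rep(c("region1", "region2"), each = 4L),
    variant   = rep(c("A", "A", "G", "G"), 2L),
    age_class = rep(c("young", "old"), 4L),
    n_cpgs    = rep(c(38L, 25L), each = 4L),
    meth_mean = c(7.92, 14.75, 7.92, 14.80, 11.47, 23.70, 9.30, 18.24),
    meth_sd   = c(1.24, 2.53, 1.22, 2.70, 2.95, 9.38, 1.19, 2.52),
    er_mean   = c(0.32, 1.36, 0.23, 1.00, 1.61, 9.52, 0.42, 2.30),
    er_sd     = c(0.75, 1.45, 0.49, 1.83, 1.96, 14.90, 0.66, 1.77),
    stringsAsFactors = FALSE
  )
}

#' Built-in DBS mixture presets
#'
#' Mixture presets for the eight (region, variant, age class) combinations of
#' the reference human sperm DBS cohorts, derived from the cohort mean
#' methylation and epimutation rates via [derive_mixture_preset()].
#'
#' In `"fixed"` dispersion mode every sample of a cohort shares the cohort
#' parameters; in `"dispersed"` mode each sample receives a mean-preserving
#' jitter of its target mean and ER matched to the reported between-sample
#' SDs, emulating the epigenetic drift visible in older donors.
#'
#' @param dispersion `"fixed"` or `"dispersed"`.
#' @param p_hyper Hypermethylated-molecule per-CpG probability.
#' @return Named list of presets keyed `region1_A_young`, ...; each preset
#'   additionally carries `region`, `variant`, `age_class`,
#'   `dispersion_mode`, `sample_sd_meth` and `sample_sd_er`.
#' @export
dbs_presets <- function(dispersion = c("fixed", "dispersed"),
                        p_hyper = 0.85) {
  dispersion <- match.arg(dispersion)
  stats <- dbs_reference_stats()
  out <- list()
  for (i in seq_len(nrow(stats))) {
    row <- stats[i, ]
    p <- derive_mixture_preset(row$meth_mean, row$er_mean, p_hyper, row$n_cpgs)
    p$region <- row$region
    p$variant <- row$variant
    p$age_class <- row$age_class
    p$dispersion_mode <- dispersion
    p$sample_sd_meth <- if (dispersion == "dispersed") row$meth_sd else 0
    p$sample_sd_er <- if (dispersion == "dispersed") row$er_sd else 0
    out[[paste(row$region, row$variant, row$age_class, sep = "_")]] <- p
  }
  out
}

# Per-sample realization of a preset. In fixed mode this is the preset
# itself; in dispersed mode the sample's target mean and ER are drawn around
# the cohort values (truncated to the feasible domain) and the mixture is
# re-derived. Uses the current RNG stream.
realize_sample_preset <- function(preset) {
  if (identical(preset$dispersion_mode, "dispersed")) {
    for (attempt in 1:50) {
      m <- rnorm(1, preset$target_mean_meth, preset$sample_sd_meth)
      e <- rnorm(1, preset$target_er, preset$sample_sd_er)
      e <- max(e, 0)
      m <- clip(m, 0.1, 99.9)
      ok <- tryCatch({
        p <- derive_mixture_preset(m, e, preset$p_hyper, preset$n_cpgs)
        TRUE
      }, error = function(cnd) FALSE)
      if (ok) {
        p$dispersion_mode <- "dispersed"
        return(p)
      }
    }
    stopf("could not realize a feasible dispersed-sample preset")
  }
  preset
}

#' Simulate single-molecule methylation states
#'
#' Draws `n_molecules` molecules from a mixture preset: each molecule is
#' hypermethylated with probability `f_hyper`, and its CpG states are then
#' independent Bernoulli draws with probability `p_hyper` (hypermethylated)
#' or `p_bg` (background).
#'
#' @param preset A [derive_mixture_preset()] object.
#' @param n_molecules Number of molecules.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return List with `meth` (binary `n_molecules x n_cpgs` matrix) and
#'   `truth` (data frame: `molecule_id`, `is_hyper`, `n_meth_cpgs`).
#' @export
simulate_molecules <- function(preset, n_molecules, seed = NULL) {
  if (!inherits(preset, "mixture_preset")) stopf("`preset` must be a mixture_preset")
  n_molecules <- check_count(n_molecules, "n_molecules")
  with_seed(seed, {
    is_hyper <- runif(n_molecules) < preset$f_hyper
    p <- ifelse(is_hyper, preset$p_hyper, preset$p_bg)
    meth <- matrix(rbinom(n_molecules * preset$n_cpgs, 1L,
                          rep(p, times = preset$n_cpgs)),
                   nrow = n_molecules, ncol = preset$n_cpgs)
    list(meth = meth,
         truth = data.frame(molecule_id = seq_len(n_molecules),
                            is_hyper = is_hyper,
                            n_meth_cpgs = rowSums(meth)))
  })
}

# Vectorized bisulfite read construction for one allele. Returns a character
# vector of reads plus per-read truth. Uses the current RNG stream.
build_reads <- function(ref, meth, allele, conversion_failure, seq_error,
                        id_prefix) {
  ref <- prepare_reference(ref)
  n <- nrow(meth)
  L <- nchar(ref$sequence)
  bases <- strsplit(ref$sequence, "")[[1]]
  mat <- matrix(rep(bases, each = n), nrow = n, ncol = L)

  # bisulfite conversion: non-CpG cytosines convert C->T unless conversion
  # fails; CpG cytosines convert only when unmethylated (again unless the
  # conversion fails)
  n_fail <- integer(n)
  for (q in ref$noncpg_c_positions) {
    fail <- runif(n) < conversion_failure
    mat[, q] <- ifelse(fail, "C", "T")
    n_fail <- n_fail + fail
  }
  for (k in seq_along(ref$cpg_positions)) {
    p <- ref$cpg_positions[k]
    fail <- runif(n) < conversion_failure
    mat[, p] <- ifelse(meth[, k] == 1L | fail, "C", "T")
    n_fail <- n_fail + (fail & meth[, k] == 0L)
  }
  mat[, ref$variant_position] <- allele

  # independent substitution sequencing errors
  if (seq_error > 0) {
    err <- which(runif(n * L) < seq_error)
    if (length(err)) {
      others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))
      cur <- mat[err]
      pick <- ceiling(runif(length(err)) * 3)
      mat[err] <- mapply(function(b, k) others[[b]][k], cur, pick,
                         USE.NAMES = FALSE)
    }
  }

  reads <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
  ids <- sprintf("%s:%s:%d", id_prefix, allele, seq_len(n))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, allele = allele,
                          is_hyper = NA, n_meth_cpgs = rowSums(meth),
                          n_conversion_failures = n_fail,
                          stringsAsFactors = FALSE))
}

#' Simulate a deep bisulfite sequencing read set
#'
#' Generates single-end full-length amplicon reads for both alleles of one
#' sample. Each read derives from one simulated molecule: methylated CpG
#' cytosines stay C, unmethylated CpG cytosines and all non-CpG cytosines
#' convert C to T (each failing independently with probability
#' `conversion_failure`, in which case the base stays C), the variant
#' position carries the allele base, and independent substitution errors are
#' applied at rate `seq_error`. Read names encode the sample prefix, allele
#' and molecule index so calls can be checked against the simulation truth.
#'
#' @param ref An [amplicon_reference()].
#' @param preset_a,preset_g Mixture presets for the A and G allele (either
#'   may be `NULL` to skip that allele).
#' @param n_reads_per_allele Reads per allele.
#' @param conversion_failure Per-cytosine probability that bisulfite
#'   conversion fails, in `[0, 1)`.
#' @param seq_error Per-base substitution error probability, in `[0, 1)`.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param id_prefix Prefix for read names.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame with per-read `allele`, `is_hyper`, `n_meth_cpgs`,
#'   `n_conversion_failures`).
#' @export
simulate_dbs_reads <- function(ref, preset_a, preset_g = NULL,
                               n_reads_per_allele,
                               conversion_failure = 0.005,
                               seq_error = 0.001,
                               seed = NULL, id_prefix = "sim") {
  check_probability(conversion_failure, "conversion_failure", allow_one = FALSE)
  check_probability(seq_error, "seq_error", allow_one = FALSE)
  n_reads_per_allele <- check_count(n_reads_per_allele, "n_reads_per_allele")
  ref <- prepare_reference(ref)
  with_seed(seed, {
    out_reads <- character(0)
    out_truth <- list()
    for (al in c("A", "G")) {
      preset <- if (al == "A") preset_a else preset_g
      if (is.null(preset)) next
      preset <- realize_sample_preset(preset)
      mol <- simulate_molecules(preset, n_reads_per_allele)
      b <- build_reads(ref, mol$meth, al, conversion_failure, seq_error,
                       id_prefix)
      b$truth$is_hyper <- mol$truth$is_hyper
      out_reads <- c(out_reads, b$reads)
      out_truth[[al]] <- b$truth
    }
    list(reads = out_reads, truth = do.call(rbind, out_truth))
  })
}

#' Write simulated reads as FASTQ
#'
#' Sanger-encoded FASTQ with a constant Q37 quality for every base (qualities
#' are not used downstream).
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(L) strrep("F", L), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readDNAStringSet(path, format = "fastq")
    setNames(as.character(s), names(s))
  } else {
    lines <- readLines(path)
    ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
    setNames(lines[seq(2, length(lines), by = 4)], ids)
  }
}
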