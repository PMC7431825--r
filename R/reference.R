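#' Amplicon reference for deep bisulfite sequencing
#'
#' Describes one bisulfite amplicon: its forward-strand sequence, the
#' positions of the CpG cytosines interrogated by the assay, and the position
#' of the single A/G variant used for allele splitting. All coordinates are
#' 1-based positions on `sequence`.
#'
#' Invariants checked at construction:
#' * every CpG position `p` satisfies `sequence[p] == "C"` and
#'   `sequence[p+1] == "G"`;
#' * CpG positions are strictly increasing;
#' * the variant position is neither a CpG cytosine nor the G of a CpG, and
#'   the reference base there is A or G (the variant must stay readable after
#'   bisulfite conversion, so it cannot involve a cytosine).
#'
#' @param name Amplicon name.
#' @param region Region label (e.g. `"ETS"`, `"UCE+promoter"`).
#' @param sequence Uppercase A/C/G/T string.
#' @param cpg_positions Integer vector, 1-based positions of CpG cytosines.
#' @param variant_position 1-based position of the A/G variant.
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(name, region, sequence, cpg_positions,
                               variant_position) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stopf("reference '%s': sequence contains non-ACGT characters", name)
  }
  cpg_positions <- as.integer(cpg_positions)
  variant_position <- as.integer(variant_position)
  L <- length(bases)
  if (any(cpg_positions < 1L) || any(cpg_positions >= L)) {
    stopf("reference '%s': CpG position out of range", name)
  }
  if (is.unsorted(cpg_positions, strictly = TRUE)) {
    stopf("reference '%s': cpg_positions must be strictly increasing", name)
  }
  for (p in cpg_positions) {
    if (bases[p] != "C" || bases[p + 1L] != "G") {
      stopf(paste0("reference '%s': position %d is not a CpG ",
                   "(found %s%s)"), name, p, bases[p], bases[p + 1L])
    }
  }
  if (variant_position < 1L || variant_position > L) {
    stopf("reference '%s': variant position out of range", name)
  }
  if (variant_position %in% cpg_positions ||
      (variant_position - 1L) %in% cpg_positions) {
    stopf("reference '%s': variant position %d overlaps a CpG",
          name, variant_position)
  }
  if (!bases[variant_position] %in% c("A", "G")) {
    stopf("reference '%s': base at variant position %d must be A or G",
          name, variant_position)
  }
  structure(
    list(name = name, region = region, sequence = sequence,
         cpg_positions = cpg_positions, variant_position = variant_position,
         variant_alleles = c("A", "G")),
    class = "amplicon_reference"
  )
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("<amplicon_reference> %s (%s): %d bp, %d CpGs, A/G variant at %d\n",
              x$name, x$region, nchar(x$sequence), length(x$cpg_positions),
              x$variant_position))
  invisible(x)
}

#' Annotate an amplicon reference for methylation calling
#'
#' Partitions the reference cytosines into the annotated CpG set and the
#' non-CpG cytosine set used for bisulfite conversion QC. Idempotent: calling
#' it on an already prepared reference returns it unchanged.
#'
#' @param ref An [amplicon_reference()].
#' @return The reference with added fields `noncpg_c_positions` (1-based) and
#'   class `prepared_reference`.
#' @export
prepare_reference <- function(ref) {
  if (inherits(ref, "prepared_reference")) return(ref)
  if (!inherits(ref, "amplicon_reference")) {
    stopf("`ref` must be an amplicon_reference")
  }
  # re-validate invariants so a hand-edited object fails loudly here
  ref <- amplicon_reference(ref$name, ref$region, ref$sequence,
                            ref$cpg_positions, ref$variant_position)
  bases <- strsplit(ref$sequence, "")[[1]]
  c_pos <- which(bases == "C")
  ref$noncpg_c_positions <- setdiff(c_pos, ref$cpg_positions)
  class(ref) <- c("prepared_reference", "amplicon_reference")
  ref
}

# Deterministic synthetic amplicon builder. Blocks of "CG" + filler are
# concatenated; fillers cycle so that roughly three of every four blocks
# carry one non-CpG cytosine (the conversion-QC sites), and the A/G variant
# sits mid-amplicon flanked by non-C bases so that neither allele can create
# or destroy a CpG.
build_synthetic_amplicon <- function(name, region, n_cpgs) {
  fillers <- c("TCAT", "ATCT", "TACT", "AATT")
  head_seq <- "AATGAT"
  tail_seq <- "TAGATT"
  var_block <- "TAATT"  # variant base is the 3rd char ('A' in the reference)
  half <- ceiling(n_cpgs / 2)

  pieces <- character(0)
  cpg_pos <- integer(0)
  pos <- nchar(head_seq)
  pieces <- c(pieces, head_seq)
  variant_position <- NA_integer_
  for (i in seq_len(n_cpgs)) {
    if (i == half + 1L) {
      variant_position <- pos + 3L
      pieces <- c(pieces, var_block)
      pos <- pos + nchar(var_block)
    }
    cpg_pos <- c(cpg_pos, pos + 1L)
    block <- paste0("CG", fillers[((i - 1L) %% length(fillers)) + 1L])
    pieces <- c(pieces, block)
    pos <- pos + nchar(block)
  }
  pieces <- c(pieces, tail_seq)
  amplicon_reference(name, region, paste(pieces, collapse = ""),
                     cpg_pos, variant_position)
}

#' Built-in synthetic rDNA amplicon references
#'
#' Two synthetic amplicons mirroring the geometry of the deep bisulfite
#' sequencing assays: region 1 covers the external transcribed spacer with 38
#' CpGs, region 2 the upstream control element plus core promoter with 25
#' CpGs, each carrying one internal A/G variant. The sequences are synthetic
#' (deterministically constructed, not genomic rDNA) but preserve the
#' features the analysis depends on: annotated CpGs, abundant non-CpG
#' cytosines for conversion QC, and a variant position that is readable after
#' bisulfite conversion.
#'
#' @return Named list with elements `region1` and `region2`, each an
#'   [amplicon_reference()].
#' @export
builtin_amplicon_references <- function() {
  list(
    region1 = build_synthetic_amplicon("rDNA_region1_synthetic", "ETS", 38L),
    region2 = build_synthetic_amplicon("rDNA_region2_synthetic",
                                       "UCE+promoter", 25L)
  )
}

#' Read an amplicon reference from FASTA + JSON annotation
#'
#' @param fasta Path to a single-record FASTA file.
#' @param annot Path to a JSON file with fields `name`, `region`,
#'   `cpg_positions`, `variant_position` (1-based).
#' @return An [amplicon_reference()].
#' @export
load_amplicon_reference <- function(fasta, annot) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stopf("load_amplicon_reference() requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stopf("expected exactly one FASTA record")
  a <- jsonlite::read_json(annot, simplifyVector = TRUE)
  amplicon_reference(a$name, a$region, as.character(seqs[[1]]),
                     a$cpg_positions, a$variant_position)
}

#' Write an amplicon reference as FASTA + JSON annotation
#'
#' @param ref An [amplicon_reference()].
#' @param fasta,annot Output paths.
#' @return Invisibly, `c(fasta, annot)`.
#' @export
write_amplicon_reference <- function(ref, fasta, annot) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stopf("write_amplicon_reference() requires the Biostrings package")
  }
  s <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(s, fasta)
  jsonlite::write_json(
    list(name = ref$name, region = ref$region,
         cpg_positions = ref$cpg_positions,
         variant_position = ref$variant_position),
    annot, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fasta, annot))
}
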