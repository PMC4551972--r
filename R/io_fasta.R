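#' Aligned mtDNA haplotype sequences
#'
#' Container for an alignment of equal-length nucleotide sequences with a
#' region label per sequence, used by the mtDNA diversity and differentiation
#' statistics.
#'
#' @param sequences character vector of equal-length nucleotide strings
#'   (A/C/G/T/N/-, case-insensitive).
#' @param sequence_ids character vector of ids.
#' @param region_id character vector of region labels (may be `NA`).
#' @return an object of class `haplotype_alignment`: list with `seq` (an
#'   uppercase character matrix, sequences in rows), `ids`, `region`.
#' @export
haplotype_alignment <- function(sequences, sequence_ids = NULL, region_id = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("empty alignment")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    bad <- which(nchar(sequences) != stats::median(nchar(sequences)))
    stop("sequences are not aligned (unequal lengths): ",
         paste(if (is.null(sequence_ids)) bad else sequence_ids[bad],
               collapse = ", "))
  }
  if (len == 0L) stop("alignment length is zero")
  if (is.null(sequence_ids)) sequence_ids <- paste0("seq", seq_along(sequences))
  if (is.null(region_id)) region_id <- rep(NA_character_, length(sequences))
  m <- t(vapply(strsplit(sequences, ""), identity, character(len)))
  bad <- !(m %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad))
    stop("invalid nucleotide symbol(s): ", paste(unique(m[bad]), collapse = ", "))
  rownames(m) <- sequence_ids
  structure(list(seq = m, ids = as.character(sequence_ids),
                 region = as.character(region_id)),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment:", nrow(x$seq), "sequences x", ncol(x$seq), "bp\n")
  if (!all(is.na(x$region)))
    cat("  regions:", paste(unique(stats::na.omit(x$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences must all have the same length. The region label is parsed from
#' the FASTA header using the convention `>id|region`; headers without a `|`
#' get an `NA` region (supply `region_id` explicitly instead).
#'
#' @param path FASTA path.
#' @param region_id optional explicit region labels overriding the header
#'   convention, recycled if length 1.
#' @return a [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path, region_id = NULL) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path)
  seqs <- vapply(as.character(dna), paste, character(1L), collapse = "")
  hdr <- names(dna)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  ids <- trimws(vapply(parts, `[`, character(1L), 1L))
  reg <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2L]) else NA_character_,
                character(1L))
  if (!is.null(region_id)) {
    reg <- rep_len(as.character(region_id), length(seqs))
  }
  haplotype_alignment(seqs, ids, reg)
}

#' Write an aligned FASTA file with `>id|region` headers
#' @param alignment a [haplotype_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  hdr <- ifelse(is.na(alignment$region), alignment$ids,
                paste(alignment$ids, alignment$region, sep = "|"))
  seqs <- apply(alignment$seq, 1L, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", hdr), seqs)), path)
  invisible(path)
}

#' Generate a toy Hardy-Weinberg genotype dataset
#'
#' Draws diploid genotypes under Hardy-Weinberg equilibrium within each
#' population from specified per-locus allele-frequency vectors; the simplest
#' fixture for exercising every statistic without real data. Allele states are
#' the integers `1..k` for a frequency vector of length `k`.
#'
#' @param allele_freqs list (per locus) of numeric frequency vectors, each
#'   summing to 1; or a single vector, recycled over `n_loci`.
#' @param n_per_pop integer vector: individuals per population; population
#'   labels become `pop1`, `pop2`, ... (used as `reef_id`).
#' @param seed integer RNG seed; same seed gives an identical dataset.
#' @param n_loci number of loci when `allele_freqs` is a single vector.
#' @param region_id optional region label per population (defaults to the
#'   population label, so region-level grouping is available).
#' @return a [genotype_dataset()].
#' @export
make_toy_fixture <- function(allele_freqs, n_per_pop, seed = 1L,
                             n_loci = NULL, region_id = NULL) {
  if (!is.list(allele_freqs)) {
    if (is.null(n_loci)) n_loci <- 1L
    allele_freqs <- rep(list(allele_freqs), n_loci)
  }
  for (f in allele_freqs) {
    if (any(f < 0)) stop("negative allele frequencies")
    if (abs(sum(f) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  }
  L <- length(allele_freqs)
  npop <- length(n_per_pop)
  pop_labels <- paste0("pop", seq_len(npop))
  if (is.null(region_id)) region_id <- pop_labels
  n <- sum(n_per_pop)
  set.seed(seed)
  alleles <- matrix(NA_integer_, n, 2L * L)
  reef <- rep(pop_labels, n_per_pop)
  region <- rep(region_id, n_per_pop)
  for (l in seq_len(L)) {
    f <- allele_freqs[[l]]
    k <- length(f)
    a <- sample.int(k, 2L * n, replace = TRUE, prob = f)
    alleles[, 2L * l - 1L] <- a[seq_len(n)]
    alleles[, 2L * l] <- a[n + seq_len(n)]
  }
  genotype_dataset(alleles, paste0("loc", seq_len(L)),
                   paste0("ind", seq_len(n)), reef, region)
}
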