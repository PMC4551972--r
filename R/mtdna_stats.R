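# Haplotype-level diversity and differentiation for aligned mtDNA sequences.
# Columns containing N or a gap in any sequence are excluded listwise: the
# haplotype definition, segregating sites, pi and Fst all operate on the
# complete columns only.

.complete_columns <- function(aln) {
  keep <- apply(aln$seq, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  which(keep)
}

#' Collapse an alignment into a haplotype table
#'
#' Identical sequences (over complete columns, i.e. columns free of N and
#' gaps in every sequence) are collapsed into haplotypes; segregating and
#' parsimony-informative sites are counted over the same columns.
#'
#' @param alignment a [haplotype_alignment()].
#' @return object of class `haplotype_table`: list with `haplotype` (integer
#'   haplotype index per sequence), `counts` (overall haplotype counts),
#'   `by_region` (region x haplotype count matrix, if regions present),
#'   `n_haplotypes`, `n_segregating`, `n_informative`, `n_complete_sites`.
#' @export
collapse_haplotypes <- function(alignment) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  cols <- .complete_columns(alignment)
  if (!length(cols))
    stop("no complete (gap- and N-free) columns in the alignment")
  m <- alignment$seq[, cols, drop = FALSE]
  key <- apply(m, 1L, paste, collapse = "")
  hap <- match(key, unique(key))
  counts <- as.vector(table(factor(hap, levels = seq_len(max(hap)))))
  seg <- 0L; inf <- 0L
  for (j in seq_len(ncol(m))) {
    tb <- table(m[, j])
    if (length(tb) >= 2L) {
      seg <- seg + 1L
      if (sum(tb >= 2L) >= 2L) inf <- inf + 1L
    }
  }
  by_region <- NULL
  if (!all(is.na(alignment$region)))
    by_region <- table(alignment$region, hap)
  structure(list(haplotype = hap, counts = counts, by_region = by_region,
                 n_haplotypes = max(hap), n_segregating = seg,
                 n_informative = inf, n_complete_sites = ncol(m),
                 region = alignment$region),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotype), "sequences,",
      x$n_haplotypes, "haplotypes\n")
  cat("  segregating sites:", x$n_segregating,
      "( parsimony informative:", x$n_informative, ") over",
      x$n_complete_sites, "complete sites\n")
  invisible(x)
}

#' Haplotype diversity h
#'
#' `h = n (1 - sum p_i^2) / (n - 1)`: the sample-corrected probability that
#' two randomly drawn sequences carry different haplotypes.
#'
#' @param table a [collapse_haplotypes()] result.
#' @param by_region also compute per region (default when regions present).
#' @return data.frame with `group` (`"overall"` plus regions), `n`,
#'   `n_haplotypes`, `h` (`NA` where n < 2).
#' @export
haplotype_diversity <- function(table, by_region = !is.null(table$by_region)) {
  stopifnot(inherits(table, "haplotype_table"))
  hdiv <- function(cnt) {
    n <- sum(cnt)
    if (n < 2L) return(NA_real_)
    p <- cnt / n
    n * (1 - sum(p^2)) / (n - 1)
  }
  out <- data.frame(group = "overall", n = length(table$haplotype),
                    n_haplotypes = table$n_haplotypes, h = hdiv(table$counts))
  if (by_region && !is.null(table$by_region)) {
    for (rg in rownames(table$by_region)) {
      cnt <- table$by_region[rg, ]
      out <- rbind(out, data.frame(group = rg, n = sum(cnt),
                                   n_haplotypes = sum(cnt > 0),
                                   h = hdiv(cnt)))
    }
  }
  out
}

#' Nucleotide diversity pi
#'
#' Mean pairwise proportion of differing sites over the complete (gap- and
#' N-free) columns of the alignment, per group and overall.
#'
#' @param alignment a [haplotype_alignment()].
#' @param grouping optional label vector (defaults to the alignment regions).
#' @return data.frame `group`, `n`, `pi`.
#' @export
nucleotide_diversity <- function(alignment, grouping = NULL) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  cols <- .complete_columns(alignment)
  if (!length(cols)) stop("no complete columns in alignment")
  m <- alignment$seq[, cols, drop = FALSE]
  if (is.null(grouping)) grouping <- alignment$region
  pi_of <- function(idx) {
    n <- length(idx)
    if (n < 2L) return(NA_real_)
    tot <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      tot <- tot + sum(m[idx[i], ] != m[idx[j], ])
    tot / choose(n, 2) / ncol(m)
  }
  out <- data.frame(group = "overall", n = nrow(m), pi = pi_of(seq_len(nrow(m))))
  if (!all(is.na(grouping))) {
    for (rg in unique(stats::na.omit(grouping))) {
      idx <- which(grouping == rg)
      out <- rbind(out, data.frame(group = rg, n = length(idx), pi = pi_of(idx)))
    }
  }
  out
}

# haploid single-locus variance-components Fst on haplotype frequencies
.haploid_fst <- function(counts) {
  # counts: groups x haplotypes matrix
  n_i <- rowSums(counts)
  r <- nrow(counts)
  N <- sum(n_i)
  p <- counts / n_i
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  pbar <- colSums(counts) / N
  msp <- colSums(n_i * (p - rep(pbar, each = r))^2) / (r - 1)
  msg <- colSums(n_i * p * (1 - p)) / (N - r)
  sa <- (msp - msg) / nc
  den <- sum(sa + msg)
  if (den == 0) return(0)
  sum(sa) / den
}

#' Pairwise mtDNA Fst between regions
#'
#' Haplotype-frequency-based Fst (variance-partition estimator treating the
#' haplotypes as alleles of one haploid multi-allelic locus), with a
#' permutation p-value obtained by shuffling sequences across the two
#' regions.
#'
#' @param alignment a [haplotype_alignment()] with region labels.
#' @param n_perm permutations per pair.
#' @param seed RNG seed.
#' @return list with matrices `fst` and `p` (regions x regions; diagonal 0/NA).
#' @export
mtdna_pairwise_fst <- function(alignment, n_perm = 999L, seed = 1L) {
  tab <- collapse_haplotypes(alignment)
  region <- alignment$region
  if (all(is.na(region))) stop("alignment has no region labels")
  sizes <- table(region)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding region(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(region %in% small) & !is.na(region)
  } else keep <- !is.na(region)
  hap <- tab$haplotype[keep]
  region <- region[keep]
  lv <- unique(region)
  if (length(lv) < 2L) stop("need at least 2 regions with n >= 2")
  fst <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  set.seed(seed)
  H <- max(hap)
  for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1L):length(lv)) {
    sel <- region %in% lv[c(i, j)]
    hh <- hap[sel]; gg <- factor(region[sel], levels = lv[c(i, j)])
    cnt <- unclass(table(gg, factor(hh, levels = seq_len(H))))
    obs <- .haploid_fst(cnt)
    cntp <- 0L
    for (b in seq_len(n_perm)) {
      gp <- gg[sample.int(length(gg))]
      v <- .haploid_fst(unclass(table(gp, factor(hh, levels = seq_len(H)))))
      if (v >= obs) cntp <- cntp + 1L
    }
    fst[i, j] <- fst[j, i] <- obs
    pmat[i, j] <- pmat[j, i] <- (cntp + 1) / (n_perm + 1)
  }
  list(fst = fst, p = pmat)
}
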