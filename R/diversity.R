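# Per-locus allele bookkeeping shared by the diversity and differentiation
# estimators. Missing genotypes are dropped pairwise per locus: a group's
# sample size n_i at a locus counts called individuals only.

# allele frequency / heterozygote-carrier tables for one locus
# returns p (G x A allele freqs), h (G x A proportion of individuals
# heterozygous AND carrying allele a), n (called individuals per group),
# vals (allele states)
.locus_tab <- function(a1, a2, g) {
  called <- !is.na(a1)
  G <- nlevels(g)
  n_i <- as.vector(rowsum(as.numeric(called), g, reorder = FALSE))
  vals <- sort(unique(c(a1[called], a2[called])))
  A <- length(vals)
  if (A == 0L)
    return(list(p = matrix(0, G, 0), h = matrix(0, G, 0), n = n_i, vals = vals))
  gi <- as.integer(g)[called]
  i1 <- match(a1[called], vals)
  i2 <- match(a2[called], vals)
  cnt <- matrix(tabulate((i1 - 1L) * G + gi, G * A) +
                tabulate((i2 - 1L) * G + gi, G * A), G, A)
  het <- i1 != i2
  hcnt <- matrix(tabulate((i1[het] - 1L) * G + gi[het], G * A) +
                 tabulate((i2[het] - 1L) * G + gi[het], G * A), G, A)
  p <- cnt / pmax(2 * n_i, 1)
  h <- hcnt / pmax(n_i, 1)
  dimnames(p) <- dimnames(h) <- list(levels(g), vals)
  list(p = p, h = h, n = n_i, vals = vals)
}

#' Allele frequencies by group
#'
#' Per-group, per-locus allele frequencies with the called sample sizes they
#' are based on (missing genotypes removed pairwise per locus). A group with
#' zero called genotypes at a locus is flagged absent (`NA` frequencies, n=0).
#'
#' @param dataset a [genotype_dataset()].
#' @param grouping `"reef"`, `"region"`, or a label vector over individuals.
#' @return data.frame with columns `locus`, `group`, `allele`, `freq`,
#'   `n_called`.
#' @export
allele_freqs <- function(dataset, grouping = "reef") {
  g <- .resolve_grouping(dataset, grouping)
  if (any(table(g) == 0L)) stop("empty group in grouping")
  out <- vector("list", length(dataset$loci))
  for (l in seq_along(dataset$loci)) {
    al <- .locus_cols(dataset, l)
    tab <- .locus_tab(al[, 1L], al[, 2L], g)
    if (length(tab$vals) == 0L) {
      out[[l]] <- data.frame(locus = dataset$loci[l], group = levels(g),
                             allele = NA_integer_, freq = NA_real_,
                             n_called = 0)
      next
    }
    df <- expand.grid(group = levels(g), allele = tab$vals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$freq <- as.vector(tab$p)
    df$n_called <- tab$n[match(df$group, levels(g))]
    df$freq[df$n_called == 0] <- NA_real_  # absent: no called genotypes
    df <- cbind(locus = dataset$loci[l], df)
    out[[l]] <- df
  }
  do.call(rbind, out)
}

#' Observed and unbiased expected heterozygosity
#'
#' `H_O` is the fraction of heterozygous called genotypes; `H_E` is Nei's
#' unbiased estimator `2n/(2n-1) * (1 - sum p^2)` with `n` the called sample
#' size. Groups with fewer than 2 called genotypes at a locus get `NA` `H_E`.
#'
#' @inheritParams allele_freqs
#' @return list with `per_locus` (data.frame locus x group) and `mean`
#'   (data.frame per group: mean over loci).
#' @export
heterozygosity <- function(dataset, grouping = "reef") {
  g <- .resolve_grouping(dataset, grouping)
  L <- length(dataset$loci)
  res <- vector("list", L)
  for (l in seq_len(L)) {
    al <- .locus_cols(dataset, l)
    tab <- .locus_tab(al[, 1L], al[, 2L], g)
    ho <- if (length(tab$vals)) rowSums(tab$h) / 2 else rep(NA_real_, nlevels(g))
    he <- rep(NA_real_, nlevels(g))
    ok <- tab$n >= 2
    if (length(tab$vals))
      he[ok] <- (2 * tab$n[ok] / (2 * tab$n[ok] - 1)) *
        (1 - rowSums(tab$p[ok, , drop = FALSE]^2))
    ho[tab$n == 0] <- NA_real_
    res[[l]] <- data.frame(locus = dataset$loci[l], group = levels(g),
                           n_called = tab$n, H_O = ho, H_E = he)
  }
  per_locus <- do.call(rbind, res)
  mean_df <- do.call(rbind, lapply(split(per_locus, per_locus$group), function(d) {
    data.frame(group = d$group[1L],
               H_O = mean(d$H_O, na.rm = TRUE),
               H_E = mean(d$H_E, na.rm = TRUE))
  }))
  rownames(mean_df) <- NULL
  mean_df <- mean_df[match(levels(g), mean_df$group), ]
  list(per_locus = per_locus, mean = mean_df)
}

#' Rarefaction allelic richness
#'
#' Expected number of alleles in a subsample of `rarefaction_n` gene copies:
#' `A_r = sum_a (1 - C(N - N_a, g) / C(N, g))` with `N` the called gene
#' copies in the group, `N_a` the copies of allele `a`, and `g` the
#' rarefaction size. Defaults to the minimum called copy number over
#' groups and loci, so every cell is defined.
#'
#' @inheritParams allele_freqs
#' @param rarefaction_n rarefaction size in gene copies (default: minimum
#'   over groups x loci).
#' @return list with `per_locus` data.frame (`locus`, `group`, `A_r`),
#'   `mean` per group, and `rarefaction_n` used.
#' @export
allelic_richness <- function(dataset, grouping = "reef", rarefaction_n = NULL) {
  g <- .resolve_grouping(dataset, grouping)
  L <- length(dataset$loci)
  tabs <- lapply(seq_len(L), function(l) {
    al <- .locus_cols(dataset, l)
    .locus_tab(al[, 1L], al[, 2L], g)
  })
  copies <- vapply(tabs, function(t) 2 * t$n, numeric(nlevels(g)))
  copies <- matrix(copies, nlevels(g), L)
  if (is.null(rarefaction_n)) rarefaction_n <- min(copies)
  if (rarefaction_n < 1) stop("rarefaction_n must be >= 1")
  bad <- which(copies < rarefaction_n, arr.ind = TRUE)
  if (nrow(bad))
    stop("rarefaction_n = ", rarefaction_n, " exceeds called gene copies for group '",
         levels(g)[bad[1L, 1L]], "' at locus ", dataset$loci[bad[1L, 2L]])
  res <- vector("list", L)
  for (l in seq_len(L)) {
    tab <- tabs[[l]]
    ar <- vapply(seq_len(nlevels(g)), function(i) {
      N <- 2 * tab$n[i]
      cnts <- round(tab$p[i, ] * N)
      # P(allele absent from a subsample of size g) = C(N - N_a, g)/C(N, g)
      sum(1 - exp(lchoose(N - cnts, rarefaction_n) - lchoose(N, rarefaction_n)))
    }, numeric(1L))
    res[[l]] <- data.frame(locus = dataset$loci[l], group = levels(g), A_r = ar)
  }
  per_locus <- do.call(rbind, res)
  mean_df <- stats::aggregate(A_r ~ group, per_locus, mean)
  mean_df <- mean_df[match(levels(g), mean_df$group), ]
  rownames(mean_df) <- NULL
  list(per_locus = per_locus, mean = mean_df, rarefaction_n = rarefaction_n)
}

#' Within-group fixation index F_is with locus-bootstrap CI
#'
#' Weir-Cockerham small-sample `f` computed within each group: per locus and
#' allele, the within-population variance components
#' `b = n/(n-1) (p(1-p) - (2n-1)/(4n) h)` and `c = h/2` are summed over
#' alleles and loci, and `f = 1 - sum(c)/sum(b + c)`. The 95% CI resamples
#' loci with replacement (percentile method).
#'
#' @inheritParams allele_freqs
#' @param n_boot number of locus bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame per group: `F_is`, `ci_low`, `ci_high`, `n_loci_used`.
#' @export
fis <- function(dataset, grouping = "reef", n_boot = 1000L, seed = 1L) {
  g <- .resolve_grouping(dataset, grouping)
  L <- length(dataset$loci)
  G <- nlevels(g)
  bmat <- cmat <- matrix(NA_real_, G, L)
  for (l in seq_len(L)) {
    al <- .locus_cols(dataset, l)
    tab <- .locus_tab(al[, 1L], al[, 2L], g)
    if (!length(tab$vals)) next
    for (i in seq_len(G)) {
      n <- tab$n[i]
      if (n < 2) next
      p <- tab$p[i, ]; h <- tab$h[i, ]
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      cc <- h / 2
      bmat[i, l] <- sum(b)
      cmat[i, l] <- sum(cc)
    }
  }
  est <- function(bl, cl) {
    tot <- sum(bl + cl, na.rm = TRUE)
    if (!is.finite(tot) || tot == 0) return(NA_real_)
    1 - sum(cl, na.rm = TRUE) / tot
  }
  out <- data.frame(group = levels(g), F_is = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, n_loci_used = 0L)
  set.seed(seed)
  for (i in seq_len(G)) {
    used <- which(is.finite(bmat[i, ]) & (bmat[i, ] + cmat[i, ]) != 0)
    out$n_loci_used[i] <- length(used)
    if (!length(used)) next  # all loci monomorphic or uncallable: undefined
    out$F_is[i] <- est(bmat[i, used], cmat[i, used])
    if (length(used) >= 2L && n_boot > 0L) {
      bs <- vapply(seq_len(n_boot), function(b) {
        j <- sample(used, length(used), replace = TRUE)
        est(bmat[i, j], cmat[i, j])
      }, numeric(1L))
      q <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      out$ci_low[i] <- q[1L]; out$ci_high[i] <- q[2L]
    }
  }
  out
}

#' Per-region diversity summary table
#'
#' Combines sample size, rarefaction allelic richness, observed and unbiased
#' expected heterozygosity (means over loci) and the fixation index with its
#' bootstrap CI into one table per group.
#'
#' @inheritParams fis
#' @param rarefaction_n passed to [allelic_richness()].
#' @return data.frame, one row per group.
#' @export
diversity_table <- function(dataset, grouping = "region", rarefaction_n = NULL,
                            n_boot = 1000L, seed = 1L) {
  g <- .resolve_grouping(dataset, grouping)
  het <- heterozygosity(dataset, g)
  ar <- allelic_richness(dataset, g, rarefaction_n)
  fi <- fis(dataset, g, n_boot = n_boot, seed = seed)
  data.frame(group = levels(g),
             N = as.vector(table(g)),
             A_r = ar$mean$A_r,
             H_O = het$mean$H_O,
             H_E = het$mean$H_E,
             F_is = fi$F_is,
             F_is_ci_low = fi$ci_low,
             F_is_ci_high = fi$ci_high)
}
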