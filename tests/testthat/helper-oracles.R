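# Independent brute-force oracles: direct transcriptions of the published
# formulas, written as plain loops with no code shared with the package
# internals. They are deliberately slow and literal.

# allele frequency / sample-size / heterozygote bookkeeping for one locus,
# one population, by explicit counting
.ora_locus_pop <- function(a1, a2) {
  called <- !is.na(a1) & !is.na(a2)
  a1 <- a1[called]; a2 <- a2[called]
  n <- length(a1)
  vals <- sort(unique(c(a1, a2)))
  p <- sapply(vals, function(v) sum(a1 == v) + sum(a2 == v)) / (2 * n)
  h <- sapply(vals, function(v) sum((a1 == v | a2 == v) & a1 != a2)) / n
  list(n = n, vals = vals, p = p, h = h)
}

# Weir & Cockerham (1984) theta by literal transcription, multi-locus by
# summing components
oracle_wc_theta <- function(ds, grouping) {
  g <- factor(grouping, levels = unique(grouping))
  L <- length(ds$loci)
  A <- B <- Cc <- 0
  for (l in seq_len(L)) {
    a1 <- ds$alleles[, 2 * l - 1]; a2 <- ds$alleles[, 2 * l]
    pops <- lapply(levels(g), function(lv)
      .ora_locus_pop(a1[g == lv], a2[g == lv]))
    pops <- pops[sapply(pops, function(x) x$n > 0)]
    r <- length(pops)
    if (r < 2) next
    vals <- sort(unique(unlist(lapply(pops, `[[`, "vals"))))
    if (!length(vals)) next
    nbar <- mean(sapply(pops, `[[`, "n"))
    if (nbar <= 1) next
    nc <- (r * nbar - sum(sapply(pops, `[[`, "n")^2) / (r * nbar)) / (r - 1)
    for (v in vals) {
      pi <- sapply(pops, function(x) {
        i <- match(v, x$vals); if (is.na(i)) 0 else x$p[i] })
      hi <- sapply(pops, function(x) {
        i <- match(v, x$vals); if (is.na(i)) 0 else x$h[i] })
      ni <- sapply(pops, `[[`, "n")
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; Cc <- Cc + cc
    }
  }
  A / (A + B + Cc)
}

# Nei & Chesser (1983) corrected Hs/Ht per locus
.ora_nc <- function(ds, grouping, l) {
  g <- factor(grouping, levels = unique(grouping))
  a1 <- ds$alleles[, 2 * l - 1]; a2 <- ds$alleles[, 2 * l]
  pops <- lapply(levels(g), function(lv) .ora_locus_pop(a1[g == lv], a2[g == lv]))
  pops <- pops[sapply(pops, function(x) x$n > 0)]
  r <- length(pops)
  if (r < 2) return(NULL)
  vals <- sort(unique(unlist(lapply(pops, `[[`, "vals"))))
  ntilde <- r / sum(1 / sapply(pops, `[[`, "n"))
  ho <- mean(sapply(pops, function(x) sum(x$h) / 2))
  sump2 <- mean(sapply(pops, function(x) {
    p <- sapply(vals, function(v) { i <- match(v, x$vals); if (is.na(i)) 0 else x$p[i] })
    sum(p^2)
  }))
  hs <- ntilde / (ntilde - 1) * (1 - sump2 - ho / (2 * ntilde))
  pbar <- sapply(vals, function(v) mean(sapply(pops, function(x) {
    i <- match(v, x$vals); if (is.na(i)) 0 else x$p[i] })))
  ht <- 1 - sum(pbar^2) + hs / (r * ntilde) - ho / (2 * r * ntilde)
  list(hs = hs, ht = ht, k = r)
}

oracle_hedrick_gst <- function(ds, grouping) {
  per <- lapply(seq_along(ds$loci), function(l) .ora_nc(ds, grouping, l))
  per <- per[!sapply(per, is.null)]
  hs <- mean(sapply(per, `[[`, "hs"))
  ht <- mean(sapply(per, `[[`, "ht"))
  k <- per[[1]]$k
  gst <- (ht - hs) / ht
  gst * (k - 1 + hs) / ((k - 1) * (1 - hs))
}

oracle_jost_d <- function(ds, grouping) {
  per <- lapply(seq_along(ds$loci), function(l) .ora_nc(ds, grouping, l))
  per <- per[!sapply(per, is.null)]
  d <- sapply(per, function(x) (x$k / (x$k - 1)) * (x$ht - x$hs) / (1 - x$hs))
  if (all(d > 0)) 1 / mean(1 / d) else mean(d)
}

# codominant squared genotypic distance between two single-locus genotypes,
# by the published case rules
oracle_codom_distance <- function(g1, g2) {
  s1 <- sort(g1); s2 <- sort(g2)
  hom1 <- s1[1] == s1[2]; hom2 <- s2[1] == s2[2]
  shared <- length(intersect(s1, s2)) > 0
  if (hom1 && hom2) { if (s1[1] == s2[1]) 0 else 4 }
  else if (hom1 != hom2) { if (shared) 1 else 3 }
  else { # both heterozygous
    if (identical(s1, s2)) 0 else if (shared) 1 else 2
  }
}

# autocorrelation r per class: literal transcription of the published matrix
# algebra (double-centered covariance from squared distances, class sums)
oracle_autocorr_r <- function(D2, class_matrix, n_classes) {
  n <- nrow(D2)
  cmat <- matrix(0, n, n)
  rowm <- rowMeans(D2); gm <- mean(D2)
  for (x in 1:n) for (y in 1:n)
    cmat[x, y] <- -0.5 * (D2[x, y] - rowm[x] - rowm[y] + gm)
  sapply(seq_len(n_classes), function(h) {
    num <- 0; den <- 0
    for (x in 1:(n - 1)) for (y in (x + 1):n) {
      if (!is.na(class_matrix[x, y]) && class_matrix[x, y] == h) {
        num <- num + cmat[x, y]
        den <- den + (cmat[x, x] + cmat[y, y]) / 2
      }
    }
    if (den == 0) NA_real_ else num / den
  })
}

# rarefaction allelic richness by direct combinatorial evaluation
oracle_allelic_richness <- function(counts, g) {
  N <- sum(counts)
  sum(sapply(counts, function(na) 1 - choose(N - na, g) / choose(N, g)))
}

# haplotype diversity by hand
oracle_hap_div <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

# nucleotide diversity by all-pairs loops over a character matrix
oracle_pi <- function(m) {
  n <- nrow(m); tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ]) / ncol(m)
  tot / choose(n, 2)
}

# haploid variance-components Fst on a groups x haplotypes count table
oracle_haploid_fst <- function(cnt) {
  ni <- rowSums(cnt); r <- nrow(cnt); N <- sum(ni)
  p <- sweep(cnt, 1, ni, "/")
  nc <- (N - sum(ni^2) / N) / (r - 1)
  num <- 0; den <- 0
  for (a in seq_len(ncol(cnt))) {
    pbar <- sum(cnt[, a]) / N
    msp <- sum(ni * (p[, a] - pbar)^2) / (r - 1)
    msg <- sum(ni * p[, a] * (1 - p[, a])) / (N - r)
    sa <- (msp - msg) / nc
    num <- num + sa; den <- den + sa + msg
  }
  num / den
}

# distance-AMOVA Fst (PhiPT flavor) by literal sums-of-squares loops
oracle_phipt <- function(D, grouping) {
  g <- factor(grouping, levels = unique(grouping))
  n <- nrow(D); r <- nlevels(g)
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]
  sst <- sst / n
  ssw <- 0
  for (lv in levels(g)) {
    ii <- which(g == lv)
    if (length(ii) >= 2)
      for (a in 1:(length(ii) - 1)) for (b in (a + 1):length(ii))
        ssw <- ssw + D[ii[a], ii[b]] / length(ii)
  }
  msb <- (sst - ssw) / (r - 1)
  msw <- ssw / (n - r)
  ng <- as.vector(table(g))
  n0 <- (n - sum(ng^2) / n) / (r - 1)
  sa <- (msb - msw) / n0
  sa / (sa + msw)
}

oracle_fpst <- function(ds, grouping) {
  D <- genotypic_distance_matrix(ds)
  g <- factor(grouping, levels = unique(grouping))
  shift <- max(ds$alleles, na.rm = TRUE) + 1L
  ds2 <- ds
  ds2$alleles <- ds$alleles + (as.integer(g) - 1L) * shift
  Dmax <- genotypic_distance_matrix(ds2)
  oracle_phipt(D, grouping) / oracle_phipt(Dmax, grouping)
}

# equilibrium Fst of two demes of N diploids exchanging migrants at rate m,
# from the classical identity-by-descent recursions (infinite-allele
# mutation u)
oracle_two_deme_fst <- function(N, m, u, gens = 50000) {
  a <- (1 - m)^2 + m^2
  b <- 2 * m * (1 - m)
  f0 <- 0; f1 <- 0
  for (g in seq_len(gens)) {
    co <- 1 / (2 * N)
    f0n <- (1 - u)^2 * (a * (co + (1 - co) * f0) + (1 - a) * f1)
    f1n <- (1 - u)^2 * (b * (co + (1 - co) * f0) + (1 - b) * f1)
    f0 <- f0n; f1 <- f1n
  }
  (f0 - f1) / (1 - f1)
}
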