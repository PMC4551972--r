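# Differentiation estimators over codominant genotypes.
#
# All estimators run off the same per-locus ingredients, computed once:
#   - Weir & Cockerham (1984) variance components a, b, c summed over alleles
#   - Nei & Chesser (1983) sample-corrected H_S and H_T and mean H_O
# Multi-locus combination conventions (recorded in every result):
#   theta:   ratio of summed components sum(a)/sum(a+b+c)
#   G'st:    computed from H_S and H_T averaged over loci
#   D:       harmonic mean of per-locus D (arithmetic mean when any
#            per-locus D <= 0, where the harmonic mean is undefined)
#   F'st:    ratio of multi-locus theta to multi-locus theta of the
#            maximal-differentiation recoded dataset
# Negative single-locus component estimates are retained, not clamped.

# Weir-Cockerham variance components for one locus.
# Groups with no called genotypes at the locus are dropped for that locus.
.wc_components <- function(tab) {
  keep <- tab$n > 0
  r <- sum(keep)
  if (r < 2L || length(tab$vals) == 0L)
    return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n_i <- tab$n[keep]
  p <- tab$p[keep, , drop = FALSE]
  h <- tab$h[keep, , drop = FALSE]
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  pbar <- colSums(n_i * p) / (r * nbar)
  s2 <- colSums(n_i * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h) / (r * nbar)
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

# Nei-Chesser corrected heterozygosities for one locus.
.nc_hets <- function(tab) {
  keep <- tab$n > 0
  r <- sum(keep)
  if (r < 2L || length(tab$vals) == 0L)
    return(c(Hs = NA_real_, Ht = NA_real_, Ho = NA_real_, k = r))
  n_i <- tab$n[keep]
  p <- tab$p[keep, , drop = FALSE]
  ho_i <- rowSums(tab$h[keep, , drop = FALSE]) / 2
  ntilde <- r / sum(1 / n_i)
  if (ntilde <= 1) return(c(Hs = NA_real_, Ht = NA_real_, Ho = NA_real_, k = r))
  Ho <- mean(ho_i)
  Hs <- ntilde / (ntilde - 1) * (1 - mean(rowSums(p^2)) - Ho / (2 * ntilde))
  pbar <- colMeans(p)
  Ht <- 1 - sum(pbar^2) + Hs / (r * ntilde) - Ho / (2 * r * ntilde)
  c(Hs = Hs, Ht = Ht, Ho = Ho, k = r)
}

# All per-locus ingredients for a dataset/grouping.
.locus_ingredients <- function(dataset, g) {
  L <- length(dataset$loci)
  comp <- matrix(NA_real_, L, 3L, dimnames = list(dataset$loci, c("a", "b", "c")))
  hets <- matrix(NA_real_, L, 4L, dimnames = list(dataset$loci,
                                                  c("Hs", "Ht", "Ho", "k")))
  for (l in seq_len(L)) {
    al <- .locus_cols(dataset, l)
    tab <- .locus_tab(al[, 1L], al[, 2L], g)
    comp[l, ] <- .wc_components(tab)
    hets[l, ] <- .nc_hets(tab)
  }
  list(comp = comp, hets = hets)
}

.theta_from_comp <- function(comp) {
  ok <- is.finite(comp[, "a"])
  if (!any(ok)) return(NA_real_)
  den <- sum(comp[ok, , drop = FALSE])
  if (den == 0) return(0)  # no variation anywhere: no differentiation
  sum(comp[ok, "a"]) / den
}

.gpst_from_hets <- function(hets) {
  ok <- is.finite(hets[, "Hs"]) & is.finite(hets[, "Ht"])
  if (!any(ok)) return(NA_real_)
  Hs <- mean(hets[ok, "Hs"]); Ht <- mean(hets[ok, "Ht"])
  k <- stats::median(hets[ok, "k"])
  if (Ht == 0) return(NA_real_)
  if (1 - Hs < 1e-12) return(NA_real_)  # H_S = 1: undefined
  gst <- (Ht - Hs) / Ht
  gst * (k - 1 + Hs) / ((k - 1) * (1 - Hs))
}

.d_per_locus <- function(hets) {
  Hs <- hets[, "Hs"]; Ht <- hets[, "Ht"]; k <- hets[, "k"]
  d <- (k / (k - 1)) * (Ht - Hs) / (1 - Hs)
  d[!is.finite(Hs) | (1 - Hs) < 1e-12] <- NA_real_
  d
}

.d_combine <- function(d_locus) {
  d <- d_locus[is.finite(d_locus)]
  if (!length(d)) return(c(NA_real_, NA_real_))
  if (all(d > 0)) c(1 / mean(1 / d), 1) else c(mean(d), 0)  # 1=harmonic, 0=arithmetic
}

.new_diff_estimate <- function(estimator, estimate, ci, n_boot, perm_p, n_perm,
                               grouping_name, k, per_locus, combination) {
  structure(list(estimator = estimator, estimate = estimate,
                 ci_low = ci[1L], ci_high = ci[2L], n_boot = n_boot,
                 perm_p = perm_p, n_perm = n_perm, grouping = grouping_name,
                 k = k, per_locus = per_locus, combination = combination),
            class = "diff_estimate")
}

#' @export
print.diff_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$estimator, x$estimate))
  if (is.finite(x$ci_low))
    cat(sprintf("  [95%% CI %.4f, %.4f; %d locus bootstraps]",
                x$ci_low, x$ci_high, x$n_boot))
  if (!is.null(x$perm_p) && is.finite(x$perm_p))
    cat(sprintf("  perm p = %.4f (%d permutations)", x$perm_p, x$n_perm))
  cat("\n  grouping:", x$grouping, "(", x$k, "groups );",
      "multi-locus:", x$combination, "\n")
  invisible(x)
}

.locus_bootstrap <- function(L_used, n_boot, statfun, seed) {
  if (n_boot <= 0L || length(L_used) < 2L) return(c(NA_real_, NA_real_))
  set.seed(seed)
  bs <- vapply(seq_len(n_boot), function(b) {
    statfun(sample(L_used, length(L_used), replace = TRUE))
  }, numeric(1L))
  stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
}

#' Weir-Cockerham theta (multi-allelic F_st)
#'
#' The 1984 variance-components estimator; loci are combined by summing the
#' among-population (a) and total (a+b+c) components. 95% CI from resampling
#' loci with replacement (percentile).
#'
#' @inheritParams allele_freqs
#' @param n_boot locus bootstrap replicates for the CI (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return a `diff_estimate`.
#' @export
wc_fst <- function(dataset, grouping = "reef", n_boot = 1000L, seed = 1L) {
  g <- .resolve_grouping(dataset, grouping)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ing <- .locus_ingredients(dataset, g)
  comp <- ing$comp
  est <- .theta_from_comp(comp)
  used <- which(is.finite(comp[, "a"]))
  ci <- .locus_bootstrap(used, n_boot,
                         function(j) .theta_from_comp(comp[j, , drop = FALSE]),
                         seed)
  per_locus <- data.frame(locus = dataset$loci,
                          theta = comp[, "a"] / rowSums(comp))
  .new_diff_estimate("wc_fst", est, ci, n_boot, NULL, 0L,
                     .grouping_name(grouping), nlevels(g), per_locus,
                     "sum of variance components over loci")
}

#' Hedrick's standardized G'st
#'
#' `G'st = G_st (k - 1 + H_S) / ((k - 1)(1 - H_S))` with Nei-Chesser
#' sample-size-corrected H_S and H_T; loci combined by averaging H_S and H_T.
#'
#' @inheritParams wc_fst
#' @return a `diff_estimate`.
#' @export
hedrick_gst <- function(dataset, grouping = "reef", n_boot = 1000L, seed = 1L) {
  g <- .resolve_grouping(dataset, grouping)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  hets <- .locus_ingredients(dataset, g)$hets
  est <- .gpst_from_hets(hets)
  used <- which(is.finite(hets[, "Hs"]))
  ci <- .locus_bootstrap(used, n_boot,
                         function(j) .gpst_from_hets(hets[j, , drop = FALSE]),
                         seed)
  per <- apply(hets, 1L, function(z) .gpst_from_hets(matrix(z, 1L, 4L,
                 dimnames = list(NULL, colnames(hets)))))
  .new_diff_estimate("hedrick_gst", est, ci, n_boot, NULL, 0L,
                     .grouping_name(grouping), nlevels(g),
                     data.frame(locus = dataset$loci, gpst = per),
                     "H_S and H_T averaged over loci")
}

#' Jost's D
#'
#' `D = (k/(k-1)) (H_T - H_S)/(1 - H_S)` per locus with sample-corrected
#' heterozygosities; loci combined by the harmonic mean of per-locus D
#' (arithmetic mean when any per-locus D is non-positive; the convention
#' used is recorded in the result).
#'
#' @inheritParams wc_fst
#' @return a `diff_estimate`.
#' @export
jost_d <- function(dataset, grouping = "reef", n_boot = 1000L, seed = 1L) {
  g <- .resolve_grouping(dataset, grouping)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  hets <- .locus_ingredients(dataset, g)$hets
  dl <- .d_per_locus(hets)
  comb <- .d_combine(dl)
  used <- which(is.finite(dl))
  ci <- .locus_bootstrap(used, n_boot, function(j) .d_combine(dl[j])[1L], seed)
  .new_diff_estimate("jost_d", comb[1L], ci, n_boot, NULL, 0L,
                     .grouping_name(grouping), nlevels(g),
                     data.frame(locus = dataset$loci, d = dl),
                     if (comb[2L] == 1) "harmonic mean of per-locus D"
                     else "arithmetic mean of per-locus D (non-positive loci present)")
}

# Recode alleles so that every group's alleles are unique to it: the
# maximal-differentiation dataset used to normalize F'st.
.recode_max_diff <- function(dataset, g) {
  alleles <- dataset$alleles
  shift <- max(alleles, na.rm = TRUE) + 1L
  offs <- (as.integer(g) - 1L) * shift
  alleles <- alleles + offs  # NA stays NA
  d2 <- dataset
  d2$alleles <- alleles
  d2
}

# distance-AMOVA Fst (PhiPT flavor: among-population variance over total,
# from squared genotypic distances, within-individual level suppressed)
.amova_phi <- function(D, g) {
  n <- nrow(D)
  r <- nlevels(g)
  idx <- split(seq_len(n), g)
  idx <- idx[lengths(idx) > 0L]
  r <- length(idx)
  if (r < 2L) return(NA_real_)
  sst <- sum(D[upper.tri(D)]) / n
  ssw <- 0
  for (i in idx)
    ssw <- ssw + sum(D[i, i][upper.tri(diag(length(i)))]) / length(i)
  ssb <- sst - ssw
  if (n - r <= 0L) return(NA_real_)
  msb <- ssb / (r - 1)
  msw <- ssw / (n - r)
  ng <- lengths(idx)
  n0 <- (n - sum(ng^2) / n) / (r - 1)
  sa <- (msb - msw) / n0
  den <- sa + msw
  if (den == 0) return(NA_real_)
  sa / den
}

#' Standardized F'st by maximal-differentiation recoding
#'
#' `F'st = F_st / F_st(max)`: the AMOVA F_st computed from the squared
#' codominant genotypic distances (the estimator behind the usual
#' spreadsheet implementation of the standardization) divided by the same
#' estimator applied to a recoded dataset in which every group's alleles are
#' made unique - the maximum differentiation attainable given the
#' within-group diversity. Significance by permuting individuals across
#' groups, using the unstandardized F_st as test statistic (the recoding
#' denominator is invariant in distribution under the null);
#' `p = (count >= observed + 1)/(n_permutations + 1)`.
#'
#' @inheritParams wc_fst
#' @param n_permutations permutations for the p-value (0 skips the test).
#' @return a `diff_estimate`.
#' @export
meirmans_fpst <- function(dataset, grouping = "reef", n_boot = 1000L,
                          n_permutations = 999L, seed = 1L) {
  g <- .resolve_grouping(dataset, grouping)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  dl_obs <- .per_locus_dist(dataset)
  dl_max <- .per_locus_dist(.recode_max_diff(dataset, g))
  L <- length(dl_obs)
  val <- function(j, strict = FALSE) {
    pol <- if (strict) "error" else "na"
    Do <- .combine_locus_dist(dl_obs[j], dataset, pol)
    Dm <- .combine_locus_dist(dl_max[j], dataset, pol)
    if (anyNA(Do) || anyNA(Dm)) return(NA_real_)  # pair uncalled on this locus set
    fst <- .amova_phi(Do, g)
    fmax <- .amova_phi(Dm, g)
    if (!is.finite(fmax) || fmax == 0) return(NA_real_)
    fst / fmax
  }
  est <- val(seq_len(L), strict = TRUE)
  if (!is.finite(est)) warning("F_st(max) is zero or undefined; F'st undefined")
  ci <- .locus_bootstrap(seq_len(L), n_boot, val, seed)
  perm_p <- NULL
  if (n_permutations > 0L) {
    D <- .combine_locus_dist(dl_obs, dataset)
    fst_obs <- .amova_phi(D, g)
    set.seed(seed + 1L)
    n <- nrow(dataset$alleles)
    cnt <- 0L
    for (b in seq_len(n_permutations)) {
      v <- .amova_phi(D, g[sample.int(n)])
      if (is.finite(v) && v >= fst_obs) cnt <- cnt + 1L
    }
    perm_p <- (cnt + 1L) / (n_permutations + 1L)
  }
  .new_diff_estimate("meirmans_fpst", est, ci, n_boot, perm_p, n_permutations,
                     .grouping_name(grouping), nlevels(g),
                     data.frame(locus = dataset$loci,
                                fpst = vapply(seq_len(L), function(l) val(l),
                                              numeric(1L))),
                     "multi-locus distance AMOVA over maximal-recoding AMOVA")
}

.grouping_name <- function(grouping) {
  if (length(grouping) == 1L && is.character(grouping)) grouping else "custom"
}

#' Pairwise differentiation matrix
#'
#' Applies an estimator to every pair of groups; the diagonal is defined
#' as 0.
#'
#' @inheritParams wc_fst
#' @param estimator one of `"wc_fst"`, `"hedrick_gst"`, `"jost_d"`,
#'   `"meirmans_fpst"`.
#' @param ... passed to the estimator (e.g. `n_boot`, `seed`).
#' @return list with `estimate` (symmetric matrix) and `detail` (list of
#'   `diff_estimate` keyed `"A|B"`).
#' @export
pairwise_matrix <- function(dataset, grouping = "region",
                            estimator = c("wc_fst", "hedrick_gst", "jost_d",
                                          "meirmans_fpst"), ...) {
  estimator <- match.arg(estimator)
  fun <- get(estimator, mode = "function")
  g <- .resolve_grouping(dataset, grouping)
  lv <- levels(g)
  if (length(lv) < 2L) stop("need at least 2 groups")
  m <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  detail <- list()
  for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1L):length(lv)) {
    sel <- g %in% lv[c(i, j)]
    sub <- subset_genotypes(dataset, individuals = which(sel))
    est <- fun(sub, as.character(g[sel]), ...)
    m[i, j] <- m[j, i] <- est$estimate
    detail[[paste(lv[i], lv[j], sep = "|")]] <- est
  }
  list(estimate = m, detail = detail)
}
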