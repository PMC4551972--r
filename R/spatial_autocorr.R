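# Individual-based multilocus genotypic spatial autocorrelation.
#
# The squared genetic distance between two diploid single-locus genotypes is
# half the squared Euclidean distance between their allele-count vectors,
# which reproduces the codominant convention: identical homozygotes 0;
# homozygote vs heterozygote sharing an allele 1; heterozygotes sharing one
# allele 1; disjoint heterozygotes 2; homozygote vs disjoint heterozygote 3;
# different homozygotes 4. Multilocus distances are sums over loci (pairs
# missing a locus are averaged over their called loci and rescaled to the
# full locus count).
#
# Distances are converted to a covariance matrix by Gower double-centering
# c_xy = -0.5 (d2_xy - mean_x d2_xy - mean_y d2_xy + mean_xy d2_xy), and the
# autocorrelation for distance class h is
#   r(h) = sum_{x!=y in h} c_xy / sum_{x!=y in h} (c_xx + c_yy)/2 .

# per-locus squared genotypic distance matrices; NA where a pair is not
# co-called at the locus
.per_locus_dist <- function(dataset) {
  n <- nrow(dataset$alleles)
  L <- length(dataset$loci)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    al <- .locus_cols(dataset, l)
    called <- !is.na(al[, 1L])
    vals <- sort(unique(c(al[called, 1L], al[called, 2L])))
    if (!length(vals)) {
      out[[l]] <- matrix(NA_real_, n, n)
      next
    }
    Y <- matrix(0, n, length(vals))
    idx <- which(called)
    i1 <- cbind(idx, match(al[idx, 1L], vals))
    i2 <- cbind(idx, match(al[idx, 2L], vals))
    Y[i1] <- Y[i1] + 1
    Y[i2] <- Y[i2] + 1
    Y[!called, ] <- NA_real_
    d2 <- 0.5 * as.matrix(stats::dist(Y))^2
    d2[outer(!called, !called, `|`)] <- NA_real_
    diag(d2) <- ifelse(called, 0, NA_real_)
    out[[l]] <- d2
  }
  out
}

# combine per-locus distance matrices: mean over co-called loci rescaled to
# the full locus count
.combine_locus_dist <- function(dlist, dataset = NULL,
                                on_missing_pair = c("error", "na")) {
  on_missing_pair <- match.arg(on_missing_pair)
  L <- length(dlist)
  n <- nrow(dlist[[1L]])
  total <- matrix(0, n, n)
  ncall <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    d2 <- dlist[[l]]
    ok <- !is.na(d2)
    d2[!ok] <- 0
    total <- total + d2
    ncall <- ncall + ok
  }
  zero <- ncall == 0L
  if (any(zero) && on_missing_pair == "error") {
    w <- which(zero, arr.ind = TRUE)[1L, ]
    ids <- if (is.null(dataset)) w else dataset$ind$individual_id[w]
    stop("individuals ", ids[1L], " and ", ids[2L], " share no called locus")
  }
  out <- total / pmax(ncall, 1L) * L
  out[zero] <- NA_real_
  out
}

#' Squared codominant genotypic distance matrix
#'
#' @inheritParams allele_freqs
#' @param on_missing_pair `"error"` (default) or `"na"`: what to do for a pair
#'   of individuals with no co-called locus.
#' @return symmetric `n x n` matrix of squared genotypic distances.
#' @export
genotypic_distance_matrix <- function(dataset, on_missing_pair = c("error", "na")) {
  if (nrow(dataset$alleles) < 2L) stop("need at least 2 individuals")
  out <- .combine_locus_dist(.per_locus_dist(dataset), dataset,
                             match.arg(on_missing_pair))
  dimnames(out) <- list(dataset$ind$individual_id, dataset$ind$individual_id)
  out
}

#' Distance classes over pairs of individuals
#'
#' The default, membership-defined specification assigns every unordered pair
#' to exactly one of three classes: `within_reef` (same reef), `within_region`
#' (same region, different reef), `between_region` (different regions).
#' A metric alternative bins pairs by Euclidean distance between coordinates.
#'
#' @param dataset a [genotype_dataset()] with reef (and region, for the
#'   default classes) metadata.
#' @param type `"membership"` or `"metric"`.
#' @param breaks for `type = "metric"`: increasing numeric km breakpoints
#'   (pairs beyond the last break form a final open class).
#' @return object of class `distance_class_spec`: list with `labels` and the
#'   `n x n` integer class matrix (`NA` on the diagonal).
#' @export
distance_classes <- function(dataset, type = c("membership", "metric"),
                             breaks = NULL) {
  type <- match.arg(type)
  n <- nrow(dataset$alleles)
  if (type == "membership") {
    reef <- dataset$ind$reef_id
    region <- dataset$ind$region_id
    if (anyNA(region))
      stop("membership distance classes need region_id for every individual")
    same_reef <- outer(reef, reef, `==`)
    same_region <- outer(region, region, `==`)
    cm <- matrix(3L, n, n)
    cm[same_region] <- 2L
    cm[same_reef] <- 1L
    labels <- c("within_reef", "within_region", "between_region")
  } else {
    x <- dataset$ind$x_km; y <- dataset$ind$y_km
    if (anyNA(x) || anyNA(y)) stop("metric distance classes need coordinates")
    if (is.null(breaks) || any(diff(breaks) <= 0))
      stop("metric classes need increasing 'breaks'")
    dd <- as.matrix(stats::dist(cbind(x, y)))
    cm <- matrix(findInterval(dd, c(-Inf, breaks)), n, n)
    labels <- c(paste0("<=", breaks, "km"), paste0(">", breaks[length(breaks)], "km"))
  }
  diag(cm) <- NA_integer_
  structure(list(labels = labels, class_matrix = cm, type = type),
            class = "distance_class_spec")
}

# upper-triangle pair indices per class
.class_pairs <- function(classes) {
  cm <- classes$class_matrix
  n <- nrow(cm)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  cl <- cm[upper.tri(cm)]
  lapply(seq_along(classes$labels), function(h) {
    sel <- which(cl == h)
    list(i = ut[sel, 1L], j = ut[sel, 2L])
  })
}

.double_center <- function(d2) {
  rm <- rowMeans(d2); gm <- mean(d2)
  -0.5 * (d2 - outer(rm, rep(1, length(rm))) - outer(rep(1, length(rm)), rm) + gm)
}

# r per class; p permutes individuals' spatial labels (genotypes fixed)
.class_r <- function(C, dg, pairs, p = NULL) {
  vapply(pairs, function(ph) {
    if (!length(ph$i)) return(NA_real_)
    i <- ph$i; j <- ph$j
    if (!is.null(p)) { i <- p[i]; j <- p[j] }
    num <- sum(C[cbind(i, j)])
    den <- sum((dg[i] + dg[j]) / 2)
    if (den == 0) return(NA_real_)
    num / den
  }, numeric(1L))
}

#' Autocorrelation coefficients per distance class
#'
#' @param gen_dist squared genotypic distance matrix from
#'   [genotypic_distance_matrix()].
#' @param classes a [distance_classes()] specification.
#' @return data.frame with `class`, `n_pairs`, `r`.
#' @export
autocorrelogram <- function(gen_dist, classes) {
  stopifnot(inherits(classes, "distance_class_spec"))
  C <- .double_center(gen_dist)
  pairs <- .class_pairs(classes)
  r <- .class_r(C, diag(C), pairs)
  data.frame(class = classes$labels,
             n_pairs = vapply(pairs, function(p) length(p$i), integer(1L)),
             r = r)
}

#' Permutation null envelope for the correlogram
#'
#' Individuals' spatial labels (their reef/region membership, hence their
#' distance-class assignment) are permuted jointly while genotypes stay
#' fixed; the envelope is the 2.5th/97.5th percentile of the permuted r per
#' class.
#'
#' @inheritParams autocorrelogram
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `envelope` (data.frame class, null_lo, null_hi) and
#'   `perm_r` (n_perm x classes matrix, for the heterogeneity test).
#' @export
permutation_null <- function(gen_dist, classes, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  C <- .double_center(gen_dist)
  dg <- diag(C)
  pairs <- .class_pairs(classes)
  n <- nrow(C)
  set.seed(seed)
  perm_r <- matrix(NA_real_, n_perm, length(classes$labels))
  for (b in seq_len(n_perm))
    perm_r[b, ] <- .class_r(C, dg, pairs, sample.int(n))
  env <- t(apply(perm_r, 2L, stats::quantile, probs = c(0.025, 0.975),
                 na.rm = TRUE, names = FALSE))
  list(envelope = data.frame(class = classes$labels,
                             null_lo = env[, 1L], null_hi = env[, 2L]),
       perm_r = perm_r)
}

#' Bootstrap confidence intervals for r
#'
#' Pairs within each distance class are resampled with replacement;
#' percentile 95% CI per class.
#'
#' @inheritParams permutation_null
#' @param n_boot number of bootstrap replicates (>= 99).
#' @return data.frame `class`, `boot_lo`, `boot_hi`.
#' @export
bootstrap_r <- function(gen_dist, classes, n_boot = 999L, seed = 1L) {
  if (n_boot < 99L) stop("n_boot must be at least 99")
  C <- .double_center(gen_dist)
  dg <- diag(C)
  pairs <- .class_pairs(classes)
  set.seed(seed)
  out <- data.frame(class = classes$labels, boot_lo = NA_real_, boot_hi = NA_real_)
  for (h in seq_along(pairs)) {
    np <- length(pairs[[h]]$i)
    if (np < 2L) next  # degenerate class: flagged by NA
    bs <- vapply(seq_len(n_boot), function(b) {
      s <- sample.int(np, np, replace = TRUE)
      i <- pairs[[h]]$i[s]; j <- pairs[[h]]$j[s]
      num <- sum(C[cbind(i, j)])
      den <- sum((dg[i] + dg[j]) / 2)
      if (den == 0) NA_real_ else num / den
    }, numeric(1L))
    q <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out$boot_lo[h] <- q[1L]; out$boot_hi[h] <- q[2L]
  }
  out
}

#' Correlogram heterogeneity test
#'
#' Per class, `t2 = (r - mean(r_perm))^2 / var(r_perm)` compares the observed
#' r to its permutation distribution; the whole-correlogram statistic `omega`
#' sums the squared standardized deviations over classes. p-values come from
#' the permutation distribution with the (k+1)/(n+1) correction.
#'
#' @inheritParams permutation_null
#' @return list with `per_class` (data.frame class, t2, t2_p), `omega`,
#'   `omega_p`, `n_perm`.
#' @export
heterogeneity_test <- function(gen_dist, classes, n_perm = 999L, seed = 1L) {
  pn <- permutation_null(gen_dist, classes, n_perm, seed)
  obs <- autocorrelogram(gen_dist, classes)$r
  .heterogeneity_from_perms(obs, pn$perm_r, classes$labels)
}

.heterogeneity_from_perms <- function(obs_r, perm_r, labels) {
  mu <- colMeans(perm_r, na.rm = TRUE)
  v <- apply(perm_r, 2L, stats::var, na.rm = TRUE)
  usable <- is.finite(obs_r) & is.finite(v) & v > 0
  if (sum(usable) < 2L)
    stop("heterogeneity test needs at least 2 usable distance classes")
  t2_obs <- (obs_r - mu)^2 / v
  t2_perm <- sweep(sweep(perm_r, 2L, mu)^2, 2L, v, `/`)
  n_perm <- nrow(perm_r)
  t2_p <- vapply(seq_along(obs_r), function(h) {
    if (!usable[h]) return(NA_real_)
    (sum(t2_perm[, h] >= t2_obs[h], na.rm = TRUE) + 1) / (n_perm + 1)
  }, numeric(1L))
  omega <- sum(t2_obs[usable])
  omega_perm <- rowSums(t2_perm[, usable, drop = FALSE], na.rm = TRUE)
  omega_p <- (sum(omega_perm >= omega) + 1) / (n_perm + 1)
  list(per_class = data.frame(class = labels, t2 = t2_obs, t2_p = t2_p),
       omega = omega, omega_p = omega_p, n_perm = n_perm)
}

#' Full genotypic spatial autocorrelation analysis
#'
#' Runs the whole correlogram pipeline: genotypic distances, per-class r,
#' permutation null envelope, pair bootstrap CIs and the heterogeneity test.
#'
#' @inheritParams allele_freqs
#' @param classes a [distance_classes()] spec; default: the membership
#'   classes (within reef / within region / between regions).
#' @param n_perm permutations for the null envelope and heterogeneity test.
#' @param n_boot bootstraps for the r CIs.
#' @param seed RNG seed.
#' @return object of class `correlogram`: list with `per_class` data.frame
#'   (`class`, `n_pairs`, `r`, `null_lo`, `null_hi`, `boot_lo`, `boot_hi`,
#'   `t2`, `t2_p`), `omega`, `omega_p`, `n_perm`, `n_boot`.
#' @export
correlogram <- function(dataset, classes = NULL, n_perm = 999L, n_boot = 999L,
                        seed = 1L) {
  if (is.null(classes)) classes <- distance_classes(dataset)
  gd <- genotypic_distance_matrix(dataset)
  ac <- autocorrelogram(gd, classes)
  pn <- permutation_null(gd, classes, n_perm, seed)
  bt <- bootstrap_r(gd, classes, n_boot, seed + 1L)
  het <- .heterogeneity_from_perms(ac$r, pn$perm_r, classes$labels)
  per_class <- cbind(ac, pn$envelope[, -1L], bt[, -1L], het$per_class[, -1L])
  structure(list(per_class = per_class, omega = het$omega,
                 omega_p = het$omega_p, n_perm = n_perm, n_boot = n_boot),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("genotypic spatial autocorrelation (", x$n_perm, "permutations,",
      x$n_boot, "bootstraps )\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("heterogeneity: omega = %.3f, p = %.4f\n", x$omega, x$omega_p))
  invisible(x)
}

#' Sex-partitioned spatial autocorrelation
#'
#' Runs the full correlogram pipeline on the subset of one sex, to detect
#' sex-biased dispersal.
#'
#' @inheritParams correlogram
#' @param sex `"male"` or `"female"`.
#' @return a [correlogram()] object.
#' @export
sex_partitioned_autocorr <- function(dataset, sex = c("male", "female"),
                                     classes = NULL, n_perm = 999L,
                                     n_boot = 999L, seed = 1L) {
  sex <- match.arg(sex)
  keep <- which(dataset$ind$sex == sex)
  if (length(keep) < 2L)
    stop("fewer than 2 individuals of sex '", sex, "'")
  sub <- subset_genotypes(dataset, individuals = keep)
  if (is.null(classes)) classes <- distance_classes(sub)
  correlogram(sub, classes, n_perm, n_boot, seed)
}

#' Export a correlogram as CSV
#' @param x a [correlogram()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlogram_csv <- function(x, path) {
  utils::write.csv(x$per_class, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Correlogram plot
#'
#' r per distance class with the permutation null envelope (dashed) and the
#' bootstrap CI (error bars).
#'
#' @param x a [correlogram()] object.
#' @return a ggplot object.
#' @export
plot_correlogram <- function(x) {
  d <- x$per_class
  d$class <- factor(d$class, levels = d$class)
  class_ <- r <- null_lo <- null_hi <- boot_lo <- boot_hi <- NULL # NSE bindings
  ggplot2::ggplot(d, ggplot2::aes(x = class, y = r, group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = null_lo, ymax = null_hi),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = boot_lo, ymax = boot_hi),
                           width = 0.15) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "distance class", y = "autocorrelation r") +
    ggplot2::theme_minimal()
}
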