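test_that("codominant genotypic distances follow the published case rules", {
  pair_ds <- function(g1, g2) genotype_dataset(rbind(g1, g2), "loc1",
                                               c("a", "b"), c("r", "r"))
  cases <- list(list(c(1L, 1L), c(1L, 1L), 0), # identical homozygotes
                list(c(1L, 1L), c(2L, 2L), 4), # different homozygotes
                list(c(1L, 2L), c(3L, 4L), 2), # disjoint heterozygotes
                list(c(1L, 1L), c(2L, 3L), 3), # homozygote vs disjoint het
                list(c(1L, 1L), c(1L, 2L), 1), # homozygote vs sharing het
                list(c(1L, 2L), c(1L, 3L), 1)) # heterozygotes sharing one
  for (cs in cases) {
    D <- genotypic_distance_matrix(pair_ds(cs[[1]], cs[[2]]))
    expect_equal(D[1, 2], cs[[3]])
    expect_equal(D[1, 2], oracle_codom_distance(cs[[1]], cs[[2]]))
  }
  # multilocus distance is the sum of single-locus distances
  ds <- genotype_dataset(rbind(c(1L, 1L, 1L, 2L), c(2L, 2L, 3L, 4L)),
                         c("l1", "l2"), c("a", "b"), c("r", "r"))
  expect_equal(genotypic_distance_matrix(ds)[1, 2], 4 + 2)
})

test_that("distances over missing loci are rescaled to the full locus count", {
  ds <- genotype_dataset(rbind(c(1L, 1L, 1L, 1L), c(2L, 2L, NA, NA)),
                         c("l1", "l2"), c("a", "b"), c("r", "r"))
  expect_equal(genotypic_distance_matrix(ds)[1, 2], 4 * 2)  # mean over called x L
  ds2 <- genotype_dataset(rbind(c(NA, NA), c(2L, 2L)), "l1", c("a", "b"),
                          c("r", "r"))
  expect_error(genotypic_distance_matrix(ds2), "share no called locus")
  expect_true(is.na(genotypic_distance_matrix(ds2, "na")[1, 2]))
})

test_that("membership classes partition all pairs", {
  ds <- two_cluster_dataset()
  cl <- distance_classes(ds)
  n <- nrow(ds$alleles)
  counts <- table(cl$class_matrix[upper.tri(cl$class_matrix)])
  expect_equal(sum(counts), n * (n - 1) / 2)
  ac <- autocorrelogram(genotypic_distance_matrix(ds), cl)
  expect_equal(sum(ac$n_pairs), n * (n - 1) / 2)
})

test_that("autocorrelation r matches the brute-force matrix algebra", {
  # 6-individual toy instance plus random instances
  ds <- genotype_dataset(
    rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(3L, 3L), c(3L, 4L), c(4L, 4L)),
    "l1", paste0("i", 1:6),
    reef_id = rep(c("r1", "r2", "r3"), each = 2),
    region_id = rep(c("north", "south"), each = 3))
  D <- genotypic_distance_matrix(ds)
  cl <- distance_classes(ds)
  got <- autocorrelogram(D, cl)$r
  want <- oracle_autocorr_r(D, cl$class_matrix, 3)
  expect_equal(got, want, tolerance = 1e-12)
  for (seed in 1:5) {
    ds <- null_spatial_fixture(seed)
    D <- genotypic_distance_matrix(ds)
    cl <- distance_classes(ds)
    expect_equal(autocorrelogram(D, cl)$r,
                 oracle_autocorr_r(D, cl$class_matrix, 3), tolerance = 1e-12)
  }
})

test_that("r is invariant to allele relabeling and individual order", {
  ds <- two_cluster_dataset(seed = 2)
  cl <- distance_classes(ds)
  r0 <- autocorrelogram(genotypic_distance_matrix(ds), cl)$r
  perm <- sample(50)
  ds2 <- ds; ds2$alleles[] <- perm[ds$alleles]
  expect_equal(autocorrelogram(genotypic_distance_matrix(ds2), cl)$r, r0,
               tolerance = 1e-12)
  ord <- sample(nrow(ds$alleles))
  ds3 <- subset_genotypes(ds, individuals = ord)
  r3 <- autocorrelogram(genotypic_distance_matrix(ds3), distance_classes(ds3))$r
  expect_equal(r3, r0, tolerance = 1e-12)
})

test_that("two fixed clusters give positive within-class and negative between", {
  ds <- two_cluster_dataset(seed = 3)
  cg <- correlogram(ds, n_perm = 199, n_boot = 199, seed = 1)
  r <- cg$per_class$r
  expect_gt(r[1], 0)                       # within reef: similar genotypes
  expect_lt(r[3], 0)                       # between regions: dissimilar
  expect_lt(cg$omega_p, 0.05)
  expect_true(all(cg$per_class$null_lo <= cg$per_class$null_hi))
  # within-class bootstrap CI excludes zero under strong structure
  expect_gt(cg$per_class$boot_lo[1], 0)
})

test_that("covariance decomposition is conserved across classes", {
  ds <- null_spatial_fixture(9)
  D <- genotypic_distance_matrix(ds)
  cl <- distance_classes(ds)
  C <- reefconn:::.double_center(D)
  pairs <- reefconn:::.class_pairs(cl)
  per_class <- vapply(pairs, function(p) sum(C[cbind(p$i, p$j)]), numeric(1))
  expect_equal(sum(per_class), sum(C[upper.tri(C)]), tolerance = 1e-9)
})

test_that("permutation null envelope is reproducible and covers the null", {
  ds <- null_spatial_fixture(4)
  D <- genotypic_distance_matrix(ds)
  cl <- distance_classes(ds)
  e1 <- permutation_null(D, cl, n_perm = 199, seed = 7)
  e2 <- permutation_null(D, cl, n_perm = 199, seed = 7)
  expect_identical(e1$envelope, e2$envelope)
  expect_error(permutation_null(D, cl, n_perm = 50), "at least 99")
  # observed r of a null fixture falls inside the envelope most of the time
  hits <- 0
  for (seed in 1:20) {
    ds <- null_spatial_fixture(seed + 100)
    D <- genotypic_distance_matrix(ds)
    cl <- distance_classes(ds)
    r <- autocorrelogram(D, cl)$r
    env <- permutation_null(D, cl, n_perm = 99, seed = seed)$envelope
    if (all(r >= env$null_lo & r <= env$null_hi)) hits <- hits + 1
  }
  expect_gte(hits, 14)  # ~85% joint coverage of three 95% intervals
})

test_that("bootstrap CIs behave under structure and under the null", {
  ds <- null_spatial_fixture(5)
  D <- genotypic_distance_matrix(ds)
  cl <- distance_classes(ds)
  b1 <- bootstrap_r(D, cl, n_boot = 199, seed = 3)
  b2 <- bootstrap_r(D, cl, n_boot = 199, seed = 3)
  expect_identical(b1, b2)
  r <- autocorrelogram(D, cl)$r
  expect_true(all(b1$boot_lo <= r & r <= b1$boot_hi))
  expect_true(any(b1$boot_lo <= 0 & b1$boot_hi >= 0))
})

test_that("heterogeneity test matches a brute-force transcription", {
  ds <- two_cluster_dataset(seed = 6, nper = 8)
  D <- genotypic_distance_matrix(ds)
  cl <- distance_classes(ds)
  het <- heterogeneity_test(D, cl, n_perm = 199, seed = 11)
  # brute force: same permutation stream, explicit standardization
  C <- reefconn:::.double_center(D)
  pairs <- reefconn:::.class_pairs(cl)
  set.seed(11)
  n <- nrow(D)
  perm_r <- t(replicate(199, reefconn:::.class_r(C, diag(C), pairs,
                                                 sample.int(n))))
  obs <- autocorrelogram(D, cl)$r
  mu <- colMeans(perm_r); v <- apply(perm_r, 2, var)
  t2 <- (obs - mu)^2 / v
  expect_equal(het$per_class$t2, t2, tolerance = 1e-12)
  expect_equal(het$omega, sum(t2), tolerance = 1e-12)
  omega_perm <- rowSums(sweep(sweep(perm_r, 2, mu)^2, 2, v, "/"))
  expect_equal(het$omega_p, (sum(omega_perm >= sum(t2)) + 1) / 200,
               tolerance = 1e-12)
})

test_that("sex-partitioned runs expose constructed philopatry contrasts", {
  ds <- male_philopatry_fixture(seed = 8)
  cf <- sex_partitioned_autocorr(ds, "female", n_perm = 199, n_boot = 199,
                                 seed = 2)
  cm <- sex_partitioned_autocorr(ds, "male", n_perm = 199, n_boot = 199,
                                 seed = 2)
  expect_gt(cf$per_class$r[1], cm$per_class$r[1])  # female within-reef r higher
  expect_lt(cf$per_class$t2_p[1], 0.05)
  sub <- subset_genotypes(ds, individuals = 1)
  expect_error(sex_partitioned_autocorr(sub, "female"), "fewer than 2")
})

test_that("metric km classes are available for synthetic coordinates", {
  ds <- two_cluster_dataset(seed = 12)
  cl <- distance_classes(ds, type = "metric", breaks = c(50, 150))
  expect_equal(length(cl$labels), 3)
  n <- nrow(ds$alleles)
  expect_equal(sum(table(cl$class_matrix[upper.tri(cl$class_matrix)])),
               n * (n - 1) / 2)
  r <- autocorrelogram(genotypic_distance_matrix(ds), cl)$r
  expect_gt(r[1], 0)
})
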