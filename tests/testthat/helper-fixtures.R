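# Programmatic fixtures shared across test files.

# random small genotype table: 2-4 pops, few individuals, few loci, with
# occasional missing genotypes
random_small_table <- function(seed, missing = TRUE) {
  set.seed(seed)
  npop <- sample(2:4, 1)
  nper <- sample(4:8, npop, replace = TRUE)
  L <- sample(2:5, 1)
  n <- sum(nper)
  alleles <- matrix(NA_integer_, n, 2 * L)
  for (l in seq_len(L)) {
    k <- sample(2:5, 1)
    freqs <- as.vector(stats::rgamma(k, 1)); freqs <- freqs / sum(freqs)
    # per-pop frequency perturbation so tables are genuinely structured
    row <- 1
    for (p in seq_len(npop)) {
      f <- freqs * stats::rgamma(k, 4) / 4
      f <- f / sum(f)
      draws <- sample.int(k, 2 * nper[p], replace = TRUE, prob = f)
      alleles[row:(row + nper[p] - 1), 2 * l - 1] <- draws[seq_len(nper[p])]
      alleles[row:(row + nper[p] - 1), 2 * l] <- draws[nper[p] + seq_len(nper[p])]
      row <- row + nper[p]
    }
  }
  if (missing) {
    # missingness confined to the first locus so every pair of individuals
    # keeps at least one co-called locus
    drop <- which(stats::runif(n) < 0.08)
    for (i in drop) alleles[i, 1:2] <- NA_integer_
  }
  genotype_dataset(alleles, paste0("loc", seq_len(L)), paste0("i", seq_len(n)),
                   reef_id = rep(paste0("pop", seq_len(npop)), nper))
}

# k populations each fixed for a private allele at every locus
fixed_different_dataset <- function(npop = 2, nper = 10, L = 3) {
  n <- npop * nper
  alleles <- matrix(rep(rep(seq_len(npop), each = nper), 2 * L), n, 2 * L)
  genotype_dataset(alleles, paste0("loc", seq_len(L)), paste0("i", seq_len(n)),
                   reef_id = rep(paste0("pop", seq_len(npop)), each = nper))
}

# one large HWE population arbitrarily split into two labels
split_panmictic <- function(seed = 1, n = 200, L = 8) {
  ds <- make_toy_fixture(c(0.4, 0.3, 0.2, 0.1), n_per_pop = n, seed = seed,
                         n_loci = L)
  ds$ind$reef_id <- rep(c("A", "B"), length.out = n)
  ds$ind$region_id <- ds$ind$reef_id
  ds
}

# spatially structured dataset: 2 regions x 2 reefs, reef-specific allele
# pools -> strong within-reef similarity
two_cluster_dataset <- function(seed = 1, nper = 12, L = 6) {
  set.seed(seed)
  pools <- list(1:3, 4:6, 7:9, 10:12)  # disjoint allele pools per reef
  alleles <- NULL
  for (p in 1:4)
    alleles <- rbind(alleles,
                     matrix(sample(pools[[p]], nper * 2 * L, replace = TRUE),
                            nper, 2 * L))
  n <- 4 * nper
  genotype_dataset(alleles, paste0("loc", seq_len(L)), paste0("i", seq_len(n)),
                   reef_id = rep(paste0("reef", 1:4), each = nper),
                   region_id = rep(c("north", "south"), each = 2 * nper),
                   x_km = rep(c(0, 10, 200, 210), each = nper),
                   y_km = 0)
}

# males drawn from one common pool (dispersers), females reef-specific
# (residents): female within-reef autocorrelation should exceed male
male_philopatry_fixture <- function(seed = 1, nper = 14, L = 8) {
  set.seed(seed)
  pools <- list(1:4, 5:8, 9:12, 13:16)
  alleles <- NULL; sex <- NULL
  for (p in 1:4) {
    nf <- nper %/% 2; nm <- nper - nf
    af <- matrix(sample(pools[[p]], nf * 2 * L, replace = TRUE), nf, 2 * L)
    am <- matrix(sample(1:16, nm * 2 * L, replace = TRUE), nm, 2 * L)
    alleles <- rbind(alleles, af, am)
    sex <- c(sex, rep("female", nf), rep("male", nm))
  }
  n <- 4 * nper
  genotype_dataset(alleles, paste0("loc", seq_len(L)), paste0("i", seq_len(n)),
                   reef_id = rep(paste0("reef", 1:4), each = nper),
                   region_id = rep(c("north", "south"), each = 2 * nper),
                   x_km = rep(c(0, 30, 300, 330), each = nper),
                   y_km = 0, sex = sex)
}

# null spatial fixture: panmictic genotypes with arbitrary reef/region labels
null_spatial_fixture <- function(seed, n_reefs = 4, nper = 8, L = 5) {
  ds <- make_toy_fixture(c(0.4, 0.3, 0.2, 0.1), n_per_pop = n_reefs * nper,
                         seed = seed, n_loci = L)
  ds$ind$reef_id <- rep(paste0("reef", seq_len(n_reefs)), each = nper)
  ds$ind$region_id <- rep(c("east", "west"), each = n_reefs * nper / 2)
  ds
}

# small alignment builder
aln <- function(seqs, regions = NULL, ids = NULL)
  haplotype_alignment(seqs, ids, regions)
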