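# Small-scale configurations keep these tests fast while exercising the same
# machinery as the full 8x8 / Ne=400 study runs.

small_cfg <- function(...) {
  seascape_config(grid_rows = 1L, grid_cols = 1L, reef_area_km2 = 2.5,
                  migration_rate = 0, ...)  # Nc = 500, Ne = 50
}

test_that("config derives demography from reef area, density and Ne:Nc", {
  cfg <- seascape_config()
  expect_equal(cfg$Nc, 4000)   # 20 km2 x 100 ha/km2 x 2 sharks/ha
  expect_equal(cfg$Ne, 400)    # Ne:Nc = 1:10
  expect_equal(cfg$n_reefs, 64)
  expect_equal(seascape_config(ne_nc_ratio = 1)$Ne, 4000)
  expect_error(seascape_config(migration_rate = 1.5), "migration_rate")
  expect_error(seascape_config(ne_nc_ratio = 2), "exceeds")
  expect_error(seascape_config(bogus = 1), "unknown config")
  expect_error(seascape_config(init_allele_states = 99L), "init_allele_states")
})

test_that("initial state has maximal diversity and respects bounds", {
  cfg <- small_cfg()
  st <- init_state(cfg, seed = 5)
  expect_equal(dim(st$alleles), c(50, 32))
  expect_true(all(st$alleles >= 1 & st$alleles <= 40))
  he0 <- reefconn:::.state_mean_he(st$alleles, cfg$n_loci)
  expect_lt(abs(he0 - (1 - 1 / 40)), 0.02)
  # restricted initial block emulates lower-diversity loci
  cfg5 <- small_cfg(init_allele_states = 5L)
  he5 <- reefconn:::.state_mean_he(init_state(cfg5, seed = 5)$alleles, 16)
  expect_lt(abs(he5 - 0.8), 0.03)
  expect_identical(init_state(cfg, seed = 9)$alleles,
                   init_state(cfg, seed = 9)$alleles)
})

test_that("simulation is reproducible and conserves population structure", {
  cfg <- seascape_config(grid_rows = 2L, grid_cols = 2L, reef_area_km2 = 1,
                         n_loci = 4L, n_generations = 10L,
                         migration_rate = 0.1)  # Ne = 20 per reef
  s1 <- run_simulation(cfg, seed = 3)
  s2 <- run_simulation(cfg, seed = 3)
  expect_identical(s1$alleles, s2$alleles)
  expect_equal(s1$generation, 10L)
  expect_equal(dim(s1$alleles), c(4 * 20, 8))
  expect_true(all(s1$alleles >= 1 & s1$alleles <= cfg$n_allele_states))
  # zero generations returns the initial state
  cfg0 <- seascape_config(grid_rows = 2L, grid_cols = 2L, reef_area_km2 = 1,
                          n_loci = 4L, n_generations = 0L)
  a <- run_simulation(cfg0, seed = 8)$alleles
  set.seed(8)
  expect_identical(a, init_state(cfg0)$alleles)
})

test_that("closed single deme loses heterozygosity at rate 1/(2Ne)", {
  cfg <- small_cfg(mutation_rate = 0, n_loci = 8L)
  mean_he <- matrix(NA_real_, 100, 20)
  for (rep in 1:20) {
    set.seed(rep + 300)
    st <- init_state(cfg)
    for (g in 1:100) {
      st <- step_generation(st, cfg)
      mean_he[g, rep] <- reefconn:::.state_mean_he(st$alleles, 8L)
    }
  }
  traj <- rowMeans(mean_he)
  fit <- lm(log(traj) ~ seq_len(100))
  expect_equal(unname(coef(fit)[2]), log(1 - 1 / (2 * 50)), tolerance = 0.12)
})

test_that("fixation is absorbing without mutation or migration", {
  cfg <- seascape_config(grid_rows = 1L, grid_cols = 1L, reef_area_km2 = 0.1,
                         ne_nc_ratio = 0.1, n_loci = 4L, mutation_rate = 0,
                         migration_rate = 0, n_allele_states = 4L,
                         init_allele_states = 4L)  # Ne = 2
  set.seed(2)
  st <- init_state(cfg)
  for (g in 1:400) st <- step_generation(st, cfg)
  for (l in 1:4)
    expect_equal(length(unique(c(st$alleles[, 2 * l - 1], st$alleles[, 2 * l]))), 1)
})

test_that("allele frequencies drift without directional change", {
  cfg <- seascape_config(grid_rows = 2L, grid_cols = 1L, reef_area_km2 = 1,
                         n_loci = 8L, migration_rate = 0.05,
                         n_generations = 30L)
  deltas <- vapply(1:10, function(s) {
    set.seed(s + 700)
    st0 <- init_state(cfg)
    st <- st0
    for (g in 1:30) st <- step_generation(st, cfg)
    mean(st$alleles) - mean(st0$alleles)
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 4 * sd(deltas) / sqrt(10))
})

test_that("two-deme equilibrium theta matches the IBD recursion", {
  cfg <- seascape_config(grid_rows = 1L, grid_cols = 2L, reef_area_km2 = 2.5,
                         n_loci = 48L, migration_rate = 0.05,
                         mutation_model = "k_allele", mutation_rate = 1e-5,
                         n_allele_states = 200L, n_generations = 150L)
  thetas <- vapply(1:3, function(s) {
    st <- run_simulation(cfg, seed = s + 50)
    ds <- genotype_dataset(st$alleles, paste0("l", 1:48),
                           paste0("i", seq_len(nrow(st$alleles))),
                           rep(c("deme1", "deme2"), each = cfg$Ne))
    wc_fst(ds, n_boot = 0)$estimate
  }, numeric(1))
  want <- oracle_two_deme_fst(50, 0.05, 1e-5)
  expect_lt(abs(mean(thetas) - want) / want, 0.4)
})

test_that("seascape sampling returns 4 regions x 3 reefs x 10 individuals", {
  cfg <- seascape_config(n_generations = 0L)
  st <- run_simulation(cfg, seed = 1)
  ds <- sample_seascape(st, cfg, seed = 2)
  expect_equal(dim(ds), c(120, 16))
  expect_equal(sort(unique(ds$ind$region_id)), c("NE", "NW", "SE", "SW"))
  expect_equal(as.vector(table(ds$ind$region_id)), rep(30, 4))
  expect_equal(length(unique(ds$ind$reef_id)), 12)
  expect_false(any(is.na(ds$ind$x_km)))
  # sampled genotypes are rows of the source state
  key <- apply(st$alleles, 1, paste, collapse = ",")
  expect_true(all(apply(ds$alleles, 1, paste, collapse = ",") %in% key))
  # reproducible under seed; oversampling refused
  ds2 <- sample_seascape(st, cfg, seed = 2)
  expect_identical(ds$alleles, ds2$alleles)
  expect_error(sample_seascape(st, cfg, individuals_per_reef = 500), "Ne")
})

test_that("mutation calibration is monotone and rejects degenerate targets", {
  cfg <- seascape_config(grid_rows = 1L, grid_cols = 1L, reef_area_km2 = 0.5,
                         migration_rate = 0)  # Ne = 10: fast pilots
  mu_low <- calibrate_mutation_rate(cfg, target_He = 0.25, tolerance = 0.05,
                                    seed = 1, burnin_factor = 6, max_iter = 8)
  mu_high <- calibrate_mutation_rate(cfg, target_He = 0.6, tolerance = 0.05,
                                     seed = 1, burnin_factor = 6, max_iter = 8)
  expect_lt(mu_low, mu_high)
  expect_lt(abs(attr(mu_high, "He") - 0.6), 0.051)
  expect_error(calibrate_mutation_rate(cfg, target_He = 0), "target_He")
  expect_error(calibrate_mutation_rate(cfg, target_He = 0.995), "unreachable")
})
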