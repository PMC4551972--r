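# The study orchestration is tested on a deliberately small seascape (2x2
# reefs, Ne = 20) so the structure and plumbing are exercised quickly; the
# full-scale study conditions are covered by the acceptance suite.

tiny_cfg <- seascape_config(grid_rows = 2L, grid_cols = 2L, reef_area_km2 = 1,
                            n_loci = 6L, n_generations = 15L)

tiny_study <- run_simulation_study(tiny_cfg, migration_levels = c(0.02, 0.2),
                                   n_replicates = 3, seed = 42, n_perm = 99,
                                   n_boot = 0, reefs_per_region = 1)

test_that("simulation study aggregates replicates with seeds and CIs", {
  expect_equal(nrow(tiny_study$fpst), 6)
  expect_equal(tiny_study$fpst_summary$level, c(0.02, 0.2))
  expect_equal(tiny_study$fpst_summary$n_replicates, c(3, 3))
  expect_true(all(tiny_study$fpst_summary$ci_low <=
                    tiny_study$fpst_summary$mean_fpst))
  expect_equal(length(unique(tiny_study$fpst$seed)), 6)
  expect_equal(nrow(tiny_study$correlogram), 6 * 3)  # 3 classes per replicate
  expect_true(all(c("config_hash", "seed", "rep_seeds") %in%
                    names(tiny_study$provenance)))
  # degenerate CI with a single replicate is flagged, not fabricated
  one <- run_simulation_study(tiny_cfg, migration_levels = 0.1,
                              n_replicates = 1, seed = 1, n_perm = 0,
                              n_boot = 0, reefs_per_region = 1)
  expect_true(is.na(one$fpst_summary$ci_low))
})

test_that("study runs are deterministic under a fixed master seed", {
  again <- run_simulation_study(tiny_cfg, migration_levels = c(0.02, 0.2),
                                n_replicates = 3, seed = 42, n_perm = 99,
                                n_boot = 0, reefs_per_region = 1)
  expect_equal(again$fpst$fpst, tiny_study$fpst$fpst)
  expect_equal(again$correlogram$r, tiny_study$correlogram$r)
})

test_that("study and standalone estimators share one code path", {
  # re-running the replicate pipeline by hand reproduces the logged value
  row <- tiny_study$fpst[4, ]
  cfg <- tiny_cfg
  cfg$migration_rate <- row$level
  ds <- sample_seascape(run_simulation(cfg, seed = row$seed), cfg,
                        reefs_per_region = 1)
  direct <- meirmans_fpst(ds, "region", n_boot = 0, n_permutations = 0)
  expect_equal(direct$estimate, row$fpst, tolerance = 1e-12)
})

test_that("study results serialize and restore losslessly", {
  f <- withr::local_tempfile(fileext = ".json")
  write_study_result(tiny_study, f)
  back <- read_study_result(f)
  expect_equal(back$fpst$fpst, tiny_study$fpst$fpst)
  expect_equal(back$fpst_summary$mean_fpst, tiny_study$fpst_summary$mean_fpst)
  expect_equal(unname(back$provenance$rep_seeds),
               unname(tiny_study$provenance$rep_seeds))
})

test_that("empirical battery runs end-to-end on files and flags gaps", {
  cfg <- tiny_cfg
  cfg$migration_rate <- 0.2
  ds <- sample_seascape(run_simulation(cfg, seed = 5), cfg,
                        reefs_per_region = 1, individuals_per_reef = 10)
  ds$ind$sex <- rep(c("male", "female"), 20)
  gp <- withr::local_tempfile(fileext = ".gen")
  md <- withr::local_tempfile(fileext = ".csv")
  write_genepop(ds, gp)
  write_metadata_csv(ds, md)
  rep <- run_empirical_analysis(gp, md, n_boot = 60, n_perm = 99, seed = 3)
  expect_s3_class(rep, "empirical_report")
  expect_equal(nrow(rep$diversity), 4)
  expect_named(rep$differentiation,
               c("wc_fst", "hedrick_gst", "jost_d", "meirmans_fpst"))
  expect_equal(dim(rep$pairwise_fst$estimate), c(4, 4))
  expect_s3_class(rep$correlogram, "correlogram")
  expect_s3_class(rep$correlogram_male, "correlogram")
  # missing metadata rows are reported by id
  md2 <- read_metadata_csv(md)[-1, ]
  expect_error(run_empirical_analysis(gp, md2), "missing from metadata")
})

test_that("panmictic input yields differentiation CIs covering zero", {
  ds <- split_panmictic(seed = 77, n = 120, L = 10)
  rep <- run_empirical_analysis(ds, grouping = "region", n_boot = 200,
                                n_perm = 99, seed = 2)
  for (d in rep$differentiation[c("wc_fst", "hedrick_gst", "jost_d")]) {
    expect_lte(d$ci_low, 0)
    expect_gte(d$ci_high, 0)
  }
  expect_gt(rep$differentiation$meirmans_fpst$perm_p, 0.05)
})

test_that("mtDNA arm of the battery reports h, pi and pairwise Fst", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1|north", "ACGTACGT", ">s2|north", "ACGTACGT",
               ">s3|north", "ACGAACGT", ">s4|south", "ACGAACGT",
               ">s5|south", "ACGTACGT", ">s6|south", "ACGAACGT"), fa)
  ds <- split_panmictic(seed = 9, n = 40, L = 4)
  rep <- run_empirical_analysis(ds, mtdna = fa, grouping = "region",
                                n_boot = 50, n_perm = 99, seed = 1)
  expect_equal(rep$mtdna$table$n_haplotypes, 2)
  expect_true(all(rep$mtdna$h$h >= 0 & rep$mtdna$h$h <= 1, na.rm = TRUE))
  expect_equal(dim(rep$mtdna$pairwise_fst$fst), c(2, 2))
})

test_that("cli dispatches, validates flags and writes deterministic outputs", {
  out1 <- withr::local_tempdir()
  expect_equal(cli_main(c("fixtures", "--preset", "null", "--out", out1,
                          "--seed", "4")), 0L)
  expect_true(file.exists(file.path(out1, "null.gen")))
  expect_true(file.exists(file.path(out1, "provenance.json")))
  out2 <- withr::local_tempdir()
  cli_main(c("fixtures", "--preset", "null", "--out", out2, "--seed", "4"))
  expect_identical(readLines(file.path(out1, "null.gen")),
                   readLines(file.path(out2, "null.gen")))
  # usage errors exit 2
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
  expect_equal(suppressMessages(cli_main(c("analyze", "--out", out1))), 2L)
  expect_equal(suppressMessages(
    cli_main(c("study", "--frobnicate", "1", "--out", out1))), 2L)
  # analyze round trip on the structured preset
  out3 <- withr::local_tempdir()
  cli_main(c("fixtures", "--preset", "structured", "--out", out3))
  expect_equal(cli_main(c("analyze",
                          "--genotypes", file.path(out3, "structured.gen"),
                          "--metadata", file.path(out3, "structured_metadata.csv"),
                          "--out", out3, "--seed", "2")), 0L)
  expect_true(file.exists(file.path(out3, "differentiation.csv")))
  expect_true(file.exists(file.path(out3, "correlogram.csv")))
})
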