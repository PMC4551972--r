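# The two study arms behind one interface: the simulation power analysis
# (replicated forward simulations at several migration levels, each pushed
# through the same F'st and correlogram code as the empirical battery) and
# the empirical-style analysis of a genotype file + metadata (+ optional
# mtDNA alignment).

#' Simulation power analysis across migration levels
#'
#' For each migration level and replicate: simulate the seascape, sample
#' `10 individuals x 3 reefs x 4 quadrant regions`, compute the overall
#' standardized F'st across regions and the three-class correlogram; then
#' aggregate replicates with 95% CIs (percentile of the replicate values by
#' default, normal-approximation optional).
#'
#' @param config a [seascape_config()] (its `migration_rate` is overridden
#'   per level).
#' @param migration_levels numeric vector of per-generation migration
#'   fractions.
#' @param n_replicates independent simulations per level.
#' @param seed master seed; per-replicate seeds are drawn from it and logged.
#' @param n_perm permutations for the F'st test and correlogram null/
#'   heterogeneity (0 skips the F'st permutation test).
#' @param n_boot locus bootstraps for the F'st CI (0 skips) and pair
#'   bootstraps for r.
#' @param ci `"percentile"` or `"normal"`: across-replicate CI method.
#' @param reefs_per_region,individuals_per_reef sampling design passed to
#'   [sample_seascape()] (study defaults 3 and 10).
#' @param progress print one line per replicate.
#' @return object of class `study_result`: list with `fpst` (data.frame:
#'   level, replicate, seed, fpst, perm_p), `fpst_summary` (per level: mean,
#'   ci), `correlogram` (data.frame: level, replicate, class, r, omega_p),
#'   `correlogram_summary`, and a `provenance` block (config hash, seeds).
#' @export
run_simulation_study <- function(config = seascape_config(),
                                 migration_levels = c(0.01, 0.10, 0.25),
                                 n_replicates = config$n_replicates,
                                 seed = 1L, n_perm = 99L, n_boot = 0L,
                                 ci = c("percentile", "normal"),
                                 reefs_per_region = 3L,
                                 individuals_per_reef = 10L,
                                 progress = FALSE) {
  ci <- match.arg(ci)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(migration_levels) * n_replicates),
                      n_replicates, length(migration_levels))
  fp <- NULL; cg <- NULL
  for (mi in seq_along(migration_levels)) {
    m <- migration_levels[mi]
    for (rep in seq_len(n_replicates)) {
      s <- rep_seeds[rep, mi]
      cfg <- config
      cfg$migration_rate <- m
      res <- .one_replicate(cfg, s, n_perm = n_perm, n_boot = n_boot,
                            reefs_per_region = reefs_per_region,
                            individuals_per_reef = individuals_per_reef)
      fp <- rbind(fp, data.frame(level = m, replicate = rep, seed = s,
                                 fpst = res$fpst,
                                 perm_p = if (is.null(res$fpst_p)) NA_real_ else res$fpst_p))
      cg <- rbind(cg, cbind(level = m, replicate = rep,
                            res$correlogram$per_class[, c("class", "n_pairs", "r")],
                            omega = res$correlogram$omega,
                            omega_p = res$correlogram$omega_p))
      if (progress)
        message(sprintf("m = %.2f replicate %d: F'st = %.3f", m, rep, res$fpst))
    }
  }
  agg_ci <- function(v) {
    if (length(v) < 2L) return(c(NA_real_, NA_real_))  # degenerate: flagged
    if (ci == "percentile")
      stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    else mean(v) + c(-1, 1) * 1.96 * stats::sd(v) / sqrt(length(v))
  }
  fps <- do.call(rbind, lapply(split(fp, fp$level), function(d) {
    q <- agg_ci(d$fpst)
    data.frame(level = d$level[1L], mean_fpst = mean(d$fpst),
               ci_low = q[1L], ci_high = q[2L], n_replicates = nrow(d))
  }))
  cgs <- do.call(rbind, lapply(split(cg, list(cg$level, cg$class)), function(d) {
    q <- agg_ci(d$r)
    data.frame(level = d$level[1L], class = d$class[1L], mean_r = mean(d$r),
               ci_low = q[1L], ci_high = q[2L],
               prop_omega_sig = mean(d$omega_p <= 0.05))
  }))
  rownames(fps) <- rownames(cgs) <- NULL
  structure(list(fpst = fp, fpst_summary = fps[order(fps$level), ],
                 correlogram = cg, correlogram_summary = cgs,
                 provenance = list(config_hash = .config_hash(config),
                                   seed = seed, rep_seeds = rep_seeds,
                                   ci_method = ci,
                                   version = as.character(utils::packageVersion("reefconn")))),
            class = "study_result")
}

# simulate + sample + F'st across regions + membership correlogram
.one_replicate <- function(cfg, s, n_perm = 99L, n_boot = 0L,
                           reefs_per_region = 3L, individuals_per_reef = 10L) {
  st <- run_simulation(cfg, seed = s)
  ds <- sample_seascape(st, cfg, reefs_per_region, individuals_per_reef)
  fpst <- meirmans_fpst(ds, "region", n_boot = n_boot,
                        n_permutations = n_perm, seed = s)
  cgm <- correlogram(ds, n_perm = max(n_perm, 99L), n_boot = max(n_boot, 99L),
                     seed = s)
  list(fpst = fpst$estimate, fpst_p = fpst$perm_p, correlogram = cgm,
       dataset = ds)
}

#' @export
print.study_result <- function(x, ...) {
  cat("simulation power analysis (", max(x$fpst$replicate), "replicates/level )\n")
  cat("\noverall F'st across regions:\n")
  print(x$fpst_summary, row.names = FALSE, digits = 3)
  cat("\ncorrelogram r by class:\n")
  print(x$correlogram_summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Round-trippable serialization of a study result
#'
#' @param x a `study_result`.
#' @param path JSON output path.
#' @return `path` invisibly; `read_study_result()` restores the object.
#' @export
write_study_result <- function(x, path) {
  y <- unclass(x)
  y$provenance$rep_seeds <- as.vector(y$provenance$rep_seeds)
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_study_result
#' @export
read_study_result <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  y$provenance$rep_seeds <- matrix(y$provenance$rep_seeds,
                                   nrow = max(y$fpst$replicate))
  structure(y, class = "study_result")
}

#' Empirical-style analysis battery
#'
#' Runs the full repertoire on a genotype file: per-region diversity table,
#' between-region differentiation (all four estimators, locus-bootstrap CIs),
#' overall standardized F'st with permutation test, membership correlograms
#' (all individuals and, where sex is recorded, males and females
#' separately), and mtDNA diversity/differentiation when an alignment is
#' supplied.
#'
#' @param genotypes path to a genepop file, or a [genotype_dataset()].
#' @param metadata path to the sidecar metadata CSV (or a data.frame);
#'   ignored if `genotypes` already carries metadata.
#' @param mtdna optional path to an aligned FASTA (headers `>id|region`) or a
#'   [haplotype_alignment()].
#' @param grouping grouping for the differentiation estimators (default
#'   `"region"`).
#' @param n_boot locus bootstraps for differentiation CIs (study default
#'   1000).
#' @param n_perm permutations for F'st, correlogram and mtDNA tests (study
#'   default 999).
#' @param seed RNG seed.
#' @return object of class `empirical_report`: list with `diversity`,
#'   `differentiation` (list of `diff_estimate`), `pairwise_fst`,
#'   `correlogram`, `correlogram_male`, `correlogram_female`, `mtdna`
#'   (haplotype table, h, pi, pairwise Fst) and `provenance`.
#' @export
run_empirical_analysis <- function(genotypes, metadata = NULL, mtdna = NULL,
                                   grouping = "region", n_boot = 1000L,
                                   n_perm = 999L, seed = 1L) {
  ds <- genotypes
  if (is.character(ds)) ds <- read_genepop(ds)
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) read_metadata_csv(metadata) else metadata
    ds <- attach_metadata(ds, md)
  }
  if (all(is.na(ds$ind$region_id)))
    stop("region_id is required for the analysis battery; supply metadata")
  div <- diversity_table(ds, grouping, n_boot = n_boot, seed = seed)
  diff <- list(
    wc_fst = wc_fst(ds, grouping, n_boot = n_boot, seed = seed),
    hedrick_gst = hedrick_gst(ds, grouping, n_boot = n_boot, seed = seed),
    jost_d = jost_d(ds, grouping, n_boot = n_boot, seed = seed),
    meirmans_fpst = meirmans_fpst(ds, grouping, n_boot = n_boot,
                                  n_permutations = n_perm, seed = seed)
  )
  pw <- pairwise_matrix(ds, grouping, "wc_fst", n_boot = n_boot, seed = seed)
  cgm <- correlogram(ds, n_perm = n_perm, n_boot = n_perm, seed = seed)
  cg_m <- cg_f <- NULL
  for (sx in c("male", "female")) {
    if (sum(ds$ind$sex == sx) >= 10L) {
      cg <- sex_partitioned_autocorr(ds, sx, n_perm = n_perm, n_boot = n_perm,
                                     seed = seed)
      if (sx == "male") cg_m <- cg else cg_f <- cg
    }
  }
  mt <- NULL
  if (!is.null(mtdna)) {
    aln <- if (is.character(mtdna)) read_fasta_alignment(mtdna) else mtdna
    tab <- collapse_haplotypes(aln)
    mt <- list(table = tab, h = haplotype_diversity(tab),
               pi = nucleotide_diversity(aln),
               pairwise_fst = mtdna_pairwise_fst(aln, n_perm = n_perm,
                                                 seed = seed))
  }
  structure(list(diversity = div, differentiation = diff, pairwise_fst = pw,
                 correlogram = cgm, correlogram_male = cg_m,
                 correlogram_female = cg_f, mtdna = mt,
                 provenance = list(
                   n_individuals = nrow(ds$alleles), n_loci = length(ds$loci),
                   grouping = grouping, n_boot = n_boot, n_perm = n_perm,
                   seed = seed,
                   missing_policy = "pairwise deletion per locus",
                   d_combination = diff$jost_d$combination)),
            class = "empirical_report")
}

#' @export
print.empirical_report <- function(x, ...) {
  cat("== diversity (per", x$provenance$grouping, ") ==\n")
  print(x$diversity, row.names = FALSE, digits = 3)
  cat("\n== differentiation ==\n")
  for (d in x$differentiation) print(d)
  cat("\n== spatial autocorrelation ==\n")
  print(x$correlogram)
  if (!is.null(x$mtdna)) {
    cat("\n== mtDNA ==\n")
    print(x$mtdna$table)
    print(x$mtdna$h, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' F'st-by-migration plot for a simulation study
#'
#' @param x a `study_result`.
#' @param empirical optional horizontal reference value (e.g. the empirical
#'   overall F'st).
#' @return a ggplot object.
#' @export
plot_fpst_by_migration <- function(x, empirical = NULL) {
  d <- x$fpst_summary
  level <- mean_fpst <- ci_low <- ci_high <- NULL # NSE bindings
  p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(level), y = mean_fpst)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                           width = 0.15) +
    ggplot2::labs(x = "migration rate m", y = "overall F'st across regions") +
    ggplot2::theme_minimal()
  if (!is.null(empirical))
    p <- p + ggplot2::geom_hline(yintercept = empirical, colour = "grey60")
  p
}

#' Tidy CSV export of the differentiation estimates
#'
#' One row per estimator x locus plus the multi-locus rows, with CIs and
#' combination conventions; the format mirrors how the estimates are usually
#' tabulated.
#'
#' @param report an `empirical_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_differentiation_csv <- function(report, path) {
  rows <- NULL
  for (d in report$differentiation) {
    per <- d$per_locus
    names(per)[2L] <- "estimate"
    rows <- rbind(rows,
                  data.frame(estimator = d$estimator, locus = per$locus,
                             estimate = per$estimate, ci_low = NA_real_,
                             ci_high = NA_real_, perm_p = NA_real_,
                             combination = ""),
                  data.frame(estimator = d$estimator, locus = "ALL",
                             estimate = d$estimate, ci_low = d$ci_low,
                             ci_high = d$ci_high,
                             perm_p = if (is.null(d$perm_p)) NA_real_ else d$perm_p,
                             combination = d$combination))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (one simulation, writes genepop + metadata),
#' `study` (the replicated power analysis, writes JSON + CSV), `analyze`
#' (empirical battery on genepop + metadata CSV), `fixtures` (writes a toy
#' dataset; presets `null`/`structured`). A thin wrapper script is installed
#' at `inst/exec/reefconn`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 ok, 2 usage error), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: reefconn <simulate|study|analyze|fixtures> [options]",
    "  simulate --seed <int> --out <dir> [--migration <m>]",
    "  study    --seed <int> --out <dir> [--replicates <n>]",
    "  analyze  --genotypes <genepop> --metadata <csv> --out <dir> [--mtdna <fasta>] [--seed <int>]",
    "  fixtures --preset <null|structured> --out <dir> [--seed <int>]",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i[1L] == length(args)) stop("missing value for ", flag, call. = FALSE)
    args[i[1L] + 1L]
  }
  fail <- function(msg) { message(msg, "\n", usage); invisible(2L) }
  if (!length(args)) return(fail("no subcommand given"))
  cmd <- args[1L]
  args <- args[-1L]
  known <- c("--seed", "--out", "--migration", "--replicates", "--genotypes",
             "--metadata", "--mtdna", "--preset")
  flags <- grep("^--", args, value = TRUE)
  if (length(bad <- setdiff(flags, known)))
    return(fail(paste("unknown flag(s):", paste(bad, collapse = " "))))
  out <- opt("--out")
  if (is.null(out)) return(fail("--out is required"))
  seed <- as.integer(opt("--seed", "1"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_provenance <- function(extra = list()) {
    jsonlite::write_json(
      c(list(command = cmd, seed = seed,
             version = as.character(utils::packageVersion("reefconn")),
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra),
      file.path(out, "provenance.json"), auto_unbox = TRUE)
  }
  status <- tryCatch({
    if (cmd == "simulate") {
      m <- as.numeric(opt("--migration", "0.01"))
      cfg <- seascape_config(migration_rate = m)
      ds <- sample_seascape(run_simulation(cfg, seed), cfg)
      write_genepop(ds, file.path(out, "simulated.gen"))
      write_metadata_csv(ds, file.path(out, "simulated_metadata.csv"))
      log_provenance(list(migration_rate = m, config_hash = .config_hash(cfg)))
      0L
    } else if (cmd == "study") {
      nrep <- as.integer(opt("--replicates", "10"))
      res <- run_simulation_study(n_replicates = nrep, seed = seed)
      write_study_result(res, file.path(out, "study_result.json"))
      utils::write.csv(res$fpst_summary, file.path(out, "fpst_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(res$correlogram_summary,
                       file.path(out, "correlogram_summary.csv"), row.names = FALSE)
      log_provenance(list(n_replicates = nrep))
      0L
    } else if (cmd == "analyze") {
      gp <- opt("--genotypes"); md <- opt("--metadata")
      if (is.null(gp) || is.null(md))
        return(fail("analyze needs --genotypes and --metadata"))
      rep <- run_empirical_analysis(gp, md, mtdna = opt("--mtdna"), seed = seed)
      utils::write.csv(rep$diversity, file.path(out, "diversity.csv"),
                       row.names = FALSE)
      write_differentiation_csv(rep, file.path(out, "differentiation.csv"))
      write_correlogram_csv(rep$correlogram, file.path(out, "correlogram.csv"))
      log_provenance(list(genotypes = gp, metadata = md))
      0L
    } else if (cmd == "fixtures") {
      preset <- opt("--preset", "null")
      ds <- if (preset == "null") {
        make_toy_fixture(rep(0.2, 5), n_per_pop = c(30, 30, 30, 30),
                         seed = seed, n_loci = 8L)
      } else {
        a <- make_toy_fixture(rep(list(c(0.9, 0.05, 0.05)), 8L), c(30),
                              seed = seed)
        b <- make_toy_fixture(rep(list(c(0.05, 0.05, 0.9)), 8L), c(30),
                              seed = seed + 1L)
        b$ind$individual_id <- paste0("b_", b$ind$individual_id)
        b$ind$reef_id <- b$ind$region_id <- "pop2"
        rownames(b$alleles) <- b$ind$individual_id
        rbind_genotypes(a, b)
      }
      write_genepop(ds, file.path(out, paste0(preset, ".gen")))
      write_metadata_csv(ds, file.path(out, paste0(preset, "_metadata.csv")))
      log_provenance(list(preset = preset))
      0L
    } else fail(paste("unknown subcommand:", cmd))
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
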