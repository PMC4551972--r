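# Forward-time simulator of microsatellite evolution on a 2-D stepping-stone
# grid of reefs.
#
# Each reef holds a constant number N_e of diploid, monoecious individuals.
# One generation is: (1) random union of gametes within each reef (parents
# uniform with replacement, selfing excluded, Mendelian transmission);
# (2) per-transmitted-allele mutation (single-step +/-1 with reflecting
# bounds, or k-allele); (3) conservative migration: neighboring reefs swap
# equal numbers of individuals, the number drawn binomially so that each
# individual's total emigration probability is the configured m split
# uniformly over its reef's von Neumann neighbors.

# calibrated single-step mutation rate reproducing the empirical mean
# multilocus heterozygosity (~0.79) at equilibrium in a single deme of
# N_e = 400 (see calibrate_mutation_rate); frozen from a calibration run
# with seed 20150729.
.default_mu <- 0.0066459

#' Build a seascape simulation configuration
#'
#' Defaults describe a reef network of 8 x 8 reefs of 20 km2 at a census
#' density of 2 sharks/ha with an effective-to-census size ratio of 1:10,
#' giving N_c = 4000 and N_e = 400 per reef; 16 microsatellite loci evolving
#' under single-step mutation at a rate calibrated to the empirical mean
#' heterozygosity; 100 non-overlapping generations; migration fraction m
#' exchanged with neighboring reefs each generation.
#'
#' @param ... overrides for any of: `grid_rows`, `grid_cols`, `reef_area_km2`,
#'   `density_per_ha`, `ne_nc_ratio`, `n_loci`, `mutation_rate`,
#'   `mutation_model` ("single_step" or "k_allele"), `n_allele_states`,
#'   `init_allele_states`, `migration_rate`, `n_generations`,
#'   `n_replicates`, `reef_spacing_km`, `torus`.
#' @return object of class `seascape_config` with the derived per-reef
#'   census size `Nc` and effective size `Ne`.
#' @export
seascape_config <- function(...) {
  cfg <- list(grid_rows = 8L, grid_cols = 8L, reef_area_km2 = 20,
              density_per_ha = 2, ne_nc_ratio = 0.1, n_loci = 16L,
              mutation_rate = .default_mu, mutation_model = "single_step",
              n_allele_states = 40L, init_allele_states = 40L,
              migration_rate = 0.01, n_generations = 100L, n_replicates = 10L,
              reef_spacing_km = 30, torus = FALSE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg$mutation_model <- match.arg(cfg$mutation_model, c("single_step", "k_allele"))
  # derived demography: 1 km2 = 100 ha
  cfg$Nc <- as.integer(round(cfg$reef_area_km2 * 100 * cfg$density_per_ha))
  cfg$Ne <- as.integer(round(cfg$Nc * cfg$ne_nc_ratio))
  cfg$n_reefs <- as.integer(cfg$grid_rows * cfg$grid_cols)
  with(cfg, {
    if (Ne < 2L) stop("derived N_e per reef must be >= 2 (got ", Ne, ")")
    if (Ne > Nc) stop("N_e exceeds N_c (ne_nc_ratio > 1)")
    if (migration_rate < 0 || migration_rate >= 1)
      stop("migration_rate must be in [0, 1)")
    if (mutation_rate < 0 || mutation_rate >= 1)
      stop("mutation_rate must be in [0, 1)")
    if (n_loci < 1L || n_generations < 0L || n_replicates < 1L ||
        grid_rows < 1L || grid_cols < 1L)
      stop("counts must be positive")
    if (init_allele_states < 1L || init_allele_states > n_allele_states)
      stop("init_allele_states must lie in [1, n_allele_states]")
  })
  structure(cfg, class = "seascape_config")
}

#' @export
print.seascape_config <- function(x, ...) {
  cat("seascape_config:", x$grid_rows, "x", x$grid_cols, "reefs,",
      "Nc =", x$Nc, ", Ne =", x$Ne, "per reef\n")
  cat("  loci:", x$n_loci, "; mutation", x$mutation_model,
      "mu =", x$mutation_rate, "over", x$n_allele_states, "states",
      "( init over", x$init_allele_states, ")\n")
  cat("  m =", x$migration_rate, ";", x$n_generations, "generations;",
      if (x$torus) "torus" else "bounded grid", "\n")
  invisible(x)
}

# content hash of a config, for provenance / run directories
#' @noRd
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config)[order(names(unclass(config)))], f)
  unname(tools::md5sum(f))
}

# neighbor pairs of the reef grid with per-pair symmetric exchange
# probability: individual emigration probability m is split uniformly over a
# reef's neighbors, and the pair probability is the mean of the two sides so
# that the exchange can be symmetric while sizes stay constant.
.neighbor_pairs <- function(config) {
  R <- config$grid_rows; Cc <- config$grid_cols
  id <- function(r, c) (r - 1L) * Cc + c
  pairs <- NULL
  for (r in seq_len(R)) for (c in seq_len(Cc)) {
    if (c < Cc) pairs <- rbind(pairs, c(id(r, c), id(r, c + 1L)))
    else if (config$torus && Cc > 2L) pairs <- rbind(pairs, c(id(r, c), id(r, 1L)))
    if (r < R) pairs <- rbind(pairs, c(id(r, c), id(r + 1L, c)))
    else if (config$torus && R > 2L) pairs <- rbind(pairs, c(id(r, c), id(1L, c)))
  }
  if (is.null(pairs)) return(list(pairs = matrix(0L, 0L, 2L), prob = numeric(0)))
  deg <- tabulate(c(pairs), config$n_reefs)
  prob <- config$migration_rate * (1 / deg[pairs[, 1L]] + 1 / deg[pairs[, 2L]]) / 2
  list(pairs = pairs, prob = prob)
}

#' Initialize a seascape state
#'
#' Generation 0 has maximal diversity: every gene copy gets an allele state
#' drawn uniformly at random from a central block of `init_allele_states`
#' states (the full state range by default), giving an expected
#' heterozygosity of `1 - 1/init_allele_states`. Lower values emulate
#' lower-diversity initial conditions for sensitivity analyses.
#'
#' @param config a [seascape_config()].
#' @param seed RNG seed (`NULL` continues the current RNG stream).
#' @return object of class `seascape_state`: list with `generation` and
#'   `alleles` (integer matrix, `n_reefs * Ne` rows, two columns per locus;
#'   rows are grouped by reef).
#' @export
init_state <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_reefs * config$Ne
  k0 <- config$init_allele_states
  lo <- (config$n_allele_states - k0) %/% 2L + 1L
  alleles <- matrix(sample.int(k0, n * 2L * config$n_loci, replace = TRUE) + lo - 1L,
                    n, 2L * config$n_loci)
  structure(list(generation = 0L, alleles = alleles), class = "seascape_state")
}

#' Advance the seascape one generation
#'
#' @param state a `seascape_state`.
#' @param config the [seascape_config()] it was built with.
#' @return the state at generation + 1.
#' @export
step_generation <- function(state, config) {
  A <- state$alleles
  n <- nrow(A)
  L <- config$n_loci
  Ne <- config$Ne
  reef_off <- rep.int((seq_len(config$n_reefs) - 1L) * Ne, rep.int(Ne, config$n_reefs))

  moms <- reef_off + sample.int(Ne, n, replace = TRUE)
  dads <- reef_off + sample.int(Ne, n, replace = TRUE)
  # exclude selfing (redraw fathers that equal the mother)
  if (Ne > 1L) {
    clash <- which(dads == moms)
    while (length(clash)) {
      dads[clash] <- reef_off[clash] + sample.int(Ne, length(clash), replace = TRUE)
      clash <- clash[dads[clash] == moms[clash]]
    }
  }

  odd <- 2L * seq_len(L) - 1L
  # Mendelian transmission: one random gene copy from each parent per locus
  um <- sample.int(2L, n * L, replace = TRUE) - 1L
  ud <- sample.int(2L, n * L, replace = TRUE) - 1L
  newA <- matrix(0L, n, 2L * L)
  colrep <- rep(odd, each = n)
  newA[, odd] <- A[cbind(rep.int(moms, L), colrep + um)]
  newA[, odd + 1L] <- A[cbind(rep.int(dads, L), colrep + ud)]

  mu <- config$mutation_rate
  if (mu > 0) {
    K <- config$n_allele_states
    nm <- stats::rbinom(1L, n * 2L * L, mu)
    if (nm > 0L) {
      pos <- sample.int(n * 2L * L, nm)
      v <- newA[pos]
      if (config$mutation_model == "single_step") {
        d <- sample(c(-1L, 1L), nm, replace = TRUE)
        v <- v + d
        v[v < 1L] <- 2L        # reflect at the bounds
        v[v > K] <- K - 1L
      } else {
        # k-allele: jump to a uniformly chosen different state
        w <- sample.int(K - 1L, nm, replace = TRUE)
        v <- ifelse(w >= v, w + 1L, w)
      }
      newA[pos] <- as.integer(v)
    }
  }

  np <- .neighbor_pairs(config)
  if (nrow(np$pairs) && config$migration_rate > 0) {
    for (q in seq_len(nrow(np$pairs))) {
      k <- stats::rbinom(1L, Ne, np$prob[q])
      if (k == 0L) next
      ia <- (np$pairs[q, 1L] - 1L) * Ne + sample.int(Ne, k)
      ib <- (np$pairs[q, 2L] - 1L) * Ne + sample.int(Ne, k)
      tmp <- newA[ia, , drop = FALSE]
      newA[ia, ] <- newA[ib, , drop = FALSE]
      newA[ib, ] <- tmp
    }
  }

  structure(list(generation = state$generation + 1L, alleles = newA),
            class = "seascape_state")
}

#' Run a seascape simulation
#'
#' `n_generations` applications of [step_generation()] from [init_state()];
#' bit-reproducible under a fixed seed and config.
#'
#' @param config a [seascape_config()].
#' @param seed integer RNG seed.
#' @return the final `seascape_state`.
#' @export
run_simulation <- function(config, seed = 1L) {
  set.seed(seed)
  state <- init_state(config)
  for (g in seq_len(config$n_generations))
    state <- step_generation(state, config)
  state
}

# quadrant region label of each reef (four blocks of the grid)
.reef_regions <- function(config) {
  r <- (seq_len(config$n_reefs) - 1L) %/% config$grid_cols + 1L
  c <- (seq_len(config$n_reefs) - 1L) %% config$grid_cols + 1L
  rr <- ifelse(r <= ceiling(config$grid_rows / 2), "N", "S")
  cc <- ifelse(c <= ceiling(config$grid_cols / 2), "W", "E")
  data.frame(reef = seq_len(config$n_reefs), row = r, col = c,
             region = paste0(rr, cc))
}

#' Sample a genotype dataset from a simulated seascape
#'
#' The seascape is partitioned into four quadrant regions; `reefs_per_region`
#' reefs are drawn per region and `individuals_per_reef` individuals per
#' chosen reef (both without replacement). Reef coordinates come from grid
#' position times the inter-reef spacing, so the sampled dataset can feed
#' every downstream analysis including the correlogram.
#'
#' @param state a `seascape_state`.
#' @param config its [seascape_config()].
#' @param reefs_per_region reefs sampled per quadrant (default 3).
#' @param individuals_per_reef individuals per sampled reef (default 10).
#' @param seed RNG seed (`NULL` continues the current stream).
#' @return a [genotype_dataset()].
#' @export
sample_seascape <- function(state, config, reefs_per_region = 3L,
                            individuals_per_reef = 10L, seed = NULL) {
  force(state)  # evaluate any simulation call (and its seeding) first
  if (!is.null(seed)) set.seed(seed)
  if (individuals_per_reef > config$Ne)
    stop("cannot sample ", individuals_per_reef, " individuals from reefs of Ne = ",
         config$Ne)
  regions <- .reef_regions(config)
  take <- NULL
  for (rg in unique(regions$region)) {
    cand <- regions$reef[regions$region == rg]
    if (length(cand) < reefs_per_region)
      stop("region ", rg, " has only ", length(cand), " reefs")
    take <- c(take, cand[sample.int(length(cand), reefs_per_region)])
  }
  rows <- integer(0); reef_id <- character(0)
  for (rf in take) {
    idx <- (rf - 1L) * config$Ne + sample.int(config$Ne, individuals_per_reef)
    rows <- c(rows, idx)
    reef_id <- c(reef_id, rep(paste0("reef_", regions$row[rf], "_", regions$col[rf]),
                              individuals_per_reef))
  }
  ri <- rep(take, each = individuals_per_reef)
  genotype_dataset(state$alleles[rows, , drop = FALSE],
                   paste0("loc", seq_len(config$n_loci)),
                   paste0("sim_ind", seq_along(rows)),
                   reef_id,
                   region_id = regions$region[ri],
                   x_km = (regions$col[ri] - 1) * config$reef_spacing_km,
                   y_km = (regions$row[ri] - 1) * config$reef_spacing_km)
}

# mean expected heterozygosity over loci of (a block of) a state
.state_mean_he <- function(alleles, L) {
  he <- numeric(L)
  for (l in seq_len(L)) {
    a <- c(alleles[, 2L * l - 1L], alleles[, 2L * l])
    p <- tabulate(a) / length(a)
    he[l] <- 1 - sum(p^2)
  }
  mean(he)
}

#' Calibrate the mutation rate to a heterozygosity target
#'
#' Bisection on log10(mu): pilot single-deme simulations are run to mutation-
#' drift equilibrium at the configured per-reef N_e and the mutation rate
#' whose equilibrium mean expected heterozygosity matches `target_He` within
#' `tolerance` is returned. Equilibrium He is measured as a time average over
#' the second half of a run of `burnin_factor * 2 * Ne` generations.
#'
#' @param config a [seascape_config()]; its `Ne`, loci and mutation model are
#'   used.
#' @param target_He target mean expected heterozygosity, in (0, 1).
#' @param tolerance acceptable |He - target|.
#' @param seed RNG seed.
#' @param burnin_factor run length in units of 2*Ne generations (default 4).
#' @param max_iter bisection iterations.
#' @return the calibrated mutation rate, with the achieved He as attribute
#'   `He`.
#' @export
calibrate_mutation_rate <- function(config, target_He = 0.79, tolerance = 0.02,
                                    seed = 1L, burnin_factor = 4, max_iter = 12L) {
  if (target_He <= 0 || target_He >= 1)
    stop("target_He must be in (0, 1)")
  hmax <- 1 - 1 / config$n_allele_states
  if (target_He > hmax - 1e-3)
    stop("target_He = ", target_He, " unreachable with ", config$n_allele_states,
         " allele states (max ~", round(hmax, 3), "); widen n_allele_states")
  one <- seascape_config(grid_rows = 1L, grid_cols = 1L,
                         reef_area_km2 = config$reef_area_km2,
                         density_per_ha = config$density_per_ha,
                         ne_nc_ratio = config$ne_nc_ratio,
                         n_loci = config$n_loci,
                         mutation_model = config$mutation_model,
                         n_allele_states = config$n_allele_states,
                         init_allele_states = config$init_allele_states,
                         migration_rate = 0)
  ngen <- as.integer(ceiling(burnin_factor * 2 * one$Ne))
  eq_he <- function(mu, sd) {
    one$mutation_rate <- mu
    set.seed(sd)
    st <- init_state(one)
    hes <- numeric(0)
    for (g in seq_len(ngen)) {
      st <- step_generation(st, one)
      if (g > ngen / 2 && g %% 10L == 0L)
        hes <- c(hes, .state_mean_he(st$alleles, one$n_loci))
    }
    mean(hes)
  }
  lo <- log10(1e-5); hi <- log10(0.2)
  he_lo <- eq_he(10^lo, seed); he_hi <- eq_he(10^hi, seed + 1L)
  if (target_He < he_lo || target_He > he_hi)
    stop("target_He outside the reachable range [", round(he_lo, 3), ", ",
         round(he_hi, 3), "] for this configuration")
  mu <- NA_real_; he <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    he <- eq_he(10^mid, seed + 1L + it)
    mu <- 10^mid
    if (abs(he - target_He) <= tolerance) break
    if (he < target_He) lo <- mid else hi <- mid
  }
  structure(mu, He = he)
}
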