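# reefconn

Genetic-connectivity analysis for reef-associated marine populations, built
around two arms that share one statistical engine:

1. **An empirical battery** for diploid multilocus genotypes (microsatellites)
   and mtDNA haplotype alignments: diversity indices, the standard
   differentiation estimators with locus-bootstrap confidence intervals and
   permutation tests, and individual-based genotypic spatial autocorrelation
   over membership-defined distance classes.
2. **A simulation power analysis**: a forward-time simulator of
   microsatellite evolution on a 2-D stepping-stone grid of reef
   subpopulations, parameterized from reef demography, whose sampled output
   is pushed through *the same* statistics — answering "if migration between
   neighboring reefs were m, would this battery have detected it?"

The motivating system is shark populations on discontinuous coral-reef
networks (e.g. the Great Barrier Reef), where empirical panmixia is only
interpretable alongside a power analysis, but the machinery is generic.

## Statistics implemented

- Observed heterozygosity H<sub>O</sub>; Nei's unbiased expected
  heterozygosity H<sub>E</sub> = 2n/(2n−1)·(1 − Σp²); rarefaction allelic
  richness A<sub>r</sub> = Σ<sub>a</sub> [1 − C(N−N<sub>a</sub>, g)/C(N, g)];
  fixation index F<sub>is</sub> (Weir–Cockerham small-sample *f*) with
  locus-bootstrap CI.
- Weir–Cockerham **θ** (F<sub>st</sub>) from the 1984 variance components
  (loci combined by summing components); Hedrick's
  **G′<sub>st</sub>** = G<sub>st</sub>(k−1+H<sub>S</sub>)/[(k−1)(1−H<sub>S</sub>)]
  with Nei–Chesser-corrected H<sub>S</sub>, H<sub>T</sub>; Jost's
  **D** = (k/(k−1))·(H<sub>T</sub>−H<sub>S</sub>)/(1−H<sub>S</sub>); the
  standardized **F′<sub>st</sub>** = F<sub>st</sub>/F<sub>st(max)</sub>,
  where F<sub>st(max)</sub> re-runs the estimator on a dataset recoded so
  every population's alleles are unique. All with 1000-locus-bootstrap 95%
  CIs; F′<sub>st</sub> with a permutation test.
- Squared codominant genotypic distances (half squared Euclidean distance
  between allele-count vectors), distance-class autocorrelation **r** from
  the double-centered covariance matrix, 999-permutation null envelopes,
  999-bootstrap CIs, and the nonparametric correlogram heterogeneity test
  (per-class t², whole-correlogram ω).
- mtDNA: haplotype collapsing, haplotype diversity
  h = n(1−Σp²)/(n−1), nucleotide diversity π, and haplotype-frequency
  F<sub>st</sub> with permutation p-values.

Genotypes travel as genepop 4.x files plus a sidecar metadata CSV
(`individual_id, reef_id, region_id, x_km, y_km, sex`); haplotypes as
aligned FASTA with `>id|region` headers.

## The seascape simulator

`seascape_config()` defaults encode the study conditions: an 8×8 grid of
20 km² reefs at a census density of 2 sharks/ha and N<sub>e</sub>:N<sub>c</sub>
= 1:10, i.e. N<sub>c</sub> = 4000 and N<sub>e</sub> = 400 diploids per reef;
16 loci under single-step mutation (rate calibrated against a
heterozygosity target, see the vignette); maximal initial diversity; 100
non-overlapping generations; per-generation migration fraction m exchanged
symmetrically with von Neumann neighbor reefs. `sample_seascape()` draws
10 individuals × 3 reefs × 4 quadrant regions (n = 120) for analysis.

## Worked example

Simulate a seascape at 10% migration, sample it, and run the battery:

```r
library(reefconn)
cfg <- seascape_config(migration_rate = 0.10)
ds  <- sample_seascape(run_simulation(cfg, seed = 7), cfg)

diversity_table(ds, "region", n_boot = 200, seed = 1)
#>   group  N  A_r   H_O   H_E      F_is F_is_ci_low F_is_ci_high
#> 1    NW 30 29.6 0.963 0.971  8.51e-03    -0.00719      0.02186
#> 2    NE 30 29.2 0.969 0.969  7.42e-05    -0.01589      0.01317
#> 3    SW 30 30.4 0.960 0.973  1.31e-02    -0.00504      0.03695
#> 4    SE 30 28.6 0.977 0.968 -9.16e-03    -0.02384      0.00193

meirmans_fpst(ds, "region", n_boot = 1000, n_permutations = 999, seed = 1)
#> meirmans_fpst = 0.1529  [95% CI 0.1113, 0.1929; 1000 locus bootstraps]  perm p = 0.0010 (999 permutations)
#>   grouping: region ( 4 groups ); multi-locus: multi-locus distance AMOVA over maximal-recoding AMOVA

correlogram(ds, n_perm = 999, n_boot = 999, seed = 1)
#> genotypic spatial autocorrelation ( 999 permutations, 999 bootstraps )
#>           class n_pairs         r   null_lo   null_hi   boot_lo   boot_hi      t2  t2_p
#>     within_reef     540  0.009796 -0.011705 -0.004677  0.005156  0.014228 105.664 0.001
#>   within_region    1200 -0.006830 -0.010583 -0.006160 -0.009144 -0.004393   1.777 0.177
#>  between_region    5400 -0.010573 -0.008977 -0.007845 -0.011639 -0.009490  57.619 0.001
#> heterogeneity: omega = 165.060, p = 0.0010
```

Reading it: after 100 generations at m = 0.10 the four quadrant regions are
still clearly differentiated (overall F′<sub>st</sub> = 0.15, permutation
p = 0.001), individuals within a reef are genetically more similar than
random (within-reef r above its null envelope), and the correlogram as a
whole departs from the no-structure null (ω, p = 0.001) — so at this
migration level the battery has ample power. A field dataset that shows
*none* of these signals therefore implies migration well above it.

Replicated power curves come from the orchestrator:

```r
study <- run_simulation_study(seascape_config(),
                              migration_levels = c(0.01, 0.10, 0.25),
                              n_replicates = 10, seed = 1)
study$fpst_summary       # mean F'st per migration level with replicate CIs
plot_fpst_by_migration(study)
```

Empirical data run through the same battery from files:

```r
report <- run_empirical_analysis("genotypes.gen", "metadata.csv",
                                 mtdna = "nd4.fasta")
```

A thin CLI wrapper (`inst/exec/reefconn`) exposes `simulate`, `study`,
`analyze` and `fixtures` subcommands over these functions.

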