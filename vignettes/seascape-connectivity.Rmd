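---
title: "Seascape connectivity: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seascape connectivity: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reefconn)
```

This vignette is the package's account of its science: the forward model,
the statistics, the conventions behind every number it prints, and the
places where the design was genuinely open and a choice had to be made.

## The question the package answers

Marine populations on discontinuous reef networks often show no detectable
genetic structure across hundreds of kilometres. On its own that is weak
evidence for high gene flow: drift in large populations is slow, so even
moderate isolation can leave allele frequencies indistinguishable over the
sampled time scale. The package therefore couples the empirical battery to
a simulation arm: a seascape of reef subpopulations is evolved forward in
time at known migration rates, sampled with the same design as the field
study, and pushed through the identical statistics. If simulated migration
at rate *m* produces signals that the empirical data lack, migration in the
field plausibly exceeds *m*.

## Forward model

Reefs form a bounded 2-D stepping-stone grid (`grid_rows` × `grid_cols`,
default 8 × 8). Each reef holds a constant number N<sub>e</sub> of diploid,
monoecious individuals; the default N<sub>e</sub> = 400 derives from reef
demography: 20 km² per reef × 2 animals/ha gives a census size
N<sub>c</sub> = 4000, reduced by an effective-to-census ratio of 1:10. The
simulation operates directly on N<sub>e</sub> individuals (an
effective-size forward simulation), not on N<sub>c</sub> with subsequent
thinning.

One generation applies, in order:

1. **Reproduction.** Within each reef, N<sub>e</sub> offspring are formed
   by random union of gametes: both parents drawn uniformly with
   replacement, selfing excluded, one Mendelian allele per parent per
   locus. This is the simplest neutral mating scheme; it makes the variance
   effective size equal the census of the reef, which is conservative
   (slower drift) relative to schemes with unequal reproductive success.
2. **Mutation.** Each transmitted allele mutates with probability μ.
   Default model is single-step (±1 repeat unit, reflecting at the state
   bounds, `n_allele_states` = 40); a k-allele model is available as a
   sensitivity hook because microsatellite homoplasy assumptions affect
   equilibrium diversity.
3. **Migration.** Neighboring reefs (von Neumann adjacency; 2–4 neighbors
   on the bounded grid, uniformly 4 in the optional torus mode) exchange
   individuals symmetrically. The number exchanged per neighbor pair is
   binomial with a probability chosen so each individual's total emigration
   probability is *m* split evenly over its reef's neighbors; symmetric
   exchange keeps every reef exactly at N<sub>e</sub>. Edge reefs
   consequently exchange fewer migrants — a boundary rule has to be chosen
   on a bounded grid, and this one is the conservative reading of "a
   fraction m migrates to neighboring reefs".

Generation 0 has maximal diversity: every gene copy drawn uniformly from a
central block of `init_allele_states` states (default: the full 40). The
40-state range mirrors the allelic richness of typical microsatellite
panels (up to ~34 alleles observed per locus in the motivating data).
Setting `init_allele_states` lower emulates lower-diversity initial
conditions; we verified that the standardized differentiation results
depend strongly on this choice (the denominator of F′st scales with
1 − H<sub>S</sub>), which is why it is exposed rather than hard-coded.

**Mutation-rate calibration.** The field rarely reports a usable μ.
`calibrate_mutation_rate()` pins it to an observable: bisection on
log μ against pilot single-deme runs until the mutation–drift equilibrium
mean H<sub>E</sub> at the configured per-reef N<sub>e</sub> matches a
target (default 0.79, a typical multilocus mean for hypervariable
microsatellite panels). The packaged default μ = 0.0066459 is the frozen
output of that calibration (target 0.79 ± 0.01, seed 20150729, runs of
8 N<sub>e</sub> generations with a time-averaged second half). Equilibrium
He is monotone in μ, so the bisection is well posed. Note the calibration
is a single-deme statement: in the full 64-reef metapopulation the
effective population is larger and diversity at generation 100 sits above
the single-deme equilibrium.

**Sensitivity.** The simulated standardized F′st at low migration falls
with μ (mutation acts as a homogenizing force comparable to migration when
μ approaches m), and rises with the initial allelic diversity through the
F′st denominator. Published forward-simulation power analyses in this
field typically do not report their mutation rate or model, so attempts to
reproduce their printed values carry an irreducible configuration
uncertainty of order tens of percent; the
`mutation_rate`, `mutation_model`, `init_allele_states` and `torus` fields
exist so users can probe it with `run_simulation_study()` overrides rather
than trust a single point configuration.

## Statistics and conventions

All estimators run off shared per-locus ingredients with **pairwise
deletion**: an individual missing a locus drops out of that locus only.
Missing data policy is a package choice (the estimators' sources do not fix
one) and is recorded in the report provenance.

- **θ (Weir–Cockerham 1984).** Per locus and allele, components a, b, c;
  multi-locus as Σa / Σ(a+b+c). Negative single-locus estimates are
  retained, never clamped; a dataset with no variation at all reports 0
  (no differentiation), not NA.
- **G′st.** H<sub>S</sub>, H<sub>T</sub> with Nei–Chesser sample-size
  corrections; multi-locus from H̄<sub>S</sub>, H̄<sub>T</sub> averaged over
  loci.
- **D.** Per locus (k/(k−1))(H<sub>T</sub>−H<sub>S</sub>)/(1−H<sub>S</sub>);
  multi-locus as the harmonic mean of per-locus D, the convention matching
  the effective-numbers interpretation. The harmonic mean is undefined when
  a per-locus D is non-positive (common near zero differentiation); the
  implementation then falls back to the arithmetic mean and records which
  convention produced the number in the result's `combination` field.
- **F′st.** F<sub>st</sub>/F<sub>st(max)</sub>, both computed as the
  distance-based AMOVA F<sub>st</sub> on the squared codominant genotypic
  distance matrix (within-individual level suppressed), with
  F<sub>st(max)</sub> from the dataset recoded so each group's alleles are
  unique. The distance-AMOVA flavor was chosen because it is the estimator
  behind the standard spreadsheet implementation of the standardization and
  shares its distance kernel with the autocorrelation module, so the two
  analyses cannot drift apart numerically. The permutation test shuffles
  individuals across groups and uses the *unstandardized* F<sub>st</sub> as
  the statistic — under the null the recoding denominator is exchangeable,
  so the test is equivalent and three times cheaper.
- **Autocorrelation r.** Squared genotypic distances are double-centered
  (Gower) into a covariance matrix C; for class h,
  r(h) = Σ<sub>x≠y∈h</sub> c<sub>xy</sub> / Σ<sub>x≠y∈h</sub>
  (c<sub>xx</sub>+c<sub>yy</sub>)/2. The three default classes are
  membership-defined (same reef / same region, different reef / different
  region) and partition all pairs — in particular the within-region class
  *excludes* same-reef pairs; a metric-binning alternative exists for
  synthetic coordinates. The null permutes individuals' spatial labels
  jointly, keeping genotypes (and hence C) fixed.
- **Heterogeneity test.** Per class t² = (r − mean r<sub>perm</sub>)² /
  var r<sub>perm</sub>; ω sums t² over usable classes; p-values from the
  same permutation stream with the (k+1)/(n+1) correction, which also
  bounds every permutation p away from 0.
- **Bootstrap CIs.** Percentile method throughout: differentiation CIs
  resample loci (1000 by default), r CIs resample pairs within class (999),
  across-replicate study CIs use the percentile of the replicate values
  (10 values; a normal-approximation option exists). Degenerate cases
  (single replicate, < 2 informative loci, empty class) yield flagged NAs,
  never fabricated intervals.
- **mtDNA.** Alignment columns containing N or a gap in any sequence are
  excluded listwise before haplotype collapsing, S, π and F<sub>st</sub>;
  mtDNA F<sub>st</sub> is the haploid variance-partition estimator on
  haplotype frequencies (no substitution-model weighting — a deliberate
  frequency-only reading, documented here because distance-weighted Φ
  variants exist).

Seeds are explicit arguments everywhere randomness enters (fixtures,
bootstraps, permutations, simulations); identical seeds give bit-identical
results, and study results carry a config hash plus the per-replicate seed
table in their provenance block.

## What the synthetic data does and does not emulate

The generator reproduces: HWE genotypes at specified frequencies
(`make_toy_fixture()`), drift/migration/mutation dynamics on the reef grid,
the field sampling design (10 × 3 × 4), and coordinates for the distance
classes. It does not emulate genotyping artefacts (null alleles, allele
binning errors, scoring dropout), departures from HWE within reefs,
overlapping generations, age or sex structure, sex-biased dispersal, or
spatially heterogeneous carrying capacity. Green tests therefore certify
the statistical machinery and the stated power analysis, not robustness to
those field artefacts.

## Problem sizes used by the test suite

The acceptance-level checks run the full study conditions (8×8 grid,
N<sub>e</sub> = 400, 16 loci, 100 generations, 10 replicates × 3 migration
levels, n = 120 samples per replicate). Unit and property tests use reduced
configurations chosen so each law being tested is still sharply expressed:
single demes of N<sub>e</sub> = 50 for the (1 − 1/2N<sub>e</sub>)
heterozygosity decay; two demes of 50 with 48 loci against the classical
identity-by-descent recursion for equilibrium θ; 200 null fixtures × 99
permutations for type-I-error calibration of the permutation tests; N<sub>e</sub> = 10
pilots for the calibration bisection. These sizes are the package's own
trade-off between Monte-Carlo resolution and a test suite that runs in
minutes.

## Known limitations

- The bounded-grid boundary rule, mating system and mutation model are
  assumptions standing in for unreported upstream choices; conclusions that
  hinge on the *absolute* level of simulated F′st at low migration (rather
  than its ordering across migration levels, which is robust) inherit that
  uncertainty.
- The AMOVA F′st treats the region as the population unit and ignores
  substructure among reefs within a region, exactly as the regional-level
  analysis it mirrors.
- Rarefaction richness assumes the missingness mechanism is unrelated to
  genotype (as does pairwise deletion generally).
- The correlogram's membership classes make r estimates between datasets
  comparable only when the sampling design (reefs per region, individuals
  per reef) matches.
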