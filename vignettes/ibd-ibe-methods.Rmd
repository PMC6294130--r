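---
title: "Methods: partitioning isolation by distance and by environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning isolation by distance and by environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators, numerical choices and known
limitations behind `ibescape`. The package analyses a sampling design in
which three habitat ecotypes (cloud forest `F`, wet sheltered depressions
`W`, dry exposed slopes `D`) co-occur within each of several localities, so
that geographic separation (isolation by distance, IBD) and ecological
separation (isolation by environment, IBE) can be contrasted on the same
genome-wide SNP data.

## Genotype data and filtering

The central container is a samples × loci dosage matrix counting copies of
the **minor allele** (0/1/2, `NA` for missing), with an optional aligned
read-depth matrix. The minor allele is fixed once per dataset, over all
samples after sample exclusion, and never redefined for subsets — per-subset
redefinition would silently flip effect signs between analyses of different
partitions.

Filtering applies, in order: the user's sample-exclusion list (misplaced
samples are an analyst judgement, not an automatic rule); then per locus
(i) mean read depth over non-missing calls strictly greater than 5 — the
depth rule is read as a per-locus mean because it is a property of the locus,
with a per-call variant (`per_call_depth`) available behind a flag; (ii)
overall MAF strictly greater than 0.05; (iii) call rate at least 0.72.
Missing dosage is a first-class state and is never imputed; each estimator
declares its own missing-data contract (pairwise-complete correlations for
LD, per-pair shared loci for kinship and F_ST, per-locus complete cases for
the scans).

## Population structure

*Kinship.* `K[i,j]` is the mean over shared non-missing loci of
`1 − |d_i − d_j|/2`, the identity-by-state allele-sharing proportion, with a
unit diagonal. Under 15% missingness the pairwise-complete construction is
not exactly positive semi-definite; eigenvalues down to about −10⁻³ of the
largest appear in practice. The mixed model therefore clips negative
eigenvalues to zero and only rejects matrices whose most negative eigenvalue
exceeds 5% of the largest.

*PCoA.* Classical metric scaling (double-centering and eigendecomposition,
via `cmdscale`) of a configurable distance, defaulting to `1 − IBS` so the
ordination lives in the same currency as the mixed-model kinship. Axes are
deterministically oriented (largest-magnitude loading positive). Negative
eigenvalues — possible because `1 − IBS` need not be Euclidean — are excluded
from the explained-variance normalization and reported separately.

*AMOVA.* Sums of squares are computed from squared Euclidean distances
between dosage vectors (pairwise-complete, rescaled by the locus count),
decomposed over localities / populations-within-locality / within-population
strata, with the standard unequal-group-size coefficients relating mean
squares to the variance components. Components are reported raw (they can be
negative); percentages truncate at zero behind a flag that defaults on.
Permutation significance for AMOVA is deliberately out of scope — the
analysis uses only the percentage decomposition.

*ΔK.* The Evanno statistic consumes a plain table of per-K, per-run
log-likelihoods from an external clustering program; the Bayesian clustering
itself is out of scope. ΔK = |L''(K)|/s(K) is defined only for interior K
with at least two runs and positive likelihood spread; zero spread is flagged
rather than divided by.

## Genome–environment association

Association is modelled as **dosage regressed on the factor** (not factor on
dosage), so a categorical locality with many levels, or a single ordinal
habitat-rank regressor, are both tested by one partial *F* test of the factor
block given intercept and covariate. Ecological factors enter as the rank
value on the configured axis; the default codings are frost `F=1, W=2, D=3`
and moisture `D=1, F=2, W=3` (frost exposure increases out of the forest
onto the open slopes; soil moisture is highest in the irrigated depressions
and lowest on the dry slopes). Both codings are configurable inputs, since
rank codes are a field judgement.

The phylogenetic covariate is the first principal coordinate of a
population-level distance matrix (a patristic matrix from a supplied tree,
or any symmetric matrix), each sample receiving its population's centered
score. One axis is the default — the drift structure of the study region is
approximately one-dimensional (a north–south cordillera chain) — with a
multi-axis option behind a flag. A caution discovered on synthetic data: if
the covariate matrix is derived from the genotypes themselves and habitat
differentiation dominates drift, the first axis *is* the habitat axis and
absorbs the signal under test; the covariate should come from an independent
phylogenetic reconstruction.

The mixed model is `y = Xβ + u + e`, `u ~ N(0, σ²_g K)` with REML profiling
of δ = σ²_e/σ²_g after a single eigendecomposition of `K` per missing-data
pattern (patterns are cached). The δ grid is 61 points log-spaced over
log₁₀ δ ∈ [−5, 5], refined by golden-section search to 10⁻⁶. `emma_full`
re-estimates δ per locus under the full design; `p3d` estimates one δ by
maximizing the *summed* per-locus REML criterion of the factor-free null over
an evenly spaced subsample of loci (200 by default) and reuses it everywhere
— the standard single-phenotype P3D shortcut has no literal analogue when
every locus is its own response, and pooling the null criterion is the
closest single-estimate counterpart. Identity kinship collapses the mixed
model onto the GLM exactly, which the tests assert.

Significance uses strict Bonferroni α/n per dataset (no FDR — the analysis
design uses a single hard threshold); p-values are floored at 10⁻³⁰⁰ so
perfect fits survive log transforms. Thresholds are always derived from α/n
at run time, never hard-coded from their printed roundings.

Two calibration facts about the GLM scan on integer dosage, measured by the
test suite: the balanced three-level rank design makes the factor slope
*exactly* zero with probability ≈ 5% (a difference of two integer sums), so
null p-values carry an atom at 1 and are mildly conservative in the far tail,
while the genomic inflation factor stays at 1.00. Calibration is therefore
asserted by λ_GC and by KS at a locus count where the discreteness artifact
is below the test's resolution; at very large locus counts a
continuous-uniform KS necessarily rejects on the atom.

## Divergence, migration, and the Mantel report

*F_ST.* The two-population Weir–Cockerham (1984) components a (among
populations), b (among individuals within populations), c (within
individuals) are computed per locus from sample sizes, minor-allele
frequencies and observed heterozygosities, and combined as the ratio of sums
θ̂ = Σa/Σ(a+b+c). Loci with undefined components are excluded and counted.
Note the finite-sample behaviour verified by the oracle tests: two
populations with *identical* samples give θ̂ ≈ −1/(2(n−1)), not exactly zero
— the a-component's bias correction — while a fixed difference gives exactly
θ̂ = 1.

*Migration.* N_e_m inverts the island-model equilibrium θ = 1/(1+4Nm); the
default closed-form moment estimator is complemented by a grid pseudo-ML
over log Nm ∈ [−2, 2] fitting the per-locus θ̂ spread. Full coalescent ML
migration inference is out of scope; the network summaries and group
contrasts depend only on relative magnitudes. Negative θ̂ maps to a capped
estimate (default ceiling 20) so network summaries stay finite; every cap is
logged. Group contrasts (among habitats within locality vs within habitat
across localities) use mean ± SE, empirical 2.5–97.5% CIs, and a two-sided
Mann–Whitney U test — the contrast test is unspecified in the source
analysis, and the rank-sum test is the conservative nonparametric default
for small, skewed sets of pairwise estimates. N_e_m > 1 flags conventional
panmixia.

*Distances.* Geographic distances are haversine great-circle arcs between
population centroids (member-sample mean coordinates) on the mean Earth
radius 6371.0087714 km. Ecological distances are absolute habitat-rank
differences per axis.

*Mantel tests.* r is the Pearson correlation of strict upper triangles; the
null jointly permutes rows and columns of the second matrix; the alternative
is one-sided positive (IBD/IBE predict positive correlation) with the
add-one convention p = (#{r* ≥ r} + 1)/(B + 1). Per-test seeds derive
deterministically from (master seed, dataset name, distance name), so the
full report is byte-reproducible. Bonferroni divides α by the dataset's pair
count N_PW — reproducing the per-dataset thresholds of the study table —
rather than by the total number of tests.

A combinatorial limit worth knowing: with 7 populations whose habitats are
(F, W, D, F, W, D, D), about 24 of the 5040 label permutations fix the
habitat-rank distance matrix, so the attainable Mantel p-value floor is
≈ 0.005 — above α/21 ≈ 0.0024. No data can clear that per-dataset Bonferroni
bar on such a partition; the package's recovery checks therefore judge
contrast-partition significance at α = 0.05 and reserve the α/N_PW bar for
the larger partitions, using 10,000 permutations where 1/(B+1) must resolve
it (α/171 ≈ 2.9×10⁻⁴ is unreachable with 1,000 permutations).

## The synthetic-data generator

`simulate_dataset` emulates the study design: 6 localities at approximately
the real centroids, 3 habitats each plus a second taxon in one dry-slope
cell (19 populations), 162 samples, 1,273 loci of which 60 are habitat loci.
Ancestral frequencies are uniform on [0.1, 0.9]. Drift follows a
nearest-neighbor chain rooted at the northernmost locality: the first
locality inherits the ancestral frequency, and each subsequent locality is a
Balding–Nichols draw around its nearest placed neighbor with
`F = d/(d + d₀)`, d₀ = 300 km — chain topology rather than a full pairwise
covariance because it is transparent, monotone in distance, and matches the
essentially linear geography. Habitat loci shift the logit of the population
frequency by δ_hab (default 1.2) per centered frost-rank unit; frequencies
leaving (0,1) clamp to [0.001, 0.999] and the clamp count is recorded in the
truth object. The second taxon receives an extra Balding–Nichols step with
F = 0.02, enough to separate it without creating a new drift axis.
Missingness is uniform at 15%; depths are 1 + NB(mean 11, dispersion 3).
The truth object carries the planted locus ids, expected population
frequencies, and the chain-path distance matrix — the simulation's true
"phylogeny", which is the appropriate input for the phylogenetic covariate
in recovery tests.

What the generator does *not* emulate: linkage between loci (all loci are
independent, so LD pruning on simulated data finds only sampling LD),
sequencing error, allele dropout or depth-dependent genotyping error,
selection through time, and admixture/hybridization events. Passing recovery
tests on this generator shows the estimators work under the assumed
statistical structure, not that the biological data meet those assumptions.

At these defaults the per-step drift parameters are large (F ≈ 0.16–0.40),
matching the differentiation range observed in the real system (θ̂ up to
≈ 0.45). A consequence the test suite documents honestly: about half of the
planted-locus frequencies sit against the clamp in some localities, so the
single-regressor GLM recovers ≈ 55% of planted loci at the Bonferroni bar
(with essentially no false positives), rising toward 80% at δ_hab = 1.6;
recall increases monotonically in δ_hab, which is the property the generator
is designed to exercise.

`simulate_island_model` is a two-deme Wright–Fisher simulator for validating
the migrant-number estimator. Migrants are drawn from the metapopulation
average frequency — the classical island-model assumption under which the
equilibrium differentiation follows θ = 1/(1+4Nm). Drawing migrants only
from the other deme (available as an option) doubles the effective exchange
rate in a two-deme system and equilibrates near 1/(1+8Nm); the default is
the model the estimator inverts. End sampling draws allele copies without
replacement from the 2N pool and pairs them into diploid genotypes.

## The partition series and pipeline

Population subsets (entire; locality-contrast; habitat-contrast, each a
locality list) cross with marker subsets (all; associated with locality,
frost, moisture — each population subset using its own scan's selections).
Every combination is re-filtered with the same MAF and call-rate rules (the
depth rule is a raw-data property and is not re-applied) and emitted only
with ≥ 2 polymorphic loci. In the study design exactly one combination
(locality-contrast × moisture-associated) is monomorphic, leaving 11
datasets and 33 Mantel tests; the packaged fixture
(`espeletia_design_fixture`) engineers that property deterministically by
confining the minor alleles of the moisture-associated set to the
habitat-contrast localities, with exactly one locus left polymorphic
elsewhere. On freshly scanned synthetic data the emitted count varies with
the seed — the arithmetic of the fixture, not of every simulation.

`run_pipeline` executes filter → structure → scans → partitions → divergence
→ Mantel report from one config (list or YAML), deriving every stage's seed
from the master seed; reruns are byte-identical. The analysis scripts under
`analysis/` present the same computation as a stepwise narrative; the
functions are the interface for everything else.

## Problem sizes used by the test suite

Unit tests run on printed toys (≤ 20 samples, ≤ 30 loci) against independent
oracles (scalar transcriptions, exhaustive permutation enumeration,
brute-force nested ANOVA, GLS at fixed variance ratio, `vegan::mantel` for
the statistic). Calibration and recovery checks use the study-scale
generator (162 samples, 1,273 loci) with 3–20 seeds, 500–2,000 null loci,
Wright–Fisher runs at N = 200 with 500–2,000 loci, and 1,000–10,000 Mantel
permutations; these sizes keep the default suite and the acceptance script
within a few minutes while leaving the statistical assertions well above
their noise floors.

## Known limitations

* Coalescent migration inference, partial Mantel tests and matrix
  regressions, FDR control, genotype imputation and phasing are out of
  scope by design.
* The AMOVA reports components and percentages only (no permutation test).
* The GEA power analysis is specific to the ordinal single-regressor model;
  categorical-habitat scans are available behind a flag but not separately
  calibrated.
* The generator's chain drift cannot represent two-dimensional isolation
  surfaces or barrier effects; IBD enters only through the distance-F curve.
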