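# ibescape

Landscape-genomics analysis of **isolation by distance (IBD)** versus
**isolation by environment (IBE)** for multi-locality, multi-habitat sampling
designs — the situation of the Andean *Espeletia* (frailejón) species
complex, where three contrasting ecotypes (cloud-forest `F`, wet sheltered
depressions `W`, dry exposed slopes `D`) co-occur in each of six páramo
localities. The package asks: is genetic differentiation among populations
explained by geographic separation, by habitat (ecological) separation, or
both — and at which subsets of markers and populations does each signal
dominate?

`ibescape` implements the full pipeline as reusable, tested functions, plus a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so every stage is verifiable on data with known truth.

## What it computes

* **GBS SNP filtering** — mean read count per locus > 5, minor allele
  frequency (MAF) > 5%, genotype call rate ≥ 72%, and an explicit
  sample-exclusion list (`apply_filters`).
* **Population structure** — identity-by-state (IBS) kinship; classical-scaling
  PCoA; hierarchical AMOVA with variance components σ²ₐ (among localities),
  σ²_b (among habitats within locality), σ²_c (within populations); the
  Evanno ΔK statistic `|L''(K)| / s(K)` from external clustering
  log-likelihoods (`ibs_kinship`, `pcoa`, `amova`, `evanno_delta_k`).
* **Genome–environment association (GEA)** — per-SNP scans of dosage on
  locality (categorical) or on ordinal habitat ranks for theoretical frost
  exposure and soil moisture, always with a phylogenetic covariate (first
  principal coordinate of the population distance matrix). Two model
  families: fixed-effect GLM (partial *F* test) and the kinship mixed model
  `y = Xβ + u + e`, `u ~ N(0, σ²_g K)`, fitted by EMMA-style REML with the
  P3D approximation (`glm_scan`, `mlm_scan`); strict Bonferroni selection
  α/n (`bonferroni_threshold`, `select_associated`).
* **Divergence and gene flow** — pairwise Weir–Cockerham (1984) F_ST from
  variance components a, b, c with θ̂ = Σa / Σ(a+b+c); Rousset linearization
  F_ST/(1−F_ST); island-model migrant numbers N_e_m = (1−θ)/(4θ) with
  migration-network group contrasts (`pairwise_fst`, `linearized_fst`,
  `nem_from_fst`, `migration_summary`).
* **IBD/IBE contrasts** — the dataset partition series (3 population subsets ×
  4 marker subsets, combinations with < 2 polymorphic loci dropped), and
  one-sided permutation Mantel tests of linearized F_ST against great-circle
  geographic distance (km) and habitat-rank ecological distances, with
  per-dataset Bonferroni thresholds α/N_PW (`partition_datasets`, `mantel`,
  `ibd_ibe_table`).
* **Synthetic data** — Balding–Nichols allele-frequency simulation with
  chain-structured drift `F_pair(d) = d/(d + d₀)` along the locality
  geography, planted habitat loci (logit shift per frost-rank unit),
  missingness and read depth; and a two-deme Wright–Fisher island model for
  validating the N_e_m estimator (`simulate_dataset`,
  `simulate_island_model`).

## Worked example

The `analysis/` directory holds the numbered workflow. From a scratch
directory:

```sh
Rscript analysis/01_simulate.R 1          # synthetic study design, seed 1
Rscript analysis/02_filter_structure.R
Rscript analysis/03_gea.R
Rscript analysis/04_divergence.R
Rscript analysis/05_ibd_ibe.R 1
```

Stage 1 simulates 162 samples in 19 locality–habitat populations with 1,273
SNPs (60 carrying a planted frost effect). Stage 2 prints

```
filter kept 1045 of 1273 loci
PCoA axes 1-4 explain 30.1 / 9.4 / 3.3 / 2.1 % of variation
AMOVA: 38.3% among localities, 1.5% among habitats within locality, 60.2% within populations
Evanno delta-K argmax at K = 9
```

— drift among localities dominates the simulated structure, as designed.
Stage 3 scans each population dataset; note the genomic inflation λ_GC of the
locality scans (locality *is* the structure) and the deflation of the mixed
model (λ_GC 0.58), which over-controls exactly as a kinship random effect is
expected to when the tested factor is itself the structure:

```
entire dataset: 1045 loci, Bonferroni threshold 4.8e-05 (-log10 4.3)
  glm locality  lambda_GC 33.73, 497 associated SNPs
  glm frost     lambda_GC 1.18, 29 associated SNPs
  glm moisture  lambda_GC 1.02, 4 associated SNPs
...
MLM (P3D) frost scan: lambda_GC 0.58 (GLM above), delta 1e-05
```

Stage 5 prints the Mantel report (excerpt):

```
entire   x all       N_PW 171 SNPs 1045  r(geo)  0.97  r(frost) -0.08  r(moist) -0.09  thr 0.0003
locality x all       N_PW  66 SNPs 1004  r(geo)  0.99  r(frost) -0.13  r(moist) -0.14  thr 0.0008
habitat  x all       N_PW  21 SNPs  901  r(geo)  0.98  r(frost) -0.07  r(moist) -0.17  thr 0.0024
habitat  x frost     N_PW  21 SNPs   14  r(geo)  0.01  r(frost)  0.85  r(moist)  0.13  thr 0.0024
```

The headline contrast is the last row against the first three: across whole
datasets genetic differentiation tracks geography (r ≈ 0.97–0.99), but on the
habitat-contrast populations restricted to frost-associated markers the
geographic correlation collapses (r ≈ 0.01) and the frost-rank correlation
takes over (r ≈ 0.85) — the IBE signal emerging from under a dominant IBD
pattern.

The same pipeline runs from a single config over real inputs
(VCF + metadata TSV):

```r
library(ibescape)
report <- run_pipeline(list(genotypes = "snps.vcf", metadata = "samples.tsv",
                            filter = list(excluded_samples = c("s101", "s102")),
                            model_family = "both", n_perm = 1000,
                            seed = 42, out_dir = "results"))
```

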