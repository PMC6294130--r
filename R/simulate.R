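#' Default study-design localities
#'
#' Six northern-Andes localities at approximately the real centroids
#' (Santurban, Cocuy, Guantiva, Chingaza, Sumapaz in the Eastern Cordillera;
#' Ruiz in the Central Cordillera), north to south.
#'
#' @return data.frame with `locality`, `latitude`, `longitude`.
#' @export
default_localities <- function() {
  data.frame(
    locality = c("SA", "CO", "GU", "CH", "SU", "RU"),
    latitude = c(7.30, 6.41, 6.00, 4.52, 4.26, 4.89),
    longitude = c(-72.95, -72.36, -72.75, -73.75, -74.21, -75.32),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The defaults mirror the study design: 6 localities at approximately the
#' real centroids, 3 habitats each plus one extra co-occurring taxon in the
#' dry slopes of Guantiva (19 populations), 162 samples, 1,273 biallelic loci
#' of which 60 carry a habitat effect. Differentiation among localities grows
#' with geographic distance through the Balding-Nichols parameter
#' `F_pair(d) = d / (d + d0)`; habitat loci are shifted on the logit scale by
#' `delta_hab` per centered frost-rank unit.
#'
#' @param localities data.frame of locality, latitude, longitude.
#' @param n_samples total samples, allocated as evenly as possible over the
#'   populations (default 162).
#' @param n_neutral_loci,n_habitat_loci locus counts (defaults 1213 + 60 =
#'   1273).
#' @param ancestral_range uniform law for the ancestral minor-allele
#'   frequency (default `c(0.1, 0.9)`).
#' @param d0 half-saturation distance (km) of the drift curve (default 300).
#' @param delta_hab logit-scale habitat effect per centered frost-rank unit
#'   at habitat loci (default 1.2).
#' @param taxon_f extra Balding-Nichols drift applied to the second taxon
#'   sharing a locality-habitat cell (default 0.02).
#' @param missingness per-call missing probability (default 0.15).
#' @param depth_mean,depth_dispersion negative-binomial read-depth law for
#'   non-missing calls (mean 12, dispersion 3); depths are shifted to be >= 1.
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(localities = default_localities(), n_samples = 162,
                       n_neutral_loci = 1213, n_habitat_loci = 60,
                       ancestral_range = c(0.1, 0.9), d0 = 300,
                       delta_hab = 1.2, taxon_f = 0.02, missingness = 0.15,
                       depth_mean = 12, depth_dispersion = 3, seed = 1L) {
  stopifnot(n_samples > 0, n_neutral_loci >= 0, n_habitat_loci >= 0,
            d0 > 0, missingness >= 0, missingness < 1)
  structure(list(localities = localities, n_samples = n_samples,
                 n_neutral_loci = n_neutral_loci,
                 n_habitat_loci = n_habitat_loci,
                 ancestral_range = ancestral_range, d0 = d0,
                 delta_hab = delta_hab, taxon_f = taxon_f,
                 missingness = missingness, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw around p with differentiation F; F <= 0 returns p
rbn <- function(p, F) {
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  out <- p
  idx <- F > 1e-12
  if (any(idx)) {
    Fp <- F[idx] <- pmin(F[idx], 1 - 1e-12)
    a <- p[idx] * (1 - Fp) / Fp
    b <- (1 - p[idx]) * (1 - Fp) / Fp
    out[idx] <- stats::rbeta(sum(idx), a, b)
  }
  out
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate a study-design genotype dataset
#'
#' Drift among localities follows a nearest-neighbor geographic chain starting
#' at the northernmost locality: the first locality inherits the ancestral
#' frequency and each subsequent locality is a Balding-Nichols draw around its
#' nearest already-placed neighbor with `F = d / (d + d0)` for the link
#' distance `d`. All populations of a locality share its frequency except at
#' habitat loci, where the logit is shifted by
#' `delta_hab * (frost_rank - mean rank)`; a second taxon sharing a
#' locality-habitat cell receives an extra small Balding-Nichols perturbation
#' (`taxon_f`). Genotypes are Binomial(2, p), then missingness and per-call
#' depths are applied.
#'
#' @param config a `sim_config`.
#' @return List with `genotypes` (a `genotype_matrix`), `samples` (a
#'   `sample_table`) and `truth` (habitat-locus ids, expected per-population
#'   frequencies, clamp count, and the config echo).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  locs <- config$localities
  # 19 populations: 6 localities x {F, W, D} + a second taxon in GU dry slopes
  pops <- data.frame(
    locality = rep(locs$locality, each = 3),
    habitat = rep(c("F", "W", "D"), times = nrow(locs)),
    taxon = "A", stringsAsFactors = FALSE)
  extra_loc <- if ("GU" %in% locs$locality) "GU" else locs$locality[1]
  pops <- rbind(pops, data.frame(locality = extra_loc, habitat = "D",
                                 taxon = "B", stringsAsFactors = FALSE))
  n_pop <- nrow(pops)
  base <- config$n_samples %/% n_pop
  extra <- config$n_samples %% n_pop
  pops$n <- base + c(rep(1L, extra), rep(0L, n_pop - extra))

  # nearest-neighbor chain over localities, rooted at the northernmost
  cd <- as.matrix(stats::dist(cbind(locs$latitude, locs$longitude)))
  gd <- geographic_distances(
    sample_table(data.frame(sample_id = locs$locality,
                            locality = locs$locality, habitat = "F",
                            latitude = locs$latitude,
                            longitude = locs$longitude)),
    populations = paste0(locs$locality, "_F"))
  dimnames(gd) <- list(locs$locality, locs$locality)
  order_chain <- integer(0)
  parent <- integer(0)
  current <- which.max(locs$latitude)
  order_chain <- current
  while (length(order_chain) < nrow(locs)) {
    remaining <- setdiff(seq_len(nrow(locs)), order_chain)
    d_to_placed <- gd[remaining, order_chain, drop = FALSE]
    pick <- which(d_to_placed == min(d_to_placed), arr.ind = TRUE)[1, ]
    order_chain <- c(order_chain, remaining[pick[1]])
    parent <- c(parent, order_chain[pick[2]])
  }
  # patristic distances of the drift topology: km summed along tree paths
  chain_km <- matrix(0, nrow(locs), nrow(locs),
                     dimnames = list(locs$locality, locs$locality))
  for (k in seq_along(parent)) {
    child <- order_chain[k + 1]
    par <- parent[k]
    step <- gd[child, par]
    placed <- order_chain[seq_len(k)]
    for (o in placed)
      chain_km[child, o] <- chain_km[o, child] <- chain_km[par, o] + step
  }

  L <- config$n_neutral_loci + config$n_habitat_loci
  locus_names <- sprintf("snp%04d", seq_len(L))
  habitat_loci <- sort(sample.int(L, config$n_habitat_loci))
  p0 <- stats::runif(L, config$ancestral_range[1], config$ancestral_range[2])

  loc_freq <- matrix(NA_real_, nrow = nrow(locs), ncol = L,
                     dimnames = list(locs$locality, locus_names))
  loc_freq[order_chain[1], ] <- p0
  for (k in seq_along(parent)) {
    child <- order_chain[k + 1]
    d <- gd[child, parent[k]]
    Fd <- d / (d + config$d0)
    loc_freq[child, ] <- rbn(loc_freq[parent[k], ], rep(Fd, L))
  }

  frost <- habitat_ranking("frost")$rank_of
  mean_rank <- mean(frost)
  n_clamped <- 0L
  # key derivation mirrors sample_table(): taxon suffix only in cells where
  # two taxa co-occur
  cell <- paste(pops$locality, pops$habitat, sep = "_")
  multi <- cell %in% cell[duplicated(cell)]
  pop_keys <- ifelse(multi, paste(cell, pops$taxon, sep = "_"), cell)
  pop_freq <- matrix(NA_real_, nrow = n_pop, ncol = L,
                     dimnames = list(pop_keys, locus_names))
  for (i in seq_len(n_pop)) {
    p <- loc_freq[pops$locality[i], ]
    shift <- config$delta_hab * (frost[[pops$habitat[i]]] - mean_rank)
    ph <- p
    ph[habitat_loci] <- inv_logit(logit(
      pmin(pmax(p[habitat_loci], 1e-4), 1 - 1e-4)) + shift)
    clamped <- ph < 0.001 | ph > 0.999
    n_clamped <- n_clamped + sum(clamped)
    ph <- pmin(pmax(ph, 0.001), 0.999)
    if (pops$taxon[i] == "B") ph <- rbn(ph, rep(config$taxon_f, L))
    pop_freq[i, ] <- ph
  }

  ids <- character(0)
  pop_of <- character(0)
  for (i in seq_len(n_pop)) {
    s <- sprintf("%s_s%02d", pop_keys[i], seq_len(pops$n[i]))
    ids <- c(ids, s)
    pop_of <- c(pop_of, rep(pop_keys[i], pops$n[i]))
  }
  n <- length(ids)
  d <- matrix(NA_integer_, nrow = n, ncol = L,
              dimnames = list(ids, locus_names))
  for (i in seq_len(n_pop)) {
    rows <- which(pop_of == pop_keys[i])
    d[rows, ] <- matrix(stats::rbinom(length(rows) * L, 2,
                                      rep(pop_freq[i, ], each = length(rows))),
                        nrow = length(rows))
  }
  miss <- matrix(stats::runif(n * L) < config$missingness, n, L)
  d[miss] <- NA_integer_
  dp <- matrix(NA_real_, n, L, dimnames = dimnames(d))
  nn <- sum(!miss)
  dp[!miss] <- 1 + stats::rnbinom(nn, mu = config$depth_mean - 1,
                                  size = config$depth_dispersion)

  meta <- data.frame(
    sample_id = ids,
    locality = sub("_.*$", "", pop_of),
    habitat = vapply(strsplit(pop_of, "_"), `[`, character(1), 2),
    taxon = ifelse(grepl("_B$", pop_of), "B", "A"),
    stringsAsFactors = FALSE)
  meta$latitude <- locs$latitude[match(meta$locality, locs$locality)] +
    stats::runif(n, -0.01, 0.01)
  meta$longitude <- locs$longitude[match(meta$locality, locs$locality)] +
    stats::runif(n, -0.01, 0.01)
  S <- sample_table(meta)
  list(genotypes = genotype_matrix(d, dp),
       samples = S,
       truth = list(habitat_loci = locus_names[habitat_loci],
                    pop_freq = pop_freq,
                    pop_distance = {
                      # population-level drift distances (the true "phylogeny"
                      # of the simulation): locality chain path lengths, with
                      # a small taxon-split branch for the second taxon
                      pd <- chain_km[sub("_.*$", "", pop_keys),
                                     sub("_.*$", "", pop_keys)]
                      dimnames(pd) <- list(pop_keys, pop_keys)
                      bt <- grepl("_B$", pop_keys)
                      pd[bt, ] <- pd[bt, ] + config$taxon_f * config$d0
                      pd[, bt] <- pd[, bt] + config$taxon_f * config$d0
                      diag(pd) <- 0
                      pd
                    },
                    n_clamped = n_clamped,
                    config = config))
}

#' Wright-Fisher two-deme island-model configuration
#'
#' @param N diploid deme size (default 200).
#' @param m symmetric per-generation migration rate in `[0, 0.5]`.
#' @param n_loci independent loci (default 2000).
#' @param generations generations simulated (default `4 * N`).
#' @param init_freq initial minor-allele frequency (default 0.5).
#' @param samples_per_deme diploid samples drawn per deme at the end
#'   (default 20).
#' @param seed RNG seed.
#' @return An object of class `wf_config`.
#' @export
wf_config <- function(N = 200, m = 0.0125, n_loci = 2000, generations = 4 * N,
                      init_freq = 0.5, samples_per_deme = 20, seed = 1L) {
  stopifnot(N >= 2, m >= 0, m <= 0.5, n_loci > 0, generations > 0,
            samples_per_deme >= 2, 2 * samples_per_deme <= 2 * N)
  structure(list(N = N, m = m, n_loci = n_loci, generations = generations,
                 init_freq = init_freq, samples_per_deme = samples_per_deme,
                 seed = as.integer(seed)),
            class = "wf_config")
}

#' Simulate a two-deme Wright-Fisher island model
#'
#' Each generation, a migrant fraction `m` of each deme's allele pool is
#' replaced by draws from the migrant pool, then 2N allele copies are
#' binomially resampled. Under the classical island model the migrant pool is
#' the metapopulation average frequency (the default), which makes the
#' equilibrium differentiation follow `theta = 1 / (1 + 4 Nm)`; drawing
#' migrants only from the other deme doubles the effective exchange rate and
#' equilibrates near `1 / (1 + 8 Nm)` instead. After the configured number of
#' generations, diploid samples are drawn without replacement from each
#' deme's 2N copies. Loci are independent. Used to validate the
#' migrant-number estimator.
#'
#' @param config a `wf_config`.
#' @param migrant_pool `"metapopulation"` (island-model default) or
#'   `"other_deme"`.
#' @return List with `genotypes`, `samples` (two populations `deme1_X`,
#'   `deme2_X` at dummy coordinates), and `final_freq` (2 x loci matrix).
#'   Emits a warning if every locus fixed.
#' @export
simulate_island_model <- function(config = wf_config(),
                                  migrant_pool = c("metapopulation",
                                                   "other_deme")) {
  stopifnot(inherits(config, "wf_config"))
  migrant_pool <- match.arg(migrant_pool)
  set.seed(config$seed)
  L <- config$n_loci
  N2 <- 2 * config$N
  p <- matrix(config$init_freq, nrow = 2, ncol = L)
  for (g in seq_len(config$generations)) {
    pool <- if (migrant_pool == "metapopulation") (p[1, ] + p[2, ]) / 2
      else rbind(p[2, ], p[1, ])
    if (migrant_pool == "metapopulation") {
      p1 <- (1 - config$m) * p[1, ] + config$m * pool
      p2 <- (1 - config$m) * p[2, ] + config$m * pool
    } else {
      p1 <- (1 - config$m) * p[1, ] + config$m * pool[1, ]
      p2 <- (1 - config$m) * p[2, ] + config$m * pool[2, ]
    }
    p[1, ] <- stats::rbinom(L, N2, p1) / N2
    p[2, ] <- stats::rbinom(L, N2, p2) / N2
  }
  if (all(p %in% c(0, 1))) warning("all loci fixed: F_ST undefined everywhere")
  s <- config$samples_per_deme
  locus_names <- sprintf("wf%05d", seq_len(L))
  d <- matrix(NA_integer_, nrow = 2 * s, ncol = L)
  for (deme in 1:2) {
    x <- round(p[deme, ] * N2)   # minor-allele copies in the pool
    for (j in seq_len(L)) {
      # allele copies drawn without replacement, paired into genotypes
      k <- stats::rhyper(1, x[j], N2 - x[j], 2 * s)
      slots <- integer(2 * s)
      if (k > 0) slots[sample.int(2 * s, k)] <- 1L
      d[(deme - 1) * s + seq_len(s), j] <-
        slots[seq(1, 2 * s, by = 2)] + slots[seq(2, 2 * s, by = 2)]
    }
  }
  ids <- c(sprintf("deme1_s%02d", seq_len(s)), sprintf("deme2_s%02d", seq_len(s)))
  dimnames(d) <- list(ids, locus_names)
  meta <- data.frame(sample_id = ids,
                     locality = rep(c("deme1", "deme2"), each = s),
                     habitat = "F",
                     latitude = rep(c(0, 1), each = s),
                     longitude = 0, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(d), samples = sample_table(meta),
       final_freq = p)
}

#' Write simulated data as VCF + metadata TSV + truth TSV
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "genotypes.vcf")
  d <- sim$genotypes$dosage
  dp <- sim$genotypes$depth
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    g <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1L])
    if (!is.null(dp)) {
      dpj <- ifelse(is.na(dp[, j]), ".", as.character(dp[, j]))
      g <- paste(g, dpj, sep = ":")
    }
    writeLines(paste(c("1", j, colnames(d)[j], "A", "T", ".", "PASS", ".",
                       if (is.null(dp)) "GT" else "GT:DP", g),
                     collapse = "\t"), con)
  }
  close(con)
  meta_path <- file.path(dir, "samples.tsv")
  utils::write.table(sim$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(locus_id = colnames(d),
               habitat_locus = colnames(d) %in% sim$truth$habitat_loci),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf, samples = meta_path, truth = truth_path))
}
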