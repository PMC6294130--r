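#' Synthetic study-design fixture
#'
#' Builds a fully synthetic dataset that reproduces the study's design
#' arithmetic at desk scale: 19 locality-habitat populations in 6 localities,
#' 162 samples, 1,273 raw loci, a locality-contrast population subset (the
#' four localities outside Cocuy/Guantiva) and a habitat-contrast subset
#' (Cocuy + Guantiva), and three associated-marker sets. The moisture set is
#' engineered so that, within the locality-contrast subset, exactly one of its
#' loci is polymorphic — the combination is then excluded by the >= 2
#' polymorphic-loci rule and the partition series yields 11 datasets (hence
#' 33 Mantel tests).
#'
#' @param seed RNG seed passed to the simulator.
#' @param n_moisture number of engineered moisture-associated loci whose
#'   minor allele is confined to the habitat-contrast localities (default 20).
#' @param n_locality number of locality-associated loci, picked by the range
#'   of per-locality allele frequencies (default 150).
#' @return List with `genotypes` (filtered), `samples`, `assoc` (per-factor
#'   locus-id sets), `subset_rules`, `truth`, and `filter_log`.
#' @export
espeletia_design_fixture <- function(seed = 1L, n_moisture = 20,
                                     n_locality = 150) {
  sim <- simulate_dataset(sim_config(seed = seed))
  G <- sim$genotypes
  S <- sim$samples
  habitat_locs <- c("CO", "GU")
  locality_locs <- setdiff(unique(S$locality), habitat_locs)
  in_hab <- sample_ids(G) %in% S$sample_id[S$locality %in% habitat_locs]

  # engineer region-private moisture loci: minor allele confined to the
  # habitat-contrast localities so the locality-contrast subset goes
  # monomorphic at them
  d <- G$dosage
  f_hab <- colSums(d[in_hab, ], na.rm = TRUE) /
    (2 * pmax(colSums(!is.na(d[in_hab, ])), 1L))
  neutral <- setdiff(locus_ids(G), sim$truth$habitat_loci)
  cand <- neutral[order(-pmin(f_hab[neutral], 1 - f_hab[neutral]))]
  private <- utils::head(cand, n_moisture)
  d[!in_hab, private] <- 0L
  # one moisture locus left polymorphic everywhere ("just one polymorphic
  # site" in the excluded combination)
  f_loc <- colSums(d[!in_hab, ], na.rm = TRUE) /
    (2 * pmax(colSums(!is.na(d[!in_hab, ])), 1L))
  loose_cand <- setdiff(cand, private)
  loose_cand <- loose_cand[order(-pmin(f_loc[loose_cand], 1 - f_loc[loose_cand]))]
  loose <- loose_cand[1]
  moisture_set <- c(private, loose)
  G <- genotype_matrix(d, G$depth)

  Gf <- suppressMessages(apply_filters(G, filter_spec()))
  moisture_set <- intersect(moisture_set, locus_ids(Gf))

  # locality-associated loci: widest spread of per-locality frequencies
  af <- allele_frequencies(Gf, S)
  locfreq <- vapply(unique(S$locality), function(l) {
    ids <- intersect(sample_ids(Gf), S$sample_id[S$locality == l])
    dd <- Gf$dosage[ids, , drop = FALSE]
    nc <- colSums(!is.na(dd))
    colSums(dd, na.rm = TRUE) / (2 * pmax(nc, 1L))
  }, numeric(ncol(Gf$dosage)))
  spread <- apply(locfreq, 1, function(x) diff(range(x)))
  loc_cand <- setdiff(locus_ids(Gf), moisture_set)
  locality_set <- loc_cand[order(-spread[match(loc_cand, locus_ids(Gf))])]
  locality_set <- sort(utils::head(locality_set, n_locality))

  frost_set <- intersect(sim$truth$habitat_loci, locus_ids(Gf))

  list(genotypes = Gf, samples = S,
       assoc = list(locality = locality_set, frost = frost_set,
                    moisture = moisture_set),
       subset_rules = list(entire = NULL, locality = locality_locs,
                           habitat = habitat_locs),
       truth = sim$truth,
       filter_log = attr(Gf, "filter_log"))
}
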