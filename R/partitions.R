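#' Partition the dataset by population subsets and marker subsets
#'
#' Crosses population subsets (the entire sampling, a locality-contrast
#' subset, and a habitat-contrast subset, each given as a list of localities)
#' with marker subsets (all markers plus the loci associated with each
#' factor). Each combination is re-filtered with the same MAF and call-rate
#' rules as the full dataset (the depth rule is a raw-data rule and is not
#' re-applied) and is emitted only when at least 2 polymorphic loci survive;
#' in the study design one combination is monomorphic, leaving 11 datasets.
#'
#' @param G the filtered `genotype_matrix` (full dataset).
#' @param S a `sample_table`.
#' @param assoc associated-marker sets: either `NULL` (all-markers subsets
#'   only), a named list of locus-id vectors per factor (applied to every
#'   population subset), or a nested list keyed by population-subset name,
#'   each holding per-factor locus-id vectors (the study design: each
#'   population subset uses its own scan's associations).
#' @param subset_rules named list of locality vectors defining the population
#'   subsets; `NULL` entries mean all localities. Default
#'   `list(entire = NULL)`.
#' @param spec `filter_spec` whose `min_maf` and `min_call_rate` are re-used
#'   for the within-subset re-filtering.
#' @return List of partitions, each a list with `name`, `population_subset`,
#'   `marker_subset`, `genotypes`, `populations` (keys with >= 2 samples),
#'   and `n_loci`. Emission order: population subsets in `subset_rules` order,
#'   marker subsets as `all`, then `assoc` order.
#' @export
partition_datasets <- function(G, S, assoc = NULL,
                               subset_rules = list(entire = NULL),
                               spec = filter_spec()) {
  refilter <- filter_spec(min_locus_depth = -Inf, min_maf = spec$min_maf,
                          min_call_rate = spec$min_call_rate)
  nested <- !is.null(assoc) && all(names(assoc) %in% names(subset_rules)) &&
    length(assoc) > 0 && is.list(assoc[[1]])
  out <- list()
  for (ps in names(subset_rules)) {
    locs <- subset_rules[[ps]]
    ids <- if (is.null(locs)) S$sample_id else
      S$sample_id[S$locality %in% locs]
    if (!is.null(locs) && !length(ids))
      stop("population subset '", ps, "' selects no samples")
    ids <- intersect(sample_ids(G), ids)
    Gs <- subset_genotypes(G, samples = ids)
    marker_sets <- list(all = locus_ids(G))
    asets <- if (nested) assoc[[ps]] else assoc
    if (!is.null(asets)) marker_sets <- c(marker_sets, asets)
    for (ms in names(marker_sets)) {
      loci <- intersect(locus_ids(Gs), marker_sets[[ms]])
      Gm <- subset_genotypes(Gs, loci = loci)
      Gm <- suppressWarnings(suppressMessages(apply_filters(Gm, refilter)))
      nm <- paste(ps, ms, sep = "_")
      if (ncol(Gm$dosage) < 2) {
        message("partition ", nm, " excluded: ", ncol(Gm$dosage),
                " polymorphic locus/loci after re-filtering")
        next
      }
      pop <- S$population[match(sample_ids(Gm), S$sample_id)]
      tab <- table(pop)
      part <- list(name = nm, population_subset = ps, marker_subset = ms,
                   genotypes = Gm, populations = names(tab)[tab >= 2],
                   n_loci = ncol(Gm$dosage))
      message("partition ", nm, ": ", part$n_loci, " loci, ",
              length(part$populations), " populations")
      out[[length(out) + 1L]] <- part
    }
  }
  out
}
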