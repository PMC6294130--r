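#' Great-circle geographic distances between population centroids
#'
#' Population coordinates are the centroids (mean latitude/longitude) of the
#' member samples; distances are haversine great-circle arcs on a sphere of
#' mean Earth radius 6371.0087714 km.
#'
#' @param S a `sample_table`; every member sample needs finite coordinates.
#' @param populations population keys (default: all in `S`, first-appearance
#'   order).
#' @return Symmetric matrix of distances in km.
#' @export
geographic_distances <- function(S, populations = unique(S$population)) {
  bad <- S$sample_id[!is.finite(S$latitude) | !is.finite(S$longitude)]
  if (length(bad)) stop("missing coordinates for sample(s): ",
                        paste(bad, collapse = ", "))
  cen <- t(vapply(populations, function(p) {
    m <- S[S$population == p, , drop = FALSE]
    c(lon = mean(m$longitude), lat = mean(m$latitude))
  }, numeric(2)))
  P <- length(populations)
  D <- matrix(0, P, P, dimnames = list(populations, populations))
  for (i in seq_len(max(0, P - 1))) for (j in seq(i + 1, P)) {
    D[i, j] <- D[j, i] <- geosphere::distHaversine(
      cen[i, ], cen[j, ], r = 6371008.7714) / 1000
  }
  D
}

#' Ecological (habitat-rank) distances between populations
#'
#' The scalar Euclidean distance `|rank_i - rank_j|` between the habitat
#' ranks of the two populations on one theoretical ecological axis.
#'
#' @param S a `sample_table`.
#' @param ranking a `habitat_ranking`.
#' @param populations population keys (default: all in `S`).
#' @return Symmetric matrix of rank distances.
#' @export
ecological_distances <- function(S, ranking,
                                 populations = unique(S$population)) {
  meta <- unique(S[, c("population", "habitat")])
  hab <- stats::setNames(meta$habitat, meta$population)
  unknown <- setdiff(unique(hab[populations]), names(ranking$rank_of))
  if (length(unknown)) stop("habitat not covered by ranking: ",
                            paste(unknown, collapse = ", "))
  r <- ranking$rank_of[hab[populations]]
  D <- abs(outer(r, r, "-"))
  dimnames(D) <- list(populations, populations)
  D
}

#' Permutation Mantel test
#'
#' Pearson correlation of the strict upper triangles of two aligned distance
#' matrices, with a one-sided (positive-association) permutation null built by
#' jointly permuting the rows and columns of `B`. P-value uses the add-one
#' convention `(#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param A,B symmetric aligned distance matrices over >= 4 populations.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @return List with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(A, B, n_perm = 1000, seed = 1L) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B))) stop("matrices must be aligned")
  n <- nrow(A)
  if (n < 4) stop("need at least 4 populations")
  ut <- upper.tri(A)
  a <- A[ut]
  b <- B[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero off-diagonal variance: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, seed = seed))
  }
  r_obs <- stats::cor(a, b)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  hits <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    bp <- B[perm, perm][ut]
    if (stats::cor(a, bp) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm, seed = seed)
}

# deterministic per-test seed from (master seed, dataset name, distance name)
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "|")
  as.integer(sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483L + seed %% 2147483L)
}

#' IBD/IBE Mantel table over dataset partitions (Table-1 analog)
#'
#' For each dataset partition: recomputes pairwise Weir-Cockerham F_ST on the
#' partition's loci and populations, linearizes it, builds the aligned
#' geographic and two ecological distance matrices, and runs the three Mantel
#' tests. The per-dataset Bonferroni threshold is `alpha / N_PW` where `N_PW`
#' is the partition's population-pair count.
#'
#' @param partitions list of partitions from [partition_datasets()].
#' @param S a `sample_table`.
#' @param rankings list with elements `frost` and `moisture`
#'   (`habitat_ranking` objects); default standard codings.
#' @param alpha family-wise level (default 0.05).
#' @param n_perm Mantel permutations (default 1000).
#' @param seed master seed; per-test seeds are derived deterministically from
#'   (seed, dataset name, distance name).
#' @return data.frame with one row per partition: `population_dataset`,
#'   `marker_dataset`, `n_pw`, `n_snps`, `r_geographic`, `r_frost`,
#'   `r_moisture`, matching p-value columns, `bonferroni_threshold`, and
#'   significance flags. Attribute `"tests"` holds the per-test detail.
#' @export
ibd_ibe_table <- function(partitions, S, rankings = NULL, alpha = 0.05,
                          n_perm = 1000, seed = 1L) {
  if (is.null(rankings))
    rankings <- list(frost = habitat_ranking("frost"),
                     moisture = habitat_ranking("moisture"))
  rows <- list()
  tests <- list()
  for (part in partitions) {
    G <- part$genotypes
    pops <- part$populations
    if (length(pops) < 4 || ncol(G$dosage) < 2) {
      message("partition ", part$name, " skipped (needs >= 4 populations, ",
              ">= 2 loci)")
      next
    }
    fst <- fst_matrix(G, S, populations = pops)
    gen <- matrix(suppressMessages(linearized_fst(fst)), nrow(fst),
                  dimnames = dimnames(fst))
    diag(gen) <- 0
    bundle <- list(
      geographic = geographic_distances(S, pops),
      frost = ecological_distances(S, rankings$frost, pops),
      moisture = ecological_distances(S, rankings$moisture, pops))
    n_pw <- length(pops) * (length(pops) - 1) / 2
    thr <- alpha / n_pw
    rr <- pp <- stats::setNames(numeric(3), names(bundle))
    for (nm in names(bundle)) {
      mt <- mantel(gen, bundle[[nm]], n_perm = n_perm,
                   seed = derive_seed(seed, part$name, nm))
      rr[nm] <- mt$r
      pp[nm] <- mt$p
      tests[[length(tests) + 1L]] <- data.frame(
        dataset = part$name, distance = nm, r = mt$r, p = mt$p,
        n_perm = mt$n_perm, seed = mt$seed, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      population_dataset = part$population_subset,
      marker_dataset = part$marker_subset,
      n_pw = n_pw, n_snps = ncol(G$dosage),
      r_geographic = rr["geographic"], r_frost = rr["frost"],
      r_moisture = rr["moisture"],
      p_geographic = pp["geographic"], p_frost = pp["frost"],
      p_moisture = pp["moisture"],
      bonferroni_threshold = thr,
      sig_geographic = !is.na(pp["geographic"]) & pp["geographic"] <= thr,
      sig_frost = !is.na(pp["frost"]) & pp["frost"] <= thr,
      sig_moisture = !is.na(pp["moisture"]) & pp["moisture"] <= thr,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tests") <- do.call(rbind, tests)
  out
}
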