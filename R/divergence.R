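#' Pairwise Weir-Cockerham F_ST between two populations
#'
#' Per-locus variance components of the Weir & Cockerham (1984) estimator for
#' two populations: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals), computed from per-population
#' sample sizes, minor-allele frequencies and observed heterozygosities. The
#' multi-locus estimate is the ratio of sums, `theta = sum(a) / sum(a+b+c)`.
#' Loci where either population has fewer than one non-missing genotype, or
#' where the mean sample size does not exceed one, are excluded and counted.
#'
#' @param G a `genotype_matrix`.
#' @param S a `sample_table`.
#' @param popA,popB population keys present in `S$population`.
#' @return List with `theta`, `components` (per-locus data.frame of `a`, `b`,
#'   `c`), `n_loci_used`, and `n_loci_excluded`.
#' @export
pairwise_fst <- function(G, S, popA, popB) {
  stopifnot(inherits(G, "genotype_matrix"))
  pop <- S$population[match(sample_ids(G), S$sample_id)]
  iA <- which(pop == popA)
  iB <- which(pop == popB)
  if (length(iA) < 2 || length(iB) < 2)
    stop("both populations need at least 2 samples")
  comp <- wc_components(G$dosage[iA, , drop = FALSE],
                        G$dosage[iB, , drop = FALSE])
  usable <- comp$usable
  if (!any(usable)) stop("no usable loci for F_ST between ", popA, " and ", popB)
  a <- comp$a[usable]; b <- comp$b[usable]; cc <- comp$c[usable]
  denom <- sum(a + b + cc)
  theta <- if (denom == 0) 0 else sum(a) / denom
  list(theta = theta,
       components = data.frame(locus_id = locus_ids(G)[usable],
                               a = a, b = b, c = cc,
                               stringsAsFactors = FALSE),
       n_loci_used = sum(usable),
       n_loci_excluded = sum(!usable))
}

# vectorized Weir-Cockerham (1984) components for two populations, r = 2
wc_components <- function(dA, dB) {
  n1 <- colSums(!is.na(dA))
  n2 <- colSums(!is.na(dB))
  p1 <- colSums(dA, na.rm = TRUE) / (2 * pmax(n1, 1L))
  p2 <- colSums(dB, na.rm = TRUE) / (2 * pmax(n2, 1L))
  h1 <- colSums(dA == 1L, na.rm = TRUE) / pmax(n1, 1L)
  h2 <- colSums(dB == 1L, na.rm = TRUE) / pmax(n2, 1L)
  r <- 2
  nbar <- (n1 + n2) / 2
  nsum <- n1 + n2
  nc <- nsum - (n1^2 + n2^2) / nsum
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1 & nc > 0 &
    is.finite(a) & is.finite(b) & is.finite(cc)
  list(a = a, b = b, c = cc, usable = usable)
}

#' F_ST matrix over all population pairs
#'
#' @param G a `genotype_matrix`.
#' @param S a `sample_table`.
#' @param populations population keys to include (default: all with >= 2
#'   samples among `G`'s samples).
#' @return Symmetric matrix of multi-locus Weir-Cockerham theta with zero
#'   diagonal.
#' @export
fst_matrix <- function(G, S, populations = NULL) {
  pop <- S$population[match(sample_ids(G), S$sample_id)]
  if (is.null(populations)) {
    tab <- table(pop)
    populations <- names(tab)[tab >= 2]
  }
  P <- length(populations)
  M <- matrix(0, P, P, dimnames = list(populations, populations))
  for (i in seq_len(P - 1)) for (j in seq(i + 1, P)) {
    th <- pairwise_fst(G, S, populations[i], populations[j])$theta
    M[i, j] <- M[j, i] <- th
  }
  M
}

#' Rousset linearization F_ST / (1 - F_ST)
#'
#' @param theta F_ST value(s), each `< 1` (`theta = 1` maps to `Inf` with a
#'   warning).
#' @param clip_negative clip negative linearized values to 0 for use as a
#'   distance (default `TRUE`; clipping is reported via `message()`).
#' @return Numeric vector of linearized values.
#' @export
linearized_fst <- function(theta, clip_negative = TRUE) {
  if (any(theta > 1)) stop("theta must be <= 1")
  out <- ifelse(theta == 1, Inf, theta / (1 - theta))
  if (any(theta == 1)) warning("theta = 1 linearizes to +Inf")
  if (clip_negative && any(out < 0, na.rm = TRUE)) {
    message(sum(out < 0, na.rm = TRUE),
            " negative linearized F_ST value(s) clipped to 0")
    out <- pmax(out, 0)
  }
  out
}

#' Migrants per generation from F_ST
#'
#' Under the equilibrium island model `theta = 1 / (1 + 4 Nm)`, inverted as
#' the moment estimator `Nm = (1 - theta) / (4 theta)` (default). The
#' `"grid_ml"` estimator instead maximizes a Gaussian pseudo-likelihood of the
#' per-locus theta values around the equilibrium expectation over a log grid
#' of `Nm` in `[1e-2, 1e2]`.
#'
#' @param theta multi-locus F_ST in `(0, 1)`; non-positive values are capped
#'   at `ceiling` migrants (reported via `message()`).
#' @param estimator `"island_moment"` or `"grid_ml"`.
#' @param per_locus_theta per-locus theta values (required for `"grid_ml"`).
#' @param ceiling cap for the estimate when `theta <= 0` (default 20).
#' @return List with `nem`, `estimator`, and `linearized` (clipped Rousset
#'   value).
#' @export
nem_from_fst <- function(theta, estimator = c("island_moment", "grid_ml"),
                         per_locus_theta = NULL, ceiling = 20) {
  estimator <- match.arg(estimator)
  if (length(theta) != 1) stop("theta must be scalar")
  if (theta >= 1) stop("theta must be < 1")
  if (theta <= 0) {
    message("theta <= 0: N_e_m capped at ", ceiling)
    return(list(nem = ceiling, estimator = estimator,
                linearized = linearized_fst(theta)))
  }
  nem <- if (estimator == "island_moment") {
    (1 - theta) / (4 * theta)
  } else {
    if (is.null(per_locus_theta)) stop("grid_ml needs per_locus_theta")
    pl <- per_locus_theta[is.finite(per_locus_theta)]
    grid <- 10^seq(-2, 2, length.out = 401)
    sse <- vapply(grid, function(nm) sum((pl - 1 / (1 + 4 * nm))^2), numeric(1))
    grid[which.min(sse)]
  }
  nem <- min(nem, ceiling)
  list(nem = nem, estimator = estimator, linearized = linearized_fst(theta))
}

#' Migration-rate group summary and network (Table-2 analog)
#'
#' Summarizes pairwise migrant-number estimates across all pairs and within
#' two contrast categories — among habitats within a locality, and within the
#' same habitat across localities — with mean, standard error and empirical
#' 95% CI, plus a two-sided Mann-Whitney U test between the two contrast
#' categories. Also returns the network edge list with a panmixia flag at
#' `N_e_m > 1`.
#'
#' @param estimates data.frame with columns `pop_a`, `pop_b`, `nem` (e.g.
#'   from [migration_edges()]).
#' @param S a `sample_table` (maps populations to locality and habitat).
#' @return List with `summary` (one row per category), `test`
#'   (Mann-Whitney U statistic and p-value between the two contrast
#'   categories, `NA` if either has < 2 pairs), and `edges` (input plus
#'   `category` and `panmictic` columns).
#' @export
migration_summary <- function(estimates, S) {
  meta <- unique(S[, c("population", "locality", "habitat")])
  loc <- stats::setNames(meta$locality, meta$population)
  hab <- stats::setNames(meta$habitat, meta$population)
  la <- loc[estimates$pop_a]; lb <- loc[estimates$pop_b]
  ha <- hab[estimates$pop_a]; hb <- hab[estimates$pop_b]
  category <- ifelse(la == lb & ha != hb, "among_habitats_within_locality",
              ifelse(la != lb & ha == hb, "within_habitat_across_localities",
                     "other"))
  edges <- estimates
  edges$category <- category
  edges$panmictic <- edges$nem > 1
  summarize <- function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
      ci_lo = unname(stats::quantile(v, 0.025)),
      ci_hi = unname(stats::quantile(v, 0.975)), n_pairs = length(v))
  }
  cats <- list(all_pairs = edges$nem,
               among_habitats_within_locality =
                 edges$nem[category == "among_habitats_within_locality"],
               within_habitat_across_localities =
                 edges$nem[category == "within_habitat_across_localities"])
  rows <- lapply(names(cats), function(nm) {
    v <- cats[[nm]]
    if (!length(v)) {
      message("category '", nm, "' is empty; omitted")
      return(NULL)
    }
    data.frame(category = nm, t(summarize(v)), stringsAsFactors = FALSE)
  })
  summary_df <- do.call(rbind, Filter(Negate(is.null), rows))
  test <- list(U = NA_real_, p = NA_real_)
  va <- cats$among_habitats_within_locality
  vb <- cats$within_habitat_across_localities
  if (length(va) >= 2 && length(vb) >= 2) {
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE))
    p <- wt$p.value
    if (is.na(p)) p <- 1  # fully tied groups carry no evidence of a shift
    test <- list(U = unname(wt$statistic), p = p)
  }
  list(summary = summary_df, test = test, edges = edges)
}

#' Pairwise F_ST / N_e_m edge list for a dataset
#'
#' @param G a `genotype_matrix`.
#' @param S a `sample_table`.
#' @param populations population keys (default: all with >= 2 samples).
#' @param estimator passed to [nem_from_fst()].
#' @param ceiling passed to [nem_from_fst()].
#' @return data.frame with `pop_a`, `pop_b`, `fst`, `linearized_fst`, `nem`,
#'   `panmictic`.
#' @export
migration_edges <- function(G, S, populations = NULL,
                            estimator = "island_moment", ceiling = 20) {
  pop <- S$population[match(sample_ids(G), S$sample_id)]
  if (is.null(populations)) {
    tab <- table(pop)
    populations <- names(tab)[tab >= 2]
  }
  out <- list()
  for (i in seq_len(length(populations) - 1))
    for (j in seq(i + 1, length(populations))) {
      fr <- pairwise_fst(G, S, populations[i], populations[j])
      pl <- fr$components$a / (fr$components$a + fr$components$b + fr$components$c)
      ne <- suppressMessages(
        nem_from_fst(fr$theta, estimator, per_locus_theta = pl,
                     ceiling = ceiling))
      out[[length(out) + 1L]] <- data.frame(
        pop_a = populations[i], pop_b = populations[j],
        fst = fr$theta, linearized_fst = ne$linearized, nem = ne$nem,
        panmictic = ne$nem > 1, stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}
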