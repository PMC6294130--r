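#' Principal coordinates analysis (classical scaling)
#'
#' Classical metric scaling of a distance matrix: the doubly centered matrix
#' `B = -1/2 J (D*D) J` is eigendecomposed and coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Axes are ordered
#' by decreasing eigenvalue and each axis is oriented so its largest-magnitude
#' loading is positive, giving a deterministic sign convention. Explained
#' percentages are eigenvalues over the sum of positive eigenvalues; negative
#' eigenvalues (non-Euclidean input) are excluded from that normalization and
#' reported separately.
#'
#' @param D symmetric distance matrix with zero diagonal and non-negative
#'   entries.
#' @param n_axes number of axes to return (default 2, capped at the number of
#'   positive eigenvalues).
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), `explained_pct` (per returned axis), and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("D must be a symmetric matrix")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D < 0)) stop("D must be non-negative")
  n <- nrow(D)
  # negative/zero eigenvalues are handled explicitly below; cmdscale's own
  # warning about them is redundant here
  cs <- suppressWarnings(stats::cmdscale(D, k = max(1, n - 1), eig = TRUE))
  ev <- cs$eig
  pos <- which(ev > sqrt(.Machine$double.eps) * max(abs(ev), 1))
  k <- min(n_axes, length(pos))
  if (k == 0) {
    coords <- matrix(0, nrow = n, ncol = n_axes,
                     dimnames = list(rownames(D), paste0("PCo", seq_len(n_axes))))
    return(list(coordinates = coords, eigenvalues = ev,
                explained_pct = rep(0, n_axes),
                negative_eigenvalues = ev[ev < 0]))
  }
  coords <- cs$points[, seq_len(k), drop = FALSE]
  # deterministic orientation: largest-|loading| entry positive on each axis
  for (a in seq_len(k)) {
    v <- coords[, a]
    if (v[which.max(abs(v))] < 0) coords[, a] <- -v
  }
  colnames(coords) <- paste0("PCo", seq_len(k))
  rownames(coords) <- rownames(D)
  expl <- 100 * ev[seq_len(k)] / sum(ev[pos])
  list(coordinates = coords, eigenvalues = ev, explained_pct = expl,
       negative_eigenvalues = ev[ev < 0])
}

# squared Euclidean distances between dosage rows, pairwise-complete and
# normalized by the total locus count: d2_ij = (L / L_ij) * sum (di - dj)^2
dosage_sq_dist <- function(d) {
  n <- nrow(d)
  L <- ncol(d)
  obs <- !is.na(d)
  dz <- d
  dz[!obs] <- 0
  shared <- obs %*% t(obs)
  # sum over shared loci of (di - dj)^2 = di^2 + dj^2 - 2 di dj on shared
  sq <- dz^2
  cross <- dz %*% t(dz)
  s_i <- sq %*% t(obs)     # sum di^2 over loci observed in both
  ss <- s_i + t(s_i) - 2 * cross
  d2 <- ifelse(shared > 0, (L / shared) * ss, NA_real_)
  diag(d2) <- 0
  dimnames(d2) <- list(rownames(d), rownames(d))
  d2
}

#' Hierarchical AMOVA (locality / habitat-within-locality / within-population)
#'
#' Analysis of molecular variance on squared Euclidean distances between
#' dosage vectors (pairwise-complete, locus-count-normalized). Sums of squares
#' follow the distance-matrix decomposition; variance components use the
#' standard nested expectations with unequal-group-size coefficients:
#' `E[MS_within] = s2_c`, `E[MS_pop|loc] = s2_c + n1 s2_b`,
#' `E[MS_loc] = s2_c + n2 s2_b + n3 s2_a`.
#'
#' @param G a `genotype_matrix`.
#' @param S a `sample_table`; `S$locality` defines groups and `S$population`
#'   the nested populations.
#' @param truncate_negative logical; truncate negative components at 0 before
#'   computing percentages (default `TRUE`). Raw components are always
#'   reported.
#' @return List with `components` (named `among_locality`,
#'   `among_population_within_locality`, `within_population`), `percent`,
#'   `ss`, `df` and `ms`.
#' @export
amova <- function(G, S, truncate_negative = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- sample_ids(G)
  idx <- match(ids, S$sample_id)
  if (anyNA(idx)) stop("samples absent from metadata")
  loc <- S$locality[idx]
  pop <- S$population[idx]
  if (length(unique(loc)) < 2) stop("need at least two localities")
  tab <- table(pop)
  if (any(tab < 2)) stop("every population needs at least 2 samples")
  d2 <- dosage_sq_dist(G$dosage)
  if (anyNA(d2)) stop("sample pairs with no shared loci: AMOVA undefined")
  N <- length(ids)
  ssd <- function(members) {
    # SS within a set = sum of squared distances over pairs / set size
    if (length(members) < 2) return(0)
    sum(d2[members, members]) / (2 * length(members))
  }
  ss_total <- ssd(seq_len(N))
  pops <- unique(pop)
  locs <- unique(loc)
  ss_wp <- sum(vapply(pops, function(p) ssd(which(pop == p)), numeric(1)))
  ss_groups <- sum(vapply(locs, function(g) ssd(which(loc == g)), numeric(1)))
  ss_ap <- ss_groups - ss_wp           # among populations within localities
  ss_ag <- ss_total - ss_groups        # among localities
  G_n <- length(locs)
  P_n <- length(pops)
  df <- c(among_locality = G_n - 1,
          among_population_within_locality = P_n - G_n,
          within_population = N - P_n)
  if (any(df == 0))
    warning("a stratum has zero degrees of freedom; its component is undefined")
  ms <- c(ss_ag, ss_ap, ss_wp) / ifelse(df > 0, df, NA_real_)
  names(ms) <- names(df)
  # unequal-size coefficients (nested design)
  n_p <- as.numeric(table(pop)[pops])
  g_of_p <- vapply(pops, function(p) loc[match(p, pop)], character(1))
  n_g <- as.numeric(table(loc)[locs])
  names(n_g) <- locs
  sum_np2_over_ng <- sum(vapply(locs, function(g) {
    sum(n_p[g_of_p == g]^2) / n_g[[g]]
  }, numeric(1)))
  n1 <- (N - sum_np2_over_ng) / (P_n - G_n)
  n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / (G_n - 1)
  n3 <- (N - sum(n_g^2) / N) / (G_n - 1)
  s2_c <- ms[["within_population"]]
  s2_b <- (ms[["among_population_within_locality"]] - s2_c) / n1
  s2_a <- (ms[["among_locality"]] - s2_c - n2 * s2_b) / n3
  comp <- c(among_locality = s2_a,
            among_population_within_locality = s2_b,
            within_population = s2_c)
  cc <- if (truncate_negative) pmax(comp, 0) else comp
  tot <- sum(cc)
  pct <- if (is.na(tot) || tot <= 0) {
    warning("total variance is zero or undefined; percentages flagged NA")
    rep(NA_real_, 3)
  } else 100 * cc / tot
  names(pct) <- names(comp)
  list(components = comp, percent = pct,
       ss = c(among_locality = ss_ag,
              among_population_within_locality = ss_ap,
              within_population = ss_wp),
       df = df, ms = ms)
}

#' Evanno delta-K from clustering run log-likelihoods
#'
#' Computes, per K, the mean and sd of the run log-likelihoods, the absolute
#' second difference `|L''(K)| = |mean L(K+1) - 2 mean L(K) + mean L(K-1)|`,
#' and `deltaK = |L''(K)| / sd(K)`. Defined only for interior K with positive
#' sd over at least two runs.
#'
#' @param runs data.frame with columns `K`, `run`, `loglik` over a contiguous
#'   K range.
#' @return data.frame per K with `mean_l`, `sd_l`, `abs_l2`, `delta_k`;
#'   attribute `"best_k"` holds the argmax of `delta_k`.
#' @export
evanno_delta_k <- function(runs) {
  need <- c("K", "run", "loglik")
  if (!all(need %in% names(runs))) stop("runs needs columns K, run, loglik")
  ks <- sort(unique(runs$K))
  if (!all(diff(ks) == 1)) stop("K range must be contiguous")
  agg <- data.frame(K = ks)
  agg$n_runs <- vapply(ks, function(k) sum(runs$K == k), numeric(1))
  agg$mean_l <- vapply(ks, function(k) mean(runs$loglik[runs$K == k]), numeric(1))
  agg$sd_l <- vapply(ks, function(k) stats::sd(runs$loglik[runs$K == k]), numeric(1))
  agg$abs_l2 <- NA_real_
  agg$delta_k <- NA_real_
  for (i in seq_along(ks)) {
    if (i == 1 || i == length(ks)) next
    if (agg$n_runs[i] < 2) next
    l2 <- abs(agg$mean_l[i + 1] - 2 * agg$mean_l[i] + agg$mean_l[i - 1])
    agg$abs_l2[i] <- l2
    if (!is.na(agg$sd_l[i]) && agg$sd_l[i] > 0) {
      agg$delta_k[i] <- l2 / agg$sd_l[i]
    } else {
      warning("sd of log-likelihoods is 0 at K = ", ks[i],
              "; deltaK undefined there")
    }
  }
  best <- if (all(is.na(agg$delta_k))) NA_integer_ else
    agg$K[which.max(agg$delta_k)]
  attr(agg, "best_k") <- best
  agg
}
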