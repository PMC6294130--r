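#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the mean, over loci non-missing in both samples, of
#' `1 - |d_i - d_j| / 2`, i.e. the expected proportion of alleles shared by
#' state. The diagonal is exactly 1. Used as the random-effect covariance in
#' the mixed-model association scans.
#'
#' @param G a `genotype_matrix` with at least one locus.
#' @return A symmetric samples x samples matrix with unit diagonal; a pair
#'   with no shared non-missing locus gets `NA` (reported via warning).
#' @export
ibs_kinship <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  if (ncol(d) < 1) stop("ibs_kinship needs at least one locus")
  n <- nrow(d)
  # shared-allele score per pair: sum over shared loci of (1 - |di - dj|/2),
  # computed via indicator matrices to stay vectorized under missingness
  obs <- !is.na(d)
  dz <- d
  dz[!obs] <- 0L
  shared_n <- obs %*% t(obs)                       # loci shared per pair
  # |di - dj| decomposes over the 0/1/2 states:
  I0 <- (dz == 0L) & obs
  I1 <- (dz == 1L) & obs
  I2 <- (dz == 2L) & obs
  # sum |di-dj| = 1*(pairs 0-1 or 1-2) + 2*(pairs 0-2)
  n01 <- I0 %*% t(I1) + I1 %*% t(I0)
  n12 <- I1 %*% t(I2) + I2 %*% t(I1)
  n02 <- I0 %*% t(I2) + I2 %*% t(I0)
  absdiff <- n01 + n12 + 2 * n02
  K <- 1 - absdiff / (2 * shared_n)
  K[shared_n == 0] <- NA_real_
  diag(K) <- 1
  dimnames(K) <- list(rownames(d), rownames(d))
  if (anyNA(K)) {
    bad <- which(is.na(K), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    warning(nrow(bad), " sample pair(s) share no non-missing locus")
  }
  K
}

#' Pairwise dosage R-squared
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples.
#' `NA` when either locus is monomorphic on the shared samples or fewer than
#' two shared samples exist.
#'
#' @param x,y dosage vectors.
#' @return Squared correlation in `[0, 1]` or `NA`.
#' @keywords internal
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium pruning
#'
#' Greedy left-to-right pruning: loci are visited in matrix order; a locus
#' still retained prunes every later locus within the sliding window whose
#' dosage R-squared with it is at least `r2_threshold`. Pairs with an
#' undefined R-squared (monomorphic on the shared samples) are skipped.
#'
#' @param G a `genotype_matrix`.
#' @param r2_threshold prune at `R^2 >= r2_threshold`; in `(0, 1]`.
#' @param window number of subsequent loci examined from each retained locus
#'   (default 50).
#' @return A list with `kept` (locus ids retained, original order) and
#'   `ld_stats`: data.frame of retained-pair R-squared plus a `summary`
#'   attribute with mean, SE and empirical 95% CI over those pairs.
#' @export
ld_prune <- function(G, r2_threshold = 0.8, window = 50) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!(r2_threshold > 0 && r2_threshold <= 1))
    stop("r2_threshold must be in (0, 1]")
  d <- G$dosage
  L <- ncol(d)
  keep <- rep(TRUE, L)
  for (i in seq_len(L)) {
    if (!keep[i]) next
    jmax <- min(L, i + window)
    for (j in seq(i + 1, length.out = max(0, jmax - i))) {
      if (!keep[j]) next
      r2 <- dosage_r2(d[, i], d[, j])
      if (!is.na(r2) && r2 >= r2_threshold) keep[j] <- FALSE
    }
  }
  kept <- locus_ids(G)[keep]
  # LD summary over pairs of retained loci within the window
  ki <- which(keep)
  pairs <- list()
  for (a in seq_along(ki)) {
    i <- ki[a]
    for (b in seq(a + 1, length.out = max(0, length(ki) - a))) {
      j <- ki[b]
      if (j - i > window) break
      r2 <- dosage_r2(d[, i], d[, j])
      if (!is.na(r2))
        pairs[[length(pairs) + 1L]] <- data.frame(
          locus_a = locus_ids(G)[i], locus_b = locus_ids(G)[j], r2 = r2,
          stringsAsFactors = FALSE)
    }
  }
  stats_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(locus_a = character(), locus_b = character(), r2 = numeric())
  r2v <- stats_df$r2
  summ <- if (length(r2v)) c(
    mean = mean(r2v),
    se = stats::sd(r2v) / sqrt(length(r2v)),
    ci_lo = unname(stats::quantile(r2v, 0.025)),
    ci_hi = unname(stats::quantile(r2v, 0.975)),
    n_pairs = length(r2v)) else
    c(mean = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      n_pairs = 0)
  attr(stats_df, "summary") <- summ
  list(kept = kept, ld_stats = stats_df)
}
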