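#' Per-sample phylogenetic covariate
#'
#' Reduces a population-level phylogenetic distance matrix (or a newick tree,
#' from which patristic distances are computed) to its first principal
#' coordinate and assigns each sample its population's score, centered.
#' Captures the dominant axis of shared ancestry as a single fixed covariate
#' for the association scans.
#'
#' @param pop_distances symmetric population distance matrix with dimnames,
#'   or an `ape::phylo` tree whose tips are population keys.
#' @param S a `sample_table`.
#' @param n_axes number of principal coordinates to use (default 1; more axes
#'   return a matrix).
#' @return Named numeric vector (or matrix when `n_axes > 1`) of centered
#'   covariate values, one per sample in `S`.
#' @export
phylo_covariate <- function(pop_distances, S, n_axes = 1) {
  if (inherits(pop_distances, "phylo")) {
    pop_distances <- ape::cophenetic.phylo(pop_distances)
  }
  D <- as.matrix(pop_distances)
  pops <- unique(S$population)
  missing <- setdiff(pops, rownames(D))
  if (length(missing))
    stop("populations missing from the distance matrix/tree: ",
         paste(missing, collapse = ", "))
  D <- D[pops, pops, drop = FALSE]
  res <- pcoa(D, n_axes = n_axes)
  ev <- res$eigenvalues
  if (length(ev) == 0 || max(ev) <= sqrt(.Machine$double.eps) * max(abs(ev), 1))
    warning("degenerate population distances: first axis carries no variance")
  scores <- res$coordinates[, seq_len(n_axes), drop = FALSE]
  idx <- match(S$population, pops)
  out <- scores[idx, , drop = FALSE]
  out <- sweep(out, 2, colMeans(out))
  rownames(out) <- S$sample_id
  if (n_axes == 1) stats::setNames(out[, 1], S$sample_id) else out
}

# factor regressors for a design: list(block = matrix of factor columns,
# df_hint). locality -> treatment contrasts; frost/moisture -> single ordinal
# regressor of the habitat rank.
design_factor_block <- function(S, fixed_factor, ranking = NULL) {
  if (fixed_factor == "locality") {
    f <- factor(S$locality)
    if (nlevels(f) < 2) stop("locality needs at least 2 observed levels")
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0("locality_", levels(f)[-1])
    m
  } else {
    if (is.null(ranking)) ranking <- habitat_ranking(fixed_factor)
    r <- ranking$rank_of[S$habitat]
    if (anyNA(r)) stop("habitat not covered by ranking")
    matrix(as.numeric(r), ncol = 1,
           dimnames = list(NULL, paste0(fixed_factor, "_rank")))
  }
}

# partial F test of the factor block given a null design, via least squares.
# Returns c(F, df1, df2, p) or NAs when the block adds no rank.
partial_f_test <- function(y, X0, X1, p_floor = 1e-300) {
  f0 <- stats::lm.fit(X0, y)
  f1 <- stats::lm.fit(X1, y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  df1 <- f1$rank - f0$rank
  df2 <- length(y) - f1$rank
  if (df1 < 1 || df2 < 1) return(c(NA_real_, df1, df2, NA_real_))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(c(0, df1, df2, 1))  # constant dosage
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (!is.finite(Fstat)) return(c(NA_real_, df1, df2, NA_real_))
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  c(Fstat, df1, df2, max(p, p_floor))
}

# appends a per-sample covariate (vector or multi-axis matrix) to a design
add_covariate <- function(X0, covariate, ids) {
  if (is.null(covariate)) return(X0)
  cv <- if (is.matrix(covariate)) {
    if (!is.null(rownames(covariate))) covariate[ids, , drop = FALSE]
    else covariate
  } else {
    m <- matrix(if (!is.null(names(covariate))) covariate[ids] else covariate,
                ncol = 1)
    colnames(m) <- "covariate"
    m
  }
  if (anyNA(cv)) stop("covariate missing for some samples")
  if (is.null(colnames(cv))) colnames(cv) <- paste0("covariate", seq_len(ncol(cv)))
  cbind(X0, cv)
}

scan_diagnostics <- function(p) {
  p <- p[!is.na(p)]
  chi <- stats::qchisq(1 - p, df = 1)
  lambda <- stats::median(chi) / stats::qchisq(0.5, df = 1)
  n <- length(p)
  qq <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                   observed = -log10(sort(p)))
  list(lambda_gc = lambda, qq = qq)
}

#' Fixed-effect (GLM) association scan
#'
#' For each locus, ordinary least squares of dosage on an intercept, the
#' phylogenetic covariate (when given) and the factor block, over samples with
#' a non-missing dosage; the factor is tested by the partial F test of its
#' block. Locality enters as one-hot contrasts; frost/moisture enter as a
#' single ordinal regressor of the habitat rank.
#'
#' @param G a `genotype_matrix`.
#' @param S a `sample_table` aligned to `G`'s samples.
#' @param fixed_factor `"locality"`, `"frost"` or `"moisture"`.
#' @param covariate optional named per-sample numeric covariate (e.g. from
#'   [phylo_covariate()]).
#' @param ranking `habitat_ranking` used when the factor is ecological
#'   (default: the standard coding for that axis).
#' @param p_floor lower clamp for p-values (default 1e-300) so perfect fits
#'   remain loggable.
#' @return List with `table` (data.frame: locus_id, F, df1, df2, p,
#'   neglog10p, n_used, model_family) and `diagnostics` (`lambda_gc`, `qq`).
#' @export
glm_scan <- function(G, S, fixed_factor = c("locality", "frost", "moisture"),
                     covariate = NULL, ranking = NULL, p_floor = 1e-300) {
  fixed_factor <- match.arg(fixed_factor)
  ids <- sample_ids(G)
  Ssub <- S[match(ids, S$sample_id), , drop = FALSE]
  if (anyNA(Ssub$sample_id)) stop("samples absent from metadata")
  block <- design_factor_block(Ssub, fixed_factor, ranking)
  X0 <- cbind(intercept = rep(1, length(ids)))
  X0 <- add_covariate(X0, covariate, ids)
  X1 <- cbind(X0, block)
  d <- G$dosage
  res <- matrix(NA_real_, nrow = ncol(d), ncol = 4,
                dimnames = list(locus_ids(G), c("F", "df1", "df2", "p")))
  n_used <- integer(ncol(d))
  for (j in seq_len(ncol(d))) {
    ok <- !is.na(d[, j])
    n_used[j] <- sum(ok)
    if (n_used[j] < ncol(X1) + 1) next
    res[j, ] <- partial_f_test(d[ok, j], X0[ok, , drop = FALSE],
                               X1[ok, , drop = FALSE], p_floor)
  }
  tab <- data.frame(locus_id = locus_ids(G),
                    F = res[, "F"], df1 = res[, "df1"], df2 = res[, "df2"],
                    p = res[, "p"], neglog10p = -log10(res[, "p"]),
                    n_used = n_used,
                    factor = fixed_factor, model_family = "glm",
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, diagnostics = scan_diagnostics(tab$p))
}

#' Bonferroni threshold
#'
#' @param n_tests number of tests (markers), at least 1.
#' @param alpha family-wise error level in (0, 1), default 0.05.
#' @return List with `threshold = alpha / n_tests` and `neglog10` its
#'   -log10.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  thr <- alpha / n_tests
  list(threshold = thr, neglog10 = -log10(thr))
}

#' Select associated loci at a p-value threshold
#'
#' @param table association table with columns `locus_id` and `p`.
#' @param threshold retain loci with `p <= threshold`.
#' @return Character vector of locus ids in stable (table) order.
#' @export
select_associated <- function(table, threshold) {
  if (nrow(table) == 0) stop("empty association table")
  table$locus_id[!is.na(table$p) & table$p <= threshold]
}
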