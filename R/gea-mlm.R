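#' @title EMMA-style mixed-model association scan
#' @description
#' Fits, per locus, the single-random-effect mixed model
#' `dosage = X beta + u + e`, `u ~ N(0, sigma_g^2 K)`, `e ~ N(0, sigma_e^2 I)`
#' with `K` the identity-by-state kinship matrix. The kinship is
#' eigendecomposed once per missing-data pattern; the REML likelihood is
#' profiled over the variance ratio `delta = sigma_e^2 / sigma_g^2` on a
#' log-spaced grid with golden-section refinement ("emma_full" re-estimates
#' `delta` for every locus). The "p3d" mode estimates `delta` once, by
#' maximizing the summed REML criterion of the factor-free null model
#' (intercept + covariate) over a capped subsample of loci, and reuses it for
#' every marker test. The factor is tested by a partial F test in the
#' whitened (rotated) coordinates.
#'
#' @param G a `genotype_matrix`.
#' @param S a `sample_table` aligned to `G`'s samples.
#' @param fixed_factor `"locality"`, `"frost"` or `"moisture"`.
#' @param K kinship matrix aligned to (a superset of) `G`'s samples; must be
#'   positive semi-definite up to `psd_tol` (small negative eigenvalues are
#'   clipped to zero).
#' @param mode `"p3d"` (default) or `"emma_full"`.
#' @param covariate optional named per-sample covariate.
#' @param ranking `habitat_ranking` for ecological factors.
#' @param p_floor p-value clamp (default 1e-300).
#' @param delta_grid number of grid points over log10(delta) in [-5, 5]
#'   (default 61).
#' @param psd_tol tolerance for negative kinship eigenvalues relative to the
#'   largest (default 0.05). Pairwise-complete IBS matrices computed under
#'   missingness carry small negative eigenvalues; anything within the
#'   tolerance is clipped to zero, larger violations are an error.
#' @param p3d_loci maximum number of loci pooled in the P3D variance-ratio
#'   estimate (default 200, evenly spaced).
#' @return List with `table` (as in [glm_scan()], plus `delta`), `diagnostics`
#'   and `fit`: the variance-component summary (`sigma_g2`, `sigma_e2`,
#'   `delta`, `reml_loglik` at the P3D estimate or averaged over loci, and the
#'   kinship eigenvalues used on complete cases).
#' @export
mlm_scan <- function(G, S, fixed_factor = c("locality", "frost", "moisture"),
                     K, mode = c("p3d", "emma_full"), covariate = NULL,
                     ranking = NULL, p_floor = 1e-300, delta_grid = 61,
                     psd_tol = 0.05, p3d_loci = 200) {
  fixed_factor <- match.arg(fixed_factor)
  mode <- match.arg(mode)
  ids <- sample_ids(G)
  if (!all(ids %in% rownames(K))) stop("kinship does not cover all samples")
  K <- K[ids, ids]
  ev_check <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_check) < -psd_tol * max(abs(ev_check)))
    stop("kinship matrix is not positive semi-definite")
  Ssub <- S[match(ids, S$sample_id), , drop = FALSE]
  block <- design_factor_block(Ssub, fixed_factor, ranking)
  X0 <- cbind(intercept = rep(1, length(ids)))
  X0 <- add_covariate(X0, covariate, ids)
  X1 <- cbind(X0, block)
  d <- G$dosage
  L <- ncol(d)

  eig_cache <- new.env(parent = emptyenv())
  get_rot <- function(ok) {
    key <- paste(which(ok), collapse = ",")
    hit <- eig_cache[[key]]
    if (!is.null(hit)) return(hit)
    e <- eigen(K[ok, ok], symmetric = TRUE)
    lam <- pmax(e$values, 0)
    rot <- list(lambda = lam, Ut = t(e$vectors))
    eig_cache[[key]] <- rot
    rot
  }

  # REML profile criterion for response ys (rotated), design Xs (rotated),
  # eigenvalues lam, at variance ratio delta. Returns list(loglik, sigma_g2,
  # rss_w, rank).
  reml_at <- function(ys, Xs, lam, delta, XtX_logdet) {
    w <- 1 / (lam + delta)
    sw <- sqrt(w)
    fit <- stats::lm.fit(Xs * sw, ys * sw)
    q <- fit$rank
    n <- length(ys)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - q)
    wX <- (Xs * sw)[, seq_len(ncol(Xs)), drop = FALSE]
    xtwx <- crossprod(wX)
    ld_xtwx <- determinant(xtwx, logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - q) * (log(2 * pi * sigma2) + 1) +
                    sum(log(lam + delta)) + ld_xtwx - XtX_logdet)
    list(loglik = as.numeric(ll), sigma_g2 = sigma2, rss_w = rss, rank = q)
  }

  grid <- 10^seq(-5, 5, length.out = delta_grid)

  profile_delta <- function(ys, Xs, lam) {
    XtX_logdet <- determinant(crossprod(Xs), logarithm = TRUE)$modulus
    ll <- vapply(grid, function(dl) reml_at(ys, Xs, lam, dl, XtX_logdet)$loglik,
                 numeric(1))
    i <- which.max(ll)
    lo <- log10(grid[max(1, i - 1)])
    hi <- log10(grid[min(length(grid), i + 1)])
    opt <- stats::optimize(function(ld)
      reml_at(ys, Xs, lam, 10^ld, XtX_logdet)$loglik,
      interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    list(delta = 10^opt$maximum, loglik = opt$objective)
  }

  # --- P3D: one delta from the null model over a locus subsample -----------
  delta_p3d <- NA_real_
  p3d_loglik <- NA_real_
  if (mode == "p3d" && L > 0) {
    take <- unique(round(seq(1, L, length.out = min(p3d_loci, L))))
    pre <- lapply(take, function(j) {
      ok <- !is.na(d[, j])
      if (sum(ok) < ncol(X0) + 2) return(NULL)
      rot <- get_rot(ok)
      Xs <- rot$Ut %*% X0[ok, , drop = FALSE]
      list(ys = drop(rot$Ut %*% d[ok, j]), Xs = Xs, lam = rot$lambda,
           ld = determinant(crossprod(Xs), logarithm = TRUE)$modulus)
    })
    pre <- Filter(Negate(is.null), pre)
    if (!length(pre)) stop("no usable loci for P3D variance estimation")
    total_ll <- function(dl) sum(vapply(pre, function(z)
      reml_at(z$ys, z$Xs, z$lam, dl, z$ld)$loglik, numeric(1)))
    ll <- vapply(grid, total_ll, numeric(1))
    i <- which.max(ll)
    lo <- log10(grid[max(1, i - 1)])
    hi <- log10(grid[min(length(grid), i + 1)])
    opt <- stats::optimize(function(ld) total_ll(10^ld),
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    delta_p3d <- 10^opt$maximum
    p3d_loglik <- opt$objective
  }

  res <- matrix(NA_real_, nrow = L, ncol = 5,
                dimnames = list(locus_ids(G), c("F", "df1", "df2", "p", "delta")))
  n_used <- integer(L)
  sig_g <- sig_e <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    ok <- !is.na(d[, j])
    n_used[j] <- sum(ok)
    if (n_used[j] < ncol(X1) + 1) next
    rot <- get_rot(ok)
    ys <- drop(rot$Ut %*% d[ok, j])
    Xs0 <- rot$Ut %*% X0[ok, , drop = FALSE]
    Xs1 <- rot$Ut %*% X1[ok, , drop = FALSE]
    dl <- if (mode == "p3d") delta_p3d else {
      pf <- tryCatch(profile_delta(ys, Xs1, rot$lambda),
                     error = function(e) NULL)
      if (is.null(pf)) next  # REML non-convergence: locus flagged NA
      pf$delta
    }
    w <- 1 / (rot$lambda + dl)
    sw <- sqrt(w)
    f0 <- stats::lm.fit(Xs0 * sw, ys * sw)
    f1 <- stats::lm.fit(Xs1 * sw, ys * sw)
    df1 <- f1$rank - f0$rank
    df2 <- n_used[j] - f1$rank
    rss0 <- sum(f0$residuals^2)
    rss1 <- sum(f1$residuals^2)
    if (df1 < 1 || df2 < 1) next
    sg <- rss1 / df2
    sig_g[j] <- sg
    sig_e[j] <- dl * sg
    if (rss1 == 0 && rss0 == 0) {            # constant (whitened) dosage
      res[j, ] <- c(0, df1, df2, 1, dl)
      next
    }
    Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    if (!is.finite(Fstat)) { res[j, c(2, 3, 5)] <- c(df1, df2, dl); next }
    p <- max(stats::pf(Fstat, df1, df2, lower.tail = FALSE), p_floor)
    res[j, ] <- c(Fstat, df1, df2, p, dl)
  }
  tab <- data.frame(locus_id = locus_ids(G),
                    F = res[, "F"], df1 = res[, "df1"], df2 = res[, "df2"],
                    p = res[, "p"], neglog10p = -log10(res[, "p"]),
                    n_used = n_used, delta = res[, "delta"],
                    factor = fixed_factor, model_family = "mlm",
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  full_ok <- rep(TRUE, length(ids))
  fit <- list(
    mode = mode,
    delta = if (mode == "p3d") delta_p3d else stats::median(res[, "delta"], na.rm = TRUE),
    sigma_g2 = stats::median(sig_g, na.rm = TRUE),
    sigma_e2 = stats::median(sig_e, na.rm = TRUE),
    reml_loglik = p3d_loglik,
    kinship_eigenvalues = get_rot(full_ok)$lambda)
  list(table = tab, diagnostics = scan_diagnostics(tab$p), fit = fit)
}
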