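test_that("phylogenetic covariate reduces population distances to one axis", {
  # two equidistant populations -> symmetric +/- scores
  D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A_F", "B_F"), c("A_F", "B_F")))
  S <- make_samples(c("A", "B"), c("F", "F"), 3)
  cv <- phylo_covariate(D, S)
  expect_equal(sum(cv), 0)
  expect_equal(abs(unname(cv)), rep(abs(cv[[1]]), 6))
  # three collinear populations: scores collinear with positions
  x <- c(0, 1, 3)
  D3 <- abs(outer(x, x, "-"))
  dimnames(D3) <- list(c("A_F", "B_F", "C_F"), c("A_F", "B_F", "C_F"))
  S3 <- make_samples(c("A", "B", "C"), c("F", "F", "F"), 2)
  cv3 <- phylo_covariate(D3, S3)
  pos <- x[match(S3$population, c("A_F", "B_F", "C_F"))]
  expect_equal(abs(cor(cv3, pos)), 1, tolerance = 1e-9)
  # star topology (all pairwise distances equal) is flagged degenerate
  tree <- ape::read.tree(text = "(A_F:1,B_F:1,C_F:1);")
  pd <- ape::cophenetic.phylo(tree)
  expect_true(all(pd[upper.tri(pd)] == 2))
  expect_error(phylo_covariate(D3[1:2, 1:2], S3), "missing")
})

test_that("GLM scan matches a direct normal-equations fit", {
  set.seed(17)
  S <- make_samples(c("A", "B"), c("F", "F"), 6)
  d <- matrix(sample(0:2, 24, TRUE), nrow = 12,
              dimnames = list(S$sample_id, c("L1", "L2")))
  cv <- stats::setNames(rnorm(12), S$sample_id)
  res <- glm_scan(genotype_matrix(d), S, "locality", covariate = cv)
  for (j in 1:2) {
    y <- d[, j]
    X0 <- cbind(1, cv)
    X1 <- cbind(X0, S$locality == "B")
    b0 <- solve(t(X0) %*% X0, t(X0) %*% y)
    b1 <- solve(t(X1) %*% X1, t(X1) %*% y)
    rss0 <- sum((y - X0 %*% b0)^2)
    rss1 <- sum((y - X1 %*% b1)^2)
    Fo <- (rss0 - rss1) / (rss1 / (12 - 3))
    expect_equal(res$table$F[j], Fo, tolerance = 1e-9)
    expect_equal(res$table$p[j], pf(Fo, 1, 9, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("degenerate loci are handled: constant dosage and perfect fits", {
  S <- make_samples(c("A", "B", "C"), c("F", "W", "D"), 4)
  frost <- habitat_ranking("frost")
  d <- cbind(L1 = rep(1L, 12),
             L2 = as.integer(frost$rank_of[S$habitat] - 1))
  rownames(d) <- S$sample_id
  res <- glm_scan(genotype_matrix(d), S, "frost", ranking = frost)
  expect_equal(res$table$F[1], 0)
  expect_equal(res$table$p[1], 1)
  # exact fit: residual SS = 0, p clamps at the configured floor
  expect_equal(res$table$p[2], 1e-300)
})

test_that("MLM with identity kinship reproduces the GLM scan", {
  set.seed(23)
  S <- make_samples(c("A", "B"), c("F", "D"), 10)
  d <- matrix(sample(c(0:2, NA), 20 * 8, TRUE, prob = c(.4, .3, .2, .1)),
              nrow = 20, dimnames = list(S$sample_id, sprintf("L%02d", 1:8)))
  G <- genotype_matrix(d)
  K <- diag(20)
  dimnames(K) <- list(S$sample_id, S$sample_id)
  glm_res <- glm_scan(G, S, "locality")
  mlm_res <- mlm_scan(G, S, "locality", K = K, mode = "emma_full")
  expect_equal(mlm_res$table$p, glm_res$table$p, tolerance = 1e-6)
  mlm_p3d <- mlm_scan(G, S, "locality", K = K, mode = "p3d")
  expect_equal(mlm_p3d$table$p, glm_res$table$p, tolerance = 1e-6)
})

test_that("EMMA REML delta and F match a direct GLS oracle", {
  set.seed(29)
  n <- 8
  S <- make_samples(c("A", "B"), c("F", "D"), 4)
  K <- kronecker(diag(2), matrix(0.5, 4, 4)) + 0.5 * diag(8)
  dimnames(K) <- list(S$sample_id, S$sample_id)
  d <- matrix(sample(0:2, n * 5, TRUE), nrow = n,
              dimnames = list(S$sample_id, sprintf("L%02d", 1:5)))
  G <- genotype_matrix(d)
  res <- mlm_scan(G, S, "locality", K = K, mode = "emma_full")
  X0 <- matrix(1, n, 1)
  X1 <- cbind(X0, S$locality == "B")
  for (j in 1:5) {
    dl <- res$table$delta[j]
    if (!is.finite(dl) || is.na(res$table$F[j])) next
    V <- K + dl * diag(n)
    Vi <- solve(V)
    gls_rss <- function(X, y) {
      b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
      r <- y - X %*% b
      drop(t(r) %*% Vi %*% r)
    }
    y <- d[, j]
    rss0 <- gls_rss(X0, y)
    rss1 <- gls_rss(X1, y)
    Fo <- (rss0 - rss1) / (rss1 / (n - 2))
    expect_equal(res$table$F[j], Fo, tolerance = 1e-5)
  }
})

test_that("GLM p-values are uniform under the null with calibrated lambda", {
  set.seed(101)
  # study-scale sampling: 6 localities x 3 habitats x 9 samples = 162
  S <- make_samples(rep(c("A", "B", "C", "D", "E", "G"), each = 3),
                    rep(c("F", "W", "D"), times = 6), 9)
  L <- 500
  p0 <- runif(L, 0.1, 0.9)
  d <- sapply(p0, function(p) rbinom(nrow(S), 2, p))
  dimnames(d) <- list(S$sample_id, sprintf("L%03d", 1:L))
  res <- glm_scan(genotype_matrix(d), S, "frost")
  ks <- suppressWarnings(ks.test(res$table$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(res$diagnostics$lambda_gc, 0.85)
  expect_lt(res$diagnostics$lambda_gc, 1.15)
})

test_that("p3d and emma_full p-values agree under moderate structure", {
  # family-structured dosage with the matching block kinship keeps the
  # variance ratio identifiable per locus, the regime P3D approximates
  set.seed(37)
  n_fam <- 12; fam_size <- 8; n <- n_fam * fam_size
  S <- sample_table(data.frame(
    sample_id = sprintf("A_F_s%03d", 1:n), locality = "A",
    habitat = rep(c("F", "W", "D"), length.out = n),
    latitude = 1, longitude = 0))
  K <- kronecker(diag(n_fam), matrix(0.5, fam_size, fam_size)) +
    0.5 * diag(n)
  dimnames(K) <- list(S$sample_id, S$sample_id)
  L <- 200
  d <- sapply(1:L, function(j) {
    p0 <- runif(1, .2, .8)
    pf <- rbeta(n_fam, p0 * (1 - .15) / .15, (1 - p0) * (1 - .15) / .15)
    rbinom(n, 2, rep(pf, each = fam_size))
  })
  dimnames(d) <- list(S$sample_id, sprintf("L%03d", 1:L))
  G <- genotype_matrix(d)
  full <- mlm_scan(G, S, "frost", K = K, mode = "emma_full")
  p3d <- mlm_scan(G, S, "frost", K = K, mode = "p3d")
  ok <- !is.na(full$table$p) & !is.na(p3d$table$p)
  expect_gt(sum(ok), 150)
  expect_gte(cor(rank(full$table$p[ok]), rank(p3d$table$p[ok])), 0.99)
})

test_that("delta is estimated large when the kinship effect is absent", {
  set.seed(5)
  S <- make_samples(c("A", "B", "C"), c("F", "F", "F"), 20)
  K <- kronecker(diag(10), matrix(0.6, 6, 6)) + 0.4 * diag(60)
  dimnames(K) <- list(S$sample_id, S$sample_id)
  d <- sapply(runif(120, .2, .8), function(p) rbinom(60, 2, p))
  dimnames(d) <- list(S$sample_id, sprintf("L%03d", 1:120))
  G <- genotype_matrix(d)
  m <- mlm_scan(G, S, "locality", K = K, mode = "p3d")
  expect_gt(m$fit$delta, 10)   # sigma_g truth 0 -> variance ratio explodes
  g <- glm_scan(G, S, "locality")
  expect_gt(cor(m$table$p, g$table$p, use = "complete.obs"), 0.999)
})

test_that("Bonferroni thresholds reproduce the printed study values", {
  expect_equal(signif(bonferroni_threshold(1273)$threshold, 2), 3.9e-5)
  expect_equal(signif(bonferroni_threshold(812)$threshold, 2), 6.2e-5)
  expect_equal(signif(bonferroni_threshold(897)$threshold, 2), 5.6e-5)
  expect_equal(bonferroni_threshold(1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(100, 0.05)$threshold * 100, 0.05)
  expect_error(bonferroni_threshold(0))
})

test_that("selection returns exactly the sub-threshold loci in stable order", {
  tab <- data.frame(locus_id = sprintf("L%02d", 1:10),
                    p = c(1e-6, 3e-5, 3.9e-5, 4e-5, 5e-5,
                          1e-3, 0.5, 1, 2e-7, 3.91e-5))
  sel <- select_associated(tab, 3.9e-5)
  expect_equal(sel, c("L01", "L02", "L03", "L09"))
  expect_equal(select_associated(tab, 1), tab$locus_id)
  tab$p <- 1
  expect_equal(length(select_associated(tab, 0.05)), 0)
})

test_that("partition driver crosses subsets and drops monomorphic combos", {
  set.seed(41)
  S <- make_samples(c("A", "A", "B", "B"), c("F", "D", "F", "D"), 5)
  d <- matrix(rbinom(20 * 12, 2, 0.4), nrow = 20,
              dimnames = list(S$sample_id, sprintf("L%02d", 1:12)))
  # locus L12 polymorphic only in locality B
  d[S$locality == "A", "L12"] <- 0L
  d[S$locality == "B", "L12"] <- rep(c(0L, 1L, 2L, 1L, 0L), 2)
  G <- genotype_matrix(d)
  rules <- list(entire = NULL, locA = "A", locB = "B")
  # no association sets -> all-markers partitions only
  p0 <- quiet(partition_datasets(G, S, assoc = NULL, subset_rules = rules))
  expect_equal(length(p0), 3)
  # a marker set with one surviving locus in locality A drops that combo
  assoc <- list(habitat = c("L01", "L02", "L03"), private = c("L11", "L12"))
  p1 <- quiet(partition_datasets(G, S, assoc = assoc, subset_rules = rules))
  nm <- vapply(p1, `[[`, character(1), "name")
  expect_false("locA_private" %in% nm)
  expect_true(all(c("entire_private", "locB_private", "entire_habitat",
                    "locA_habitat", "locB_habitat") %in% nm))
  expect_equal(length(p1), 8)  # 9 combinations minus the monomorphic one
  # fully polymorphic sets keep all combinations
  assoc2 <- list(habitat = sprintf("L%02d", 1:6))
  p2 <- quiet(partition_datasets(G, S, assoc = assoc2, subset_rules = rules))
  expect_equal(length(p2), 6)
})
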