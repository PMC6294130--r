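test_that("Weir-Cockerham theta matches the scalar component oracle", {
  A <- rbind(c(0L, 1L, 2L), c(0L, 1L, 1L), c(1L, 2L, 0L))
  B <- rbind(c(2L, 0L, 1L), c(1L, 0L, 1L), c(2L, 1L, 1L))
  d <- rbind(A, B)
  dimnames(d) <- list(c("A_F_s01", "A_F_s02", "A_F_s03",
                        "B_F_s01", "B_F_s02", "B_F_s03"),
                      c("L1", "L2", "L3"))
  S <- make_samples(c("A", "B"), c("F", "F"), 3)
  res <- pairwise_fst(genotype_matrix(d), S, "A_F", "B_F")
  expect_equal(res$theta, wc_theta_oracle(A, B), tolerance = 1e-10)
  expect_equal(res$theta, 0.2727272727, tolerance = 1e-6)  # frozen oracle value
  # per-locus components against the scalar transcription
  for (j in 1:3)
    expect_equal(unname(unlist(res$components[j, c("a", "b", "c")])),
                 unname(wc_scalar(A[, j], B[, j])), tolerance = 1e-10)
  # with a missing call the components change accordingly
  d2 <- d; d2["A_F_s02", "L1"] <- NA
  res2 <- pairwise_fst(genotype_matrix(d2), S, "A_F", "B_F")
  expect_equal(res2$theta, 0.2098635887, tolerance = 1e-6)
})

test_that("theta hits the boundary cases: fixed difference and identity", {
  S <- make_samples(c("A", "B"), c("F", "F"), 10)
  d_fixed <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  dimnames(d_fixed) <- list(S$sample_id, sprintf("L%02d", 1:5))
  expect_equal(pairwise_fst(genotype_matrix(d_fixed), S, "A_F", "B_F")$theta, 1)
  # identical dosage tables: theta carries only the O(1/n) finite-sample
  # correction of the a-component, vanishing as samples grow
  S50 <- make_samples(c("A", "B"), c("F", "F"), 50)
  set.seed(19)
  half <- sapply(runif(30, .2, .8), function(p) rbinom(50, 2, p))
  d_same <- rbind(half, half)
  dimnames(d_same) <- list(S50$sample_id, sprintf("L%02d", 1:30))
  th <- pairwise_fst(genotype_matrix(d_same), S50, "A_F", "B_F")$theta
  expect_lt(abs(th), 0.02)
})

test_that("theta is invariant to population label swap and locus order", {
  set.seed(43)
  S <- make_samples(c("A", "B"), c("F", "F"), 6)
  d <- matrix(sample(c(0:2, NA), 12 * 15, TRUE, prob = c(.4, .3, .2, .1)),
              nrow = 12, dimnames = list(S$sample_id, sprintf("L%02d", 1:15)))
  G <- genotype_matrix(d)
  t1 <- pairwise_fst(G, S, "A_F", "B_F")$theta
  t2 <- pairwise_fst(G, S, "B_F", "A_F")$theta
  expect_equal(t1, t2)
  Gp <- genotype_matrix(d[, sample(ncol(d))])
  expect_equal(pairwise_fst(Gp, S, "A_F", "B_F")$theta, t1)
})

test_that("Rousset linearization is exact and strictly increasing", {
  expect_equal(linearized_fst(0), 0)
  expect_equal(linearized_fst(0.5), 1)
  expect_equal(linearized_fst(0.2), 0.25)
  th <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(linearized_fst(th)) > 0))
  expect_message(linearized_fst(-0.1), "clipped")
  expect_equal(suppressMessages(linearized_fst(-0.1)), 0)
  expect_equal(linearized_fst(-0.1, clip_negative = FALSE), -0.1 / 1.1)
})

test_that("island-model moment estimator inverts the equilibrium curve", {
  expect_equal(nem_from_fst(0.2)$nem, 1)
  expect_equal(nem_from_fst(0.5)$nem, 0.25)
  for (nm in c(0.05, 0.25, 1, 4, 19)) {
    th <- 1 / (1 + 4 * nm)
    expect_equal(nem_from_fst(th)$nem, nm, tolerance = 1e-12)
  }
  expect_equal(suppressMessages(nem_from_fst(-0.02))$nem, 20)  # capped
  # grid pseudo-ML recovers the equilibrium Nm from per-locus spread
  set.seed(3)
  pl <- pmin(pmax(rnorm(400, 1 / (1 + 4 * 1), 0.05), 0), 0.9)
  est <- nem_from_fst(mean(pl), "grid_ml", per_locus_theta = pl)
  expect_equal(est$nem, 1, tolerance = 0.15)
})

test_that("migration summary computes group means and the rank-sum test", {
  est <- data.frame(
    pop_a = c("A_F", "A_F", "A_D", "A_F"),
    pop_b = c("A_D", "A_W", "A_W", "B_F"),
    nem = c(3, 4, 5, 0.5))
  S <- make_samples(c("A", "A", "A", "B", "B"),
                    c("F", "D", "W", "F", "D"), 2)
  ms <- migration_summary(est, S)
  amh <- ms$summary[ms$summary$category == "among_habitats_within_locality", ]
  expect_equal(amh$mean, 4)       # {3, 4, 5}
  expect_equal(amh$n_pairs, 3)
  # within-habitat-across-localities has one pair (A_F-B_F) -> test undefined
  expect_true(is.na(ms$test$p))
  # with two pairs per category the U statistic is the hand rank-sum
  est2 <- rbind(est, data.frame(pop_a = "A_D", pop_b = "B_D", nem = 0.6))
  ms2 <- migration_summary(est2, S)
  expect_equal(unname(ms2$test$U), 6)   # all A values exceed all B values
  expect_equal(ms2$summary$mean[ms2$summary$category ==
                                  "within_habitat_across_localities"], 0.55)
  # degenerate case: identical estimates give SE 0 and p 1
  est3 <- est2
  est3$nem <- 2
  ms3 <- migration_summary(est3, S)
  expect_equal(ms3$summary$se, rep(0, 3))
  expect_equal(ms3$test$p, 1)
})

test_that("edge list carries linearized F_ST and the panmixia flag", {
  set.seed(47)
  S <- make_samples(c("A", "B"), c("F", "F"), 8)
  d <- rbind(sapply(runif(40, .3, .7), function(p) rbinom(8, 2, p)),
             sapply(runif(40, .3, .7), function(p) rbinom(8, 2, p)))
  dimnames(d) <- list(S$sample_id, sprintf("L%02d", 1:40))
  ed <- migration_edges(genotype_matrix(d), S)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$linearized_fst,
               suppressMessages(linearized_fst(ed$fst)))
  expect_equal(ed$panmictic, ed$nem > 1)
})
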