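test_that("VCF loading codes dosage as the minor-allele count", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b"), collapse = "\t"),
    paste(c("1", "100", "snp1", "A", "T", ".", "PASS", ".", "GT:DP",
            "0/0:9", "0/1:7"), collapse = "\t")), vcf)
  G <- load_genotypes(vcf, "vcf")
  expect_equal(unname(G$dosage[, "snp1"]), c(0L, 1L))  # ALT is minor
  expect_equal(unname(G$depth[, "snp1"]), c(9, 7))
})

test_that("when ALT is the major allele the REF allele is counted", {
  # 4 samples, ALT frequency 6/8 = 0.75 -> minor allele is REF;
  # GT 1/1 carries zero copies of the minor allele
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b", "c", "d"), collapse = "\t"),
    paste(c("1", "1", "snp1", "A", "T", ".", "PASS", ".", "GT",
            "1/1", "1/1", "0/1", "0/1"), collapse = "\t")), vcf)
  G <- load_genotypes(vcf, "vcf")
  expect_equal(unname(G$dosage[, "snp1"]), c(0L, 0L, 1L, 1L))
})

test_that("an empty variant section yields a valid 0-locus object", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b"), collapse = "\t")), vcf)
  G <- suppressWarnings(load_genotypes(vcf, "vcf"))
  expect_s3_class(G, "genotype_matrix")
  expect_equal(ncol(G$dosage), 0L)
})

test_that("TSV round-trip preserves dosage and missingness", {
  d <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("L1", "L2", "L3")))
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = rownames(d), d,
                                check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  G <- load_genotypes(tsv, "tsv")
  expect_equal(G$dosage, d)
})

test_that("each filtering rule removes exactly the loci that violate it", {
  # 5 loci crossing each threshold once: L1 fails depth (mean 4 <= 5),
  # L2 fails MAF (0 < 0.05), L3 fails call rate (0.4 < 0.72),
  # L4 and L5 pass every rule
  d <- cbind(L1 = c(0L, 1L, 1L, 0L, 1L), L2 = c(0L, 0L, 0L, 0L, 0L),
             L3 = c(1L, 0L, NA, NA, NA), L4 = c(0L, 1L, 2L, 1L, 0L),
             L5 = c(2L, 1L, 0L, 1L, 2L))
  rownames(d) <- paste0("s", 1:5)
  dp <- matrix(10, 5, 5, dimnames = dimnames(d))
  dp[, "L1"] <- 4
  G <- genotype_matrix(d, dp)
  out <- suppressMessages(apply_filters(G, filter_spec()))
  expect_equal(locus_ids(out), c("L4", "L5"))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["n_loci_out"]), 2)
})

test_that("excluded samples are removed before locus rules apply", {
  d <- cbind(L1 = c(0L, 1L, 2L, 2L), L2 = c(0L, 0L, 2L, 2L))
  rownames(d) <- paste0("s", 1:4)
  G <- genotype_matrix(d)
  out <- suppressMessages(suppressWarnings(
    apply_filters(G, filter_spec(min_locus_depth = -Inf,
                                 excluded_samples = c("s3", "s4")))))
  expect_equal(sample_ids(out), c("s1", "s2"))
  # L2 is monomorphic among the remaining samples -> removed
  expect_equal(locus_ids(out), "L1")
})

test_that("filtering is idempotent", {
  set.seed(42)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 300, replace = TRUE,
                     prob = c(.4, .3, .2, .1)), nrow = 15)
  dimnames(d) <- list(sprintf("s%02d", 1:15), sprintf("L%02d", 1:20))
  G <- genotype_matrix(d)
  spec <- filter_spec(min_locus_depth = -Inf)
  once <- quiet(apply_filters(G, spec))
  twice <- quiet(apply_filters(once, spec))
  expect_equal(twice$dosage, once$dosage)
})

test_that("filtered matrices satisfy the MAF and call-rate bounds", {
  set.seed(7)
  S <- make_samples("A", "F", 20)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 1000, replace = TRUE,
                     prob = c(.5, .25, .15, .1)), nrow = 20)
  dimnames(d) <- list(S$sample_id, sprintf("L%02d", 1:50))
  G <- quiet(apply_filters(genotype_matrix(d),
                           filter_spec(min_locus_depth = -Inf)))
  af <- allele_frequencies(G, S)
  expect_true(all(af$maf > 0.05))
  expect_true(all(af$call_rate >= 0.72))
})

test_that("allele frequencies are per-population minor-allele proportions", {
  d <- rbind(c(1L, 0L), c(2L, 0L),            # pop A_F: p = 3/4, 0
             c(0L, NA), c(0L, NA))            # pop B_F: p = 0, all-missing
  dimnames(d) <- list(c("A_F_s01", "A_F_s02", "B_F_s01", "B_F_s02"),
                      c("L1", "L2"))
  S <- make_samples(c("A", "B"), c("F", "F"), 2)
  af <- allele_frequencies(genotype_matrix(d), S)
  expect_equal(af$freq["L1", "A_F"], 0.75)
  expect_equal(af$freq["L1", "B_F"], 0)
  expect_true(is.na(af$freq["L2", "B_F"]))   # missing, never coerced to 0
  expect_equal(af$overall[["L1"]], 3 / 8)
})

test_that("IBS kinship matches the allele-sharing definition", {
  expect_equal(unname(ibs_kinship(make_gm(rbind(c(0, 1, 2), c(0, 1, 2))))),
               matrix(1, 2, 2))
  expect_equal(ibs_kinship(make_gm(rbind(c(0, 0), c(2, 2))))["s01", "s02"], 0)
  # 3 samples x 4 loci with one missing call, against an explicit loop
  d <- rbind(c(0, 1, 2, 1), c(1, 1, 0, NA), c(2, 0, 2, 2))
  K <- ibs_kinship(make_gm(d))
  for (i in 1:3) for (j in 1:3) {
    ok <- !is.na(d[i, ]) & !is.na(d[j, ])
    expect_equal(K[i, j],
                 if (i == j) 1 else mean(1 - abs(d[i, ok] - d[j, ok]) / 2))
  }
})

test_that("kinship is invariant to locus order and allele relabeling", {
  set.seed(11)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 120, TRUE, prob = c(.4, .3, .2, .1)),
              nrow = 6)
  dimnames(d) <- list(sprintf("s%02d", 1:6), sprintf("L%02d", 1:20))
  K <- ibs_kinship(genotype_matrix(d))
  perm <- sample(ncol(d))
  expect_equal(ibs_kinship(genotype_matrix(d[, perm])), K)
  flip <- d
  flip[, 1:7] <- 2L - flip[, 1:7]   # consistent relabeling at some loci
  expect_equal(ibs_kinship(genotype_matrix(flip)), K)
})

test_that("LD pruning matches brute-force R2 and handles complements", {
  x <- c(0L, 1L, 2L, 0L, 2L, 1L, 0L, 2L)
  d <- cbind(L1 = x, L2 = x, L3 = 2L - x,
             L4 = c(0L, 0L, 1L, 2L, 1L, 0L, 2L, 1L))
  rownames(d) <- sprintf("s%02d", 1:8)
  G <- genotype_matrix(d)
  # identical and complementary loci both have R2 = 1 with L1
  expect_equal(dosage_r2 <- suppressWarnings(cor(d[, "L1"], d[, "L3"])^2), 1)
  out <- ld_prune(G, r2_threshold = 0.8, window = 10)
  expect_equal(out$kept, c("L1", "L4"))
  # R2 over retained pairs equals a double-loop Pearson computation
  r2_brute <- cor(d[, "L1"], d[, "L4"])^2
  expect_equal(out$ld_stats$r2, r2_brute, tolerance = 1e-12)
})

test_that("pruning on a hand-computed 6-locus toy removes one pair member", {
  set.seed(3)
  base <- sample(c(0L, 1L, 2L), 12, TRUE)
  noise <- sample(c(0L, 1L, 2L), 12, TRUE)
  d <- cbind(L1 = base, L2 = noise,
             L3 = sample(c(0L, 1L, 2L), 12, TRUE),
             L4 = base,                       # correlated pair (L1, L4)
             L5 = sample(c(0L, 1L, 2L), 12, TRUE),
             L6 = sample(c(0L, 1L, 2L), 12, TRUE))
  rownames(d) <- sprintf("s%02d", 1:12)
  r2_all <- outer(1:6, 1:6, Vectorize(function(i, j) cor(d[, i], d[, j])^2))
  # only the planted pair exceeds the threshold in this draw
  expect_equal(sum(r2_all[upper.tri(r2_all)] >= 0.8), 1)
  out <- ld_prune(genotype_matrix(d), 0.8, window = 6)
  expect_equal(out$kept, c("L1", "L2", "L3", "L5", "L6"))
})
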