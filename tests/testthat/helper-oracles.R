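# Independent oracles, deliberately written in a different style from the
# package implementations they check.

# scalar transcription of the Weir-Cockerham (1984) two-population variance
# components for one locus
wc_scalar <- function(gA, gB) {
  n1 <- sum(!is.na(gA)); n2 <- sum(!is.na(gB)); r <- 2
  p1 <- sum(gA, na.rm = TRUE) / (2 * n1)
  p2 <- sum(gB, na.rm = TRUE) / (2 * n2)
  h1 <- mean(gA == 1, na.rm = TRUE)
  h2 <- mean(gB == 1, na.rm = TRUE)
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

wc_theta_oracle <- function(dA, dB) {
  comp <- sapply(seq_len(ncol(dA)), function(j) wc_scalar(dA[, j], dB[, j]))
  sum(comp["a", ]) / sum(colSums(comp))
}

# exhaustive-permutation Mantel p-value (one-sided, >=) for small matrices
mantel_exact <- function(A, B) {
  n <- nrow(A)
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  perms <- gtools_permutations(n)
  r_all <- apply(perms, 1, function(pm) cor(A[ut], B[pm, pm][ut]))
  mean(r_all >= r_obs - 1e-12)
}

# all permutations of 1..n (n small), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1
    }
  }
  out
}

# brute-force nested ANOVA variance components for a single numeric trait
# (localities / populations-within-locality / within-population)
nested_anova_oracle <- function(x, loc, pop) {
  N <- length(x)
  locs <- unique(loc); pops <- unique(pop)
  Gn <- length(locs); Pn <- length(pops)
  ss_t <- sum((x - mean(x))^2)
  ss_wp <- sum(sapply(pops, function(p) sum((x[pop == p] - mean(x[pop == p]))^2)))
  ss_wg <- sum(sapply(locs, function(g) sum((x[loc == g] - mean(x[loc == g]))^2)))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_t - ss_wg
  ms <- c(ss_ag / (Gn - 1), ss_ap / (Pn - Gn), ss_wp / (N - Pn))
  n_p <- as.numeric(table(pop)[pops])
  n_g <- as.numeric(table(loc)[locs]); names(n_g) <- locs
  g_of_p <- sapply(pops, function(p) loc[match(p, pop)])
  s1 <- sum(sapply(locs, function(g) sum(n_p[g_of_p == g]^2) / n_g[[g]]))
  n1 <- (N - s1) / (Pn - Gn)
  n2 <- (s1 - sum(n_p^2) / N) / (Gn - 1)
  n3 <- (N - sum(n_g^2) / N) / (Gn - 1)
  s2c <- ms[3]
  s2b <- (ms[2] - s2c) / n1
  s2a <- (ms[1] - s2c - n2 * s2b) / n3
  c(a = s2a, b = s2b, c = s2c)
}

# small genotype-matrix builder with auto names
make_gm <- function(dosage, depth = NULL) {
  dosage <- as.matrix(dosage)
  rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  colnames(dosage) <- sprintf("L%02d", seq_len(ncol(dosage)))
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    dimnames(depth) <- dimnames(dosage)
  }
  genotype_matrix(dosage, depth)
}

# metadata builder: populations named <locality>_<habitat>
make_samples <- function(localities, habitats, n_each,
                         lat = NULL, lon = NULL) {
  stopifnot(length(localities) == length(habitats))
  k <- length(localities)
  if (is.null(lat)) lat <- seq_len(k)
  if (is.null(lon)) lon <- rep(0, k)
  rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(
      sample_id = sprintf("%s_%s_s%02d", localities[i], habitats[i],
                          seq_len(n_each)),
      locality = localities[i], habitat = habitats[i],
      latitude = lat[i], longitude = lon[i], stringsAsFactors = FALSE)
  }))
  sample_table(rows)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
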