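#' Genotype matrix container
#'
#' Bundles a samples x loci minor-allele dosage matrix (0/1/2 or `NA`) with an
#' optional aligned per-call read-depth matrix. Dosages always count the minor
#' allele as determined over all samples at load time; that orientation is
#' frozen for every downstream analysis of the dataset, so effect signs cannot
#' silently flip when samples or loci are subset.
#'
#' @param dosage integer/numeric matrix, samples in rows, loci in columns,
#'   entries in `{0, 1, 2, NA}`; must carry unique row and column names.
#' @param depth optional matrix of non-negative read counts with the same
#'   shape and dimnames as `dosage`; `NULL` when depth is unavailable.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, depth = NULL) {
  if (!is.matrix(dosage)) stop("dosage must be a matrix")
  if ((nrow(dosage) > 0 && is.null(rownames(dosage))) ||
      (ncol(dosage) > 0 && is.null(colnames(dosage))))
    stop("dosage must have sample (row) and locus (column) names")
  dimnames(dosage) <- list(rownames(dosage) %||% character(0),
                           colnames(dosage) %||% character(0))
  if (anyDuplicated(rownames(dosage))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(dosage))) stop("duplicate locus ids")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("non-missing dosage values must be 0, 1 or 2")
  storage.mode(dosage) <- "integer"
  if (!is.null(depth)) {
    if (!is.matrix(depth) || !identical(dim(depth), dim(dosage)))
      stop("depth must match the shape of dosage")
    if (any(depth[!is.na(depth)] < 0)) stop("depth must be non-negative")
    dimnames(depth) <- dimnames(dosage)
    storage.mode(depth) <- "double"
  }
  structure(list(dosage = dosage, depth = depth), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d loci (%.1f%% missing, depth %s)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage)),
    if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample ids of a genotype matrix
#' @param G a `genotype_matrix`.
#' @return Character vector of sample ids (row order).
#' @export
sample_ids <- function(G) rownames(G$dosage)

#' Locus ids of a genotype matrix
#' @param G a `genotype_matrix`.
#' @return Character vector of locus ids (column order).
#' @export
locus_ids <- function(G) colnames(G$dosage)

#' Subset a genotype matrix
#'
#' @param G a `genotype_matrix`.
#' @param samples character vector of sample ids to keep (default all).
#' @param loci character vector of locus ids to keep (default all).
#' @return A `genotype_matrix` restricted to the requested rows/columns,
#'   preserving the given order.
#' @export
subset_genotypes <- function(G, samples = sample_ids(G), loci = locus_ids(G)) {
  miss_s <- setdiff(samples, sample_ids(G))
  if (length(miss_s)) stop("unknown sample ids: ", paste(miss_s, collapse = ", "))
  miss_l <- setdiff(loci, locus_ids(G))
  if (length(miss_l)) stop("unknown locus ids: ", paste(miss_l, collapse = ", "))
  d <- G$dosage[samples, loci, drop = FALSE]
  dp <- if (is.null(G$depth)) NULL else G$depth[samples, loci, drop = FALSE]
  genotype_matrix(d, dp)
}

#' Sample metadata table
#'
#' Validates and normalizes a sample metadata data.frame and derives the
#' population key. A population is a locality-habitat combination, optionally
#' refined by a taxon label where two taxa co-occur in the same
#' locality-habitat cell.
#'
#' @param df data.frame with columns `sample_id`, `locality`, `habitat`
#'   (one of `"F"`, `"W"`, `"D"`), `latitude`, `longitude`, and optionally
#'   `taxon`.
#' @param use_taxon logical; include the taxon label in the population key
#'   when a locality-habitat cell holds more than one taxon (default `TRUE`).
#' @return The input data.frame with a derived `population` column, class
#'   `sample_table`.
#' @export
sample_table <- function(df, use_taxon = TRUE) {
  need <- c("sample_id", "locality", "habitat", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing metadata columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$habitat %in% c("F", "W", "D")))
    stop("habitat must be one of F, W, D")
  if (any(!is.finite(df$latitude)) || any(abs(df$latitude) > 90))
    stop("latitude must be finite and in [-90, 90]")
  if (any(!is.finite(df$longitude)) || any(abs(df$longitude) > 180))
    stop("longitude must be finite and in [-180, 180]")
  pop <- paste(df$locality, df$habitat, sep = "_")
  if (use_taxon && "taxon" %in% names(df) && any(nzchar(df$taxon %||% ""))) {
    # refine only cells where >1 taxon share a locality-habitat combination
    for (cell in unique(pop)) {
      idx <- pop == cell
      tx <- df$taxon[idx]
      if (length(unique(tx[nzchar(tx)])) > 1)
        pop[idx] <- paste(cell, tx, sep = "_")
    }
  }
  df$population <- pop
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Load a sample metadata TSV
#'
#' Expected columns: `sample_id`, `locality`, `habitat`, `latitude`,
#' `longitude`, optional `taxon`.
#'
#' @param path TSV path.
#' @param ... passed to [sample_table()].
#' @return A `sample_table`.
#' @export
load_sample_table <- function(path, ...) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df, ...)
}

#' Habitat ranking for an ecological axis
#'
#' Ordinal rank codes for the three habitats along one theoretical ecological
#' axis (exposure to frost or soil moisture content). Defaults: frost
#' increases from cloud forest through wet depressions to dry exposed slopes
#' (F=1, W=2, D=3); soil moisture is lowest on dry slopes and highest in the
#' well-irrigated depressions (D=1, F=2, W=3).
#'
#' @param axis `"frost"` or `"moisture"`, or any label for a custom axis.
#' @param ranks named numeric vector with entries for `F`, `W` and `D`;
#'   `NULL` selects the default coding for the named axis.
#' @return An object of class `habitat_ranking`.
#' @export
habitat_ranking <- function(axis = c("frost", "moisture"), ranks = NULL) {
  axis <- axis[1L]
  if (is.null(ranks)) {
    ranks <- switch(axis,
      frost = c(F = 1, W = 2, D = 3),
      moisture = c(D = 1, F = 2, W = 3),
      stop("no default ranks for axis '", axis, "'; supply `ranks`"))
  }
  if (!all(c("F", "W", "D") %in% names(ranks)))
    stop("ranks must name all of F, W, D")
  if (any(!is.finite(ranks))) stop("ranks must be finite")
  structure(list(axis = axis, rank_of = ranks[c("F", "W", "D")]),
            class = "habitat_ranking")
}

#' Load a habitat ranking from a two-column TSV (habitat, rank)
#' @param path TSV path with columns `habitat` and `rank`.
#' @param axis axis label to attach.
#' @return A `habitat_ranking`.
#' @export
load_habitat_ranking <- function(path, axis) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  habitat_ranking(axis, stats::setNames(df$rank, df$habitat))
}

#' GBS filtering rule set
#'
#' The rule set applied to called variants: mean read count per locus strictly
#' above `min_locus_depth`, minor allele frequency across all samples strictly
#' above `min_maf`, and genotype observation (call) rate of at least
#' `min_call_rate`. Samples listed in `excluded_samples` are dropped before
#' any locus rule is evaluated.
#'
#' @param min_locus_depth exclusive lower bound on mean depth over non-missing
#'   calls at a locus (default 5). Use `-Inf` to disable.
#' @param min_maf exclusive lower bound on the overall minor allele frequency
#'   (default 0.05).
#' @param min_call_rate inclusive lower bound on the fraction of non-missing
#'   genotypes at a locus (default 0.72).
#' @param excluded_samples character vector of sample ids removed up front
#'   (e.g. reiteratively misplaced samples identified by the analyst).
#' @param per_call_depth logical; if `TRUE`, individual calls with depth
#'   `<= min_locus_depth` are set missing before the locus rules are applied
#'   (default `FALSE`: depth is a per-locus mean rule).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_locus_depth = 5, min_maf = 0.05,
                        min_call_rate = 0.72, excluded_samples = character(),
                        per_call_depth = FALSE) {
  if (!(min_maf >= 0 && min_maf < 0.5)) stop("min_maf must be in [0, 0.5)")
  if (!(min_call_rate > 0 && min_call_rate <= 1))
    stop("min_call_rate must be in (0, 1]")
  structure(list(min_locus_depth = min_locus_depth, min_maf = min_maf,
                 min_call_rate = min_call_rate,
                 excluded_samples = as.character(excluded_samples),
                 per_call_depth = isTRUE(per_call_depth)),
            class = "filter_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load genotypes from VCF or a dosage TSV
#'
#' Dosage is coded as the count of the minor allele, where the minor allele is
#' determined once over all samples in the file (ties at frequency 0.5 are
#' broken toward the alphabetically smaller allele string). Per-genotype read
#' depth is taken from the `DP` FORMAT field when present.
#'
#' The TSV dialect is a header row `sample_id` followed by locus ids, one
#' sample per row, cells in `{0, 1, 2, NA}` counting the minor allele; an
#' optional companion depth TSV has the identical shape.
#'
#' @param path VCF (optionally gzipped) or TSV path.
#' @param format `"vcf"` or `"tsv"`.
#' @param depth_path optional companion depth TSV (TSV format only).
#' @return A `genotype_matrix`.
#' @export
load_genotypes <- function(path, format = c("vcf", "tsv"), depth_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") return(load_genotypes_tsv(path, depth_path))

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    samples <- colnames(v@gt)[-1] %||% character()
    d <- matrix(integer(), nrow = length(samples), ncol = 0,
                dimnames = list(samples, character()))
    return(genotype_matrix(d))
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message(sum(multi), " multi-allelic site(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  keep <- which(!multi)
  loci <- rownames(gt) %||% paste0("locus", seq_len(nrow(gt)))
  loci[is.na(loci) | loci == "."] <- paste0("locus", which(is.na(loci) | loci == "."))
  # ALT allele count per genotype; "." or missing -> NA
  alt_count <- function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == "." | a == "")) return(NA_integer_)
    sum(a != "0")
  }
  n_samp <- ncol(gt)
  d <- matrix(NA_integer_, nrow = n_samp, ncol = length(keep),
              dimnames = list(colnames(gt), make.unique(loci[keep])))
  dmat <- if (is.null(dp)) NULL else
    matrix(NA_real_, nrow = n_samp, ncol = length(keep), dimnames = dimnames(d))
  for (j in seq_along(keep)) {
    i <- keep[j]
    ac <- vapply(gt[i, ], alt_count, integer(1))
    # minor allele over all samples; tie -> alphabetically smaller allele
    tot <- sum(!is.na(ac)) * 2L
    alt_freq <- if (tot > 0) sum(ac, na.rm = TRUE) / tot else 0
    minor_is_alt <- if (tot == 0) TRUE
      else if (alt_freq < 0.5) TRUE
      else if (alt_freq > 0.5) FALSE
      else fix[i, "ALT"] < fix[i, "REF"]
    d[, j] <- if (minor_is_alt) ac else 2L - ac
    if (!is.null(dmat)) dmat[, j] <- dp[i, ]
  }
  genotype_matrix(d, dmat)
}

load_genotypes_tsv <- function(path, depth_path = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "sample_id")
    stop("parse error in ", path, ": first column must be 'sample_id'")
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df$sample_id
  dp <- NULL
  if (!is.null(depth_path)) {
    dd <- utils::read.table(depth_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    dp <- as.matrix(dd[, -1, drop = FALSE])
    rownames(dp) <- dd$sample_id
    dp <- dp[rownames(d), colnames(d), drop = FALSE]
  }
  genotype_matrix(d, dp)
}

#' Apply the GBS filtering rule set
#'
#' Samples in `spec$excluded_samples` are removed first; loci are then kept
#' iff mean depth over non-missing calls exceeds `min_locus_depth` (skipped
#' with a warning when depth is absent), overall MAF exceeds `min_maf`, and
#' call rate is at least `min_call_rate`. Locus order is preserved. Counts
#' removed per rule are attached as attribute `"filter_log"` and reported
#' via `message()`.
#'
#' @param G a `genotype_matrix`.
#' @param spec a `filter_spec`.
#' @return The filtered `genotype_matrix`.
#' @export
apply_filters <- function(G, spec = filter_spec()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "filter_spec"))
  keep_s <- setdiff(sample_ids(G), spec$excluded_samples)
  G <- subset_genotypes(G, samples = keep_s)
  d <- G$dosage
  dp <- G$depth
  if (spec$per_call_depth && !is.null(dp) && is.finite(spec$min_locus_depth)) {
    d[!is.na(dp) & dp <= spec$min_locus_depth] <- NA_integer_
  }
  n <- nrow(d)
  ncall <- colSums(!is.na(d))
  call_rate <- if (n > 0) ncall / n else rep(0, ncol(d))
  af <- colSums(d, na.rm = TRUE) / (2 * pmax(ncall, 1L))
  af[ncall == 0] <- NA_real_
  maf <- pmin(af, 1 - af)

  if (is.null(dp) || spec$per_call_depth || !is.finite(spec$min_locus_depth)) {
    pass_depth <- rep(TRUE, ncol(d))
    if (is.null(dp) && is.finite(spec$min_locus_depth) && ncol(d) > 0)
      warning("depth absent: mean-depth rule skipped")
  } else {
    mdep <- colSums(dp * !is.na(d), na.rm = TRUE) / pmax(ncall, 1L)
    pass_depth <- ncall > 0 & mdep > spec$min_locus_depth
  }
  pass_maf <- !is.na(maf) & maf > spec$min_maf
  pass_call <- call_rate >= spec$min_call_rate
  keep <- pass_depth & pass_maf & pass_call
  log <- c(n_loci_in = ncol(d),
           fail_depth = sum(!pass_depth),
           fail_maf = sum(!pass_maf),
           fail_call_rate = sum(!pass_call),
           n_loci_out = sum(keep),
           n_samples_excluded = length(spec$excluded_samples))
  message(sprintf(
    "filter: %d -> %d loci (depth fails %d, MAF fails %d, call-rate fails %d); %d sample(s) excluded",
    log["n_loci_in"], log["n_loci_out"], log["fail_depth"], log["fail_maf"],
    log["fail_call_rate"], log["n_samples_excluded"]))
  if (sum(keep) == 0) warning("all loci removed by filtering")
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         if (is.null(dp)) NULL else dp[, keep, drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

#' Per-locus allele frequencies by population and overall
#'
#' The per-population frequency is the minor-allele count over twice the
#' number of non-missing genotypes in that population; a population with no
#' non-missing call at a locus gets `NA`, never 0.
#'
#' @param G a `genotype_matrix`.
#' @param S a `sample_table` covering every sample in `G`.
#' @return A list with `freq` (loci x populations matrix of minor-allele
#'   frequencies), `overall` (frequency over all samples), `maf`
#'   (`min(overall, 1 - overall)`), `call_rate`, and `mean_depth` (`NA`
#'   when depth is absent).
#' @export
allele_frequencies <- function(G, S) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- setdiff(sample_ids(G), S$sample_id)
  if (length(miss)) stop("samples absent from metadata: ",
                         paste(miss, collapse = ", "))
  pop <- S$population[match(sample_ids(G), S$sample_id)]
  d <- G$dosage
  pops <- unique(pop)
  freq <- matrix(NA_real_, nrow = ncol(d), ncol = length(pops),
                 dimnames = list(locus_ids(G), pops))
  for (p in pops) {
    dp <- d[pop == p, , drop = FALSE]
    nc <- colSums(!is.na(dp))
    f <- colSums(dp, na.rm = TRUE) / (2 * pmax(nc, 1L))
    f[nc == 0] <- NA_real_
    freq[, p] <- f
  }
  nc_all <- colSums(!is.na(d))
  overall <- colSums(d, na.rm = TRUE) / (2 * pmax(nc_all, 1L))
  overall[nc_all == 0] <- NA_real_
  mean_depth <- if (is.null(G$depth)) rep(NA_real_, ncol(d)) else
    colSums(G$depth * !is.na(d), na.rm = TRUE) / pmax(nc_all, 1L)
  list(freq = freq,
       overall = overall,
       maf = pmin(overall, 1 - overall),
       call_rate = nc_all / max(nrow(d), 1L),
       mean_depth = mean_depth)
}
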