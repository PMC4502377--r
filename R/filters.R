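filter_report <- function(rule, unit, n_in, n_removed) {
  tibble(
    rule = rule, unit = unit,
    n_in = as.integer(n_in), n_removed = as.integer(n_removed),
    n_out = as.integer(n_in - n_removed)
  )
}

#' Mask low-confidence genotype calls by PL margin
#'
#' A call's confidence is its second-smallest phred-scaled genotype
#' likelihood: the margin by which the best genotype beats the runner-up.
#' Calls whose second-smallest PL is below `pl_min` become missing, as do
#' called cells with no PL triple at all. The boundary is strict: a margin
#' exactly equal to `pl_min` is retained.
#'
#' @param gm a [genotype_matrix()] with PL data.
#' @param pl_min phred threshold on the secondary call (default 35).
#' @return A list with `gm` (masked matrix) and `report` (cells masked).
#' @export
mask_low_confidence <- function(gm, pl_min = 35) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_called <- sum(!is.na(gm$dosage))
  if (is.null(gm$pl)) {
    gm$dosage[] <- NA_integer_
    return(list(
      gm = gm,
      report = filter_report("pl_margin", "cells", n_called, n_called)
    ))
  }
  p1 <- gm$pl[, , 1]; p2 <- gm$pl[, , 2]; p3 <- gm$pl[, , 3]
  second <- p1 + p2 + p3 - pmin(p1, p2, p3) - pmax(p1, p2, p3)
  mask <- !is.na(gm$dosage) & (is.na(second) | second < pl_min)
  gm$dosage[mask] <- NA_integer_
  list(
    gm = gm,
    report = filter_report("pl_margin", "cells", n_called, sum(mask))
  )
}

#' Filter loci by sequencing coverage across samples
#'
#' Keeps a locus only if at least `ceiling(min_fraction * N)` samples have
#' read depth of `min_depth` or more -- the "10x in at least 80% of
#' individuals" rule by default. The ceiling makes "at least" strict while
#' letting exact ties (e.g. 8 of 10 at 80%) pass.
#'
#' @param gm a [genotype_matrix()].
#' @param min_depth minimum per-call read depth (default 10).
#' @param min_fraction minimum fraction of samples at that depth (default 0.8).
#' @return A list with `gm` (surviving loci) and `report` (loci removed).
#' @export
filter_site_coverage <- function(gm, min_depth = 10, min_fraction = 0.8) {
  stopifnot(inherits(gm, "genotype_matrix"))
  need <- ceiling(min_fraction * n_samples(gm))
  keep <- colSums(gm$depth >= min_depth) >= need
  list(
    gm = gm_subset(gm, loci = keep),
    report = filter_report("site_coverage", "loci", n_loci(gm), sum(!keep))
  )
}

#' Filter loci by minimum alternate-allele support
#'
#' Keeps a locus only if the alternate allele is observed at least
#' `min_alt_obs` times across called genotypes: a heterozygote contributes 1,
#' a homozygous-alternate call 2. Monomorphic-reference loci are therefore
#' removed.
#'
#' @param gm a [genotype_matrix()].
#' @param min_alt_obs minimum alternate observations (default 4).
#' @return A list with `gm` and `report` (loci removed).
#' @export
filter_alt_support <- function(gm, min_alt_obs = 4) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- colSums(gm$dosage, na.rm = TRUE) >= min_alt_obs
  list(
    gm = gm_subset(gm, loci = keep),
    report = filter_report("alt_support", "loci", n_loci(gm), sum(!keep))
  )
}

#' Filter loci by maximum missing genotypes
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum number of missing calls tolerated per locus
#'   among the samples in `gm`.
#' @return A list with `gm` and `report` (loci removed).
#' @export
filter_max_missing <- function(gm, max_missing) {
  stopifnot(inherits(gm, "genotype_matrix"), max_missing >= 0)
  keep <- colSums(is.na(gm$dosage)) <= max_missing
  list(
    gm = gm_subset(gm, loci = keep),
    report = filter_report("max_missing", "loci", n_loci(gm), sum(!keep))
  )
}

#' Apply the full genotype-quality filter chain
#'
#' Composes, in order: PL-margin masking, site-coverage filtering,
#' alternate-support filtering, and the per-analysis missingness cap.
#' Re-running the chain on its own output removes nothing further.
#'
#' @param gm a [genotype_matrix()].
#' @param pl_min,min_depth,min_fraction,min_alt_obs see the individual
#'   filters; defaults are the pipeline defaults (35, 10, 0.8, 4).
#' @param max_missing per-locus missing-call cap; default `Inf` (off) because
#'   the cap is analysis-specific (e.g. 10 for tree building, 8 for structure,
#'   15 for cultivar-only allelic scans).
#' @return A list with `gm` (filtered) and `report` (one row per rule, in
#'   application order).
#' @export
filter_genotypes <- function(gm, pl_min = 35, min_depth = 10,
                             min_fraction = 0.8, min_alt_obs = 4,
                             max_missing = Inf) {
  s1 <- mask_low_confidence(gm, pl_min)
  s2 <- filter_site_coverage(s1$gm, min_depth, min_fraction)
  s3 <- filter_alt_support(s2$gm, min_alt_obs)
  if (is.finite(max_missing)) {
    s4 <- filter_max_missing(s3$gm, max_missing)
  } else {
    s4 <- list(gm = s3$gm,
               report = filter_report("max_missing", "loci", n_loci(s3$gm), 0))
  }
  list(
    gm = s4$gm,
    report = dplyr::bind_rows(s1$report, s2$report, s3$report, s4$report)
  )
}

#' Concordance and predicted accuracy of duplicated samples
#'
#' Compares each duplicate pair over loci called in both members.
#' `predicted_accuracy = 1 - (1 - concordance) / 2`, the accuracy implied by
#' the observed discordance when errors are assumed equally likely in both
#' members of the pair.
#'
#' @param gm a [genotype_matrix()].
#' @param pairs data frame with columns `sample` and `duplicate_of` naming
#'   the two members of each pair.
#' @return Tibble: `sample`, `duplicate_of`, `n_compared`, `concordance`,
#'   `predicted_accuracy`. Pairs with no co-called loci get `n_compared = 0`
#'   and `NA` metrics.
#' @export
duplicate_concordance <- function(gm, pairs) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pairs <- as_tibble(pairs)[, c("sample", "duplicate_of")]
  missing_ids <- setdiff(
    c(pairs$sample, pairs$duplicate_of), gm$samples
  )
  if (length(missing_ids)) {
    stop("pair member(s) absent from matrix: ", paste(missing_ids, collapse = ", "))
  }
  purrr::pmap_dfr(pairs, function(sample, duplicate_of) {
    a <- gm$dosage[sample, ]
    b <- gm$dosage[duplicate_of, ]
    both <- !is.na(a) & !is.na(b)
    n <- sum(both)
    conc <- if (n > 0) mean(a[both] == b[both]) else NA_real_
    tibble(
      sample = sample, duplicate_of = duplicate_of,
      n_compared = n, concordance = conc,
      predicted_accuracy = 1 - (1 - conc) / 2
    )
  })
}
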