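#' Resolve a two-group comparison from population assignments
#'
#' Maps assignment labels into two named groups of samples. The default
#' grouping used by the survey pools the smaller western cluster with the
#' admixed samples (`west = pop_1 + Mixed`) against the eastern cluster; the
#' strict west-vs-east comparison is a config override.
#'
#' @param assignment tibble with columns `sample` and `label` (e.g. from
#'   [assign_populations()]).
#' @param grouping named list of two character vectors of labels; each group
#'   collects the samples whose label is in the vector.
#' @return Named list of two character vectors of sample ids.
#' @export
group_samples <- function(assignment,
                          grouping = list(west = c("pop_1", "Mixed"),
                                          east = "pop_2")) {
  assignment <- as_tibble(assignment)
  stopifnot(all(c("sample", "label") %in% names(assignment)))
  if (length(grouping) != 2 || is.null(names(grouping))) {
    stop("`grouping` must be a named list of exactly two label sets")
  }
  groups <- lapply(grouping, function(labs) {
    assignment$sample[assignment$label %in% labs]
  })
  empty <- lengths(groups) == 0
  if (any(empty)) {
    stop("group(s) with zero samples: ", paste(names(groups)[empty], collapse = ", "))
  }
  if (length(intersect(groups[[1]], groups[[2]]))) {
    stop("groups overlap")
  }
  groups
}

#' Per-locus allele counts in two populations
#'
#' Counts reference and alternate alleles per locus and group, treating the
#' two alleles of a heterozygote independently (a het adds 1 to each count, a
#' homozygote adds 2 to one). Missing genotypes contribute nothing to the
#' allele counts and are tallied separately.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of two sample-id vectors from [group_samples()],
#'   or an assignment tibble (then `grouping` applies).
#' @param grouping label grouping, used when `groups` is an assignment table.
#' @return Long tibble: `locus` (column index), `contig`, `pos`, `ref`,
#'   `alt`, `group`, `n_ref`, `n_alt`, `n_missing`.
#' @export
allele_counts <- function(gm, groups, grouping = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.data.frame(groups)) {
    groups <- if (is.null(grouping)) group_samples(groups) else
      group_samples(groups, grouping)
  }
  empty <- lengths(groups) == 0
  if (any(empty)) {
    stop("group(s) with zero samples: ",
         paste(names(groups)[empty], collapse = ", "))
  }
  purrr::imap_dfr(groups, function(ids, name) {
    d <- gm$dosage[ids, , drop = FALSE]
    n_called <- colSums(!is.na(d))
    n_alt <- colSums(d, na.rm = TRUE)
    tibble(
      locus = seq_len(n_loci(gm)),
      contig = gm$loci$contig, pos = gm$loci$pos,
      ref = gm$loci$ref, alt = gm$loci$alt,
      group = name,
      n_ref = 2L * n_called - n_alt,
      n_alt = n_alt,
      n_missing = colSums(is.na(d))
    )
  })
}

# wide two-group view of an allele_counts table; columns suffixed _1/_2
counts_wide <- function(counts) {
  gs <- unique(counts$group)
  if (length(gs) != 2) stop("expected exactly two groups")
  a <- counts[counts$group == gs[1], ]
  b <- counts[counts$group == gs[2], ]
  stopifnot(identical(a$locus, b$locus))
  tibble(
    locus = a$locus, contig = a$contig, pos = a$pos, ref = a$ref, alt = a$alt,
    group_1 = gs[1], group_2 = gs[2],
    ref_1 = a$n_ref, alt_1 = a$n_alt, miss_1 = a$n_missing,
    ref_2 = b$n_ref, alt_2 = b$n_alt, miss_2 = b$n_missing
  )
}

#' Private alleles between two populations
#'
#' A position carries a nonreference private allele when the alternate
#' allele is observed (at least once) in exactly one of the two groups and
#' never in the other; reference-private positions are tracked separately
#' and excluded from the headline count, since with a reference genome drawn
#' from one population the nonreference count is the informative one. No
#' call-rate or frequency filters are applied.
#'
#' @param counts an [allele_counts()] table for two groups.
#' @return A list:
#'   \describe{
#'     \item{table}{per-locus tibble with `nonref_private`,
#'       `nonref_private_group`, `ref_private`, `ref_private_group`.}
#'     \item{summary}{tibble of nonreference-private counts per group.}
#'     \item{total_private_positions}{headline count of nonreference-private
#'       positions.}
#'     \item{fraction}{headline count over all positions.}
#'   }
#' @export
private_alleles <- function(counts) {
  w <- counts_wide(counts)
  alt_priv_1 <- w$alt_1 >= 1 & w$alt_2 == 0
  alt_priv_2 <- w$alt_2 >= 1 & w$alt_1 == 0
  ref_priv_1 <- w$ref_1 >= 1 & w$ref_2 == 0
  ref_priv_2 <- w$ref_2 >= 1 & w$ref_1 == 0
  tab <- w
  tab$nonref_private <- alt_priv_1 | alt_priv_2
  tab$nonref_private_group <- dplyr::case_when(
    alt_priv_1 ~ w$group_1[1], alt_priv_2 ~ w$group_2[1],
    TRUE ~ NA_character_
  )
  tab$ref_private <- ref_priv_1 | ref_priv_2
  tab$ref_private_group <- dplyr::case_when(
    ref_priv_1 ~ w$group_1[1], ref_priv_2 ~ w$group_2[1],
    TRUE ~ NA_character_
  )
  summary <- tibble(
    group = c(w$group_1[1], w$group_2[1]),
    n_nonref_private = c(sum(alt_priv_1), sum(alt_priv_2)),
    n_ref_private = c(sum(ref_priv_1), sum(ref_priv_2))
  )
  list(
    table = tab, summary = summary,
    total_private_positions = sum(tab$nonref_private),
    fraction = sum(tab$nonref_private) / nrow(w)
  )
}

#' Weir-Cockerham Fst between populations
#'
#' Computes the per-locus variance components of the Weir-Cockerham (1984)
#' estimator for diploid biallelic data from genotype counts: `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals, i.e. heterozygosity). Two summaries are reported: the mean of
#' per-locus ratios `a / (a + b + c)` and the "weighted" ratio of sums
#' `sum(a) / sum(a + b + c)`. Loci with a zero denominator (monomorphic) or
#' with a group lacking called genotypes are excluded from both summaries and
#' counted. Negative per-locus estimates are retained (the estimator is
#' unbiased, not range-restricted).
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of sample-id vectors (two or more), or an
#'   assignment tibble (then `grouping` applies as in [allele_counts()]).
#' @param grouping label grouping for assignment input.
#' @return An object of class `fst_result`: `per_locus` tibble (`locus`,
#'   `contig`, `pos`, `a`, `b`, `c`, `theta`), `mean_fst`, `weighted_fst`,
#'   `n_used`, `n_excluded`.
#' @export
weir_cockerham_fst <- function(gm, groups, grouping = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.data.frame(groups)) {
    groups <- if (is.null(grouping)) group_samples(groups) else
      group_samples(groups, grouping)
  }
  r <- length(groups)
  if (r < 2) stop("need at least two groups")
  L <- n_loci(gm)
  n <- p <- h <- matrix(0, r, L)
  for (g in seq_len(r)) {
    d <- gm$dosage[groups[[g]], , drop = FALSE]
    n[g, ] <- colSums(!is.na(d))
    p[g, ] <- ifelse(n[g, ] > 0, colSums(d, na.rm = TRUE) / (2 * n[g, ]), NA)
    h[g, ] <- ifelse(n[g, ] > 0, colSums(d == 1L, na.rm = TRUE) / n[g, ], NA)
  }
  usable <- colSums(n >= 1) == r
  nbar <- colMeans(n)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  usable <- usable & nbar > 1        # single diploid total cannot be decomposed
  a[!usable] <- b[!usable] <- cc[!usable] <- NA
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom > 0, a / denom, NA)
  used <- !is.na(denom) & denom > 0
  if (!any(used)) stop("no informative loci")
  structure(
    list(
      per_locus = tibble(
        locus = seq_len(L), contig = gm$loci$contig, pos = gm$loci$pos,
        a = a, b = b, c = cc, theta = theta
      ),
      mean_fst = mean(theta[used]),
      weighted_fst = sum(a[used]) / sum(denom[used]),
      n_used = sum(used),
      n_excluded = L - sum(used)
    ),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "<fst_result> mean Fst = %.3f, weighted Fst = %.3f (%d loci used, %d excluded)\n",
    x$mean_fst, x$weighted_fst, x$n_used, x$n_excluded
  ))
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_locus

#' @export
glance.fst_result <- function(x, ...) {
  tibble(
    mean_fst = x$mean_fst, weighted_fst = x$weighted_fst,
    n_used = x$n_used, n_excluded = x$n_excluded
  )
}

#' Fisher exact allele-frequency scan
#'
#' Two-sided Fisher exact test on the 2x2 table of (ref, alt) allele counts
#' by group at every locus, with Bonferroni correction over the loci actually
#' tested (both groups contribute at least one called allele). A locus is
#' significant when its corrected p-value is below `alpha`.
#'
#' @param counts an [allele_counts()] table for two groups.
#' @param alpha significance level on the corrected p-value (default 0.01).
#' @return Per-locus tibble with `tested`, `p`, `p_adj` (`min(1, p * m)`,
#'   `m` = number tested) and `significant`.
#' @export
fisher_scan <- function(counts, alpha = 0.01) {
  w <- counts_wide(counts)
  tested <- (w$ref_1 + w$alt_1) >= 1 & (w$ref_2 + w$alt_2) >= 1
  p <- rep(NA_real_, nrow(w))
  p[tested] <- vapply(which(tested), function(i) {
    fisher.test(matrix(
      c(w$ref_1[i], w$alt_1[i], w$ref_2[i], w$alt_2[i]), nrow = 2
    ))$p.value
  }, numeric(1))
  m <- sum(tested)
  dplyr::mutate(
    w[, c("locus", "contig", "pos")],
    tested = tested,
    p = p,
    p_adj = pmin(1, p * m),
    significant = !is.na(p) & .data$p_adj < alpha
  )
}

#' Fixed allele differences between two populations
#'
#' A locus is fixed when one group carries only the alternate allele and the
#' other only the reference allele among called genotypes, each group
#' contributing at least one called allele. Loci where a group is entirely
#' uncalled are untested and never fixed.
#'
#' @param counts an [allele_counts()] table for two groups.
#' @return Per-locus tibble with `tested` and `fixed`.
#' @export
fixed_differences <- function(counts) {
  w <- counts_wide(counts)
  tested <- (w$ref_1 + w$alt_1) >= 1 & (w$ref_2 + w$alt_2) >= 1
  fixed <- tested & (
    (w$alt_1 > 0 & w$ref_1 == 0 & w$alt_2 == 0 & w$ref_2 > 0) |
    (w$alt_2 > 0 & w$ref_2 == 0 & w$alt_1 == 0 & w$ref_1 > 0)
  )
  dplyr::mutate(w[, c("locus", "contig", "pos")], tested = tested, fixed = fixed)
}

#' Combined per-locus differentiation table
#'
#' One row per locus with the two-group allele counts, private-allele and
#' fixed-difference flags, and the Fisher scan columns -- the table consumed
#' by the enrichment and window-density reports.
#'
#' @inheritParams weir_cockerham_fst
#' @param alpha significance level for the Fisher scan.
#' @return Tibble, one row per locus.
#' @export
differentiation_table <- function(gm, groups, grouping = NULL, alpha = 0.01) {
  if (is.data.frame(groups)) {
    groups <- if (is.null(grouping)) group_samples(groups) else
      group_samples(groups, grouping)
  }
  counts <- allele_counts(gm, groups)
  priv <- private_alleles(counts)
  fis <- fisher_scan(counts, alpha)
  fix <- fixed_differences(counts)
  priv$table |>
    dplyr::left_join(
      fis[, c("locus", "tested", "p", "p_adj", "significant")], by = "locus"
    ) |>
    dplyr::left_join(fix[, c("locus", "fixed")], by = "locus")
}
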