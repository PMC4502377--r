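#' Loci segregating completely between two populations
#'
#' A locus qualifies when every called genotype in the first group is
#' homozygous for one allele and every called genotype in the second group is
#' homozygous for the other allele; a heterozygote anywhere disqualifies the
#' locus, and both groups must have at least one called genotype.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of two sample-id vectors, or an assignment
#'   tibble (then `grouping` applies as in [allele_counts()]).
#' @param grouping label grouping for assignment input.
#' @return Tibble of qualifying loci: `locus`, `contig`, `pos`, and the
#'   fixed base carried by each group (`allele_1`, `allele_2`, named after
#'   the groups in `group_1`/`group_2`).
#' @export
region_segregating <- function(gm, groups, grouping = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.data.frame(groups)) {
    groups <- if (is.null(grouping)) group_samples(groups) else
      group_samples(groups, grouping)
  }
  stopifnot(length(groups) == 2)
  d1 <- gm$dosage[groups[[1]], , drop = FALSE]
  d2 <- gm$dosage[groups[[2]], , drop = FALSE]
  mono_state <- function(d) {
    # per locus: 0 or 2 if all called genotypes are that homozygote, else NA
    n_called <- colSums(!is.na(d))
    any_het <- colSums(d == 1L, na.rm = TRUE) > 0
    all0 <- colSums(d == 0L, na.rm = TRUE) == n_called & n_called > 0
    all2 <- colSums(d == 2L, na.rm = TRUE) == n_called & n_called > 0
    out <- rep(NA_integer_, ncol(d))
    out[all0 & !any_het] <- 0L
    out[all2 & !any_het] <- 2L
    out
  }
  s1 <- mono_state(d1)
  s2 <- mono_state(d2)
  qual <- !is.na(s1) & !is.na(s2) & s1 != s2
  base_of <- function(state, loci) ifelse(state == 0L, loci$ref, loci$alt)
  out <- tibble(
    locus = which(qual),
    contig = gm$loci$contig[qual],
    pos = gm$loci$pos[qual],
    group_1 = names(groups)[1],
    group_2 = names(groups)[2],
    allele_1 = base_of(s1[qual], gm$loci[qual, ]),
    allele_2 = base_of(s2[qual], gm$loci[qual, ])
  )
  out
}

#' Polarize region-segregating SNPs against an outgroup genome
#'
#' Classifies each completely segregating locus by which population deviates
#' from the ancestral (outgroup) allele: `deviated_2` when group 1 carries
#' the ancestral base and group 2 the derived one (and symmetrically
#' `deviated_1`), `both_deviated` when the ancestral base matches neither
#' group, and `unaligned` when no ancestral allele is available. With groups
#' named west/east, an east-deviated SNP is one where the western cultivars
#' kept the outgroup allele.
#'
#' @param seg a [region_segregating()] table.
#' @param ancestral data frame with `contig`, `pos`, `allele` (a base or
#'   `"unaligned"`).
#' @return A list:
#'   \describe{
#'     \item{records}{per-locus tibble with a `class` column in
#'       `<group_1>_deviated` / `<group_2>_deviated` / `both_deviated` /
#'       `unaligned`, using the group names carried by `seg`.}
#'     \item{by_scaffold}{per-contig summary: `n_seg`, class counts
#'       (`n_deviated_1` for group 1, `n_deviated_2` for group 2, `n_both`,
#'       `n_unaligned`), and integer percentages rounded half away from
#'       zero.}
#'   }
#' @export
classify_polarization <- function(seg, ancestral) {
  ancestral <- as_tibble(ancestral)
  stopifnot(all(c("contig", "pos", "allele") %in% names(ancestral)))
  if (nrow(seg) == 0) stop("no region-segregating loci to classify")
  g1 <- seg$group_1[1]; g2 <- seg$group_2[1]
  dev1 <- paste0(g1, "_deviated"); dev2 <- paste0(g2, "_deviated")
  rec <- seg |>
    dplyr::left_join(ancestral, by = c("contig", "pos")) |>
    dplyr::mutate(
      allele = ifelse(is.na(.data$allele), "unaligned", .data$allele),
      class = dplyr::case_when(
        .data$allele == "unaligned" ~ "unaligned",
        .data$allele == .data$allele_1 & .data$allele != .data$allele_2 ~ dev2,
        .data$allele == .data$allele_2 & .data$allele != .data$allele_1 ~ dev1,
        TRUE ~ "both_deviated"
      )
    )
  by_scaffold <- rec |>
    dplyr::group_by(scaffold = .data$contig) |>
    dplyr::summarise(
      n_seg = dplyr::n(),
      n_deviated_1 = sum(.data$class == dev1),
      n_deviated_2 = sum(.data$class == dev2),
      n_both = sum(.data$class == "both_deviated"),
      n_unaligned = sum(.data$class == "unaligned"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_deviated_1 = round_half_up(100 * .data$n_deviated_1 / .data$n_seg),
      pct_deviated_2 = round_half_up(100 * .data$n_deviated_2 / .data$n_seg),
      pct_both = round_half_up(100 * .data$n_both / .data$n_seg),
      pct_unaligned = round_half_up(100 * .data$n_unaligned / .data$n_seg)
    )
  list(records = rec, by_scaffold = by_scaffold)
}
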