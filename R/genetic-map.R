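#' Genetic map with artificial-chromosome offsets
#'
#' Validates a genetic map (linkage group, contig, order within the group,
#' contig length) and derives each contig's artificial-chromosome offset:
#' the cumulative length of the contigs preceding it in its linkage group.
#' Concatenating contigs in map order gives unanchored assemblies map-scale
#' coordinates for density and enrichment plots.
#'
#' @param df data frame with columns `lg`, `contig`, `order`, `length`.
#' @return Tibble of class `genetic_map` sorted by (`lg`, `order`) with an
#'   added `offset` column, strictly increasing within each linkage group.
#' @export
genetic_map <- function(df) {
  df <- as_tibble(df)
  need <- c("lg", "contig", "order", "length")
  if (!all(need %in% names(df))) {
    stop("genetic map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$contig)) {
    stop("duplicate contig(s) in map: ",
         paste(unique(df$contig[duplicated(df$contig)]), collapse = ", "))
  }
  if (anyDuplicated(df[, c("lg", "order")])) stop("(lg, order) pairs must be unique")
  if (any(df$length <= 0)) stop("contig lengths must be positive")
  df <- df |>
    dplyr::arrange(.data$lg, .data$order) |>
    dplyr::group_by(.data$lg) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$length, default = 0))) |>
    dplyr::ungroup()
  class(df) <- c("genetic_map", class(df))
  df
}

#' Artificial-chromosome coordinates for loci
#'
#' Maps each `contig:pos` locus to its linkage group and artificial position
#' `offset(contig) + pos`. Loci on contigs absent from the map are routed to
#' the `"unmapped"` bucket with `NA` position.
#'
#' @param loci data frame with `contig` and `pos` columns (e.g. `gm$loci` or
#'   a differentiation table).
#' @param map a [genetic_map()].
#' @return The input with `lg` and `art_pos` columns added.
#' @export
artificial_coordinates <- function(loci, map) {
  stopifnot(inherits(map, "genetic_map"))
  loci <- as_tibble(loci)
  i <- match(loci$contig, map$contig)
  loci |>
    dplyr::mutate(
      lg = ifelse(is.na(i), "unmapped", map$lg[i]),
      art_pos = map$offset[i] + loci$pos
    )
}

#' Per-linkage-group enrichment of flagged SNPs
#'
#' For each linkage group, counts total loci and loci with a per-locus flag
#' set (significant, private, or fixed), and reports the fold change of the
#' group's proportion over the genome-wide proportion. A fold near 3 means
#' the group carries roughly three times its expected share.
#'
#' @param table per-locus tibble with `contig`, `pos` and the flag column
#'   (e.g. from [differentiation_table()]).
#' @param map a [genetic_map()].
#' @param flag name of the logical flag column (default `"significant"`).
#' @return Tibble: `lg`, `n_snps`, `n_flagged`, `proportion`, `fold`.
#' @export
lg_enrichment <- function(table, map, flag = "significant") {
  stopifnot(flag %in% names(table))
  tab <- artificial_coordinates(table, map)
  genome_prop <- sum(tab[[flag]], na.rm = TRUE) / nrow(tab)
  tab |>
    dplyr::group_by(.data$lg) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      n_flagged = sum(.data[[flag]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      proportion = .data$n_flagged / .data$n_snps,
      fold = if (genome_prop > 0) .data$proportion / genome_prop else 0
    ) |>
    dplyr::arrange(.data$lg)
}

#' Windowed density of flagged SNPs on artificial chromosomes
#'
#' Bins loci into half-open windows `[start, start + window_bp)` on
#' artificial coordinates and counts, per window, total SNPs and any of the
#' standard flags present in the table (`nonref_private`, `fixed`,
#' `significant`). Unmapped loci are excluded.
#'
#' @param table per-locus tibble with `contig` and `pos` plus flag columns.
#' @param map a [genetic_map()].
#' @param window_bp window width in base pairs (> 0).
#' @return Tibble: `lg`, `window_start`, `n_snps`, and one `n_<flag>` column
#'   per flag found.
#' @export
window_density <- function(table, map, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be positive")
  tab <- artificial_coordinates(table, map) |>
    dplyr::filter(.data$lg != "unmapped")
  flags <- intersect(c("nonref_private", "fixed", "significant"), names(tab))
  tab |>
    dplyr::mutate(window_start = floor(.data$art_pos / window_bp) * window_bp) |>
    dplyr::group_by(.data$lg, .data$window_start) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      dplyr::across(dplyr::all_of(flags), ~ sum(.x, na.rm = TRUE), .names = "n_{.col}"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lg, .data$window_start)
}

#' Drop all loci on one linkage group
#'
#' Removes every locus whose contig the map assigns to `lg_id`, enabling
#' re-analysis with a linkage group excluded (e.g. the group carrying the
#' sex-determination region, whose elevated differentiation can dominate
#' structure inference).
#'
#' @param gm a [genotype_matrix()].
#' @param map a [genetic_map()].
#' @param lg_id linkage group identifier present in the map.
#' @return A [genotype_matrix()] without the excluded loci.
#' @export
exclude_lg <- function(gm, map, lg_id) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(map, "genetic_map"))
  if (!lg_id %in% map$lg) stop("unknown linkage group: ", lg_id)
  contigs <- map$contig[map$lg == lg_id]
  gm_subset(gm, loci = !(gm$loci$contig %in% contigs))
}
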