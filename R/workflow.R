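#' Pipeline configuration
#'
#' Collects every stage setting with the survey defaults: PL margin 35,
#' 10x coverage in 80% of samples, alternate allele seen at least 4 times,
#' per-analysis missingness caps (10 for tree export, 8 for structure
#' inference, 15 for cultivar-only allelic scans), K swept 2-7 with 4
#' replicates of 5000 burn-in + 25000 retained sweeps, 75% purity
#' assignment, and a 0.01 corrected-p cutoff for the Fisher scan. Desk-scale
#' runs override `k_range`, `replicates`, `burn_in` and `n_reps` downward.
#'
#' @param sim a [sim_config()] describing the synthetic input (used when no
#'   VCF path is supplied).
#' @param vcf,sample_sheet,map,ancestral optional input file paths (VCF and
#'   three TSVs); when `vcf` is `NULL` the pipeline simulates its input from
#'   `sim`.
#' @param pl_min,min_depth,min_fraction,min_alt_obs quality-filter settings.
#' @param max_missing named numeric vector of per-analysis missingness caps
#'   (`tree`, `structure`, `allelic`).
#' @param k_range,replicates,burn_in,n_reps admixture sweep settings.
#' @param purity assignment purity threshold.
#' @param alpha Fisher-scan significance level on corrected p.
#' @param seed master seed for every random stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            vcf = NULL, sample_sheet = NULL, map = NULL,
                            ancestral = NULL,
                            pl_min = 35, min_depth = 10, min_fraction = 0.8,
                            min_alt_obs = 4,
                            max_missing = c(tree = 10, structure = 8, allelic = 15),
                            k_range = 2:7, replicates = 4,
                            burn_in = 5000, n_reps = 25000,
                            purity = 0.75, alpha = 0.01, seed = 42) {
  stopifnot(all(c("tree", "structure", "allelic") %in% names(max_missing)))
  if (purity <= 0.5 || purity > 1) stop("purity must lie in (0.5, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Rename inferred clusters by claimed region
#'
#' Cluster labels out of the admixture model are arbitrary (`pop_1`,
#' `pop_2`, ...). This maps each cluster to the majority claimed region of
#' its assigned cultivar samples (e.g. `west` / `east`), leaving `Mixed`
#' untouched, so that downstream groupings can be stated in region terms.
#'
#' @param assignment tibble from [assign_populations()].
#' @param sample_sheet tibble with `sample`, `region`, `species`.
#' @return `assignment` with `label` renamed where a majority exists.
#' @export
rename_clusters_by_region <- function(assignment, sample_sheet) {
  info <- dplyr::left_join(assignment, as_tibble(sample_sheet), by = "sample")
  lut <- info |>
    dplyr::filter(startsWith(.data$label, "pop_"),
                  .data$region %in% c("West", "East")) |>
    dplyr::count(.data$label, .data$region) |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  new <- setNames(tolower(lut$region), lut$label)
  assignment |>
    dplyr::mutate(label = dplyr::coalesce(new[.data$label], .data$label))
}

stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  message("[palmpop] stage: ", name)
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.null(log_con)) {
    writeLines(sprintf(
      "%s\t%.2fs", name, as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ), log_con)
  }
  out
}

write_tsv0 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> quality filters -> admixture sweep
#' with Evanno model choice and replicate alignment -> purity assignment ->
#' ordination -> differentiation statistics -> polarization -> alignment
#' export, writing every stage's tables plus a machine-readable summary into
#' `out_dir`. The summary (`summary.json`, `summary.txt`) is a pure function
#' of the config, so identical seeds give byte-identical summaries; stage
#' timings go to `log.txt` only.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "log.txt"), "w")
  on.exit(close(log_con))
  writeLines(sprintf("palmpop %s\tseed %d",
                     as.character(utils::packageVersion("palmpop")), cfg$seed),
             log_con)
  summary <- list(seed = cfg$seed)

  ## inputs
  inp <- stage("input", log_con, {
    if (is.null(cfg$vcf)) {
      sim <- simulate_dataset(cfg$sim)
      list(gm = sim$gm, sheet = sim$sample_sheet, map = sim$map,
           ancestral = sim$ancestral)
    } else {
      list(
        gm = read_vcf(cfg$vcf),
        sheet = as_tibble(utils::read.delim(cfg$sample_sheet)),
        map = genetic_map(utils::read.delim(cfg$map)),
        ancestral = as_tibble(utils::read.delim(cfg$ancestral))
      )
    }
  })
  summary$n_samples <- n_samples(inp$gm)
  summary$n_raw_loci <- n_loci(inp$gm)

  ## quality filters (shared part), then per-analysis missingness caps
  filt <- stage("filter", log_con, {
    filter_genotypes(inp$gm, cfg$pl_min, cfg$min_depth, cfg$min_fraction,
                     cfg$min_alt_obs)
  })
  write_tsv0(filt$report, file.path(out_dir, "filter_report.tsv"))
  summary$filter <- as.list(setNames(filt$report$n_removed, filt$report$rule))
  summary$n_filtered_loci <- n_loci(filt$gm)

  cultivars <- inp$sheet$sample[inp$sheet$species == "P_dactylifera" &
                                  is.na(inp$sheet$duplicate_of)]
  gm_structure <- filter_max_missing(filt$gm, cfg$max_missing[["structure"]])$gm
  gm_allelic0 <- gm_subset(filt$gm, samples = cultivars)
  gm_allelic <- filter_max_missing(gm_allelic0, cfg$max_missing[["allelic"]])$gm
  summary$n_structure_loci <- n_loci(gm_structure)
  summary$n_allelic_loci <- n_loci(gm_allelic)
  write_vcf(filt$gm, file.path(out_dir, "filtered.vcf"))

  ## admixture sweep, model choice, replicate alignment, assignment
  adm <- stage("structure", log_con, {
    runs <- fit_admixture_replicates(
      gm_structure, cfg$k_range, cfg$replicates,
      burn_in = cfg$burn_in, n_reps = cfg$n_reps, seed = cfg$seed
    )
    ev <- evanno_delta_k(runs)
    best <- ev$best_k
    aln <- align_runs(Filter(function(r) r$K == best, runs))
    list(runs = runs, evanno = ev, alignment = aln)
  })
  write_tsv0(adm$evanno$table, file.path(out_dir, "evanno.tsv"))
  write_tsv0(tidy(adm$alignment), file.path(out_dir, "consensus_q.tsv"))
  summary$best_k <- adm$evanno$best_k
  summary$h_prime <- adm$alignment$h_prime

  assignment <- stage("assign", log_con, {
    assign_populations(adm$alignment, cfg$purity) |>
      rename_clusters_by_region(inp$sheet)
  })
  write_tsv0(assignment, file.path(out_dir, "assignments.tsv"))
  summary$assignment <- as.list(table(
    assignment$label[assignment$sample %in% cultivars]
  ))

  ## ordination
  pca <- stage("pca", log_con, pca_genotypes(gm_structure))
  write_tsv0(pca$scores, file.path(out_dir, "pca_scores.tsv"))
  write_tsv0(pca$variance, file.path(out_dir, "pca_variance.tsv"))
  summary$pca_variance <- pca$variance$variance_fraction[1:2]

  ## differentiation (cultivars only)
  cult_assign <- assignment[assignment$sample %in% cultivars, ]
  diff <- stage("differentiate", log_con, {
    groups_wm <- group_samples(
      cult_assign, list(west = c("west", "Mixed"), east = "east")
    )
    tab <- differentiation_table(gm_allelic, groups_wm, alpha = cfg$alpha)
    fst_wm <- weir_cockerham_fst(gm_allelic, groups_wm)
    groups_we <- group_samples(
      cult_assign, list(west = "west", east = "east")
    )
    fst_we <- weir_cockerham_fst(gm_allelic, groups_we)
    enr <- lg_enrichment(tab, inp$map, flag = "significant")
    wins <- window_density(tab, inp$map, window_bp = 1e6)
    list(table = tab, fst_wm = fst_wm, fst_we = fst_we,
         enrichment = enr, windows = wins, groups_we = groups_we)
  })
  write_tsv0(diff$table, file.path(out_dir, "differentiation.tsv"))
  write_tsv0(diff$enrichment, file.path(out_dir, "lg_enrichment.tsv"))
  write_tsv0(diff$windows, file.path(out_dir, "window_density.tsv"))
  n_all <- nrow(diff$table)
  n_priv <- sum(diff$table$nonref_private)
  n_sig <- sum(diff$table$significant, na.rm = TRUE)
  n_fixed <- sum(diff$table$fixed, na.rm = TRUE)
  summary$differentiation <- list(
    n_positions = n_all,
    n_nonref_private = n_priv, pct_nonref_private = 100 * n_priv / n_all,
    n_significant = n_sig, pct_significant = 100 * n_sig / n_all,
    n_fixed = n_fixed,
    fst_west_mixed_vs_east = list(mean = diff$fst_wm$mean_fst,
                                  weighted = diff$fst_wm$weighted_fst),
    fst_west_vs_east = list(mean = diff$fst_we$mean_fst,
                            weighted = diff$fst_we$weighted_fst)
  )

  ## duplicates
  dup_pairs <- inp$sheet[!is.na(inp$sheet$duplicate_of),
                         c("sample", "duplicate_of")]
  if (nrow(dup_pairs)) {
    dup <- stage("duplicates", log_con, duplicate_concordance(filt$gm, dup_pairs))
    write_tsv0(dup, file.path(out_dir, "duplicates.tsv"))
    summary$duplicate_predicted_accuracy <-
      mean(dup$predicted_accuracy, na.rm = TRUE)
  }

  ## polarization of strictly segregating SNPs
  pol <- stage("polarize", log_con, {
    seg <- region_segregating(gm_allelic, diff$groups_we)
    if (nrow(seg) == 0) NULL else classify_polarization(seg, inp$ancestral)
  })
  if (!is.null(pol)) {
    write_tsv0(pol$records, file.path(out_dir, "polarization.tsv"))
    write_tsv0(pol$by_scaffold, file.path(out_dir, "polarization_by_scaffold.tsv"))
    cls <- table(factor(pol$records$class,
                        c("west_deviated", "east_deviated", "both_deviated",
                          "unaligned")))
    summary$polarization <- c(list(n_seg = nrow(pol$records)), as.list(cls))
  }

  ## alignment export (tree set: all samples, tree missingness cap)
  stage("export", log_con, {
    gm_tree <- filter_max_missing(filt$gm, cfg$max_missing[["tree"]])$gm
    summary$n_tree_loci <- n_loci(gm_tree)
    if (n_loci(gm_tree) > 0) {
      aln <- export_alignment(gm_tree, mode = "homozygous")
      write_alignment(aln, file.path(out_dir, "alignment.fasta"), "fasta")
      write_alignment(aln, file.path(out_dir, "alignment.phy"), "phylip")
      d <- pairwise_distances(aln)
      write_tsv0(as.data.frame(d) |> tibble::rownames_to_column("sample"),
                 file.path(out_dir, "distances.tsv"))
    }
    NULL
  })

  ## machine-readable and formatted summaries
  stage("summarize", log_con, {
    jsonlite::write_json(
      summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE
    )
    writeLines(format_summary(summary), file.path(out_dir, "summary.txt"))
    NULL
  })
  invisible(summary)
}

#' Format a pipeline summary in report style
#'
#' Counts carry thousands separators; percentages print with one decimal
#' below 10% and as integers otherwise, rounded half away from zero.
#'
#' @param s summary list from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
format_summary <- function(s) {
  lines <- c(
    sprintf("samples: %d; raw loci: %s; after filters: %s",
            s$n_samples, fmt_count(s$n_raw_loci), fmt_count(s$n_filtered_loci)),
    sprintf("structure set: %s SNPs; allelic set: %s SNPs; tree set: %s SNPs",
            fmt_count(s$n_structure_loci), fmt_count(s$n_allelic_loci),
            fmt_count(s$n_tree_loci)),
    sprintf("best K = %d (H' = %.2f)", s$best_k, s$h_prime)
  )
  d <- s$differentiation
  if (!is.null(d)) {
    lines <- c(
      lines,
      sprintf("nonreference private alleles: %s of %s",
              fmt_count_pct(d$n_nonref_private, d$n_positions),
              fmt_count(d$n_positions)),
      sprintf("significantly segregating SNPs: %s",
              fmt_count_pct(d$n_significant, d$n_positions)),
      sprintf("fixed differences: %s", fmt_count(d$n_fixed)),
      sprintf("Fst west+mixed vs east: mean %.3f, weighted %.3f",
              d$fst_west_mixed_vs_east$mean, d$fst_west_mixed_vs_east$weighted),
      sprintf("Fst west vs east: mean %.3f, weighted %.3f",
              d$fst_west_vs_east$mean, d$fst_west_vs_east$weighted)
    )
  }
  if (!is.null(s$duplicate_predicted_accuracy)) {
    lines <- c(lines, sprintf("duplicate predicted accuracy: %.1f%%",
                              100 * s$duplicate_predicted_accuracy))
  }
  p <- s$polarization
  if (!is.null(p)) {
    lines <- c(lines, sprintf(
      "segregating SNPs: %d (east-deviated %s, west-deviated %s, both %s, unaligned %s)",
      p$n_seg,
      fmt_pct(p$east_deviated, p$n_seg), fmt_pct(p$west_deviated, p$n_seg),
      fmt_pct(p$both_deviated, p$n_seg), fmt_pct(p$unaligned, p$n_seg)
    ))
  }
  lines
}
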