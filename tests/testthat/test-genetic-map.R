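toy_map <- function() {
  genetic_map(tibble::tibble(
    lg = c("LG1", "LG1", "LG2"),
    contig = c("c1", "c2", "c3"),
    order = c(1L, 2L, 1L),
    length = c(100L, 200L, 150L)
  ))
}

test_that("artificial chromosomes concatenate contigs in map order", {
  map <- toy_map()
  expect_equal(map$offset, c(0, 100, 0))
  loci <- tibble::tibble(contig = c("c2", "c1", "c9"), pos = c(50L, 1L, 10L))
  got <- artificial_coordinates(loci, map)
  expect_equal(got$art_pos, c(150, 1, NA))    # offset(c2) + 50 = 100 + 50
  expect_equal(got$lg, c("LG1", "LG1", "unmapped"))
  expect_error(
    genetic_map(tibble::tibble(lg = "LG1", contig = c("c1", "c1"),
                               order = 1:2, length = c(10L, 20L))),
    "duplicate"
  )
})

test_that("linkage-group enrichment reproduces the fold arithmetic", {
  # genome: 1000 SNPs, 50 significant; LG1 has 100 SNPs with 15 significant
  map <- genetic_map(tibble::tibble(
    lg = c("LG1", "LG2"), contig = c("c1", "c2"), order = c(1L, 1L),
    length = c(2e6L, 2e6L)
  ))
  tab <- tibble::tibble(
    contig = rep(c("c1", "c2"), c(100, 900)),
    pos = c(seq_len(100), seq_len(900)),
    significant = c(rep(TRUE, 15), rep(FALSE, 85),
                    rep(TRUE, 35), rep(FALSE, 865))
  )
  enr <- lg_enrichment(tab, map)
  expect_equal(enr$fold[enr$lg == "LG1"], (15 / 100) / (50 / 1000))  # 3.0
  expect_equal(enr$fold[enr$lg == "LG1"], 3.0)
  # an LG with no significant SNPs has fold 0
  tab0 <- dplyr::mutate(tab, significant = ifelse(contig == "c2", FALSE, significant))
  enr0 <- lg_enrichment(tab0, map)
  expect_equal(enr0$fold[enr0$lg == "LG2"], 0)
})

test_that("window counts conserve per-LG totals", {
  map <- toy_map()
  withr::with_seed(19, {
    tab <- tibble::tibble(
      contig = sample(c("c1", "c2", "c3"), 200, replace = TRUE),
      significant = runif(200) < 0.2,
      fixed = runif(200) < 0.1
    )
    tab$pos <- as.integer(ceiling(runif(200) *
      c(c1 = 100, c2 = 200, c3 = 150)[tab$contig]))
  })
  wins <- window_density(tab, map, window_bp = 40)
  per_lg <- artificial_coordinates(tab, map) |>
    dplyr::group_by(lg) |>
    dplyr::summarise(n = dplyr::n(), sig = sum(significant), fx = sum(fixed))
  agg <- wins |>
    dplyr::group_by(lg) |>
    dplyr::summarise(n = sum(n_snps), sig = sum(n_significant), fx = sum(n_fixed))
  expect_equal(as.data.frame(agg), as.data.frame(per_lg))
  expect_error(window_density(tab, map, window_bp = 0), "positive")
})

test_that("excluding a linkage group removes exactly its loci", {
  sim <- simulate_dataset(sim_config(n_loci = 200, seed = 23))
  lg <- sim$map$lg[1]
  contigs <- sim$map$contig[sim$map$lg == lg]
  k <- sum(sim$gm$loci$contig %in% contigs)
  gm2 <- exclude_lg(sim$gm, sim$map, lg)
  expect_equal(n_loci(gm2), n_loci(sim$gm) - k)
  expect_false(any(gm2$loci$contig %in% contigs))
  expect_error(exclude_lg(sim$gm, sim$map, "LG99"), "unknown")
  # an excluded matrix still feeds the admixture model
  run <- fit_admixture(gm_subset(gm2, loci = 1:30), 2,
                       burn_in = 50, n_reps = 100, seed = 1)
  expect_true(all(is.finite(run$lnl)))
})

test_that("a linkage group absent from the data leaves the matrix unchanged", {
  sim <- simulate_dataset(sim_config(n_loci = 50, n_contigs = 30, n_lg = 10, seed = 29))
  # build a map with an extra LG that owns no loci
  map2 <- genetic_map(dplyr::bind_rows(
    sim$map[, c("lg", "contig", "order", "length")],
    tibble::tibble(lg = "LG_extra", contig = "c_extra", order = 1L, length = 1000L)
  ))
  gm2 <- exclude_lg(sim$gm, map2, "LG_extra")
  expect_equal(n_loci(gm2), n_loci(sim$gm))
})
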