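two_groups <- function(gm, n1) {
  list(g1 = gm$samples[seq_len(n1)], g2 = gm$samples[-seq_len(n1)])
}

test_that("allele counts treat the two alleles of a het independently", {
  d <- rbind(c(1L), c(2L), c(0L), c(NA))
  gm <- make_gm(d)
  counts <- allele_counts(gm, list(a = c("s01", "s02"), b = c("s03", "s04")))
  a <- counts[counts$group == "a", ]
  b <- counts[counts$group == "b", ]
  expect_equal(c(a$n_ref, a$n_alt), c(1L, 3L))   # het + hom-alt
  expect_equal(c(b$n_ref, b$n_alt, b$n_missing), c(2L, 0L, 1L))
  # all-missing group at a locus: zero alleles, all missing
  d2 <- rbind(c(1L), c(NA), c(NA))
  c2 <- allele_counts(make_gm(d2), list(a = "s01", b = c("s02", "s03")))
  bb <- c2[c2$group == "b", ]
  expect_equal(c(bb$n_ref, bb$n_alt, bb$n_missing), c(0L, 0L, 2L))
  expect_error(
    allele_counts(gm, list(a = character(0), b = "s01")), "zero samples"
  )
})

test_that("allele counts match a brute-force tally on random fixtures", {
  gm <- random_gm(20, 100, miss = 0.2, seed = 41)
  grp <- two_groups(gm, 8)
  counts <- allele_counts(gm, grp)
  for (g in c("g1", "g2")) {
    idx <- grp[[g]]
    sub <- counts[counts$group == g, ]
    for (l in c(1, 17, 58, 100)) {
      gvec <- gm$dosage[idx, l]; gvec <- gvec[!is.na(gvec)]
      expect_equal(sub$n_alt[l], sum(gvec))
      expect_equal(sub$n_ref[l], sum(2L - gvec))
      expect_equal(sub$n_ref[l] + sub$n_alt[l], 2L * length(gvec))
    }
  }
})

test_that("private alleles follow the exclusivity definition", {
  # locus 1: alt only in group a; locus 2: alt in both, ref only in b;
  # locus 3: both alleles in both groups
  d <- rbind(
    c(1L, 2L, 1L), c(0L, 2L, 1L),   # group a
    c(0L, 1L, 1L), c(0L, 2L, 0L)    # group b
  )
  counts <- allele_counts(make_gm(d), two_groups(make_gm(d), 2))
  priv <- private_alleles(counts)
  expect_equal(priv$table$nonref_private, c(TRUE, FALSE, FALSE))
  expect_equal(priv$table$nonref_private_group[1], "g1")
  expect_equal(priv$table$ref_private, c(FALSE, TRUE, FALSE))
  expect_equal(priv$table$ref_private_group[2], "g2")
  expect_equal(priv$total_private_positions, 1L)
  expect_equal(priv$fraction, 1 / 3)
  # per-group nonreference counts sum to the headline total
  expect_equal(sum(priv$summary$n_nonref_private), priv$total_private_positions)
})

test_that("Weir-Cockerham components are exact for an oppositely fixed locus", {
  d <- rbind(c(0L), c(0L), c(2L), c(2L))   # {AA, AA} vs {aa, aa}
  fst <- weir_cockerham_fst(make_gm(d), two_groups(make_gm(d), 2))
  expect_equal(fst$per_locus$a, 0.5)
  expect_equal(fst$per_locus$b, 0)
  expect_equal(fst$per_locus$c, 0)
  expect_equal(fst$per_locus$theta, 1.0)
  expect_equal(fst$mean_fst, 1.0)
  expect_equal(fst$weighted_fst, 1.0)
})

test_that("monomorphic loci are excluded and degenerate inputs refused", {
  d <- cbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 0L, 0L))
  gm <- make_gm(d)
  fst <- weir_cockerham_fst(gm, two_groups(gm, 2))
  expect_equal(fst$n_used, 1L)
  expect_equal(fst$n_excluded, 1L)
  mono <- make_gm(cbind(c(0L, 0L, 0L, 0L)))
  expect_error(weir_cockerham_fst(mono, two_groups(mono, 2)), "no informative")
})

test_that("per-locus components match the textbook oracle to 1e-12", {
  gm <- random_gm(30, 150, miss = 0.15, seed = 43)
  grp <- two_groups(gm, 12)
  fst <- weir_cockerham_fst(gm, grp)
  oracle <- wc_oracle_matrix(
    gm$dosage, match(grp$g1, gm$samples), match(grp$g2, gm$samples)
  )
  expect_equal(fst$per_locus$a, unname(oracle[, "a"]), tolerance = 1e-12)
  expect_equal(fst$per_locus$b, unname(oracle[, "b"]), tolerance = 1e-12)
  expect_equal(fst$per_locus$c, unname(oracle[, "c"]), tolerance = 1e-12)
  # a single informative locus makes the two summaries coincide
  one <- gm_subset(gm, loci = which(!is.na(fst$per_locus$theta))[1])
  f1 <- weir_cockerham_fst(one, grp)
  expect_equal(f1$mean_fst, f1$weighted_fst)
})

test_that("estimated divergence rises with simulated divergence", {
  est <- vapply(c(0.05, 0.2, 0.4), function(f) {
    sim <- simulate_dataset(sim_config(
      n_loci = 400, n_per_pop = c(west = 25, east = 25), n_admixed = 0,
      n_outgroup = 1, n_duplicates = 0, private_rate = 0, fst_true = f,
      missing_rate = 0, seed = 47
    ))
    grp <- list(
      west = sim$sample_sheet$sample[sim$sample_sheet$region == "West"],
      east = sim$sample_sheet$sample[sim$sample_sheet$region == "East"]
    )
    weir_cockerham_fst(sim$gm, grp)$weighted_fst
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("Fisher scan matches enumeration and applies Bonferroni over tested loci", {
  # identical counts in both groups: p = 1
  d <- rbind(c(1L, 2L), c(0L, 0L), c(1L, 2L), c(0L, 0L))
  gm <- make_gm(d)
  fs <- fisher_scan(allele_counts(gm, two_groups(gm, 2)))
  expect_equal(fs$p, c(1, 1))
  # [[10, 0], [0, 10]]: p = 2 / choose(20, 10)
  d2 <- cbind(rep(c(2L, 0L), each = 5))
  gm2 <- make_gm(d2)
  fs2 <- fisher_scan(allele_counts(gm2, two_groups(gm2, 5)))
  expect_equal(fs2$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(fs2$p_adj, fs2$p)   # m = 1: Bonferroni is the identity
  # untestable loci (one group uncalled) are excluded from m
  d3 <- cbind(c(2L, 2L, NA, NA), c(2L, 0L, 0L, 0L))
  gm3 <- make_gm(d3)
  fs3 <- fisher_scan(allele_counts(gm3, two_groups(gm3, 2)))
  expect_false(fs3$tested[1])
  expect_true(is.na(fs3$p[1]))
  expect_equal(fs3$p_adj[2], min(1, fs3$p[2] * 1))
})

test_that("fixed differences require opposite monomorphism among called alleles", {
  d <- cbind(
    c(2L, 2L, 0L, 0L),   # fixed
    c(2L, 1L, 0L, 0L),   # het in group 1: not fixed
    c(2L, 2L, NA, NA)    # group 2 uncalled: untested
  )
  gm <- make_gm(d)
  fx <- fixed_differences(allele_counts(gm, two_groups(gm, 2)))
  expect_equal(fx$fixed, c(TRUE, FALSE, FALSE))
  expect_equal(fx$tested, c(TRUE, TRUE, FALSE))
})

test_that("fixed implies private implies minimal Fisher p at fixed margins", {
  gm <- random_gm(16, 120, miss = 0.2, seed = 45)
  grp <- two_groups(gm, 7)
  counts <- allele_counts(gm, grp)
  priv <- private_alleles(counts)$table
  fx <- fixed_differences(counts)
  fs <- fisher_scan(counts)
  fixed_idx <- which(fx$fixed)
  expect_true(all(priv$nonref_private[fixed_idx] | priv$ref_private[fixed_idx]))
  # a fixed table attains the smallest two-sided p among tables sharing its margins
  for (l in head(fixed_idx, 3)) {
    w <- priv[priv$locus == l, ]
    tab <- matrix(c(w$ref_1, w$alt_1, w$ref_2, w$alt_2), 2)
    margins_min <- min(vapply(0:sum(tab[, 1]), function(x) {
      m <- sum(tab[, 1]); k <- sum(tab[1, ])
      if (x > k || (m - x) > sum(tab[2, ])) return(Inf)
      fisher_enum_oracle(matrix(c(x, m - x, k - x, sum(tab[2, ]) - (m - x)), 2))
    }, numeric(1)))
    expect_equal(fs$p[l], margins_min, tolerance = 1e-9)
  }
})

test_that("private and segregating scans agree with brute force on random fixtures", {
  for (s in 1:10) {
    gm <- random_gm(30, 200, miss = 0.15, seed = 100 + s)
    grp <- two_groups(gm, 13)
    idx1 <- match(grp$g1, gm$samples); idx2 <- match(grp$g2, gm$samples)
    counts <- allele_counts(gm, grp)
    priv <- private_alleles(counts)$table
    want <- brute_private(gm$dosage, idx1, idx2)
    expect_equal(priv$nonref_private,
                 unname(want[, "alt_private_1"] | want[, "alt_private_2"]))
    expect_equal(priv$ref_private,
                 unname(want[, "ref_private_1"] | want[, "ref_private_2"]))
    seg <- region_segregating(gm, grp)
    expect_equal(seg$locus, which(brute_segregating(gm$dosage, idx1, idx2)))
  }
})
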