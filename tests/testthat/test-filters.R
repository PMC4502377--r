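test_that("PL-margin masking uses the second-smallest PL with a strict boundary", {
  dosage <- matrix(c(0L, 0L, 0L), 1, 3, dimnames = list("s1", NULL))
  gm <- make_gm(dosage)
  gm$pl[1, 1, ] <- c(0, 34, 200)   # margin 34: masked
  gm$pl[1, 2, ] <- c(0, 35, 200)   # margin exactly 35: retained
  gm$pl[1, 3, ] <- c(0, 80, 120)
  out <- mask_low_confidence(gm, pl_min = 35)
  expect_true(is.na(out$gm$dosage[1, 1]))
  expect_identical(unname(out$gm$dosage[1, 2]), 0L)
  expect_identical(unname(out$gm$dosage[1, 3]), 0L)
  expect_equal(out$report$n_removed, 1L)

  # all margins at or above the threshold: identity
  out2 <- mask_low_confidence(out$gm, pl_min = 35)
  expect_identical(out2$gm$dosage, out$gm$dosage)
  expect_equal(out2$report$n_removed, 0L)
})

test_that("site coverage keeps a locus at the 10x/80% boundary and not below", {
  depth <- matrix(10L, 10, 2)
  depth[9:10, 1] <- 9L   # 8 of 10 at >= 10x: ceiling(0.8 * 10) = 8, kept
  depth[8:10, 2] <- 9L   # 7 of 10: dropped
  gm <- make_gm(matrix(0L, 10, 2), depth = depth)
  out <- filter_site_coverage(gm, min_depth = 10, min_fraction = 0.8)
  expect_equal(n_loci(out$gm), 1L)
  expect_equal(out$gm$loci$pos, 1L)
  expect_equal(filter_site_coverage(gm, min_fraction = 0)$report$n_removed, 0L)
})

test_that("alternate-allele support counts hets as one and hom-alts as two", {
  d <- matrix(0L, 10, 3)
  d[1:3, 1] <- 1L          # 3 hets: alt count 3, dropped at >= 4
  d[1:2, 2] <- 2L          # 2 hom-alt: alt count 4, kept
  # column 3 monomorphic reference: dropped
  out <- filter_alt_support(make_gm(d), min_alt_obs = 4)
  expect_equal(n_loci(out$gm), 1L)
  expect_equal(out$gm$loci$pos, 2L)
  expect_equal(out$report$n_removed, 2L)
})

test_that("max-missing filtering matches an independent per-locus recount", {
  d <- matrix(2L, 12, 2)
  d[1:9, 1] <- NA; d[1:8, 2] <- NA
  out <- filter_max_missing(make_gm(d), max_missing = 8)
  expect_equal(out$gm$loci$pos, 2L)
  # max_missing = N is the identity
  expect_equal(filter_max_missing(make_gm(d), 12)$report$n_removed, 0L)

  gm <- random_gm(20, 50, miss = 0.3, seed = 4)
  for (cap in c(0, 3, 6)) {
    got <- filter_max_missing(gm, cap)$gm$loci$pos
    want <- which(vapply(seq_len(50), function(l) {
      sum(is.na(gm$dosage[, l])) <= cap
    }, logical(1)))
    expect_identical(got, as.integer(want))
  }
})

test_that("every filter agrees with a brute-force scan and the chain is idempotent", {
  gm <- random_gm(30, 200, miss = 0.15, seed = 21)
  withr::with_seed(22, {
    gm$depth[] <- sample(0:25, length(gm$depth), replace = TRUE)
  })
  keep_cov <- vapply(seq_len(200), function(l) {
    sum(gm$depth[, l] >= 10) >= ceiling(0.8 * 30)
  }, logical(1))
  expect_identical(
    filter_site_coverage(gm)$gm$loci$pos, gm$loci$pos[keep_cov]
  )
  keep_alt <- vapply(seq_len(200), function(l) {
    sum(gm$dosage[, l], na.rm = TRUE) >= 4
  }, logical(1))
  expect_identical(
    filter_alt_support(gm)$gm$loci$pos, gm$loci$pos[keep_alt]
  )

  chain <- filter_genotypes(gm, max_missing = 5)
  again <- filter_genotypes(chain$gm, max_missing = 5)
  expect_identical(again$gm$dosage, chain$gm$dosage)
  expect_true(all(again$report$n_removed == 0L))
  # removed + surviving = input at each stage
  expect_true(all(chain$report$n_in - chain$report$n_removed == chain$report$n_out))
})

test_that("duplicate concordance implies predicted accuracy under equal errors", {
  d <- matrix(0L, 2, 1000, dimnames = list(c("a", "a_dup"), NULL))
  gm <- make_gm(d)
  pairs <- tibble::tibble(sample = "a_dup", duplicate_of = "a")
  expect_equal(duplicate_concordance(gm, pairs)$predicted_accuracy, 1.0)

  d2 <- d; d2[2, 1:12] <- 1L   # discordance 0.012
  dc <- duplicate_concordance(make_gm(d2), pairs)
  expect_equal(dc$concordance, 0.988)
  expect_equal(dc$predicted_accuracy, 0.994)

  d3 <- d; d3[2, ] <- NA
  dc3 <- duplicate_concordance(make_gm(d3), pairs)
  expect_equal(dc3$n_compared, 0L)
  expect_true(is.na(dc3$concordance))
})
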