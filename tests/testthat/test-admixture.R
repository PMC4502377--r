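fake_run <- function(k, lnl_values) {
  # minimal admixture_run for model-choice arithmetic
  structure(
    list(Q = matrix(1, 2, k), P = NULL, lnl = lnl_values, K = as.integer(k),
         burn_in = 0L, n_reps = length(lnl_values), seed = NULL),
    class = "admixture_run"
  )
}

test_that("a single component gives ancestry exactly one and posterior-mean frequencies", {
  d <- matrix(c(0L, 1L, 2L, 2L, 0L, 0L, 1L, 1L), 4, 2)
  gm <- make_gm(d)
  run <- fit_admixture(gm, k = 1, burn_in = 200, n_reps = 3000, seed = 1)
  expect_true(all(run$Q == 1))
  # with a uniform Beta prior the posterior mean is (1 + alt) / (2 + 2n)
  want <- (1 + colSums(d)) / (2 + 2 * nrow(d))
  expect_equal(as.numeric(run$P), want, tolerance = 0.02)
  expect_length(run$lnl, 3200)
  expect_true(all(is.finite(run$lnl)))
})

test_that("invalid component counts are refused", {
  gm <- make_gm(matrix(0:2, 3, 2))
  expect_error(fit_admixture(gm, k = 4), "exceeds")
  expect_error(fit_admixture(gm, k = 0), "at least 1")
})

test_that("two diverged populations are recovered with high ancestry purity", {
  sim <- simulate_dataset(sim_config(
    n_loci = 150, n_per_pop = c(west = 12, east = 12), n_admixed = 0,
    n_outgroup = 1, n_duplicates = 0, fst_true = 0.5, missing_rate = 0.02,
    seed = 31
  ))
  cult <- sim$sample_sheet$sample[sim$sample_sheet$region != "Outgroup"]
  gm <- gm_subset(sim$gm, samples = cult)
  run2 <- fit_admixture(gm, 2, burn_in = 300, n_reps = 1500, seed = 7)
  expect_true(mean(apply(run2$Q, 1, max) >= 0.8) >= 0.9)
  # the two-population model explains the data better than one population
  run1 <- fit_admixture(gm, 1, burn_in = 300, n_reps = 1500, seed = 8)
  expect_gt(
    mean(run2$lnl[-(1:300)]), mean(run1$lnl[-(1:300)])
  )
  # sample order permutation permutes Q rows identically (same seed)
  perm <- rev(seq_along(cult))
  run2p <- fit_admixture(gm_subset(gm, samples = perm), 2,
                         burn_in = 300, n_reps = 1500, seed = 7)
  expect_equal(dim(run2p$Q), dim(run2$Q))
  expect_true(all(rownames(run2p$Q) == rev(rownames(run2$Q))))
})

test_that("replicate alignment recovers label permutations and bounds similarity", {
  withr::with_seed(5, {
    q <- matrix(runif(20), 10, 2)
    q <- q / rowSums(q)
  })
  r1 <- fake_run(2, -100); r1$Q <- q
  r2 <- fake_run(2, -101); r2$Q <- q[, 2:1]
  aln <- align_runs(list(r1, r2))
  expect_equal(aln$permutations[[2]], c(2L, 1L))
  expect_equal(aln$h_prime, 1.0)
  expect_equal(aln$consensus_q, q, ignore_attr = TRUE)

  # hand-evaluated Frobenius similarity: N = 2, one row replaced by complement
  qa <- matrix(c(0.9, 0.6, 0.1, 0.4), 2, 2)
  qb <- qa; qb[2, ] <- c(0.4, 0.6)
  ra <- fake_run(2, -1); ra$Q <- qa
  rb <- fake_run(2, -1); rb$Q <- qb
  got <- align_runs(list(ra, rb))
  hand <- 1 - sqrt(sum((qa - qb)^2)) / sqrt(2 * 2)
  expect_equal(got$similarity[1, 2], hand)

  single <- align_runs(list(r1))
  expect_true(single$single_run)
  expect_equal(single$h_prime, 1.0)

  expect_error(align_runs(list(r1, fake_run(3, -1))), "same")
})

test_that("similarity and H' stay within [0, 1] on random replicate sets", {
  for (s in 1:5) {
    runs <- withr::with_seed(s, lapply(1:3, function(i) {
      q <- matrix(runif(30), 10, 3); q <- q / rowSums(q)
      r <- fake_run(3, -1); r$Q <- q; r
    }))
    aln <- align_runs(runs)
    expect_true(all(aln$similarity >= 0 & aln$similarity <= 1))
    expect_true(aln$h_prime >= 0 && aln$h_prime <= 1)
  }
})

test_that("delta-K arithmetic matches hand evaluation and flags degeneracies", {
  x <- 10 / sqrt(2)   # two replicates at mean +/- x have sd 10
  runs <- unlist(lapply(1:4, function(k) {
    m <- c(-1000, -800, -790, -785)[k]
    list(fake_run(k, m - x), fake_run(k, m + x))
  }), recursive = FALSE)
  ev <- evanno_delta_k(runs)
  expect_equal(ev$table$sd_lnl, rep(10, 4))
  expect_equal(ev$table$delta_k, c(NA, 19, 0.5, NA))
  expect_equal(ev$best_k, 2L)

  # exactly linear mean likelihoods: second difference vanishes
  lin <- unlist(lapply(1:4, function(k) {
    list(fake_run(k, -1000 + 5 * k - x), fake_run(k, -1000 + 5 * k + x))
  }), recursive = FALSE)
  expect_equal(evanno_delta_k(lin)$table$delta_k[2:3], c(0, 0))

  # zero replicate sd: delta-K reported as Inf with a warning
  degen <- unlist(lapply(1:3, function(k) {
    list(fake_run(k, c(-1000, -900, -600)[k]),
         fake_run(k, c(-1000, -900, -600)[k]))
  }), recursive = FALSE)
  expect_warning(ev0 <- evanno_delta_k(degen), "Inf")
  expect_true(is.infinite(ev0$table$delta_k[2]))

  expect_error(evanno_delta_k(runs[1:2]), "consecutive")
  expect_error(
    evanno_delta_k(list(fake_run(1, -1), fake_run(2, -1), fake_run(3, -1))),
    "two replicates"
  )
})

test_that("purity assignment is inclusive at the threshold", {
  q <- rbind(a = c(0.80, 0.20), b = c(0.75, 0.25), c = c(0.60, 0.40),
             d = c(0.10, 0.90))
  colnames(q) <- c("pop_1", "pop_2")
  got <- assign_populations(q, threshold = 0.75)
  expect_equal(got$label, c("pop_1", "pop_1", "Mixed", "pop_2"))
  expect_error(assign_populations(q, threshold = 0.5), "0.5")
})
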