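#' Fit a K-population admixture model by Gibbs sampling
#'
#' Models each individual's genome as a mixture of `K` ancestral populations
#' with independent per-population allele frequencies (uniform Beta prior)
#' and a symmetric Dirichlet(`alpha`) prior on ancestry proportions. Allele
#' copies carry latent origin indicators updated by Gibbs sampling; reported
#' `Q` (ancestry proportions) and `P` (alternate-allele frequencies) are
#' posterior means over the post-burn-in sweeps. Missing dosages are skipped
#' in the likelihood.
#'
#' @param gm a [genotype_matrix()] with at least one locus.
#' @param k number of ancestral populations (`1 <= k <=` number of samples).
#' @param burn_in,n_reps burn-in and retained MCMC sweeps (defaults 5000 and
#'   25000, the survey settings; tests and desk-scale runs use shorter
#'   chains).
#' @param alpha Dirichlet concentration for ancestry proportions (default 1).
#' @param seed optional integer seed for a reproducible chain.
#' @return An object of class `admixture_run`: `Q` (samples x k), `P`
#'   (k x loci), `lnl` (per-sweep log-likelihood trace of length
#'   `burn_in + n_reps`), and the settings.
#' @export
fit_admixture <- function(gm, k, burn_in = 5000, n_reps = 25000,
                          alpha = 1, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (k < 1) stop("k must be at least 1")
  if (k > n_samples(gm)) stop("k exceeds the number of samples")
  if (n_loci(gm) < 1) stop("matrix has no loci")
  run_it <- function() gibbs_admixture(gm$dosage, as.integer(k),
                                       as.integer(burn_in), as.integer(n_reps),
                                       alpha)
  fit <- if (is.null(seed)) run_it() else withr::with_seed(seed, run_it())
  if (any(!is.finite(fit$lnl))) {
    stop("non-finite log-likelihood at sweep ", which(!is.finite(fit$lnl))[1])
  }
  Q <- fit$Q
  rownames(Q) <- gm$samples
  colnames(Q) <- paste0("pop_", seq_len(k))
  if (k == 1) Q[] <- 1  # single component: proportions are exactly 1
  structure(
    list(
      Q = Q, P = fit$P, lnl = as.numeric(fit$lnl),
      K = as.integer(k), burn_in = as.integer(burn_in),
      n_reps = as.integer(n_reps), seed = seed
    ),
    class = "admixture_run"
  )
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf(
    "<admixture_run> K = %d, %d samples, mean post-burn-in lnL = %.1f\n",
    x$K, nrow(x$Q), run_lnl(x)
  ))
  invisible(x)
}

# mean post-burn-in log-likelihood: the run's estimate of ln P(data | K)
run_lnl <- function(run) {
  post <- if (run$burn_in > 0) run$lnl[-seq_len(run$burn_in)] else run$lnl
  mean(post)
}

#' Replicate admixture runs over a range of K
#'
#' Runs `n_replicates` independent chains for every `k` in `k_range`, with
#' per-run seeds derived deterministically from `seed` so the whole sweep is
#' reproducible from one integer.
#'
#' @inheritParams fit_admixture
#' @param k_range integer vector of K values.
#' @param n_replicates chains per K.
#' @return A list of `admixture_run` objects (flat, in K-major order).
#' @export
fit_admixture_replicates <- function(gm, k_range, n_replicates = 4,
                                     burn_in = 5000, n_reps = 25000,
                                     alpha = 1, seed = 42) {
  runs <- list()
  for (k in k_range) {
    for (r in seq_len(n_replicates)) {
      runs[[length(runs) + 1L]] <- fit_admixture(
        gm, k, burn_in = burn_in, n_reps = n_reps, alpha = alpha,
        seed = derive_seed(seed, k, r)
      )
    }
  }
  runs
}

# similarity of two aligned Q matrices: 1 - ||A - B||_F / sqrt(2N)
q_similarity <- function(a, b) {
  1 - norm(a - b, type = "F") / sqrt(2 * nrow(a))
}

#' Align replicate admixture runs over label permutations
#'
#' Cluster labels are arbitrary per run, so replicates are aligned by an
#' exhaustive search over column permutations (exact for K <= 8) maximizing
#' similarity to the first run, where the similarity of two Q matrices is
#' `1 - ||Qa - Qb||_F / sqrt(2N)`. The summary `h_prime` is the mean pairwise
#' similarity after alignment; 1 means the replicates agree perfectly.
#'
#' @param runs list of `admixture_run` objects with identical samples and K.
#' @return An object of class `run_alignment`: `permutations` (list, one per
#'   run), `similarity` (aligned pairwise similarity matrix), `h_prime`,
#'   `consensus_q` (cell-wise mean of aligned Q), and `single_run` flag (a
#'   lone run has vacuous concordance, reported as `h_prime = 1`).
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "admixture_run")))
  K <- unique(vapply(runs, function(r) r$K, integer(1)))
  Ns <- unique(vapply(runs, function(r) nrow(r$Q), integer(1)))
  if (length(K) != 1 || length(Ns) != 1) {
    stop("all runs must share the same number of samples and the same K")
  }
  if (K > 8) stop("exhaustive alignment supports K <= 8")
  perms <- all_permutations(K)
  ref <- runs[[1]]$Q
  aligned <- vector("list", length(runs))
  chosen <- vector("list", length(runs))
  aligned[[1]] <- ref
  chosen[[1]] <- seq_len(K)
  for (j in seq_along(runs)[-1]) {
    sims <- vapply(perms, function(p) q_similarity(ref, runs[[j]]$Q[, p, drop = FALSE]),
                   numeric(1))
    best <- perms[[which.max(sims)]]
    chosen[[j]] <- best
    aligned[[j]] <- runs[[j]]$Q[, best, drop = FALSE]
    colnames(aligned[[j]]) <- colnames(ref)
  }
  R <- length(runs)
  sim <- matrix(1, R, R)
  if (R > 1) {
    for (a in seq_len(R - 1)) {
      for (b in seq(a + 1, R)) {
        sim[a, b] <- sim[b, a] <- q_similarity(aligned[[a]], aligned[[b]])
      }
    }
  }
  h_prime <- if (R > 1) mean(sim[upper.tri(sim)]) else 1
  consensus <- Reduce(`+`, aligned) / R
  structure(
    list(
      permutations = chosen, similarity = sim, h_prime = h_prime,
      consensus_q = consensus, single_run = R == 1, K = K
    ),
    class = "run_alignment"
  )
}

#' @export
print.run_alignment <- function(x, ...) {
  cat(sprintf(
    "<run_alignment> %d run(s), K = %d, H' = %.3f%s\n",
    length(x$permutations), x$K, x$h_prime,
    if (x$single_run) " (single run, vacuous)" else ""
  ))
  invisible(x)
}

#' Choose K by the Evanno delta-K method
#'
#' For each K with at least two replicate runs, computes the mean and
#' standard deviation of the run log-likelihoods `L(K)`, the successive
#' differences `L'(K) = L(K) - L(K-1)`, the absolute second differences
#' `L''(K) = |L'(K+1) - L'(K)|`, and `delta_K = L''(K) / sd(L(K))`. The
#' supported number of clusters is the K maximizing `delta_K`, which is only
#' defined for interior K values.
#'
#' @param runs flat list of `admixture_run` objects covering at least three
#'   consecutive K values with two or more replicates each.
#' @return An object of class `evanno_result`: `table` (tibble with columns
#'   `k`, `n_runs`, `mean_lnl`, `sd_lnl`, `lnl_prime`, `lnl_dprime`,
#'   `delta_k`) and `best_k`.
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(vapply(runs, inherits, TRUE, "admixture_run")))
  ks <- vapply(runs, function(r) r$K, integer(1))
  lnls <- vapply(runs, run_lnl, numeric(1))
  tab <- tibble(k = ks, lnl = lnls) |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_lnl = mean(.data$lnl),
      sd_lnl = sd(.data$lnl),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$k)
  if (nrow(tab) < 3 || any(diff(tab$k) != 1)) {
    stop("need at least three consecutive K values")
  }
  if (any(tab$n_runs < 2)) stop("need at least two replicates per K")
  nK <- nrow(tab)
  lp <- c(NA, diff(tab$mean_lnl))                       # L'(K)
  ldp <- c(NA, abs(diff(lp[-1])), NA)                   # L''(K), interior only
  if (any(tab$sd_lnl == 0 & !is.na(ldp))) {
    warning("zero replicate sd at some K; delta_K reported as Inf")
  }
  dk <- ldp / tab$sd_lnl
  tab <- tab |>
    dplyr::mutate(lnl_prime = lp, lnl_dprime = ldp, delta_k = dk)
  best <- tab$k[which.max(tab$delta_k)]
  structure(list(table = tab, best_k = best), class = "evanno_result")
}

#' @export
print.evanno_result <- function(x, ...) {
  cat(sprintf("<evanno_result> best K = %d\n", x$best_k))
  print(x$table)
  invisible(x)
}

#' Assign samples to populations by ancestry purity
#'
#' A sample is assigned to population k when its consensus ancestry
#' proportion for that cluster is at least `threshold` (inclusive, so 0.75
#' purity passes a 75% rule); otherwise it is labelled `"Mixed"`.
#'
#' @param q a consensus Q matrix (samples x K, rownames = sample ids), or a
#'   `run_alignment` / `admixture_run` object.
#' @param threshold purity threshold in (0.5, 1].
#' @return Tibble: `sample`, `purity` (max ancestry proportion),
#'   `label` (`pop_k` or `"Mixed"`).
#' @export
assign_populations <- function(q, threshold = 0.75) {
  if (inherits(q, "run_alignment")) q <- q$consensus_q
  if (inherits(q, "admixture_run")) q <- q$Q
  stopifnot(is.matrix(q))
  if (threshold <= 0.5 || threshold > 1) stop("threshold must lie in (0.5, 1]")
  best <- max.col(q, ties.method = "first")
  purity <- q[cbind(seq_len(nrow(q)), best)]
  tibble(
    sample = rownames(q),
    purity = purity,
    label = ifelse(purity >= threshold, paste0("pop_", best), "Mixed")
  )
}
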