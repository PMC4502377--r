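# Fixture builders and independent oracles shared across the suite.

# genotype matrix from a bare dosage matrix: auto loci on one contig,
# saturating depth and PL triples consistent with each call (margin 100)
make_gm <- function(dosage, depth = NULL, contig = "c1") {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  }
  storage.mode(dosage) <- "integer"
  L <- ncol(dosage)
  loci <- tibble::tibble(
    contig = contig, pos = seq_len(L), ref = "A", alt = "G"
  )
  if (is.null(depth)) {
    depth <- matrix(30L, nrow(dosage), L, dimnames = dimnames(dosage))
  }
  pl <- array(NA_real_, c(nrow(dosage), L, 3))
  for (i in seq_len(nrow(dosage))) {
    for (j in seq_len(L)) {
      if (!is.na(dosage[i, j])) {
        tr <- c(100, 100, 100)
        tr[dosage[i, j] + 1] <- 0
        pl[i, j, ] <- tr
      }
    }
  }
  palmpop::genotype_matrix(dosage, loci, depth = depth, pl = pl)
}

# random dosage matrix with missingness, reproducible
random_gm <- function(n_samples, n_loci, miss = 0.1, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(sample(0:2, n_samples * n_loci, replace = TRUE),
                n_samples, n_loci)
    d[runif(length(d)) < miss] <- NA_integer_
    make_gm(d)
  })
}

# textbook Weir-Cockerham (1984) variance components for one biallelic
# locus, written as a direct scalar transcription: n_i called individuals,
# p_i alt frequency, h_i het proportion per population
wc_components_oracle <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

# per-locus oracle over a dosage matrix and two sample index sets
wc_oracle_matrix <- function(dosage, idx1, idx2) {
  t(vapply(seq_len(ncol(dosage)), function(l) {
    comp <- lapply(list(idx1, idx2), function(idx) {
      g <- dosage[idx, l]
      g <- g[!is.na(g)]
      list(n = length(g), p = if (length(g)) sum(g) / (2 * length(g)) else NA,
           h = if (length(g)) mean(g == 1) else NA)
    })
    n_i <- vapply(comp, `[[`, numeric(1), "n")
    if (any(n_i < 1) || mean(n_i) <= 1) return(c(a = NA, b = NA, c = NA))
    wc_components_oracle(
      n_i, vapply(comp, `[[`, numeric(1), "p"),
      vapply(comp, `[[`, numeric(1), "h")
    )
  }, c(a = 0, b = 0, c = 0)))
}

# two-sided Fisher exact p by full hypergeometric enumeration of all tables
# with the observed margins; ties included up to the standard relative slack
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# brute-force scans used against the vectorized implementations
brute_private <- function(dosage, idx1, idx2) {
  t(vapply(seq_len(ncol(dosage)), function(l) {
    cnt <- function(idx) {
      g <- dosage[idx, l]; g <- g[!is.na(g)]
      c(ref = sum(2 - g), alt = sum(g))
    }
    c1 <- cnt(idx1); c2 <- cnt(idx2)
    c(
      alt_private_1 = unname(c1[["alt"]] >= 1 && c2[["alt"]] == 0),
      alt_private_2 = unname(c2[["alt"]] >= 1 && c1[["alt"]] == 0),
      ref_private_1 = unname(c1[["ref"]] >= 1 && c2[["ref"]] == 0),
      ref_private_2 = unname(c2[["ref"]] >= 1 && c1[["ref"]] == 0)
    )
  }, logical(4)))
}

brute_segregating <- function(dosage, idx1, idx2) {
  vapply(seq_len(ncol(dosage)), function(l) {
    g1 <- dosage[idx1, l]; g1 <- g1[!is.na(g1)]
    g2 <- dosage[idx2, l]; g2 <- g2[!is.na(g2)]
    if (!length(g1) || !length(g2)) return(FALSE)
    if (any(g1 == 1) || any(g2 == 1)) return(FALSE)
    length(unique(g1)) == 1 && length(unique(g2)) == 1 && g1[1] != g2[1]
  }, logical(1))
}
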