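#' Simulation settings for a two-population genotyping survey
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' mirror the study design the package targets: 70 cultivar samples split into
#' a small western group (11), a large eastern group (52) and 7 admixed
#' individuals, plus 4 outgroup trees of two related species and 4 duplicated
#' samples used as an internal genotyping control.
#'
#' Population divergence follows the Balding-Nichols model: each locus has an
#' ancestral alternate-allele frequency `p` drawn Uniform(0.05, 0.95), and
#' each population's frequency is drawn from
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` so that the divergence
#' parameter `F` is also the expected Weir-Cockerham Fst between the two
#' populations -- which gives parameter-recovery tests a known target.
#'
#' @param n_loci number of biallelic SNV loci.
#' @param n_per_pop named integer vector `c(west = ..., east = ...)`: number
#'   of unadmixed individuals per population.
#' @param n_admixed number of admixed individuals.
#' @param admix_q probability, per locus, that an admixed individual draws its
#'   genotype from the western population.
#' @param fst_true Balding-Nichols divergence `F` between the two cultivar
#'   populations, strictly inside (0, 1).
#' @param n_outgroup number of outgroup-species samples.
#' @param outgroup_divergence Balding-Nichols `F` for outgroup frequencies
#'   relative to the shared ancestral frequency.
#' @param private_rate fraction of loci forced private: monomorphic for the
#'   alternate allele in one population and absent from the other
#'   (alternating which population carries it).
#' @param mean_depth expected sequencing depth per genotype call (Poisson).
#' @param missing_rate extra per-call missingness injected after depth-zero
#'   dropout.
#' @param genotype_error per-call error rate applied independently to each
#'   member of a duplicate pair, so the expected pair discordance is about
#'   `2 * e * (1 - e)`.
#' @param n_duplicates number of cultivar samples re-genotyped as duplicates.
#' @param n_contigs,n_lg size of the genetic map: contigs are assigned
#'   round-robin to linkage groups.
#' @param unaligned_rate fraction of loci whose ancestral allele cannot be
#'   determined (reported as "unaligned" in the ancestral-allele table).
#' @param seed integer RNG seed; identical seeds give byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 2000,
                       n_per_pop = c(west = 11, east = 52),
                       n_admixed = 7,
                       admix_q = 0.5,
                       fst_true = 0.25,
                       n_outgroup = 4,
                       outgroup_divergence = 0.5,
                       private_rate = 0.05,
                       mean_depth = 20,
                       missing_rate = 0.05,
                       genotype_error = 0.006,
                       n_duplicates = 4,
                       n_contigs = 40,
                       n_lg = 18,
                       unaligned_rate = 0.13,
                       seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci), n_per_pop = n_per_pop,
    n_admixed = as.integer(n_admixed), admix_q = admix_q,
    fst_true = fst_true, n_outgroup = as.integer(n_outgroup),
    outgroup_divergence = outgroup_divergence, private_rate = private_rate,
    mean_depth = mean_depth, missing_rate = missing_rate,
    genotype_error = genotype_error, n_duplicates = as.integer(n_duplicates),
    n_contigs = as.integer(n_contigs), n_lg = as.integer(n_lg),
    unaligned_rate = unaligned_rate, seed = as.integer(seed)
  )
  rates <- c(
    admix_q = cfg$admix_q, private_rate = cfg$private_rate,
    missing_rate = cfg$missing_rate, genotype_error = cfg$genotype_error,
    unaligned_rate = cfg$unaligned_rate
  )
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ", paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  for (f in c(cfg$fst_true, cfg$outgroup_divergence)) {
    if (f <= 0 || f >= 1) {
      stop("divergence parameters must lie strictly inside (0, 1); ",
           "F = 0 or 1 makes the Balding-Nichols Beta degenerate")
    }
  }
  if (cfg$n_loci < 1) stop("n_loci must be positive")
  if (length(cfg$n_per_pop) != 2 || any(cfg$n_per_pop < 1)) {
    stop("n_per_pop must give two positive counts (west, east)")
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$n_contigs < 1 || cfg$n_lg < 1 || cfg$n_lg > cfg$n_contigs) {
    stop("need 1 <= n_lg <= n_contigs")
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols draw of population frequencies around ancestral p
rbalding_nichols <- function(p, f) {
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# phred-scaled likelihoods for dosages 0/1/2 given alt reads k of depth d,
# binomial read split with sequencing error `err`; best genotype gets PL 0
pl_from_reads <- function(k, d, err = 0.01) {
  ll <- cbind(
    stats::dbinom(k, d, err, log = TRUE),
    stats::dbinom(k, d, 0.5, log = TRUE),
    stats::dbinom(k, d, 1 - err, log = TRUE)
  )
  pl <- round(-10 * (ll - apply(ll, 1, max)) / log(10))
  # cap so phred values stay finite and VCF-friendly
  pmin(pl, 9999)
}

#' Simulate a two-population genotyping-by-sequencing dataset
#'
#' Generates a full synthetic survey: diploid genotypes for two diverged
#' cultivar populations (Balding-Nichols divergence at `fst_true`), admixed
#' individuals, outgroup-species samples, per-call depth and phred-scaled
#' genotype likelihoods derived from a binomial read split, injected
#' missingness, duplicated control samples with independent per-call errors,
#' a genetic map (contigs ordered on linkage groups) and an ancestral-allele
#' table. Everything downstream of the generator treats these outputs exactly
#' like field data read from disk.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{gm}{[genotype_matrix()] of observed calls (all samples,
#'       including outgroup and duplicates).}
#'     \item{sample_sheet}{tibble: `sample`, `region` (West/East/Mixed/
#'       Outgroup), `species`, `duplicate_of` (`NA` for originals).}
#'     \item{map}{[genetic_map()] tibble: `lg`, `contig`, `order`, `length`,
#'       `offset`.}
#'     \item{ancestral}{tibble: `contig`, `pos`, `allele` (base or
#'       "unaligned").}
#'     \item{truth}{list of generating values: per-sample `q` (western
#'       ancestry fraction), per-locus frequencies (`p_anc`, `p_west`,
#'       `p_east`, `p_outgroup`), the true dosage matrix, the ancestral
#'       allele per locus, and the duplicate-pair registry.}
#'   }
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_loci = 50, seed = 7))
#' sim$gm
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  L <- cfg$n_loci

  ## genetic map: contigs round-robin over linkage groups
  contig <- sprintf("contig_%03d", seq_len(cfg$n_contigs))
  len <- as.integer(round(runif(cfg$n_contigs, 5e4, 5e5)))
  lg <- ((seq_len(cfg$n_contigs) - 1L) %% cfg$n_lg) + 1L
  ord <- stats::ave(lg, lg, FUN = seq_along)
  map <- genetic_map(tibble(
    lg = sprintf("LG%02d", lg), contig = contig, order = ord, length = len
  ))

  ## loci: placed uniformly on contigs, unique positions, sorted
  ci <- sample.int(cfg$n_contigs, L, replace = TRUE)
  pos <- as.integer(ceiling(runif(L) * len[ci]))
  while (anyDuplicated(paste(ci, pos))) {
    dup <- duplicated(paste(ci, pos))
    pos[dup] <- as.integer(ceiling(runif(sum(dup)) * len[ci[dup]]))
  }
  o <- order(contig[ci], pos)
  ci <- ci[o]; pos <- pos[o]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  loci <- tibble(contig = contig[ci], pos = pos, ref = ref, alt = unname(alt))

  ## allele frequencies under Balding-Nichols
  p_anc <- runif(L, 0.05, 0.95)
  p_w <- rbalding_nichols(p_anc, cfg$fst_true)
  p_e <- rbalding_nichols(p_anc, cfg$fst_true)
  p_o <- rbalding_nichols(p_anc, cfg$outgroup_divergence)
  n_priv <- round(cfg$private_rate * L)
  if (n_priv > 0) {
    idx <- sample.int(L, n_priv)
    west_side <- seq_len(n_priv) %% 2L == 1L
    p_w[idx[west_side]] <- 1; p_e[idx[west_side]] <- 0
    p_e[idx[!west_side]] <- 1; p_w[idx[!west_side]] <- 0
  }

  ## ancestral allele (outgroup-genome state) per locus
  anc_is_alt <- rbinom(L, 1, p_anc) == 1
  anc_allele <- ifelse(anc_is_alt, loci$alt, loci$ref)
  anc_allele[runif(L) < cfg$unaligned_rate] <- "unaligned"

  ## sample layout
  n_w <- cfg$n_per_pop[["west"]]; n_e <- cfg$n_per_pop[["east"]]
  ids <- c(
    sprintf("W%02d", seq_len(n_w)),
    sprintf("E%02d", seq_len(n_e)),
    if (cfg$n_admixed > 0) sprintf("M%02d", seq_len(cfg$n_admixed)),
    if (cfg$n_outgroup > 0) sprintf("OG%d", seq_len(cfg$n_outgroup))
  )
  region <- c(
    rep("West", n_w), rep("East", n_e),
    rep("Mixed", cfg$n_admixed), rep("Outgroup", cfg$n_outgroup)
  )
  species <- c(
    rep("P_dactylifera", n_w + n_e + cfg$n_admixed),
    rep(c("P_hanceana", "P_sylvestris"), length.out = cfg$n_outgroup)
  )
  q_west <- c(
    rep(1, n_w), rep(0, n_e), rep(cfg$admix_q, cfg$n_admixed),
    rep(NA_real_, cfg$n_outgroup)
  )
  N <- length(ids)

  ## true dosages (Hardy-Weinberg within the source population)
  true_dos <- matrix(NA_integer_, N, L, dimnames = list(ids, NULL))
  for (i in seq_len(N)) {
    p_i <- switch(region[i],
      West = p_w, East = p_e, Outgroup = p_o,
      Mixed = ifelse(runif(L) < cfg$admix_q, p_w, p_e)
    )
    true_dos[i, ] <- rbinom(L, 2, p_i)
  }

  ## duplicate registry: re-genotyped copies of the first cultivar samples,
  ## spread over both populations
  n_dup <- min(cfg$n_duplicates, n_w + n_e)
  dup_src <- character(0)
  if (n_dup > 0) {
    take_w <- min(ceiling(n_dup / 2), n_w)
    dup_src <- c(ids[seq_len(take_w)], ids[n_w + seq_len(n_dup - take_w)])
    dup_ids <- paste0(dup_src, "_dup")
    true_dos <- rbind(true_dos, true_dos[dup_src, , drop = FALSE])
    rownames(true_dos) <- c(ids, dup_ids)
    ids <- c(ids, dup_ids)
    region <- c(region, region[match(dup_src, rownames(true_dos))])
    species <- c(species, rep("P_dactylifera", n_dup))
    q_west <- c(q_west, q_west[match(dup_src, ids)])
    N <- length(ids)
  }

  ## observation layer: depth, read split, PL, call, missingness
  depth <- matrix(rpois(N * L, cfg$mean_depth), N, L, dimnames = list(ids, NULL))
  g <- as.vector(true_dos)
  k_alt <- rbinom(N * L, as.vector(depth), c(0.01, 0.5, 0.99)[g + 1L])
  pl_flat <- pl_from_reads(k_alt, as.vector(depth))
  called <- max.col(-pl_flat, ties.method = "first") - 1L
  miss <- as.vector(depth) == 0L | runif(N * L) < cfg$missing_rate
  called[miss] <- NA_integer_
  pl_flat[miss, ] <- NA_real_
  dosage <- matrix(called, N, L, dimnames = list(ids, NULL))
  pl <- array(pl_flat, dim = c(N, L, 3), dimnames = list(ids, NULL, NULL))

  ## independent per-call error flips on both members of each duplicate pair
  if (n_dup > 0) {
    for (s in c(dup_src, paste0(dup_src, "_dup"))) {
      i <- match(s, ids)
      row <- dosage[i, ]
      flip <- !is.na(row) & runif(L) < cfg$genotype_error
      if (any(flip)) {
        row[flip] <- vapply(
          row[flip], function(d) sample(setdiff(0:2, d), 1L), integer(1)
        )
        dosage[i, ] <- row
        for (j in which(flip)) {
          tr <- c(60, 60, 60); tr[row[j] + 1L] <- 0
          pl[i, j, ] <- tr
        }
      }
    }
  }

  sheet <- tibble(
    sample = ids,
    region = region,
    species = species,
    duplicate_of = ifelse(
      endsWith(ids, "_dup"), sub("_dup$", "", ids), NA_character_
    )
  )

  gm <- genotype_matrix(dosage, loci, depth = depth, pl = pl)
  truth <- list(
    q = tibble(sample = ids, q_west = q_west),
    freqs = tibble(
      contig = loci$contig, pos = loci$pos,
      p_anc = p_anc, p_west = p_w, p_east = p_e, p_outgroup = p_o
    ),
    dosage_true = true_dos,
    ancestral = tibble(contig = loci$contig, pos = loci$pos, allele = anc_allele),
    duplicates = tibble(sample = paste0(dup_src, "_dup"), duplicate_of = dup_src)
  )
  list(
    gm = gm, sample_sheet = sheet, map = map,
    ancestral = truth$ancestral, truth = truth
  )
}
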