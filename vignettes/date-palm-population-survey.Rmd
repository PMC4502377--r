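---
title: "Methods: population structure and differentiation from GBS genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and differentiation from GBS genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

palmpop reconstructs, as a tested and reusable pipeline, the analysis used
in genome-wide surveys of cultivated date palm: starting from multi-sample
SNV calls, it splits cultivars into subpopulations with an admixture model,
assigns samples by ancestry purity, and quantifies differentiation between
the resulting groups. This vignette explains the models, the tunable
parameters, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the design was genuinely open.

## Genotype container and filters

Genotypes live in a `genotype_matrix`: per-cell alternate-allele dosage
(0/1/2, `NA` missing), read depth, and the phred-scaled genotype likelihood
(PL) triple, plus an ordered locus table restricted to biallelic SNVs —
indels and multi-allelic records are dropped at VCF read time and counted.

Four filters mirror standard GBS practice and are applied in a fixed order
(each is also available separately, and re-running the chain on its own
output removes nothing):

1. **PL margin** (`pl_min = 35`, phred units): a call is trusted only when
   the second-smallest PL — the margin by which the best genotype beats the
   runner-up — is at least 35. The boundary is inclusive (a margin of
   exactly 35 is kept) because the rule is "mask below 35". Cells without a
   PL triple are masked and counted.
2. **Site coverage** (`min_depth = 10`, `min_fraction = 0.8`): a locus
   needs `ceiling(0.8 N)` samples at 10x or better. The ceiling makes "at
   least 80%" strict while letting exact ties (8 of 10) pass.
3. **Alternate support** (`min_alt_obs = 4`): the alternate allele must be
   seen at least four times across called genotypes, a het counting once
   and a homozygote twice. Counting uses genotypes rather than raw reads
   because read-level evidence is no longer available downstream of the
   VCF.
4. **Missingness cap** (`max_missing`): analysis-specific — 10 missing
   genotypes for the tree-export set, 8 for the structure set, 15 for the
   cultivar-only allelic set. The cap counts missing calls among exactly
   the samples passed to the operation.

Duplicated control samples are compared over co-called loci;
`predicted_accuracy = 1 - (1 - concordance) / 2` converts observed pair
discordance into a per-sample accuracy under the assumption that errors
are equally likely in both members.

## Admixture model

The model is the independent-frequency admixture model: individual `i` has
ancestry proportions `q_i` over `K` populations (symmetric Dirichlet prior,
`alpha = 1`), population `k` has alternate-allele frequency `p_kl` at locus
`l` (uniform Beta prior), and each allele copy independently chooses an
origin population from `q_i` and then its allele from `p`. A Gibbs sampler
(compiled, single-threaded) alternates: origins given `(Q, P)`, `P` given
origins (`Beta(1 + alt, 1 + ref)`), and `Q` given origins
(`Dirichlet(1 + counts)`). Missing dosages are simply skipped. Reported
`Q` and `P` are posterior means over post-burn-in sweeps — the natural
analogue of the proportions STRUCTURE-style software reports — rather than
MAP estimates. The per-sweep log-likelihood
`sum log sum_k q_ik f(p_kl, allele)` over called allele copies is recorded
for the whole chain.

This is deliberately the simplest published variant of the model (no
correlated-frequency prior, no linkage model, no location priors): for two
well-separated populations it is adequate, and its conjugate structure
makes the sampler exact and fast. Full-survey chain settings are 5000
burn-in + 25000 retained sweeps; tests and the acceptance script use
reduced chains (hundreds to a few thousand sweeps), which the recovery
experiments below show to be sufficient at desk scale.

**Replicate alignment.** Cluster labels are arbitrary per run, so
replicates are aligned by exhaustive search over column permutations
(exact for `K <= 8`, unlike greedy heuristics; the surveys of interest use
`K` of 2–3) maximizing similarity to the first run, with
`G(Qa, Qb) = 1 - ||Qa - Qb||_F / sqrt(2N)` and `H'` the mean pairwise `G`
after alignment. A single run has vacuously perfect concordance and is
reported as `H' = 1` with a flag.

**Choosing K.** The Evanno delta-K statistic is computed from run mean
log-likelihoods: `L'(K) = L(K) - L(K-1)`,
`L''(K) = |L'(K+1) - L'(K)|`, `delta_K = L''(K) / sd[L(K)]`, defined for
interior K with positive replicate sd; zero sd yields `Inf` with a
warning rather than an error, since it still identifies the K at which
likelihood gains collapse. At least three consecutive K values with two or
more replicates are required.

**Assignment.** A sample joins population k when its consensus ancestry
reaches the purity threshold (default 0.75, inclusive — "at least 75%");
everything else is `Mixed`. Thresholds at or below 0.5 are rejected since
two clusters could then both claim a sample.

**Seed discipline.** One master seed deterministically derives a per-run
seed from `(K, replicate)`, so a replicate sweep is reproducible from a
single integer and runs are independent chains, not a shared stream.

## Ordination

PCA uses the 1/2/3 genotype coding (hom-ref / het / hom-alt), column-mean
imputation of missing codes, and column-centred SVD without unit-variance
scaling (`pca.scale = false`: scaling to unit variance would up-weight rare
variants and the reference behaviour being reconstructed does not document
scaling). Variance fractions are squared singular values over the total;
all-missing loci are dropped with a warning.

## Differentiation statistics

Allele counts per locus and population treat the two alleles of a het
independently — a het adds one to each allele's count. All two-group scans
run off these counts:

* **Private alleles**: the alternate allele seen in exactly one group.
  Reference-private positions are tracked separately and excluded from the
  headline count, because with a reference genome drawn from one of the two
  populations, nonreference-private positions are the informative ones (the
  imbalance between the two groups' counts is expected for the same
  reason). No call-rate or frequency filters are applied.
* **Weir–Cockerham Fst**: per-locus variance components a (among
  populations), b (among individuals within populations), c (within
  individuals), computed from genotype counts — the het fraction enters b
  and c, so this is not an allele-count approximation. Two summaries are
  reported: the mean of per-locus `a/(a+b+c)` and the ratio-of-sums
  `sum(a)/sum(a+b+c)` — the pair of summaries conventionally printed
  together (mean and "weighted"). Monomorphic loci (zero denominator) and
  loci where a group has no called genotype are excluded from both
  summaries and counted. Negative per-locus estimates are retained: the
  estimator is unbiased around zero and truncation would bias the means
  upward.
* **Fisher scan**: two-sided Fisher exact test on the 2x2 table of
  ref/alt allele counts by group. Allele counts (not genotype counts) are
  tested, matching the counting convention above. Bonferroni uses
  `m =` number of loci actually tested — loci with an entirely uncalled
  group carry no p-value and do not inflate the correction. Significance is
  corrected p < 0.01.
* **Fixed differences**: each group monomorphic for a different allele
  among called alleles, both groups called at least once. No missingness
  tolerance beyond that is applied; the rule is stated, not inferred.
* **Grouping**: the default two-group comparison pools the smaller western
  cluster with the admixed samples against the eastern cluster (the admixed
  cultivars sit geographically with the west in the surveys this package
  reconstructs); the strict west-vs-east comparison is the documented
  override, and both are reported by the pipeline.

**Genetic map.** Unanchored contigs get map-scale coordinates by
concatenating them in genetic-map order within each linkage group
("artificial chromosomes"): a SNP's artificial position is its contig's
cumulative offset plus its position. Enrichment per linkage group is the
group's flagged-SNP proportion over the genome-wide proportion; window
densities use half-open windows on artificial coordinates. Loci on contigs
absent from the map go to an explicit `unmapped` bucket rather than being
dropped silently. `exclude_lg()` removes one linkage group for re-analysis
(the motivating case: a sex-determination-carrying linkage group with
elevated fixation that can dominate structure inference).

## Polarization

Loci that segregate completely — every called genotype in one group
homozygous for one allele, every called genotype in the other group
homozygous for the other, hets disqualifying — are classified against an
outgroup ancestral-allele table: one side deviated (the other kept the
ancestral base), both deviated (ancestral matches neither), or unaligned.
Because the two group alleles differ by construction, the ancestral base
can never match both; the classes are mutually exclusive and exhaustive.
Whether "segregating completely" should tolerate missing calls is an open
reading; palmpop requires only the *called* genotypes to be opposite and
homozygous, and states that choice here. Percentages are rounded half away
from zero (so 4 of 32 prints as 13%), applied uniformly by the reporting
layer; percentages below 10% are printed with one decimal, others as
integers, reproducing the mixed style of survey reports.

## Synthetic data: what it emulates and what it does not

The generator's defaults are the study design being reconstructed: 70
cultivars (11 western, 52 eastern, 7 admixed at `q = 0.5`), 4 outgroup
trees of two species, 4 duplicated samples, and per-analysis missingness
caps as above. Divergence follows the Balding–Nichols model — ancestral
frequency `p ~ Uniform(0.05, 0.95)` per locus, population frequency
`~ Beta(p(1-F)/F, (1-p)(1-F)/F)` — chosen because the divergence parameter
`F` is then also the expected Weir–Cockerham Fst, giving recovery tests a
known target. `F = 0` or `1` is rejected (degenerate Beta). Defaults not
fixed by the study design were chosen once as field-realistic values:
`fst_true = 0.25` (between the two reported grouping summaries),
`mean_depth = 20` (comfortably above the 10x filter), `missing_rate =
0.05`, `genotype_error = 0.006` (whose implied duplicate predicted accuracy
is ~99.4%), `outgroup_divergence = 0.5` (a stand-in — no printed value
calibrates outgroup allele sharing), `unaligned_rate = 0.13`, 40 contigs on
18 linkage groups with lengths uniform in 50–500 kb (only contig order
matters downstream), and 2000 loci as the desk-scale default.

Observation noise: depth is Poisson, alternate reads are binomial given
the true genotype (error 0.01), PLs are the phred-scaled binomial
likelihoods normalized to minimum 0 (the convention the PL filter
thresholds against), calls are the PL argmin, and depth-zero or randomly
masked cells are missing. Both members of a duplicate pair receive
independent per-call error flips at `genotype_error`, so pair discordance
is `~2e(1-e)` — the "errors equally likely in both samples" model that the
predicted-accuracy formula inverts. A forced fraction of private loci
(`private_rate = 0.05`, alternating sides) guarantees material for the
private/fixed scans.

Deliberately not emulated: linkage disequilibrium between loci (every
locus is independent, so structure inference is easier than on real
linked data), read-level artifacts (barcode bleed, paralog collapse,
allele-specific bias), restriction-site dropout structure of GBS, and any
calibrated outgroup allele-sharing pattern. Passing recovery tests
therefore shows the estimators are correct under the stated model, not
that real GBS data meet that model.

## Numerical choices and degenerate inputs

* Second-smallest PL is computed as `sum - min - max` of the triple;
  exactly tied PLs give a zero margin and are masked unless above
  threshold.
* The call `argmin` over PLs breaks ties toward the lower dosage
  (first index), deterministically.
* With `K = 1` the ancestry matrix is exactly 1 by construction and `P`'s
  posterior mean is `(1 + alt)/(2 + 2n)` under the uniform prior; the
  sampler reproduces this to Monte-Carlo error.
* Fst loci with mean sample size of one diploid cannot be decomposed and
  are excluded as uninformative; an entirely monomorphic dataset is an
  error ("no informative loci") rather than a silent zero.
* Fisher p-values use the standard two-sided rule (sum of all table
  probabilities not exceeding the observed one, with the usual 1e-7
  relative tie slack); the suite checks equality against full
  hypergeometric enumeration for every table with total at most 24.
* Pairwise p-distances ignore positions where either sequence is not a
  plain base; pairs with no comparable site are `NA` and flagged, not 0.
* All report rounding is half-away-from-zero, never banker's rounding.

## Problem sizes

Test and acceptance runs use deliberately desk-scale problems chosen as the
package's own validation sizes: recovery of `F = 0.2` from 50+50 diploids
at 2000 loci (binomial sampling error then keeps the weighted-Fst estimate
within about 0.02 of the target), admixture recovery at `F = 0.3` with
40+40 unadmixed plus 10 admixed samples at 500 loci under reduced chains
(1000 burn-in + 5000 sweeps, 3 replicates, K from 1 to 4), and a full
pipeline on ~20–80 samples at 120–2000 loci. The full-survey chain settings
remain the config defaults.

## Known limitations

* The admixture sampler is a single chain per run; convergence is assessed
  only through replicate concordance (H') and the likelihood trace, not
  through formal diagnostics.
* Exhaustive label alignment is factorial in K and capped at `K = 8`.
* Mean imputation in PCA shrinks missing samples toward the centroid,
  which can mildly compress cluster separation at high missingness.
* The Fisher scan treats alleles within a genotype as independent draws,
  as does the private-allele definition; both inherit that convention from
  the counting rule they reconstruct.
* Dataset-scale published quantities (e.g. specific SNP totals or
  variance-explained percentages of a particular survey) depend on the
  original raw data and are out of reach of synthetic reconstruction; the
  package validates arithmetic identities and parameter recovery instead.
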