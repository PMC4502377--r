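#' Genotype matrix container
#'
#' Holds diploid biallelic SNV calls for a set of samples: per-cell alternate
#' allele dosage (0/1/2, `NA` = missing), read depth, and the phred-scaled
#' genotype likelihood (PL) triple, together with an ordered locus table
#' (contig, pos, ref, alt). Loci are restricted to single-nucleotide,
#' two-allele variants; indels and multi-allelic records never enter the
#' container.
#'
#' @param dosage integer matrix, samples x loci, values in `{0, 1, 2, NA}`;
#'   rownames are sample ids.
#' @param loci data frame with columns `contig`, `pos`, `ref`, `alt`, one row
#'   per dosage column.
#' @param depth optional integer matrix of per-call read depths (same shape as
#'   `dosage`); defaults to all zero.
#' @param pl optional numeric array `samples x loci x 3` of phred-scaled
#'   genotype likelihoods, minimum 0 per called cell; `NA` where unavailable.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci, depth = NULL, pl = NULL) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  if (is.null(rownames(dosage))) stop("`dosage` must carry sample ids as rownames")
  loci <- as_tibble(loci)
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("`loci` must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(loci) != ncol(dosage)) stop("ncol(dosage) must equal nrow(loci)")
  if (nrow(loci) > 0) {
    if (any(nchar(loci$ref) != 1L) || any(nchar(loci$alt) != 1L)) {
      stop("loci must be single-nucleotide variants (ref and alt one base each)")
    }
    if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  }
  storage.mode(dosage) <- "integer"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(depth)) {
    depth <- matrix(0L, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  }
  storage.mode(depth) <- "integer"
  if (!all(dim(depth) == dim(dosage))) stop("`depth` must match `dosage` in shape")
  if (!is.null(pl)) {
    if (!is.array(pl) || length(dim(pl)) != 3L ||
        !all(dim(pl)[1:2] == dim(dosage)) || dim(pl)[3] != 3L) {
      stop("`pl` must be a samples x loci x 3 array")
    }
  }
  structure(
    list(
      dosage = dosage, depth = depth, pl = pl,
      loci = loci, samples = rownames(dosage)
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci (%s PL, %.1f%% missing)\n",
    n_samples(x), n_loci(x),
    if (is.null(x$pl)) "no" else "with",
    if (length(x$dosage)) 100 * mean(is.na(x$dosage)) else 0
  ))
  invisible(x)
}

#' Dimensions of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of sample ids or logical/integer index;
#'   `NULL` keeps all.
#' @param loci logical or integer index over loci; `NULL` keeps all.
#' @return A `genotype_matrix` with the selected rows/columns, order preserved.
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  si <- seq_along(gm$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  li <- seq_len(n_loci(gm))
  if (!is.null(loci)) li <- li[loci]
  genotype_matrix(
    dosage = gm$dosage[si, li, drop = FALSE],
    loci = gm$loci[li, , drop = FALSE],
    depth = gm$depth[si, li, drop = FALSE],
    pl = if (!is.null(gm$pl)) gm$pl[si, li, , drop = FALSE]
  )
}

#' Per-locus table of a genotype matrix as a tibble
#'
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return Long tibble with one row per sample x locus call.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(
    sample = rep(x$samples, times = n_loci(x)),
    contig = rep(x$loci$contig, each = n_samples(x)),
    pos = rep(x$loci$pos, each = n_samples(x)),
    dosage = as.vector(x$dosage),
    depth = as.vector(x$depth)
  )
}
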