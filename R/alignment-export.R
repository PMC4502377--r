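IUPAC_PAIR <- c(
  AC = "M", CA = "M", AG = "R", GA = "R", AT = "W", TA = "W",
  CG = "S", GC = "S", CT = "Y", TC = "Y", GT = "K", TG = "K"
)

#' Concatenated-SNP alignment from genotype calls
#'
#' Builds one character sequence per sample by concatenating the allele at
#' every locus, in matrix order. In `"homozygous"` mode a homozygous
#' reference call yields the reference base, homozygous alternate the
#' alternate base, and heterozygous or missing calls yield `N` -- the coding
#' used when only homozygous sites should inform tree topology. In `"iupac"`
#' mode heterozygotes become the two-base ambiguity code instead.
#'
#' @param gm a [genotype_matrix()].
#' @param mode `"homozygous"` (default) or `"iupac"`.
#' @return An object of class `snp_alignment`: named character vector of
#'   equal-length sequences, with the locus table as attribute `loci` and the
#'   mode as attribute `mode`.
#' @export
export_alignment <- function(gm, mode = c("homozygous", "iupac")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mode <- match.arg(mode)
  N <- n_samples(gm); L <- n_loci(gm)
  chars <- matrix("N", N, L)
  d <- gm$dosage
  ref <- matrix(gm$loci$ref, N, L, byrow = TRUE)
  alt <- matrix(gm$loci$alt, N, L, byrow = TRUE)
  chars[!is.na(d) & d == 0L] <- ref[!is.na(d) & d == 0L]
  chars[!is.na(d) & d == 2L] <- alt[!is.na(d) & d == 2L]
  if (mode == "iupac") {
    het <- !is.na(d) & d == 1L
    chars[het] <- IUPAC_PAIR[paste0(ref[het], alt[het])]
  }
  seqs <- apply(chars, 1, paste, collapse = "")
  names(seqs) <- gm$samples
  structure(seqs, loci = gm$loci, mode = mode, class = "snp_alignment")
}

#' @export
print.snp_alignment <- function(x, ...) {
  cat(sprintf(
    "<snp_alignment> %d sequences x %d sites (%s mode)\n",
    length(x), if (length(x)) nchar(x[[1]]) else 0L, attr(x, "mode")
  ))
  invisible(x)
}

#' Bootstrap-resample alignment columns
#'
#' Resamples sites with replacement (seeded) for feeding external tree
#' builders; tree search itself is out of scope.
#'
#' @param aln a [export_alignment()] result.
#' @param seed integer seed.
#' @return A `snp_alignment` of the same length with resampled columns.
#' @export
bootstrap_alignment <- function(aln, seed = 1) {
  L <- nchar(aln[[1]])
  idx <- withr::with_seed(seed, sample.int(L, L, replace = TRUE))
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  seqs <- apply(m[, idx, drop = FALSE], 1, paste, collapse = "")
  names(seqs) <- names(aln)
  structure(seqs, loci = attr(aln, "loci")[idx, ], mode = attr(aln, "mode"),
            class = "snp_alignment")
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param aln a [export_alignment()] result.
#' @param path output file.
#' @param format `"fasta"` or `"phylip"` (relaxed: full names, one space).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", names(aln)), unclass(aln)))
  } else {
    lines <- c(
      sprintf("%d %d", length(aln), nchar(aln[[1]])),
      paste(names(aln), unclass(aln))
    )
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an alignment written by [write_alignment()]
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return Named character vector of sequences.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    d <- ape::read.FASTA(path)
    seqs <- vapply(
      as.character(d), function(s) paste(toupper(s), collapse = ""), character(1)
    )
  } else {
    lines <- readLines(path)[-1]
    parts <- strsplit(lines, " +")
    seqs <- vapply(parts, `[`, character(1), 2)
    names(seqs) <- vapply(parts, `[`, character(1), 1)
  }
  seqs
}

#' Pairwise p-distances between aligned sequences
#'
#' Proportion of mismatching sites over positions where both sequences carry
#' an unambiguous base (`A`, `C`, `G` or `T`); `N` and ambiguity codes are
#' ignored. Pairs with no comparable site get `NA` and are flagged.
#'
#' @param aln a [export_alignment()] result (or named character vector).
#' @return Symmetric numeric matrix of distances in `[0, 1]` with zero
#'   diagonal; attribute `undefined_pairs` lists pairs with no comparable
#'   sites.
#' @export
pairwise_distances <- function(aln) {
  seqs <- unclass(aln)
  if (length(seqs) < 2) stop("need at least two sequences")
  m <- do.call(rbind, strsplit(seqs, ""))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  undef <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        undef[[length(undef) + 1L]] <- c(names(seqs)[i], names(seqs)[j])
      } else {
        d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
      }
    }
  }
  attr(d, "undefined_pairs") <- undef
  d
}
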