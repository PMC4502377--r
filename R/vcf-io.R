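#' Write a genotype matrix to a VCF 4.2 file
#'
#' Emits a plain-text multi-sample VCF with `GT:DP:PL` genotype fields.
#' Missing calls are written `./.`; when no PL triple is available the PL
#' field is `.`. Output is deterministic given the matrix, so identical
#' simulations produce byte-identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))

  N <- n_samples(gm); L <- n_loci(gm)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=palmpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      gm$samples
    ), collapse = "\t")
  )
  writeLines(header, con, sep = "\n")
  if (L == 0) return(invisible(path))

  gt <- matrix("./.", N, L)
  ok <- !is.na(gm$dosage)
  gt[ok] <- c("0/0", "0/1", "1/1")[gm$dosage[ok] + 1L]
  if (is.null(gm$pl)) {
    pl_str <- matrix(".", N, L)
  } else {
    pl_str <- matrix(
      paste(gm$pl[, , 1], gm$pl[, , 2], gm$pl[, , 3], sep = ","), N, L
    )
    pl_str[is.na(gm$pl[, , 1])] <- "."
  }
  cells <- matrix(
    paste(gt, gm$depth, pl_str, sep = ":"), N, L
  )
  body <- paste(
    gm$loci$contig, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
    ".", "PASS", ".", "GT:DP:PL",
    apply(cells, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (plain or gzipped) and keeps only biallelic single-nucleotide
#' variants: indels and multi-allelic records are dropped and counted in the
#' `dropped` attribute. Per-call `DP` and `PL` are read when present; absent
#' fields become depth 0 / PL unavailable.
#'
#' @param path VCF file path.
#' @return A [genotype_matrix()] with attribute `dropped`, a tibble of
#'   per-reason drop counts (`multiallelic`, `indel`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) == 0) stop("VCF has no sample columns: ", path)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    gm <- genotype_matrix(
      matrix(integer(0), length(samples), 0, dimnames = list(samples, NULL)),
      tibble(contig = character(), pos = integer(),
             ref = character(), alt = character())
    )
    attr(gm, "dropped") <- tibble(reason = c("multiallelic", "indel"), n = c(0L, 0L))
    return(gm)
  }

  alt <- fix$ALT
  multi <- grepl(",", alt) | is.na(alt)
  indel <- !multi & (nchar(fix$REF) != 1L | nchar(alt) != 1L)
  keep <- !multi & !indel
  dropped <- tibble(
    reason = c("multiallelic", "indel"), n = c(sum(multi), sum(indel))
  )

  gt_raw <- v@gt[keep, -1, drop = FALSE]
  fmt <- v@gt[keep, 1]
  loci <- tibble(
    contig = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = alt[keep]
  )
  L <- nrow(loci); N <- length(samples)

  split_field <- function(i) {
    # returns L x N character matrix of the i-th FORMAT field per record
    out <- matrix(NA_character_, L, N)
    for (l in seq_len(L)) {
      keys <- strsplit(fmt[l], ":", fixed = TRUE)[[1]]
      parts <- strsplit(gt_raw[l, ], ":", fixed = TRUE)
      j <- match(i, keys)
      if (!is.na(j)) {
        out[l, ] <- vapply(
          parts, function(p) if (length(p) >= j) p[j] else NA_character_,
          character(1)
        )
      }
    }
    out
  }

  gt <- split_field("GT")
  dos <- matrix(NA_integer_, L, N)
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L

  dp <- suppressWarnings(matrix(as.integer(split_field("DP")), L, N))
  dp[is.na(dp)] <- 0L

  pl_chr <- split_field("PL")
  pl <- NULL
  if (any(!is.na(pl_chr) & pl_chr != ".")) {
    pl <- array(NA_real_, dim = c(N, L, 3))
    has <- !is.na(pl_chr) & pl_chr != "."
    vals <- strsplit(pl_chr[has], ",", fixed = TRUE)
    ok3 <- lengths(vals) == 3L
    idx <- which(has, arr.ind = TRUE)[ok3, , drop = FALSE]
    m <- matrix(suppressWarnings(as.numeric(unlist(vals[ok3]))), ncol = 3, byrow = TRUE)
    for (d in 1:3) pl[cbind(idx[, 2], idx[, 1], d)] <- m[, d]
  }

  gm <- genotype_matrix(
    dosage = t(dos) |> `dimnames<-`(list(samples, NULL)),
    loci = loci,
    depth = t(dp) |> `dimnames<-`(list(samples, NULL)),
    pl = pl
  )
  attr(gm, "dropped") <- dropped
  gm
}
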