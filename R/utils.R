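#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero, so `round_half_up(12.5)` is 13
#' and `round_half_up(-12.5)` is -13. Used by every reporting layer so that
#' printed percentages are reproducible from the printed counts.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded to `digits`.
#' @export
#' @examples
#' round_half_up(c(12.5, 4.25), c(0, 1))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format counts and percentages in report style
#'
#' Counts get thousands separators. Percentages are printed with one decimal
#' when below 10% and as integers otherwise, rounding half away from zero, so
#' e.g. 3219 of 67496 prints as "4.8%" while 23988 of 67496 prints as "36%".
#'
#' @param n integer count(s).
#' @param total denominator count(s).
#' @return character vector.
#' @export
#' @examples
#' fmt_count_pct(23988, 67496)
fmt_count <- function(n) formatC(n, format = "d", big.mark = ",")

#' @rdname fmt_count
#' @export
fmt_pct <- function(n, total) {
  p <- 100 * n / total
  ifelse(p < 10,
    sprintf("%.1f%%", round_half_up(p, 1)),
    sprintf("%d%%", as.integer(round_half_up(p, 0)))
  )
}

#' @rdname fmt_count
#' @export
fmt_count_pct <- function(n, total) {
  sprintf("%s (%s)", fmt_count(n), fmt_pct(n, total))
}

# contig:pos keys used to join locus tables
locus_key <- function(loci) paste(loci$contig, loci$pos, sep = ":")

# all permutations of 1..n as a list of integer vectors
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  idx <- 1L
  for (i in seq_len(n)) {
    for (p in sub) {
      q <- p + as.integer(p >= i)
      out[[idx]] <- c(i, q)
      idx <- idx + 1L
    }
  }
  out
}

# derive a per-run RNG seed below 2^31 from a master seed and run labels
derive_seed <- function(master, k, replicate) {
  as.integer((master %% 100000L) * 10007 + k * 1009 + replicate * 101) %% 2147483647L
}
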