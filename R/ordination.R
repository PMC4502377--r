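#' Encode genotypes for ordination
#'
#' Uses the 1/2/3 coding: homozygous reference = 1, heterozygous = 2,
#' homozygous alternate = 3. Missing calls are imputed with the column mean
#' of the observed codes; columns with no observed calls at all are dropped
#' with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return Numeric matrix (samples x retained loci) of codes.
#' @export
encode_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  x <- gm$dosage + 1
  all_miss <- colSums(!is.na(x)) == 0
  if (any(all_miss)) {
    warning(sum(all_miss), " all-missing locus/loci dropped before encoding")
    x <- x[, !all_miss, drop = FALSE]
  }
  cm <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- cm[idx[, 2]]
  storage.mode(x) <- "double"
  x
}

#' Principal components analysis of encoded genotypes
#'
#' Column-centred singular value decomposition (no unit-variance scaling) of
#' the 1/2/3 genotype codes. Variance fractions are squared singular values
#' over the total variance.
#'
#' @param x numeric matrix from [encode_genotypes()], samples in rows.
#' @param n_components number of components to keep (capped at `min(N, L)`).
#' @return An object of class `palm_pca`: `scores` (tibble, one row per
#'   sample) and `variance` (tibble: `component`, `variance_fraction`).
#' @export
run_pca <- function(x, n_components = 10) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  nc <- min(n_components, nrow(x) - 1, ncol(x))
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(fit$sdev^2)
  frac <- if (total > 0) fit$sdev^2 / total else rep(0, length(fit$sdev))
  nc <- min(nc, ncol(fit$x))
  scores <- as_tibble(fit$x[, seq_len(nc), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample = rownames(x)), scores)
  structure(
    list(
      scores = scores,
      variance = tibble(
        component = seq_len(nc),
        variance_fraction = frac[seq_len(nc)]
      )
    ),
    class = "palm_pca"
  )
}

#' @rdname run_pca
#' @param gm a [genotype_matrix()].
#' @param ... passed on to [run_pca()].
#' @export
pca_genotypes <- function(gm, ...) run_pca(encode_genotypes(gm), ...)

#' @export
print.palm_pca <- function(x, ...) {
  v <- x$variance$variance_fraction
  cat(sprintf(
    "<palm_pca> %d samples, %d components; PC1 %.1f%%, PC2 %s of variance\n",
    nrow(x$scores), nrow(x$variance), 100 * v[1],
    if (length(v) > 1) sprintf("%.1f%%", 100 * v[2]) else "-"
  ))
  invisible(x)
}

#' @export
tidy.palm_pca <- function(x, ...) {
  tidyr::pivot_longer(
    x$scores, -"sample", names_to = "component", values_to = "score"
  )
}

#' @export
glance.palm_pca <- function(x, ...) {
  tibble(
    n_components = nrow(x$variance),
    pc1_variance = x$variance$variance_fraction[1],
    pc2_variance = if (nrow(x$variance) > 1) x$variance$variance_fraction[2] else NA_real_
  )
}

#' @export
autoplot.palm_pca <- function(object, labels = NULL, ...) {
  d <- object$scores
  v <- object$variance$variance_fraction
  if (!is.null(labels)) {
    d <- dplyr::left_join(d, as_tibble(labels), by = "sample")
  }
  aes <- if (!is.null(labels)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$label)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * v[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * v[2])
    ) +
    ggplot2::theme_minimal()
}
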