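#' @export
tidy.admixture_run <- function(x, ...) {
  as_tibble(x$Q, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "proportion")
}

#' @export
glance.admixture_run <- function(x, ...) {
  post <- if (x$burn_in > 0) x$lnl[-seq_len(x$burn_in)] else x$lnl
  tibble(
    k = x$K, n_samples = nrow(x$Q),
    mean_lnl = mean(post), sd_lnl = sd(post),
    burn_in = x$burn_in, n_reps = x$n_reps
  )
}

#' @export
tidy.run_alignment <- function(x, ...) {
  as_tibble(x$consensus_q, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "proportion")
}

#' @export
glance.run_alignment <- function(x, ...) {
  tibble(
    n_runs = length(x$permutations), k = x$K,
    h_prime = x$h_prime, single_run = x$single_run
  )
}

#' @export
tidy.evanno_result <- function(x, ...) x$table

#' @export
glance.evanno_result <- function(x, ...) {
  tibble(best_k = x$best_k,
         max_delta_k = max(x$table$delta_k, na.rm = TRUE))
}

# stacked ancestry bars, samples ordered by first component
plot_ancestry <- function(q_long) {
  ord <- q_long |>
    dplyr::filter(.data$component == sort(unique(q_long$component))[1]) |>
    dplyr::arrange(dplyr::desc(.data$proportion))
  q_long |>
    dplyr::mutate(sample = factor(.data$sample, levels = ord$sample)) |>
    ggplot2::ggplot(ggplot2::aes(.data$sample, .data$proportion,
                                 fill = .data$component)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' @export
autoplot.admixture_run <- function(object, ...) plot_ancestry(tidy(object))

#' @export
autoplot.run_alignment <- function(object, ...) plot_ancestry(tidy(object))

#' @export
autoplot.evanno_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$k, .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Plot per-linkage-group enrichment folds
#'
#' @param enrichment a [lg_enrichment()] table.
#' @return A ggplot bar chart of fold enrichment per linkage group.
#' @export
plot_lg_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment, ggplot2::aes(.data$lg, .data$fold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "linkage group", y = "fold enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
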