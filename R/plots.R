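# ggplot2 views of the main result types.

#' Plot the realized-FDR curve of a permutation FDR result
#'
#' Estimated FDR as a step function of the candidate p threshold, with the
#' nominal level and the selected threshold marked.
#'
#' @param object A `linc_fdr` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.linc_fdr <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$threshold, y = .data$est_fdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$level, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$p_threshold,
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "candidate p threshold",
                  y = "estimated FDR",
                  title = sprintf("Permutation FDR (%s level, %d permutations)",
                                  object$unit, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result against its permutation null
#'
#' Histogram of the permuted fold-enrichment scores with the observed fold
#' marked.
#'
#' @param object A `linc_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.linc_enrichment <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fold)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$fold, colour = "red") +
    ggplot2::labs(x = "fold enrichment (permuted)",
                  y = "permutations",
                  title = sprintf("%s: observed fold %.2f, one-sided p %.3g",
                                  object$track, object$fold,
                                  object$p_one_sided)) +
    ggplot2::theme_minimal()
}

#' Plot the signed-distance distribution of cis-eQTLs
#'
#' @param x Either the output of [distance_histogram()] or a record tibble
#'   with a `distance` column.
#' @param window,n_bins Passed to [distance_histogram()] when `x` is a
#'   record tibble.
#' @return A ggplot of per-bin fractions.
#' @export
plot_distance_histogram <- function(x, window = 250000, n_bins = 25) {
  h <- if ("fraction" %in% names(x)) x else {
    distance_histogram(x, window = window, n_bins = n_bins)
  }
  ggplot2::ggplot(h, ggplot2::aes(x = .data$midpoint / 1000,
                                  y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "distance from probe center (kb)",
                  y = "fraction of cis-eQTLs") +
    ggplot2::theme_minimal()
}
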