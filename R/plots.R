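#' Plot a 96-class trinucleotide spectrum
#'
#' Bar chart of per-context counts faceted by substitution class and clone,
#' the standard signature-analysis spectrum layout.
#'
#' @param spectrum A [build_spectrum()] tibble.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  d <- dplyr::mutate(spectrum,
    substitution = substr(.data$context, 3, 5),
    flanks = paste0(substr(.data$context, 1, 1), ".",
                    substr(.data$context, 7, 7)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flanks, y = .data$count,
                                  fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(clone ~ substitution, scales = "free_y") +
    ggplot2::labs(x = "trinucleotide context", y = "SNV count") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn plot_spectrum Autoplot for signature sets: profile bars per
#'   signature.
#' @param object A `"signature_set"`.
#' @param ... Unused.
#' @export
autoplot.signature_set <- function(object, ...) {
  d <- as_tibble(object$profiles, rownames = "context") |>
    tidyr::pivot_longer(-"context", names_to = "signature",
                        values_to = "weight") |>
    dplyr::mutate(substitution = substr(.data$context, 3, 5),
                  context = factor(.data$context,
                                   levels = sbs96_classes()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$weight,
                                  fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~signature, ncol = 1) +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn plot_spectrum Autoplot for rate fits: burden vs age with the
#'   fitted line.
#' @export
autoplot.rate_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age,
                                  y = .data[[object$response]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$individual %||% NULL)) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope) +
    ggplot2::labs(x = "age (years)", y = object$response,
                  colour = "donor",
                  subtitle = sprintf("slope %.2f / year (p = %.2g)",
                                     object$slope, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_spectrum Autoplot for threshold derivations: culture
#'   time vs burden with the healthy band and old-clone regression.
#' @export
autoplot.threshold_result <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$old_clones, group = "old"),
    dplyr::mutate(object$young_clones, group = "young"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mutation_count,
                                       y = .data$days_in_culture,
                                       colour = .data$group)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$band[1], ymax = object$band[2],
                      alpha = 0.15) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$old_intercept,
                         slope = object$old_slope) +
    ggplot2::labs(x = "somatic mutations per clone",
                  y = "days in culture") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                 linetype = "dashed")
  }
  p
}

#' Plot enrichment/depletion results
#'
#' @param results Row-bound [enrichment_depletion()] tibbles.
#' @param alpha Significance mark threshold (default 0.05).
#' @return A ggplot object of log2 observed/expected ratios.
#' @export
plot_enrichment <- function(results, alpha = 0.05) {
  d <- dplyr::mutate(results,
                     sig = ifelse(.data$p < alpha, "#", ""),
                     log2_plot = ifelse(is.finite(.data$log2_ratio),
                                        .data$log2_ratio, NA_real_))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$log2_plot)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), vjust = -0.3) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "log2(observed / expected)") +
    ggplot2::theme_minimal()
}
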