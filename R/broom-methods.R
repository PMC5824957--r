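#' Tidy a rate fit
#'
#' @param x A [fit_rate()] result.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, p-value.
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "age"),
         estimate = c(x$intercept, x$slope),
         std.error = c(NA_real_, x$slope_se),
         p.value = c(NA_real_, x$p_value))
}

#' @rdname tidy.rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble(n_clones = x$n_clones, n_donors = x$n_donors, method = x$method,
         slope = x$slope, slope_se = x$slope_se, p.value = x$p_value)
}

#' Tidy a signature set
#'
#' @param x A `"signature_set"`.
#' @param ... Unused.
#' @return Long tibble of per-clone signature contributions (absolute and
#'   relative).
#' @export
tidy.signature_set <- function(x, ...) {
  rel <- relative_contributions(x)
  as_tibble(x$contributions, rownames = "signature") |>
    tidyr::pivot_longer(-"signature", names_to = "clone",
                        values_to = "contribution") |>
    dplyr::left_join(
      as_tibble(rel, rownames = "signature") |>
        tidyr::pivot_longer(-"signature", names_to = "clone",
                            values_to = "relative"),
      by = c("signature", "clone"))
}

#' @rdname tidy.signature_set
#' @export
glance.signature_set <- function(x, ...) {
  tibble(kind = x$kind, n_signatures = ncol(x$profiles),
         n_clones = ncol(x$contributions),
         objective = x$objective %||% NA_real_)
}

#' Tidy a false-negative-rate estimate
#'
#' @param x An [estimate_fnr()] result.
#' @param ... Unused.
#' @return One-row tibble of counts and rates.
#' @export
tidy.fnr_result <- function(x, ...) {
  tibble(n_control_sites = x$n_control_sites,
         n_detected_in_window = x$n_detected_in_window,
         het_rate = x$het_rate, hom_rate = x$hom_rate,
         positive_prediction_rate = x$positive_prediction_rate,
         fnr = x$fnr)
}

#' Tidy a threshold derivation
#'
#' @param x A [derive_threshold()] result.
#' @param ... Unused.
#' @return Old clones with their healthy/diseased status.
#' @export
tidy.threshold_result <- function(x, ...) {
  as_tibble(x$old_clones)
}

#' @rdname tidy.threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  tibble(young_mean = x$young_mean, young_sd = x$young_sd,
         band_lower = x$band[1], band_upper = x$band[2],
         old_slope = x$old_slope, old_intercept = x$old_intercept,
         threshold = x$threshold)
}

#' Tidy a gene-set resampling null
#'
#' @param x A [disease_gene_null()] result.
#' @param ... Unused.
#' @return One-row tibble with observed count, null moments, Z and p.
#' @export
tidy.geneset_null <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, z_score = x$z_score, p = x$p,
         p_empirical = x$p_empirical)
}
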