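#' Robust mixed-model fit of mutation burden on age
#'
#' Fits a linear model of a per-clone response (mutation count, normalized
#' burden, or a signature contribution) on donor age, with a donor-level
#' random intercept and bounded-influence robust estimation: the mixed
#' model is re-fitted iteratively with Huber weights (tuning constant
#' 1.345) computed from the scaled residuals. With a single donor, or when
#' the mixed fit is degenerate, the fit falls back to robust simple
#' regression (with a warning).
#'
#' @param data Tibble with columns `age`, `individual` (donor id) and the
#'   response.
#' @param response Name of the response column (default
#'   `"mutation_count"`).
#' @param method `"robust_mixed"` (default), `"mixed"` (plain random
#'   intercept model) or `"robust_simple"` ([MASS::rlm]).
#' @param huber_c Huber tuning constant (default 1.345).
#' @param max_iter Reweighting iterations.
#' @return A list of class `"rate_fit"`: `slope` (response units per
#'   year), `intercept`, `slope_se`, `p_value`, `method` (the method
#'   actually used), `ranef` (per-donor random intercepts, mixed fits
#'   only), `n_clones`, `n_donors`, `data`, `response`.
#' @export
#' @examples
#' md <- tibble::tibble(individual = letters[1:5], age = c(20, 35, 50, 65, 80),
#'                      mutation_count = 100 + 13.1 * c(20, 35, 50, 65, 80))
#' fit_rate(md)$slope
fit_rate <- function(data, response = "mutation_count",
                     method = c("robust_mixed", "mixed", "robust_simple"),
                     huber_c = 1.345, max_iter = 20) {
  method <- match.arg(method)
  stopifnot(all(c("age", response) %in% names(data)))
  if (length(unique(data$age)) < 2) {
    stop("a single age value cannot identify a rate", call. = FALSE)
  }
  y <- data[[response]]
  n_donors <- if ("individual" %in% names(data)) {
    length(unique(data$individual))
  } else 1L
  used <- method
  if (method != "robust_simple" && n_donors < 2) {
    warning("fewer than 2 donors: falling back to robust simple regression")
    used <- "robust_simple"
  }

  if (used == "robust_simple") {
    fit <- MASS::rlm(y ~ age, data = data.frame(age = data$age, y = y),
                     k = huber_c, maxit = 100)
    sm <- summary(fit)$coefficients
    tval <- sm["age", "Value"] / sm["age", "Std. Error"]
    out <- list(slope = unname(coef(fit)["age"]),
                intercept = unname(coef(fit)["(Intercept)"]),
                slope_se = unname(sm["age", "Std. Error"]),
                p_value = 2 * pt(-abs(tval), df = nrow(data) - 2),
                ranef = NULL, model = fit)
  } else {
    df <- data.frame(age = data$age, y = y,
                     individual = factor(data$individual))
    w <- rep(1, nrow(df))
    fit <- NULL
    ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.nRE = "ignore")
    satterthwaite <- TRUE
    fit_one <- function(w) {
      # lmerTest's Satterthwaite machinery can fail on exactly singular
      # (noiseless) fits; fall back to plain lme4 with a t approximation.
      f <- tryCatch(
        suppressMessages(suppressWarnings(
          lmerTest::lmer(y ~ age + (1 | individual), data = df,
                         weights = w, REML = TRUE, control = ctrl))),
        error = function(e) NULL)
      if (is.null(f)) {
        satterthwaite <<- FALSE
        f <- suppressMessages(suppressWarnings(
          lme4::lmer(y ~ age + (1 | individual), data = df, weights = w,
                     REML = TRUE, control = ctrl)))
      }
      f
    }
    for (it in seq_len(if (used == "mixed") 1 else max_iter)) {
      fit <- fit_one(w)
      if (used == "mixed") break
      r <- resid(fit)
      s <- mad(r)
      if (s < 1e-8) break  # (near-)exact fit: weights stay at 1
      w_new <- pmin(1, huber_c / abs(r / s))
      if (max(abs(w_new - w)) < 1e-6) { w <- w_new; break }
      w <- w_new
    }
    est <- lme4::fixef(fit)
    sm <- tryCatch(coef(summary(fit)), error = function(e) NULL)
    if (is.null(sm)) {
      # degenerate (noiseless) fit: mixed-model vcov unavailable; take
      # dispersion from the weighted fixed-effect regression instead
      sm <- summary(lm(y ~ age, data = df, weights = w))$coefficients
      colnames(sm)[colnames(sm) == "Pr(>|t|)"] <- "Pr(>|t|)"
      satterthwaite <- FALSE
    }
    if (!"Pr(>|t|)" %in% colnames(sm)) {
      tval <- sm[, "Estimate"] / sm[, "Std. Error"]
      sm <- cbind(sm, "Pr(>|t|)" = 2 * pt(-abs(tval),
                                          df = max(1, nrow(df) - 2)))
    }
    re <- tryCatch(lme4::ranef(fit)$individual, error = function(e) NULL)
    out <- list(slope = unname(est["age"]),
                intercept = unname(est["(Intercept)"]),
                slope_se = unname(sm["age", "Std. Error"]),
                p_value = unname(sm["age", "Pr(>|t|)"]),
                ranef = if (!is.null(re)) {
                  tibble(individual = rownames(re), intercept = re[[1]])
                } else NULL,
                model = fit)
  }
  structure(c(out, list(method = used, n_clones = nrow(data),
                        n_donors = n_donors, data = data,
                        response = response)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> ", x$response, " ~ age (", x$method, "): slope ",
      signif(x$slope, 4), " +/- ", signif(x$slope_se, 3), " per year, p = ",
      signif(x$p_value, 3), " (", x$n_clones, " clones, ", x$n_donors,
      " donors)\n", sep = "")
  invisible(x)
}

#' Cell divisions per year implied by the mutation rate
#'
#' Divides the yearly somatic SNV rate by the per-division mutation rate
#' (2.5 SNVs per genome per division by default); 13.1 SNVs/year implies
#' 5.24 divisions/year. Reported to two decimals.
#'
#' @param yearly_rate SNVs per genome per year.
#' @param per_division_rate SNVs per genome per cell division (default 2.5).
#' @return Divisions per year, rounded to 2 decimals.
#' @export
#' @examples
#' divisions_per_year(13.1)
divisions_per_year <- function(yearly_rate, per_division_rate = 2.5) {
  if (any(per_division_rate <= 0)) {
    stop("per-division rate must be positive", call. = FALSE)
  }
  round(yearly_rate / per_division_rate, 2)
}

#' Derive the proliferation-compromising mutation threshold
#'
#' Defines the healthy band of culture times as the mean +/- SD of
#' `days_in_culture` among young clones, regresses days in culture on
#' mutation count among old clones (ordinary least squares), and takes the
#' mutation count at which the regression line crosses the band's upper
#' border as the threshold above which proliferation is compromised. Old
#' clones are partitioned into healthy (at or below threshold) and
#' diseased (above). When the old-clone slope is not positive, the
#' threshold is undefined (`NA`).
#'
#' @param metadata Tibble with `clone`, `group` (`young` / `old`),
#'   `days_in_culture`, `mutation_count`.
#' @param sd_type `"sample"` (n - 1 divisor, default) or `"population"`.
#' @return A list of class `"threshold_result"`: `young_mean`, `young_sd`,
#'   `band` (lower/upper), `old_slope`, `old_intercept`, `threshold`,
#'   `old_clones` (with `status` healthy/diseased).
#' @export
#' @examples
#' md <- tibble::tibble(
#'   clone = c("y1", "y2", "y3", "o1", "o2"),
#'   group = c("young", "young", "young", "old", "old"),
#'   days_in_culture = c(50, 52, 54, 45, 55),
#'   mutation_count = c(300, 320, 310, 500, 1500))
#' derive_threshold(md)$threshold
derive_threshold <- function(metadata, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  young <- dplyr::filter(metadata, .data$group == "young")
  old <- dplyr::arrange(dplyr::filter(metadata, .data$group == "old"),
                        .data$clone)
  if (nrow(young) == 0 || nrow(old) == 0) {
    stop("both young and old groups must be non-empty", call. = FALSE)
  }
  if (length(unique(old$mutation_count)) < 2) {
    stop("old group needs >= 2 distinct mutation counts", call. = FALSE)
  }
  m <- mean(young$days_in_culture)
  s <- sd(young$days_in_culture)
  if (sd_type == "population") {
    s <- s * sqrt((nrow(young) - 1) / nrow(young))
  }
  fit <- lm(days_in_culture ~ mutation_count, data = old)
  slope <- unname(coef(fit)["mutation_count"])
  intercept <- unname(coef(fit)["(Intercept)"])
  threshold <- if (is.finite(slope) && slope > 1e-10) {
    (m + s - intercept) / slope
  } else NA_real_
  old$status <- if (is.na(threshold)) NA_character_ else {
    ifelse(old$mutation_count > threshold, "diseased", "healthy")
  }
  structure(list(young_mean = m, young_sd = s, band = c(m - s, m + s),
                 old_slope = slope, old_intercept = intercept,
                 threshold = threshold, old_clones = old,
                 young_clones = young),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> healthy band ", signif(x$band[1], 4), "-",
      signif(x$band[2], 4), " days; threshold ",
      if (is.na(x$threshold)) "undefined" else signif(x$threshold, 5),
      " mutations\n", sep = "")
  invisible(x)
}

#' Aggregate per-variant deleteriousness scores into a global clone score
#'
#' Sums PHRED-like deleteriousness scores (e.g. CADD) over a clone's
#' mutations, optionally restricted to a region scope (such as the
#' expressed regions). Variants without a score are counted and excluded.
#'
#' @param catalog Mutation tibble with `clone`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param scores Tibble with `chrom`, `pos`, `ref`, `alt`, `score`.
#' @param scope Optional region tibble (`chrom`, `start`, `end`); only
#'   variants inside it contribute.
#' @return Tibble per clone: `global_score`, `n_scored`, `n_unscored`.
#' @export
aggregate_deleteriousness <- function(catalog, scores, scope = NULL) {
  x <- catalog
  if (!is.null(scope)) {
    x <- x[pos_in_regions(x$chrom, x$pos, scope), , drop = FALSE]
  }
  x <- dplyr::left_join(x, dplyr::select(scores, "chrom", "pos", "ref",
                                         "alt", "score"),
                        by = c("chrom", "pos", "ref", "alt"))
  x |>
    dplyr::group_by(.data$clone) |>
    dplyr::summarise(global_score = sum(.data$score, na.rm = TRUE),
                     n_scored = sum(!is.na(.data$score)),
                     n_unscored = sum(is.na(.data$score)),
                     .groups = "drop")
}

#' Convert a variant allele fraction to a cell fraction
#'
#' For a heterozygous variant in diploid cells, the fraction of cells
#' carrying the variant is twice its allele fraction (capped at 1): a
#' variant on 1.3% of alleles is carried by 2.6% of cells.
#'
#' @param vaf Variant allele fraction(s) in \[0, 1\].
#' @param ploidy Ploidy (default 2).
#' @return Cell fraction(s), capped at 1.
#' @export
#' @examples
#' allele_to_cell_fraction(0.013)
allele_to_cell_fraction <- function(vaf, ploidy = 2) {
  stopifnot(all(vaf >= 0), all(vaf <= 1), ploidy >= 1)
  pmin(1, ploidy * vaf)
}
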