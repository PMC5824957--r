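#' Pipeline configuration
#'
#' Assembles the options of the end-to-end analysis runner. The default
#' pipeline simulates its own cohort; point `callsets`/`metadata`/
#' `reference` at real inputs to skip simulation.
#'
#' @param sim A [sim_config()] used when simulating.
#' @param filter A [filter_params()].
#' @param thresholds A [fantom_thresholds()].
#' @param rank,n_restarts Signature-extraction options.
#' @param n_resamples Disease-gene null resamples.
#' @param cluster_starts k-means initializations for clone clustering.
#' @param fnr_correct Apply the FNR correction before the rate fit
#'   (default `FALSE`: the headline rate is fitted on observed counts).
#' @param seed Master seed propagated to every stochastic stage.
#' @param out_dir Output directory (`NULL` for no files).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), filter = filter_params(),
                            thresholds = fantom_thresholds(),
                            rank = 3, n_restarts = 10, n_resamples = 1e4,
                            cluster_starts = 1000, fnr_correct = FALSE,
                            seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full clone-based somatic mutation analysis
#'
#' Executes simulate -> filter -> false-negative-rate estimation ->
#' spectra -> signature extraction and refit -> clustering -> region
#' construction and enrichment -> aging inference (rate fit, divisions per
#' year, proliferation threshold), and returns a structured report with
#' one entry per stage. With an `out_dir`, per-stage TSVs and a JSON
#' report are written.
#'
#' @param config A [pipeline_config()].
#' @return The report list (class `"clonesoma_report"`), invisibly when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  sim <- config$sim
  sim$seed <- seed
  report <- list()

  reference <- simulate_reference(sim)
  cohort <- simulate_cohort(reference, sim, seed = seed + 1)
  report$simulate <- list(
    n_clones = nrow(cohort$metadata),
    n_donors = length(unique(cohort$metadata$individual)),
    n_candidates = nrow(cohort$callsets)
  )

  fp <- config$filter
  fp$blacklist <- fp$blacklist %||% reference$blacklist
  catalog <- filter_somatic(cohort$callsets, fp)
  acc <- accepted_catalog(catalog)
  report$filter <- list(
    n_candidates = nrow(catalog), n_accepted = nrow(acc),
    rejection = as.list(setNames(rejection_summary(catalog)$n_rejected,
                                 rejection_summary(catalog)$reason))
  )

  # FNR from the simulated germline heterozygotes as control sites:
  # a control passes when it reached the union callset (detected) with a
  # clone allele fraction inside the somatic window.
  het <- germline_controls(cohort)
  fnr <- estimate_fnr(het,
                      vaf_window = fp$vaf_window,
                      blood_vaf_max = fp$blood_vaf_max,
                      min_depth = fp$min_depth)
  report$fnr <- list(fnr = fnr$fnr,
                     positive_prediction_rate = fnr$positive_prediction_rate,
                     n_control_sites = fnr$n_control_sites)

  counts <- acc |>
    dplyr::count(.data$clone, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  if (!"SNV" %in% names(counts)) counts$SNV <- 0L
  if (!"indel" %in% names(counts)) counts$indel <- 0L
  md <- dplyr::left_join(cohort$metadata, counts, by = "clone") |>
    dplyr::mutate(
      SNV = dplyr::coalesce(.data$SNV, 0L),
      indel = dplyr::coalesce(.data$indel, 0L),
      mutation_count = if (config$fnr_correct) {
        correct_for_fnr(.data$SNV, fnr$fnr)
      } else .data$SNV,
      normalized_count = normalize_burden(.data$mutation_count,
                                          .data$callable_fraction),
      total_mutations = .data$SNV + .data$indel
    )
  report$burden <- list(
    snv_range = range(md$SNV),
    corrected_range = as.numeric(correct_for_fnr(range(md$SNV), fnr$fnr))
  )

  spectra <- build_spectrum(acc, reference)
  sig <- extract_signatures(spectra, rank = config$rank,
                            n_restarts = config$n_restarts,
                            seed = seed + 2)
  refit <- refit_to_reference(spectra, read_reference_signatures())
  clust <- cluster_clones(sig, n_starts = config$cluster_starts,
                          seed = seed + 3)
  trend <- signature_age_trend(sig$contributions, md)
  report$signatures <- list(
    rank = config$rank, objective = sig$objective,
    top_refit = names(sort(rowSums(refit$contributions),
                           decreasing = TRUE))[1:3],
    cluster_sizes = as.list(table(clust$clusters$cluster)),
    age_trend = as.list(setNames(trend$slope, trend$signature))
  )

  expr <- simulate_expression_table(reference, sim, seed = seed + 4)
  fantom <- build_fantom_regions(expr, config$thresholds, reference)
  acc_ann <- annotate_catalog(acc, reference)
  callable <- sum(reference$contig_lengths)
  enrich <- if (nrow(reference$exons) > 0) {
    enrichment_depletion(acc, reference$exons, callable, name = "exons")
  } else NULL
  load <- if (nrow(fantom) > 0) {
    regional_mutation_load(acc, fantom, md)
  } else NULL
  report$regions <- list(
    fantom_sets = nrow(fantom),
    exon_enrichment = if (!is.null(enrich)) {
      list(observed = enrich$observed, expected = enrich$expected,
           log2_ratio = enrich$log2_ratio, p = enrich$p)
    } else NULL
  )

  rate <- fit_rate(md, response = "normalized_count")
  thr <- derive_threshold(
    dplyr::mutate(md, mutation_count = .data$total_mutations))
  report$aging <- list(
    slope = rate$slope, slope_se = rate$slope_se, p = rate$p_value,
    method = rate$method,
    divisions_per_year = divisions_per_year(rate$slope),
    threshold = thr$threshold
  )

  out <- structure(list(report = report, metadata = md, catalog = catalog,
                        fnr = fnr, signatures = sig, refit = refit,
                        clusters = clust, fantom = fantom,
                        annotated = acc_ann, rate = rate, threshold = thr,
                        regional_load = load),
                   class = "clonesoma_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(md, file.path(config$out_dir, "metadata.tsv"))
    write_catalog(catalog, file.path(config$out_dir, "catalog.tsv"))
    readr::write_tsv(spectra, file.path(config$out_dir, "spectra.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Germline heterozygote control sites from a simulated cohort
#'
#' Joins the cohort's true germline het sites against the union callsets to
#' flag detection and attach clone read evidence, yielding the control
#' table [estimate_fnr()] consumes. Undetected sites carry zero alt reads
#' and a nominal passing depth so they count as misses rather than being
#' dropped by the control depth requirement.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Control tibble with `detected`, `clone_alt`, `clone_depth`.
#' @export
germline_controls <- function(cohort) {
  truth_germ <- dplyr::filter(cohort$truth, .data$origin == "germline")
  evidence <- cohort$callsets |>
    dplyr::mutate(clone_alt = .data$clone_alt_fwd + .data$clone_alt_rev,
                  detected = TRUE) |>
    dplyr::select("clone", "chrom", "pos", "alt", "clone_alt",
                  "clone_depth", "detected")
  dplyr::left_join(
    dplyr::select(truth_germ, "clone", "chrom", "pos", "alt"),
    evidence, by = c("clone", "chrom", "pos", "alt")
  ) |>
    dplyr::mutate(detected = dplyr::coalesce(.data$detected, FALSE),
                  clone_alt = dplyr::coalesce(.data$clone_alt, 0L),
                  clone_depth = dplyr::coalesce(.data$clone_depth, 9999L))
}

#' @export
print.clonesoma_report <- function(x, ...) {
  r <- x$report
  cat("<clonesoma_report>\n")
  cat("  clones: ", r$simulate$n_clones, " (", r$simulate$n_donors,
      " donors); accepted variants: ", r$filter$n_accepted, "/",
      r$filter$n_candidates, "\n", sep = "")
  cat("  FNR: ", signif(r$fnr$fnr, 3), "; rate: ",
      signif(r$aging$slope, 4), " /yr (p = ", signif(r$aging$p, 3),
      "); divisions/yr: ", r$aging$divisions_per_year, "\n", sep = "")
  invisible(x)
}
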