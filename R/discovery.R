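#' Somatic filter parameters
#'
#' Thresholds of the clone-versus-blood somatic discovery filter. Defaults
#' follow the published filter chain: clone variant allele fraction within
#' the closed window \[0.4, 0.6\] (so a fully clonal heterozygote passes and
#' subclonal culture-acquired variants at VAF <= 0.25 do not), blood
#' alternative-allele fraction strictly below 0.1, at least 15 reads in both
#' clone and blood, at most 1000 reads in the clone, alternative reads on
#' both strands, and exclusion of blacklist regions, sex chromosomes, and
#' variants recurring across individuals.
#'
#' @param vaf_window Closed clone-VAF acceptance interval.
#' @param blood_vaf_max Exclusive upper bound on blood alt fraction.
#' @param min_depth Minimum depth in clone and blood.
#' @param max_depth Maximum clone depth.
#' @param require_both_strands Require >= 1 alt read on each strand.
#' @param blacklist Tibble of problematic regions (`chrom`, `start`, `end`;
#'   0-based half-open), or `NULL`.
#' @param exclude_sex_chroms Drop chrX/chrY (and X/Y) candidates.
#' @return A list of class `"filter_params"`.
#' @export
filter_params <- function(vaf_window = c(0.4, 0.6),
                          blood_vaf_max = 0.1,
                          min_depth = 15,
                          max_depth = 1000,
                          require_both_strands = TRUE,
                          blacklist = NULL,
                          exclude_sex_chroms = TRUE) {
  stopifnot(length(vaf_window) == 2, vaf_window[1] <= vaf_window[2],
            all(vaf_window >= 0), all(vaf_window <= 1),
            blood_vaf_max >= 0, blood_vaf_max <= 1,
            min_depth >= 0, min_depth <= max_depth)
  structure(list(vaf_window = vaf_window, blood_vaf_max = blood_vaf_max,
                 min_depth = min_depth, max_depth = max_depth,
                 require_both_strands = require_both_strands,
                 blacklist = blacklist,
                 exclude_sex_chroms = exclude_sex_chroms),
            class = "filter_params")
}

#' Union of per-caller callsets
#'
#' Merges candidate variant lists produced by independent callers into a
#' single callset keyed on (individual, clone, chrom, pos, ref, alt),
#' retaining caller provenance. Read evidence is taken from the first
#' record carrying it. Together with the per-individual pooling of
#' positions across clones (see [interesting_positions()]) this reproduces
#' the union-of-callers candidate list the filter operates on.
#'
#' @param callsets A list of candidate tibbles, each with a `callers` column
#'   (single caller name or `;`-separated) or a `caller` column.
#' @return A tibble with merged `callers` provenance.
#' @export
union_callsets <- function(callsets) {
  stopifnot(is.list(callsets))
  callsets <- purrr::map(callsets, function(x) {
    if ("caller" %in% names(x) && !"callers" %in% names(x)) {
      x <- dplyr::rename(x, callers = "caller")
    }
    x
  })
  all <- dplyr::bind_rows(callsets)
  if (nrow(all) == 0) return(all)
  conflict <- all |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref) |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    stop("conflicting ref alleles at ", nrow(conflict),
         " position(s), e.g. ", conflict$chrom[1], ":", conflict$pos[1],
         call. = FALSE)
  }
  keys <- intersect(c("individual", "clone", "chrom", "pos", "ref", "alt",
                      "class"), names(all))
  all |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric), ~ .x[!is.na(.x)][1]),
      callers = paste(sort(unique(unlist(
        strsplit(stats::na.omit(.data$callers), ";", fixed = TRUE)))),
        collapse = ";"),
      .groups = "drop"
    )
}

#' Per-individual comprehensive position list
#'
#' Pools candidate positions across all clones of each individual, the
#' "interesting positions" at which every clone of that individual is
#' re-examined for read evidence.
#'
#' @param candidates Candidate tibble with `individual`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @return A tibble of distinct (individual, chrom, pos, ref, alt).
#' @export
interesting_positions <- function(candidates) {
  dplyr::distinct(candidates, .data$individual, .data$chrom, .data$pos,
                  .data$ref, .data$alt)
}

is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom)) %in% c("X", "Y")
}

# 1-based positions vs 0-based half-open intervals on the same contig set.
pos_in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1,
                                               regions$end))
  IRanges::overlapsAny(q, s)
}

#' Apply the somatic discovery filter chain
#'
#' Evaluates every candidate against the filter criteria in a fixed order
#' and records, for rejected candidates, the first criterion that failed.
#' Evaluation order: clone VAF window; blood VAF; minimum depth (clone and
#' blood); sex chromosomes; both-strand support; maximum clone depth;
#' blacklist; cross-individual recurrence. Accepted records form the
#' somatic catalog.
#'
#' @param candidates Candidate tibble (see [simulate_clone_trio()] /
#'   [read_callset()]): columns `individual`, `clone`, `chrom`, `pos`,
#'   `ref`, `alt`, `class`, `clone_alt_fwd`, `clone_alt_rev`, `clone_depth`,
#'   `blood_alt`, `blood_depth`.
#' @param params A [filter_params()] object.
#' @return The input tibble with added `clone_vaf`, `accepted` (logical) and
#'   `reason` (first failing criterion, `NA` when accepted), of class
#'   `somatic_catalog` (a tibble).
#' @export
#' @examples
#' x <- tibble::tibble(individual = "D1", clone = "c1", chrom = "chr1",
#'   pos = 100L, ref = "C", alt = "T", class = "SNV",
#'   clone_alt_fwd = 5L, clone_alt_rev = 5L, clone_depth = 20L,
#'   blood_alt = 0L, blood_depth = 30L)
#' filter_somatic(x, filter_params())
filter_somatic <- function(candidates, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  need <- c("chrom", "pos", "ref", "alt", "clone_alt_fwd", "clone_alt_rev",
            "clone_depth", "blood_alt", "blood_depth")
  missing <- setdiff(need, names(candidates))
  if (length(missing)) {
    stop("candidates lack required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(candidates$blood_depth))) {
    stop("blood read evidence is missing for some candidates; ",
         "the filter requires a matched blood bulk", call. = FALSE)
  }
  x <- dplyr::mutate(candidates,
    clone_alt = .data$clone_alt_fwd + .data$clone_alt_rev,
    clone_vaf = ifelse(.data$clone_depth > 0,
                       .data$clone_alt / .data$clone_depth, NA_real_)
  )
  blood_frac <- ifelse(x$blood_depth > 0, x$blood_alt / x$blood_depth, 0)

  recurrent <- rep(FALSE, nrow(x))
  if ("individual" %in% names(x)) {
    multi <- x |>
      dplyr::distinct(.data$individual, .data$chrom, .data$pos, .data$ref,
                      .data$alt) |>
      dplyr::count(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::filter(.data$n > 1)
    if (nrow(multi)) {
      key <- paste(x$chrom, x$pos, x$ref, x$alt)
      recurrent <- key %in% paste(multi$chrom, multi$pos, multi$ref,
                                  multi$alt)
    }
  }

  checks <- list(
    vaf_window = !is.na(x$clone_vaf) &
      x$clone_vaf >= params$vaf_window[1] &
      x$clone_vaf <= params$vaf_window[2],
    blood_vaf = blood_frac < params$blood_vaf_max,
    min_depth = x$clone_depth >= params$min_depth &
      x$blood_depth >= params$min_depth,
    sex_chrom = if (params$exclude_sex_chroms) !is_sex_chrom(x$chrom)
      else rep(TRUE, nrow(x)),
    strand = if (params$require_both_strands)
      x$clone_alt_fwd >= 1 & x$clone_alt_rev >= 1 else rep(TRUE, nrow(x)),
    max_depth = x$clone_depth <= params$max_depth,
    blacklist = !pos_in_regions(x$chrom, x$pos, params$blacklist),
    recurrent = !recurrent
  )
  reason <- rep(NA_character_, nrow(x))
  for (nm in rev(names(checks))) reason[!checks[[nm]]] <- nm
  x$accepted <- is.na(reason)
  x$reason <- reason
  class(x) <- c("somatic_catalog", class(x))
  x
}

#' Accepted records of a filtered catalog
#'
#' @param catalog A [filter_somatic()] result.
#' @return Tibble of accepted variants.
#' @export
accepted_catalog <- function(catalog) {
  dplyr::filter(catalog, .data$accepted)
}

#' Rejection-reason audit counts
#'
#' @param catalog A [filter_somatic()] result.
#' @return Tibble of counts per first-failing criterion; reasons partition
#'   the rejected candidates.
#' @export
rejection_summary <- function(catalog) {
  catalog |>
    dplyr::filter(!.data$accepted) |>
    dplyr::count(.data$reason, name = "n_rejected")
}

#' Estimate the discovery false negative rate from germline control sites
#'
#' The positive prediction rate of the pipeline is measured on germline
#' control sites: heterozygous SNVs are counted as recovered when they were
#' detected by at least one caller in the clone with an allele fraction
#' inside the somatic acceptance window, and homozygous SNVs are counted as
#' correctly handled when their blood minor-allele fraction falls below the
#' blood threshold. The false negative rate is one minus the combined
#' positive prediction rate (sites passing / total control sites); the two
#' components are also reported separately.
#'
#' @param het_controls Tibble of heterozygous control sites with columns
#'   `detected` (logical: called by >= 1 caller in the clone), `clone_alt`,
#'   `clone_depth`. Sites with clone depth below `min_depth` are dropped
#'   (the published control selection requires 15x).
#' @param hom_controls Optional tibble of homozygous control sites with
#'   columns `blood_minor`, `blood_depth`.
#' @param vaf_window,blood_vaf_max,min_depth Acceptance thresholds, as in
#'   [filter_params()].
#' @return A list of class `"fnr_result"` with counts, per-component rates,
#'   `positive_prediction_rate` and `fnr`.
#' @export
#' @examples
#' het <- tibble::tibble(detected = rep(c(TRUE, FALSE), c(59, 41)),
#'   clone_alt = rep(15L, 100), clone_depth = rep(30L, 100))
#' het$clone_alt[!het$detected] <- 5L
#' estimate_fnr(het)$fnr # 0.41
estimate_fnr <- function(het_controls, hom_controls = NULL,
                         vaf_window = c(0.4, 0.6), blood_vaf_max = 0.1,
                         min_depth = 15) {
  het <- dplyr::filter(het_controls, .data$clone_depth >= min_depth)
  n_het <- nrow(het)
  n_hom <- if (is.null(hom_controls)) 0L else nrow(hom_controls)
  if (n_het + n_hom == 0) {
    stop("no control sites: positive prediction rate undefined",
         call. = FALSE)
  }
  het_pass <- if (n_het) {
    vaf <- het$clone_alt / het$clone_depth
    sum(het$detected & vaf >= vaf_window[1] & vaf <= vaf_window[2])
  } else 0L
  hom_pass <- if (n_hom) {
    frac <- ifelse(hom_controls$blood_depth > 0,
                   hom_controls$blood_minor / hom_controls$blood_depth, 0)
    sum(frac < blood_vaf_max)
  } else 0L
  ppr <- (het_pass + hom_pass) / (n_het + n_hom)
  structure(list(
    n_control_sites = n_het + n_hom,
    n_detected_in_window = het_pass + hom_pass,
    n_het = n_het, n_het_pass = het_pass,
    n_hom = n_hom, n_hom_pass = hom_pass,
    het_rate = if (n_het) het_pass / n_het else NA_real_,
    hom_rate = if (n_hom) hom_pass / n_hom else NA_real_,
    positive_prediction_rate = ppr,
    fnr = 1 - ppr
  ), class = "fnr_result")
}

#' @export
print.fnr_result <- function(x, ...) {
  cat("<fnr_result> ", x$n_detected_in_window, "/", x$n_control_sites,
      " control sites recovered; PPR = ",
      signif(x$positive_prediction_rate, 4), ", FNR = ", signif(x$fnr, 4),
      "\n", sep = "")
  invisible(x)
}

#' Correct an observed mutation burden for the false negative rate
#'
#' Scales an observed count by `1 / (1 - fnr)` and floors the result, the
#' correction under which 209 and 1371 observed SNVs at a false negative
#' rate of 0.41 become 354 and 2323 estimated mutations per genome.
#'
#' @param observed Observed mutation count(s).
#' @param fnr False negative rate in \[0, 1).
#' @return Corrected integer count(s).
#' @export
#' @examples
#' correct_for_fnr(c(209, 1371), 0.41)
correct_for_fnr <- function(observed, fnr) {
  stopifnot(all(observed >= 0), fnr >= 0)
  if (any(fnr >= 1)) stop("fnr = 1 leaves the burden undefined",
                          call. = FALSE)
  floor(observed / (1 - fnr))
}

#' Normalize a burden to the callable genome fraction
#'
#' Divides a mutation count by the fraction of the autosomes covered by
#' sequencing (or by callable gigabases, for per-Gb rates).
#'
#' @param count Mutation count(s).
#' @param callable_fraction Fraction of the autosomes callable (0, 1\];
#'   pass callable gigabases instead to obtain mutations/Gb.
#' @return Normalized count(s).
#' @export
#' @examples
#' normalize_burden(500, 0.95)
normalize_burden <- function(count, callable_fraction) {
  if (any(callable_fraction <= 0)) {
    stop("`callable_fraction` must be positive", call. = FALSE)
  }
  count / callable_fraction
}
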