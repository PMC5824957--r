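#' Simulate a CAGE-style expression table over differentiation timepoints
#'
#' Emulates promoter/enhancer expression measurements across a myoblast to
#' myotube differentiation time course: candidate promoter peaks near each
#' gene's transcription start site and candidate enhancer intervals in
#' intergenic space, scored per timepoint and replicate. A fraction of
#' regions is expressed from day 0 ("basal"), a fraction switches on only at
#' later timepoints (so the "upon differentiation" set is non-empty), and
#' the rest stay silent.
#'
#' @param reference A [simulate_reference()] result (gene model required for
#'   promoter candidates).
#' @param config A [sim_config()] (only `seed` is used by default).
#' @param timepoints Number of timepoints (>= 2); timepoint 0 is the basal
#'   day-0 measurement.
#' @param n_enhancers Number of candidate enhancer intervals.
#' @param replicates Number of donor replicates per measurement.
#' @param p_basal,p_late Probabilities that a region is expressed from day 0,
#'   or only from a later timepoint.
#' @param seed Seed (defaults to `config$seed + 2`).
#'
#' @return A tibble with columns `region_id`, `type` (promoter/enhancer),
#'   `gene` (promoters only), `chrom`, `start`, `end`, `strand`,
#'   `timepoint`, `replicate`, `score`. Coordinates are 0-based half-open
#'   peak intervals (not yet padded).
#' @export
simulate_expression_table <- function(reference, config, timepoints = 8,
                                      n_enhancers = 12, replicates = 3,
                                      p_basal = 0.5, p_late = 0.3,
                                      seed = config$seed + 2) {
  stopifnot(inherits(reference, "sim_reference"), timepoints >= 2)
  with_seed(seed, {
    chrom <- names(reference$sequence)[1]
    L <- reference$contig_lengths[[chrom]]
    genes <- reference$genes
    proms <- if (nrow(genes) > 0) {
      tss <- ifelse(genes$strand == "+", genes$start, genes$end)
      tibble(
        region_id = paste0("p_", genes$gene_id), type = "promoter",
        gene = genes$gene_id, chrom = chrom,
        start = as.integer(pmax(0, tss - 50L)),
        end = as.integer(pmin(L, tss + 50L)),
        strand = genes$strand
      )
    } else {
      tibble(region_id = character(), type = character(), gene = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character())
    }
    enh <- if (n_enhancers > 0) {
      es <- sample.int(L - 200L, n_enhancers)
      tibble(
        region_id = sprintf("e_%03d", seq_len(n_enhancers)),
        type = "enhancer", gene = NA_character_, chrom = chrom,
        start = as.integer(es), end = as.integer(es + 200L),
        strand = "."
      )
    } else proms[0, ]
    regions <- dplyr::bind_rows(proms, enh)
    if (nrow(regions) == 0) return(regions)

    pattern <- sample(c("basal", "late", "off"), nrow(regions), replace = TRUE,
                      prob = c(p_basal, p_late, 1 - p_basal - p_late))
    onset <- ifelse(pattern == "basal", 0L,
                    ifelse(pattern == "late",
                           sample(seq_len(timepoints - 1L),
                                  nrow(regions), replace = TRUE), NA))
    regions$onset <- as.integer(onset)

    grid <- tidyr::expand_grid(regions,
                               timepoint = 0:(timepoints - 1L),
                               replicate = seq_len(replicates))
    thr <- ifelse(grid$type == "promoter", 30, 1)
    on <- !is.na(grid$onset) & grid$timepoint >= grid$onset
    score <- ifelse(on, thr * (1.5 + stats::rgamma(nrow(grid), 2, 1)),
                    thr * runif(nrow(grid), 0, 0.5))
    grid$score <- round(score, 3)
    dplyr::select(grid, -"onset")
  })
}
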