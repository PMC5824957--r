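#' Simulation configuration
#'
#' Collects the parameters of the clonal whole-genome-sequencing simulator.
#' Defaults describe the study design the analysis targets: 29 single
#' cell-derived clones from 7 donors aged 21--78 years, sequenced at an
#' average depth of 30x together with a blood bulk, with somatic single
#' nucleotide variants accumulating at 13.1 per genome per year of adult life.
#'
#' @param genome_length Length in bases of the synthetic autosome (>= 10 kb).
#' @param gc_content Fraction of G/C bases in the reference.
#' @param n_genes Number of non-overlapping gene models to place.
#' @param exons_per_gene,exon_length,intron_length Gene geometry in bases.
#' @param n_blacklist,blacklist_length Problematic-region intervals to place.
#' @param n_donors Number of donors.
#' @param ages Numeric vector of donor ages in years (length `n_donors`).
#' @param clones_per_donor Integer vector of clones per donor.
#' @param young_age_max Ages at or below this are labelled `"young"`.
#' @param yearly_rate Somatic SNVs per genome per year (fixed-effect slope).
#' @param intercept Somatic SNVs at age 0.
#' @param donor_sd Standard deviation (SNV count scale) of the Gaussian
#'   donor-level random effect added to the Poisson mean, truncated at 0.
#' @param indel_fraction Fraction of in-vivo somatic events that are indels.
#' @param signature_weights Per-clone mixing proportions over the generative
#'   signature profiles; a numeric vector summing to 1 (recycled to all
#'   clones) or a matrix with one column per clone.
#' @param n_germline_het Germline heterozygous sites per donor.
#' @param n_culture_mutations Culture-acquired variants per clone.
#' @param culture_division_p Geometric parameter for the division of origin of
#'   culture variants; division `k ~ 1 + Geom(p)`, variant allele fraction
#'   `2^-(k+1)` (0.25 at the first division).
#' @param depth_mean Mean sequencing depth (reads); per-site depths are
#'   Poisson around this in clone and bulk independently.
#' @param caller_sensitivity Probability that a true variant is present in the
#'   union callset of the three callers.
#' @param blood_contamination Fraction of blood cells carrying the clone
#'   lineage's in-vivo somatic variants (default 0).
#' @param error_rate Optional per-candidate rate of spurious callset entries
#'   (sequencing-error stress tests); default 0.
#' @param seed Integer seed controlling all simulator randomness.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 5e4, n_genes = 3, seed = 1)
#' cfg$yearly_rate
sim_config <- function(genome_length = 2e5,
                       gc_content = 0.41,
                       n_genes = 8,
                       exons_per_gene = 4,
                       exon_length = 300,
                       intron_length = 800,
                       n_blacklist = 3,
                       blacklist_length = 500,
                       n_donors = 7,
                       ages = c(21, 26, 31, 66, 71, 74, 78),
                       clones_per_donor = c(4, 4, 5, 4, 4, 4, 4),
                       young_age_max = 40,
                       yearly_rate = 13.1,
                       intercept = 50,
                       donor_sd = 50,
                       indel_fraction = 0.07,
                       signature_weights = c(0.5, 0.3, 0.2),
                       n_germline_het = 200,
                       n_culture_mutations = 30,
                       culture_division_p = 0.5,
                       depth_mean = 30,
                       caller_sensitivity = 0.8,
                       blood_contamination = 0,
                       error_rate = 0,
                       seed = 1L) {
  stopifnot(
    genome_length >= 1e4,
    gc_content >= 0, gc_content <= 1,
    n_genes >= 0,
    n_donors >= 1,
    length(ages) == n_donors,
    all(ages >= 0), all(ages <= 120),
    length(clones_per_donor) %in% c(1L, n_donors),
    all(clones_per_donor >= 1),
    yearly_rate >= 0, intercept >= 0, donor_sd >= 0,
    indel_fraction >= 0, indel_fraction <= 1,
    n_germline_het >= 0, n_culture_mutations >= 0,
    culture_division_p > 0, culture_division_p <= 1,
    depth_mean > 0,
    caller_sensitivity > 0, caller_sensitivity <= 1,
    blood_contamination >= 0, blood_contamination <= 1
  )
  if (is.matrix(signature_weights)) {
    ok <- all(abs(colSums(signature_weights) - 1) < 1e-8)
  } else {
    ok <- abs(sum(signature_weights) - 1) < 1e-8
  }
  if (!ok) stop("`signature_weights` must sum to 1 per clone", call. = FALSE)
  if (length(clones_per_donor) == 1L) {
    clones_per_donor <- rep(clones_per_donor, n_donors)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generative mutational-signature profiles for the simulator
#'
#' Three fixed probability vectors over the 96 trinucleotide substitution
#' classes used to give simulated in-vivo somatic SNVs a signature-structured
#' spectrum: a clock-like profile concentrated on C>T at NpCpG sites, a flat
#' profile spread over all classes, and a C>A-rich profile of the kind
#' associated with oxidative damage and cell culture. These are synthetic
#' constructions, not published reference signatures.
#'
#' @return A 96 x 3 matrix with columns summing to 1, rownames from
#'   [sbs96_classes()].
#' @export
generative_signatures <- function() {
  cls <- sbs96_classes()
  p1 <- rep(0.1, 96)
  p1[grepl("\\[C>T\\]G", cls)] <- 12          # clock-like: C>T at CpG
  p1[grepl("\\[C>T\\]", cls) & !grepl("\\[C>T\\]G", cls)] <- 2
  p2 <- rep(1, 96)                            # flat, weakly structured
  p2[grepl("\\[T>C\\]", cls)] <- 1.8
  p3 <- rep(0.05, 96)
  p3[grepl("\\[C>A\\]", cls)] <- 4            # C>A rich
  p3[grepl("T\\[C>A\\]T", cls)] <- 12
  m <- cbind(clock = p1, flat = p2, c_to_a = p3)
  rownames(m) <- cls
  sweep(m, 2, colSums(m), "/")
}
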