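#' Variant allele fraction of a culture-acquired mutation
#'
#' Under a neutral synchronous binary expansion of the clone, a mutation
#' arising in one daughter cell at division `k` is carried by a cell fraction
#' `2^-k` and, for a heterozygous diploid site, observed at allele fraction
#' `2^-(k + 1)`: a first-division mutation has VAF 0.25.
#'
#' @param k Division of origin (integer >= 1); vectorised.
#' @return Expected variant allele fraction(s).
#' @export
#' @examples
#' culture_vaf(1) # 0.25
culture_vaf <- function(k) {
  stopifnot(all(k >= 1))
  2^-(k + 1)
}

caller_names <- c("HaplotypeCaller", "MuTect2", "FermiKit")

# Random non-empty subset of the three callers, as "A;B" strings.
draw_callers <- function(n, p = 0.8) {
  if (n == 0) return(character(0))
  m <- matrix(runif(3 * n) < p, nrow = n)
  none <- !rowSums(m)
  if (any(none)) m[cbind(which(none), sample.int(3, sum(none), TRUE))] <- TRUE
  apply(m, 1, function(r) paste(caller_names[r], collapse = ";"))
}

# Draw clone + blood read evidence for a variant table with true VAFs.
draw_reads <- function(df, depth_mean, blood_vaf) {
  n <- nrow(df)
  clone_depth <- rpois(n, depth_mean)
  clone_alt <- rbinom(n, clone_depth, df$true_vaf)
  alt_fwd <- rbinom(n, clone_alt, 0.5)
  ref_fwd <- rbinom(n, clone_depth - clone_alt, 0.5)
  blood_depth <- rpois(n, depth_mean)
  blood_alt <- rbinom(n, blood_depth, blood_vaf)
  dplyr::mutate(df,
    clone_alt_fwd = alt_fwd,
    clone_alt_rev = clone_alt - alt_fwd,
    clone_ref_fwd = ref_fwd,
    clone_ref_rev = clone_depth - clone_alt - ref_fwd,
    clone_depth = clone_depth,
    blood_alt = blood_alt,
    blood_depth = blood_depth
  )
}

base_at <- function(sequence, chrom, pos) {
  substring(sequence[[chrom]], pos, pos)
}

# Sample `n` SNV positions whose collapsed context matches signature-drawn
# classes; returns chrom/pos/ref/alt/signature rows.
draw_signature_snvs <- function(reference, n, weights, profiles) {
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), signature = character()))
  }
  sig <- sample(colnames(profiles), n, replace = TRUE, prob = weights)
  cls <- vapply(sig, function(s) {
    sample(rownames(profiles), 1, prob = profiles[, s])
  }, character(1))
  ctx <- paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7))
  target <- substr(cls, 5, 5)
  chrom <- names(reference$sequence)[1]
  idx <- reference$context_index[[chrom]]
  pos <- integer(n)
  for (u in unique(ctx)) {
    w <- which(ctx == u)
    cand <- idx[[u]]
    if (is.null(cand) || length(cand) < length(w)) {
      stop("reference too short to host ", length(w),
           " SNVs in context ", u, call. = FALSE)
    }
    pos[w] <- sample(cand, length(w))
  }
  ref <- base_at(reference$sequence, chrom, pos)
  alt <- ifelse(ref %in% c("C", "T"), target, comp_base(target))
  tibble(chrom = chrom, pos = pos, ref = ref, alt = alt, signature = sig)
}

# Simple 1-bp indels at random positions (VCF left-anchored representation).
draw_indels <- function(reference, n) {
  chrom <- names(reference$sequence)[1]
  L <- reference$contig_lengths[[chrom]]
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character()))
  }
  pos <- sample(2:(L - 2L), n)
  del <- runif(n) < 0.5
  anchor <- base_at(reference$sequence, chrom, pos)
  nxt <- base_at(reference$sequence, chrom, pos + 1L)
  ins <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  tibble(
    chrom = chrom, pos = as.integer(pos),
    ref = ifelse(del, paste0(anchor, nxt), anchor),
    alt = ifelse(del, anchor, paste0(anchor, ins))
  )
}

draw_germline <- function(reference, n) {
  chrom <- names(reference$sequence)[1]
  L <- reference$contig_lengths[[chrom]]
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character()))
  }
  pos <- sort(sample(2:(L - 1L), n))
  ref <- base_at(reference$sequence, chrom, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Simulate the callset of one clone/blood trio
#'
#' Draws the three variant classes the discovery filter must separate --
#' germline heterozygotes (true VAF 0.5 in clone and blood), in-vivo somatic
#' variants (clone VAF 0.5, absent from blood), and culture-acquired variants
#' (clone VAF `2^-(k+1)` for division-of-origin `k`) -- then samples
#' per-site read evidence (Poisson depths, binomial allele and strand
#' counts) and caller drop-out, and returns both the union callset and the
#' generating truth set.
#'
#' The expected in-vivo somatic count is
#' `intercept + yearly_rate * age + donor_effect`, Poisson-distributed;
#' SNV trinucleotide contexts follow the configured signature mixture.
#'
#' @param reference A [simulate_reference()] result.
#' @param config A [sim_config()].
#' @param donor,clone Identifiers.
#' @param age Donor age in years (0--120).
#' @param germline Optional tibble of donor germline het sites
#'   (chrom/pos/ref/alt); drawn if `NULL`.
#' @param donor_effect Donor-level shift of the expected somatic count.
#' @param signature_weights Optional per-clone override of
#'   `config$signature_weights`.
#' @param seed Optional seed; when `NULL`, draws from the current RNG stream.
#'
#' @return A list with tibbles `callset` (detected candidates with read
#'   evidence and caller provenance) and `truth` (all variants with origin,
#'   true VAF, signature, division of origin).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 5e4, n_genes = 2, seed = 7)
#' ref <- simulate_reference(cfg)
#' trio <- simulate_clone_trio(ref, cfg, donor = "D1", clone = "D1c1",
#'                             age = 70, seed = 7)
#' table(trio$truth$origin)
simulate_clone_trio <- function(reference, config, donor, clone, age,
                                germline = NULL, donor_effect = 0,
                                signature_weights = NULL, seed = NULL) {
  stopifnot(inherits(reference, "sim_reference"),
            inherits(config, "sim_config"))
  if (age < 0 || age > 120) {
    stop("`age` must be within [0, 120]", call. = FALSE)
  }
  with_seed(seed, {
    profiles <- generative_signatures()
    weights <- signature_weights %||% config$signature_weights
    if (is.matrix(weights)) weights <- weights[, 1]

    if (is.null(germline)) germline <- draw_germline(reference,
                                                     config$n_germline_het)

    # yearly_rate is an SNV rate; indels ride on top so that they make up
    # indel_fraction of all in-vivo events in expectation.
    mu <- max(0, config$intercept + config$yearly_rate * age + donor_effect)
    n_snv <- rpois(1, mu)
    n_indel <- if (config$indel_fraction > 0) {
      rpois(1, mu * config$indel_fraction / (1 - config$indel_fraction))
    } else 0L

    invivo_snv <- draw_signature_snvs(reference, n_snv, weights, profiles)
    invivo_indel <- draw_indels(reference, n_indel)

    n_cult <- config$n_culture_mutations
    culture <- draw_germline(reference, n_cult)  # positions/alleles only
    culture$division <- if (n_cult > 0) {
      rgeom(n_cult, config$culture_division_p) + 1L
    } else integer(0)

    truth <- dplyr::bind_rows(
      dplyr::mutate(germline, class = "SNV", origin = "germline",
                    true_vaf = 0.5, signature = NA_character_,
                    division = NA_integer_),
      dplyr::mutate(invivo_snv, class = "SNV", origin = "invivo",
                    true_vaf = 0.5, division = NA_integer_),
      dplyr::mutate(invivo_indel, class = "indel", origin = "invivo",
                    true_vaf = 0.5, signature = NA_character_,
                    division = NA_integer_),
      dplyr::mutate(culture, class = "SNV", origin = "culture",
                    true_vaf = culture_vaf(.data$division),
                    signature = NA_character_)
    )
    truth <- dplyr::distinct(truth, .data$chrom, .data$pos,
                             .keep_all = TRUE)
    truth <- dplyr::mutate(truth, individual = donor, clone = clone,
                           .before = 1)

    blood_vaf <- dplyr::case_when(
      truth$origin == "germline" ~ 0.5,
      truth$origin == "invivo" ~ 0.5 * config$blood_contamination,
      TRUE ~ 0
    )
    reads <- draw_reads(truth, config$depth_mean, blood_vaf)
    detected <- runif(nrow(reads)) < config$caller_sensitivity
    callset <- reads[detected, , drop = FALSE]
    callset$callers <- draw_callers(nrow(callset))
    callset <- dplyr::select(callset, "individual", "clone", "chrom", "pos",
                             "ref", "alt", "class", dplyr::starts_with("clone_"),
                             "blood_alt", "blood_depth", "callers")
    list(callset = as_tibble(callset), truth = as_tibble(truth))
  })
}

#' Simulate a whole clone cohort
#'
#' Runs [simulate_clone_trio()] for every clone of every donor in the
#' configuration, sharing one germline het set and one Gaussian random
#' effect per donor, and assembles clone metadata (age, young/old group,
#' days in culture, callable autosome fraction, true burden).
#'
#' Days in culture are generated so that the proliferation-threshold
#' analysis is exercised: young clones draw from Normal(52, 2) days,
#' old clones from `40 + 0.012 * true burden` plus Normal(0, 1) noise.
#'
#' @param reference A [simulate_reference()] result.
#' @param config A [sim_config()].
#' @param seed Seed for the cohort draw (defaults to `config$seed + 1`).
#'
#' @return A list of class `"sim_cohort"` with tibbles `callsets`, `truth`,
#'   `metadata`, plus the `reference` and `config`.
#' @export
simulate_cohort <- function(reference, config, seed = config$seed + 1) {
  stopifnot(inherits(reference, "sim_reference"))
  with_seed(seed, {
    callsets <- list(); truths <- list(); meta <- list()
    for (d in seq_len(config$n_donors)) {
      donor <- sprintf("D%02d", d)
      age <- config$ages[d]
      eff <- rnorm(1, 0, config$donor_sd)
      germ <- draw_germline(reference, config$n_germline_het)
      for (k in seq_len(config$clones_per_donor[d])) {
        clone <- sprintf("%sc%d", donor, k)
        trio <- simulate_clone_trio(reference, config, donor, clone, age,
                                    germline = germ, donor_effect = eff)
        callsets[[clone]] <- trio$callset
        truths[[clone]] <- trio$truth
        n_snv <- sum(trio$truth$origin == "invivo" &
                       trio$truth$class == "SNV")
        n_indel <- sum(trio$truth$origin == "invivo" &
                         trio$truth$class == "indel")
        young <- age <= config$young_age_max
        days <- if (young) rnorm(1, 52, 2) else {
          40 + 0.012 * (n_snv + n_indel) + rnorm(1, 0, 1)
        }
        meta[[clone]] <- tibble(
          clone = clone, individual = donor, age = age,
          group = if (young) "young" else "old",
          days_in_culture = max(1, days),
          callable_fraction = runif(1, 0.93, 0.99),
          true_snv = n_snv, true_indel = n_indel
        )
      }
    }
    structure(list(
      callsets = dplyr::bind_rows(callsets),
      truth = dplyr::bind_rows(truths),
      metadata = dplyr::bind_rows(meta),
      reference = reference, config = config
    ), class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$metadata), " clones / ",
      length(unique(x$metadata$individual)), " donors; ",
      nrow(x$callsets), " callset records\n", sep = "")
  invisible(x)
}
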