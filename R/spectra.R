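#' Build 96-class trinucleotide substitution spectra
#'
#' Counts catalog SNVs into the 96 pyrimidine-collapsed trinucleotide
#' substitution classes per clone, using the 5' and 3' reference bases
#' flanking each mutated site. Substitutions from a purine reference base
#' are mapped to their pyrimidine-strand class with the context
#' reverse-complemented. Positions at contig edges (no flanking base) are
#' excluded and counted in the `n_excluded` attribute, with a warning.
#'
#' @param catalog Tibble of accepted SNVs with `clone`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`. Non-SNV rows (multi-base alleles, or a
#'   `class` column not equal to `"SNV"`) are dropped.
#' @param reference A `"sim_reference"` object, a named character vector of
#'   contig sequences, or a [Biostrings::DNAStringSet].
#' @return A tibble with columns `clone`, `context` (all 96 classes in
#'   canonical order per clone) and `count`; attribute `n_excluded`.
#' @export
#' @examples
#' ref <- c(chr1 = "AACGT")
#' cat <- tibble::tibble(clone = "c1", chrom = "chr1", pos = 3L,
#'                       ref = "C", alt = "T")
#' sp <- build_spectrum(cat, ref)
#' sp[sp$count > 0, ] # one A[C>T]G
build_spectrum <- function(catalog, reference) {
  seqs <- reference_sequences(reference)
  x <- catalog
  if ("class" %in% names(x)) x <- dplyr::filter(x, .data$class == "SNV")
  x <- dplyr::filter(x, nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  if (!"clone" %in% names(x)) x$clone <- "catalog"
  clones <- unique(catalog$clone %||% "catalog")
  if (nrow(x) > 0) clones <- unique(x$clone)

  lens <- vapply(seqs, nchar, integer(1))
  edge <- x$pos <= 1 | x$pos >= lens[x$chrom]
  if (any(edge)) {
    warning(sum(edge), " SNV(s) at contig edges excluded from the spectrum")
    x <- x[!edge, , drop = FALSE]
  }
  up <- substring(seqs[x$chrom], x$pos - 1L, x$pos - 1L)
  down <- substring(seqs[x$chrom], x$pos + 1L, x$pos + 1L)
  ref_obs <- substring(seqs[x$chrom], x$pos, x$pos)
  if (any(ref_obs != x$ref)) {
    stop("catalog ref allele disagrees with the reference sequence at ",
         sum(ref_obs != x$ref), " site(s)", call. = FALSE)
  }
  lab <- sbs96_label(x$ref, x$alt, up, down)
  cls <- sbs96_classes()
  out <- tidyr::expand_grid(clone = clones, context = cls) |>
    dplyr::left_join(
      tibble(clone = x$clone, context = lab) |>
        dplyr::count(.data$clone, .data$context, name = "count"),
      by = c("clone", "context")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  attr(out, "n_excluded") <- sum(edge)
  out
}

reference_sequences <- function(reference) {
  if (inherits(reference, "sim_reference")) return(reference$sequence)
  if (inherits(reference, "DNAStringSet")) {
    return(setNames(as.character(reference), names(reference)))
  }
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  stop("unsupported reference representation", call. = FALSE)
}

#' Spectrum tibble to 96 x n matrix
#'
#' @param spectrum A [build_spectrum()] result (long tibble).
#' @return Numeric matrix, 96 classes (rows, canonical order) by clones.
#' @export
spectrum_matrix <- function(spectrum) {
  cls <- sbs96_classes()
  wide <- tidyr::pivot_wider(spectrum, names_from = "clone",
                             values_from = "count")
  m <- as.matrix(wide[match(cls, wide$context), -1, drop = FALSE])
  rownames(m) <- cls
  m
}
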