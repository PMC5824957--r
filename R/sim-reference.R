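#' Simulate a reference genome with gene models and region sets
#'
#' Generates a synthetic autosome with a specified GC content, places
#' non-overlapping gene models (exons, introns, UTRs, strand, promoter
#' positions), and places a blacklist of problematic regions. All interval
#' coordinates are 0-based half-open; variant positions elsewhere in the
#' package are 1-based (VCF convention).
#'
#' A trinucleotide context index over the whole sequence is precomputed and
#' attached, so that downstream simulation can draw somatic SNV positions
#' matching signature-specified contexts.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `"sim_reference"` with elements `sequence` (named
#'   character vector of contig sequences), `contig_lengths`, `genes`,
#'   `exons`, `utr5`, `utr3`, `blacklist` (tibbles), `context_index`
#'   (positions per pyrimidine-collapsed trinucleotide), and `config`.
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(genome_length = 2e4, n_genes = 2))
#' ref$genes
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- as.integer(config$genome_length)
    gc <- config$gc_content
    seq <- paste(sample(c("A", "T", "G", "C"), L, replace = TRUE,
                        prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
                 collapse = "")
    chrom <- "chr1"

    gene_len <- config$exons_per_gene * config$exon_length +
      (config$exons_per_gene - 1) * config$intron_length
    genes <- exons <- utr5 <- utr3 <- tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character()
    )
    if (config$n_genes > 0) {
      block <- L %/% config$n_genes
      if (block < gene_len + 400) {
        stop("genome too short to place ", config$n_genes,
             " genes of length ", gene_len, call. = FALSE)
      }
      starts <- vapply(seq_len(config$n_genes), function(i) {
        lo <- (i - 1L) * block + 200L
        hi <- i * block - gene_len - 200L
        as.integer(sample(lo:hi, 1))
      }, integer(1))
      strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
      coding <- rep(TRUE, config$n_genes)
      if (config$n_genes >= 4) coding[seq(4, config$n_genes, by = 4)] <- FALSE
      genes <- tibble(
        gene_id = sprintf("G%03d", seq_len(config$n_genes)),
        chrom = chrom, start = starts, end = starts + gene_len,
        strand = strands, coding = coding
      )
      exons <- purrr::pmap_dfr(genes, function(gene_id, chrom, start, end,
                                               strand, coding) {
        off <- start + (seq_len(config$exons_per_gene) - 1L) *
          (config$exon_length + config$intron_length)
        tibble(gene_id = gene_id, chrom = chrom, start = as.integer(off),
               end = as.integer(off + config$exon_length), strand = strand,
               rank = seq_along(off))
      })
      # UTRs: 60 bp at the transcript ends, strand-aware, within the
      # terminal exons of coding genes.
      utr_len <- min(60L, config$exon_length %/% 3L)
      first_ex <- dplyr::filter(exons, .data$rank == 1)
      last_ex <- dplyr::filter(exons, .data$rank == config$exons_per_gene)
      mk_utr <- function(ex, five_prime) {
        up <- (ex$strand == "+") == five_prime
        tibble(
          gene_id = ex$gene_id, chrom = ex$chrom,
          start = ifelse(up, ex$start, ex$end - utr_len),
          end = ifelse(up, ex$start + utr_len, ex$end),
          strand = ex$strand
        )
      }
      coding_ids <- genes$gene_id[genes$coding]
      utr5 <- dplyr::bind_rows(
        mk_utr(dplyr::filter(first_ex, .data$strand == "+",
                             .data$gene_id %in% coding_ids), TRUE),
        mk_utr(dplyr::filter(last_ex, .data$strand == "-",
                             .data$gene_id %in% coding_ids), TRUE)
      )
      utr3 <- dplyr::bind_rows(
        mk_utr(dplyr::filter(last_ex, .data$strand == "+",
                             .data$gene_id %in% coding_ids), FALSE),
        mk_utr(dplyr::filter(first_ex, .data$strand == "-",
                             .data$gene_id %in% coding_ids), FALSE)
      )
      utr5$start <- as.integer(utr5$start); utr5$end <- as.integer(utr5$end)
      utr3$start <- as.integer(utr3$start); utr3$end <- as.integer(utr3$end)
    }

    blacklist <- tibble(chrom = character(), start = integer(),
                        end = integer())
    if (config$n_blacklist > 0) {
      bs <- sort(sample.int(L - config$blacklist_length,
                            config$n_blacklist))
      blacklist <- tibble(chrom = chrom, start = as.integer(bs),
                          end = as.integer(bs + config$blacklist_length))
    }

    structure(list(
      sequence = setNames(seq, chrom),
      contig_lengths = setNames(L, chrom),
      genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
      blacklist = blacklist,
      context_index = build_context_index(setNames(seq, chrom)),
      config = config
    ), class = "sim_reference")
  })
}

# Index positions (1-based, per contig) by pyrimidine-collapsed trinucleotide
# context of the central base.
build_context_index <- function(sequences) {
  idx <- list()
  for (chrom in names(sequences)) {
    s <- sequences[[chrom]]
    L <- nchar(s)
    if (L < 3) next
    p <- 2:(L - 1L)
    tri <- substring(s, p - 1L, p + 1L)
    mid <- substring(s, p, p)
    rc <- paste0(comp_base(substring(s, p + 1L, p + 1L)),
                 comp_base(mid),
                 comp_base(substring(s, p - 1L, p - 1L)))
    ctx <- ifelse(mid %in% c("C", "T"), tri, rc)
    keep <- grepl("^[ACGT]{3}$", ctx)
    sp <- split(p[keep], ctx[keep])
    idx[[chrom]] <- sp
  }
  idx
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference> ", sum(x$contig_lengths), " bp on ",
      length(x$contig_lengths), " contig(s); ", nrow(x$genes), " genes, ",
      nrow(x$blacklist), " blacklist intervals\n", sep = "")
  invisible(x)
}

#' Write a simulated reference to FASTA
#'
#' @param reference A `"sim_reference"` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  dna <- Biostrings::DNAStringSet(reference$sequence)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}
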