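#' @keywords internal
#' @noRd
regions_to_granges <- function(regions) {
  if (nrow(regions) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- if ("strand" %in% names(regions)) {
    ifelse(regions$strand %in% c("+", "-"), regions$strand, "*")
  } else "*"
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1, regions$end),
                         strand = strand)
}

granges_to_tibble <- function(gr) {
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

region_width <- function(regions) sum(pmax(0, regions$end - regions$start))

#' Annotate catalog variants with genomic feature classes
#'
#' Assigns each variant exactly one class by fixed precedence:
#' coding exon > 3' UTR > 5' UTR > splice region > regulatory region >
#' intron > upstream gene > downstream gene > non-coding transcript exon >
#' intergenic. Splice regions are the 2 intronic bases adjacent to an exon
#' boundary; upstream/downstream flanks extend 5 kb from the gene body,
#' strand-aware.
#'
#' @param catalog Variant tibble with `chrom`, `pos` (1-based).
#' @param reference A `"sim_reference"` (gene model source) or a list with
#'   `genes`, `exons`, `utr5`, `utr3` tibbles (0-based half-open).
#' @param regulatory Optional regulatory-region tibble.
#' @param flank Upstream/downstream flank size in bases (default 5000).
#' @return The catalog with added `annotation` and `gene` columns.
#' @export
annotate_catalog <- function(catalog, reference, regulatory = NULL,
                             flank = 5000) {
  genes <- reference$genes
  exons <- reference$exons
  utr5 <- reference$utr5 %||% genes[0, ]
  utr3 <- reference$utr3 %||% genes[0, ]

  coding_ids <- if ("coding" %in% names(genes)) {
    genes$gene_id[genes$coding]
  } else genes$gene_id
  cod_ex <- dplyr::filter(exons, .data$gene_id %in% coding_ids)
  nc_ex <- dplyr::filter(exons, !.data$gene_id %in% coding_ids)

  # exon space minus UTR space = coding exon
  utr <- dplyr::bind_rows(utr5, utr3)
  splice <- dplyr::bind_rows(
    dplyr::mutate(exons, start = pmax(0L, .data$start - 2L),
                  end = .data$start + 2L),
    dplyr::mutate(exons, start = .data$end - 2L, end = .data$end + 2L)
  )
  introns <- genes  # gene body; lower precedence than exons so acts as intron
  up <- dplyr::transmute(genes, gene_id = .data$gene_id, chrom = .data$chrom,
    start = as.integer(ifelse(.data$strand == "+",
                              pmax(0, .data$start - flank), .data$end)),
    end = as.integer(ifelse(.data$strand == "+", .data$start,
                            .data$end + flank)))
  down <- dplyr::transmute(genes, gene_id = .data$gene_id,
    chrom = .data$chrom,
    start = as.integer(ifelse(.data$strand == "+", .data$end,
                              pmax(0, .data$start - flank))),
    end = as.integer(ifelse(.data$strand == "+", .data$end + flank,
                            .data$start)))

  layers <- list(
    exon = cod_ex, `3'UTR` = utr3, `5'UTR` = utr5, `splice region` = splice,
    `regulatory region` = regulatory %||% genes[0, ],
    intron = introns, `upstream gene` = up, `downstream gene` = down,
    `non-coding transcript exon` = nc_ex
  )
  # UTRs outrank plain exon space at the same positions: evaluate UTR first
  # within exons by removing UTR space from the coding-exon layer.
  ann <- rep("intergenic", nrow(catalog))
  gene <- rep(NA_character_, nrow(catalog))
  # exon space outranks UTR, but UTR intervals are subsets of exons;
  # subtract them so both classes are reachable.
  layers[["exon"]] <- subtract_regions(layers[["exon"]], utr)
  done <- rep(FALSE, nrow(catalog))
  for (nm in c("exon", "3'UTR", "5'UTR", "splice region",
               "regulatory region", "intron", "upstream gene",
               "downstream gene", "non-coding transcript exon")) {
    layer <- layers[[nm]]
    if (is.null(layer) || nrow(layer) == 0) next
    hit <- !done & pos_in_regions(catalog$chrom, catalog$pos, layer)
    if (any(hit)) {
      ann[hit] <- nm
      if ("gene_id" %in% names(layer)) {
        gene[hit] <- assign_gene(catalog$chrom[hit], catalog$pos[hit], layer)
      }
      done <- done | hit
    }
  }
  dplyr::mutate(catalog, annotation = ann, gene = gene)
}

# First overlapping gene_id per position (deterministic by layer row order).
assign_gene <- function(chrom, pos, layer) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  s <- regions_to_granges(layer)
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  layer$gene_id[hits]
}

# Genomic set difference on interval tibbles (strand-blind).
subtract_regions <- function(a, b) {
  if (is.null(a) || nrow(a) == 0) return(a)
  if (is.null(b) || nrow(b) == 0) return(a)
  ga <- regions_to_granges(a); GenomicRanges::strand(ga) <- "*"
  gb <- regions_to_granges(b); GenomicRanges::strand(gb) <- "*"
  res <- GenomicRanges::setdiff(ga, GenomicRanges::reduce(gb))
  out <- granges_to_tibble(res)
  if ("gene_id" %in% names(a)) {
    out$gene_id <- assign_gene(out$chrom, out$start + 1L, a)
  }
  out
}

#' Per-clone annotation percentage table
#'
#' @param catalog An [annotate_catalog()] result.
#' @return Tibble of per-clone class percentages (rows sum to 100).
#' @export
annotation_summary <- function(catalog) {
  catalog |>
    dplyr::count(.data$clone, .data$annotation) |>
    dplyr::group_by(.data$clone) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Observed/expected mutation enrichment-depletion test
#'
#' Compares the number of catalog mutations falling in a region set with the
#' count expected under uniform mutation opportunity over the callable
#' genome (`expected = total * surveyed_length / callable_length`), and
#' tests the deviation with a one-sided exact binomial test. With
#' `direction = "auto"` the tail follows the observed deviation (lower tail
#' when observed < expected); `"less"` and `"greater"` fix the tail.
#'
#' @param catalog Mutation tibble with `chrom`, `pos` (1-based); pass
#'   accepted variants only.
#' @param regions Region tibble (`chrom`, `start`, `end`; 0-based
#'   half-open). Overlapping intervals are reduced before measuring.
#' @param callable_length Callable genome size in bases.
#' @param name Region-set label for the output row.
#' @param direction Tail choice (see above).
#' @return One-row tibble: `region`, `surveyed_length`, `observed`,
#'   `expected`, `log2_ratio` (`-Inf` when observed is 0), `p`.
#' @export
#' @examples
#' cat <- tibble::tibble(chrom = "chr1", pos = c(5L, 15L))
#' reg <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
#' enrichment_depletion(cat, reg, callable_length = 100)
enrichment_depletion <- function(catalog, regions, callable_length,
                                 name = "region",
                                 direction = c("auto", "less", "greater")) {
  direction <- match.arg(direction)
  if (callable_length <= 0) stop("callable_length must be > 0",
                                 call. = FALSE)
  red <- granges_to_tibble(GenomicRanges::reduce(
    regions_to_granges(regions)))
  surveyed <- region_width(red)
  if (surveyed <= 0) stop("region surveyed length is 0", call. = FALSE)
  total <- nrow(catalog)
  observed <- sum(pos_in_regions(catalog$chrom, catalog$pos, red))
  p_hit <- surveyed / callable_length
  expected <- total * p_hit
  dir <- switch(direction,
                auto = if (observed < expected) "less" else "greater",
                direction)
  p <- if (dir == "less") pbinom(observed, total, p_hit)
       else pbinom(observed - 1, total, p_hit, lower.tail = FALSE)
  tibble(region = name, surveyed_length = surveyed, observed = observed,
         expected = expected,
         log2_ratio = ifelse(observed == 0, -Inf,
                             log2(observed / expected)),
         direction = dir, p = p)
}

#' FANTOM-style region-building thresholds
#'
#' @param enhancer_min_score Minimum enhancer expression score (default 1).
#' @param enhancer_pad Symmetric enhancer padding in bp (default 100).
#' @param promoter_min_score Minimum promoter expression score (default 30).
#' @param promoter_upstream,promoter_downstream Strand-aware promoter
#'   window in bp (defaults 860 upstream, 100 downstream of the peak).
#' @param replicates_required Replicates that must pass (default 1).
#' @return A list of class `"fantom_thresholds"`.
#' @export
fantom_thresholds <- function(enhancer_min_score = 1, enhancer_pad = 100,
                              promoter_min_score = 30,
                              promoter_upstream = 860,
                              promoter_downstream = 100,
                              replicates_required = 1) {
  stopifnot(enhancer_pad >= 0, promoter_upstream >= 0,
            promoter_downstream >= 0, replicates_required >= 1)
  structure(as.list(environment()), class = "fantom_thresholds")
}

#' Build basal and upon-differentiation expressed region sets
#'
#' From a per-timepoint expression table, constructs the actively
#' transcribed enhancer, promoter and exon region sets at day 0 ("basal")
#' and those transcribed only after differentiation stimuli ("upon
#' differentiation" = union over all timepoints minus the basal genomic
#' space). Enhancers require a score at or above the enhancer threshold in
#' at least the required number of replicates and are padded symmetrically;
#' promoters require the promoter threshold and are extended by a
#' strand-aware asymmetric window (860 bp upstream, 100 bp downstream by
#' default); exons are all exons of genes owning an expressed promoter.
#' Where promoter and enhancer intervals overlap, the promoter wins
#' (enhancer space is trimmed). Basal and upon-differentiation sets are
#' disjoint by construction.
#'
#' @param expression A [simulate_expression_table()]-shaped tibble.
#' @param thresholds A [fantom_thresholds()] object.
#' @param reference Gene-model source (for exon lookup and contig bounds).
#' @return Tibble with columns `set` (`basal` / `upon_differentiation`),
#'   `type` (`enhancer` / `promoter` / `exon`), `chrom`, `start`, `end`.
#' @export
build_fantom_regions <- function(expression,
                                 thresholds = fantom_thresholds(),
                                 reference) {
  stopifnot(inherits(thresholds, "fantom_thresholds"))
  th <- thresholds
  empty <- tibble(set = character(), type = character(), chrom = character(),
                  start = integer(), end = integer())
  if (nrow(expression) == 0) return(empty)
  lens <- reference$contig_lengths

  expressed_at <- function(df, tp, min_score) {
    df |>
      dplyr::filter(.data$timepoint == tp, .data$score >= min_score) |>
      dplyr::count(.data$region_id) |>
      dplyr::filter(.data$n >= th$replicates_required) |>
      dplyr::pull(.data$region_id)
  }
  expressed_any <- function(df, min_score) {
    unique(unlist(lapply(unique(df$timepoint), expressed_at, df = df,
                         min_score = min_score)))
  }

  pad_enhancer <- function(reg) {
    dplyr::transmute(reg, chrom = .data$chrom,
      start = as.integer(pmax(0, .data$start - th$enhancer_pad)),
      end = as.integer(pmin(lens[.data$chrom], .data$end + th$enhancer_pad)))
  }
  pad_promoter <- function(reg) {
    if (nrow(reg) > 0 && any(!reg$strand %in% c("+", "-"))) {
      stop("promoter peak without strand: window undefined", call. = FALSE)
    }
    dplyr::transmute(reg, chrom = .data$chrom,
      start = as.integer(pmax(0, ifelse(.data$strand == "+",
        .data$start - th$promoter_upstream,
        .data$start - th$promoter_downstream))),
      end = as.integer(pmin(lens[.data$chrom], ifelse(.data$strand == "+",
        .data$end + th$promoter_downstream,
        .data$end + th$promoter_upstream))))
  }

  day0 <- min(expression$timepoint)
  peaks <- dplyr::distinct(expression, .data$region_id, .data$type,
                           .data$gene, .data$chrom, .data$start, .data$end,
                           .data$strand)
  sets <- list()
  for (ty in c("enhancer", "promoter")) {
    df <- dplyr::filter(expression, .data$type == ty)
    minsc <- if (ty == "enhancer") th$enhancer_min_score
             else th$promoter_min_score
    basal_ids <- expressed_at(df, day0, minsc)
    all_ids <- expressed_any(df, minsc)
    pk <- dplyr::filter(peaks, .data$type == ty)
    pad <- if (ty == "enhancer") pad_enhancer else pad_promoter
    basal_iv <- pad(dplyr::filter(pk, .data$region_id %in% basal_ids))
    all_iv <- pad(dplyr::filter(pk, .data$region_id %in% all_ids))
    basal_red <- granges_to_tibble(GenomicRanges::reduce(
      regions_to_granges(basal_iv)))
    upon <- subtract_regions(
      granges_to_tibble(GenomicRanges::reduce(regions_to_granges(all_iv))),
      basal_red)
    sets[[paste0("basal_", ty)]] <-
      dplyr::mutate(basal_red, set = "basal", type = ty)
    sets[[paste0("upon_", ty)]] <-
      dplyr::mutate(upon, set = "upon_differentiation", type = ty)

    if (ty == "promoter") {
      # exons of genes owning an expressed promoter
      gene_basal <- unique(stats::na.omit(
        pk$gene[pk$region_id %in% basal_ids]))
      gene_all <- unique(stats::na.omit(pk$gene[pk$region_id %in% all_ids]))
      ex <- reference$exons
      ex_basal <- granges_to_tibble(GenomicRanges::reduce(regions_to_granges(
        dplyr::filter(ex, .data$gene_id %in% gene_basal))))
      ex_all <- granges_to_tibble(GenomicRanges::reduce(regions_to_granges(
        dplyr::filter(ex, .data$gene_id %in% gene_all))))
      ex_upon <- subtract_regions(ex_all, ex_basal)
      sets[["basal_exon"]] <- dplyr::mutate(ex_basal, set = "basal",
                                            type = "exon")
      sets[["upon_exon"]] <- dplyr::mutate(ex_upon,
                                           set = "upon_differentiation",
                                           type = "exon")
    }
  }
  out <- dplyr::bind_rows(sets)
  if (nrow(out) == 0) return(empty)
  # promoter precedence over enhancers (within the pooled promoter space)
  prom_space <- dplyr::filter(out, .data$type == "promoter")
  out <- dplyr::bind_rows(
    out |>
      dplyr::filter(.data$type == "enhancer") |>
      dplyr::group_by(.data$set) |>
      dplyr::group_modify(~ subtract_regions(.x, prom_space)) |>
      dplyr::ungroup() |>
      dplyr::mutate(type = "enhancer"),
    dplyr::filter(out, .data$type != "enhancer")
  )
  out |>
    dplyr::filter(.data$end > .data$start) |>
    dplyr::select("set", "type", "chrom", "start", "end") |>
    dplyr::arrange(.data$set, .data$type, .data$chrom, .data$start)
}

#' Surveyed sizes of built region sets
#'
#' @param fantom A [build_fantom_regions()] result.
#' @return Tibble of total bases per (set, type).
#' @export
fantom_sizes <- function(fantom) {
  fantom |>
    dplyr::group_by(.data$set, .data$type) |>
    dplyr::summarise(surveyed_length = sum(.data$end - .data$start),
                     .groups = "drop")
}

#' Per-clone mutation load in region sets, by age group
#'
#' Counts SNVs + indels per clone in every (set, type) region set, reports
#' group means with standard errors and old/young fold changes, and runs a
#' two-sided t-test on per-clone totals over the expressed regions (basal
#' plus upon-differentiation).
#'
#' @param catalog Accepted mutation tibble with `clone`, `chrom`, `pos`.
#' @param fantom A [build_fantom_regions()] result (or any tibble with
#'   `set`, `type`, `chrom`, `start`, `end`).
#' @param metadata Clone metadata with `clone` and `group`
#'   (`young` / `old`).
#' @return A list of class `"regional_load"`: `per_clone`, `summary`
#'   (means, SEM, fold change), `t_test` (htest on expressed totals).
#' @export
regional_mutation_load <- function(catalog, fantom, metadata) {
  stopifnot(all(c("clone", "group") %in% names(metadata)))
  if (!nrow(metadata) || length(unique(metadata$group)) < 1) {
    stop("empty group assignment", call. = FALSE)
  }
  combos <- dplyr::distinct(fantom, .data$set, .data$type)
  per_clone <- tidyr::expand_grid(clone = sort(metadata$clone), combos) |>
    purrr::pmap_dfr(function(clone, set, type) {
      reg <- dplyr::filter(fantom, .data$set == !!set, .data$type == !!type)
      cat1 <- dplyr::filter(catalog, .data$clone == !!clone)
      tibble(clone = clone, set = set, type = type,
             n = sum(pos_in_regions(cat1$chrom, cat1$pos, reg)))
    }) |>
    dplyr::left_join(dplyr::select(metadata, "clone", "group"),
                     by = "clone")
  summary <- per_clone |>
    dplyr::group_by(.data$set, .data$type, .data$group) |>
    dplyr::summarise(mean = mean(.data$n),
                     sem = sd(.data$n) / sqrt(dplyr::n()),
                     .groups = "drop")
  fold <- summary |>
    dplyr::select(-"sem") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean") |>
    dplyr::mutate(fold_old_young = .data$old / .data$young)
  totals <- per_clone |>
    dplyr::group_by(.data$clone, .data$group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  tt <- if (length(unique(totals$group)) == 2 &&
            all(table(totals$group) >= 2)) {
    t.test(n ~ group, data = totals)
  } else NULL
  structure(list(per_clone = per_clone, summary = summary, fold = fold,
                 t_test = tt), class = "regional_load")
}

#' Gene-set mutation load
#'
#' Counts exonic catalog mutations whose gene belongs to a gene set and
#' reports the average number of mutations per gene per clone:
#' `count / (n_clones * n_genes)`. Gene symbols are case-normalized before
#' matching.
#'
#' @param catalog Annotated mutation tibble (needs a `gene` column).
#' @param gene_set Character vector of gene names.
#' @param n_clones Number of clones tested.
#' @return One-row tibble: `n_hits`, `n_clones`, `n_genes`,
#'   `avg_per_gene_per_clone`.
#' @export
gene_set_load <- function(catalog, gene_set, n_clones) {
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  hits <- sum(toupper(catalog$gene) %in% toupper(gene_set), na.rm = TRUE)
  tibble(n_hits = hits, n_clones = n_clones, n_genes = length(gene_set),
         avg_per_gene_per_clone = hits / (n_clones * length(gene_set)))
}

#' Extended gene regions (exons + introns + flanks)
#'
#' @param reference Gene-model source.
#' @param flank Flank size in bases (default 5000).
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
extended_gene_regions <- function(reference, flank = 5000) {
  genes <- reference$genes
  dplyr::transmute(genes, gene_id = .data$gene_id, chrom = .data$chrom,
                   start = as.integer(pmax(0, .data$start - flank)),
                   end = as.integer(.data$end + flank))
}

#' Disease-gene mutation-count null by length-weighted exon resampling
#'
#' Tests whether gene-attributed mutations hit a disease-gene set more
#' often than expected. The null resamples, `n_resamples` times, the same
#' number of exons as there are gene-attributed mutations, with
#' replacement and with probability proportional to exon length, and
#' counts how many sampled exons belong to disease genes. The empirical
#' count is compared against the null draws by Z-score and one-sided
#' p-value (normal approximation, enrichment direction), with an empirical
#' resampling p-value alongside.
#'
#' @param gene_hits Character vector: the gene attributed to each mutation
#'   (one entry per gene-annotated mutation, e.g. from extended-gene-region
#'   assignment).
#' @param exons Exon tibble with `gene_id`, `start`, `end`; zero-length
#'   exons are excluded.
#' @param disease_genes Character vector of disease gene ids.
#' @param n_resamples Number of resampling draws (default 1e4).
#' @param seed Seed.
#' @return A list of class `"geneset_null"`: `observed`, `null_mean`,
#'   `null_sd`, `z_score`, `p` (one-sided normal), `p_empirical`, `draws`.
#' @export
disease_gene_null <- function(gene_hits, exons, disease_genes,
                              n_resamples = 1e4, seed = NULL) {
  ex <- dplyr::filter(exons, .data$end > .data$start)
  if (nrow(ex) == 0) stop("no exons with positive length", call. = FALSE)
  n_mut <- length(gene_hits)
  observed <- sum(gene_hits %in% disease_genes)
  w <- ex$end - ex$start
  in_set <- ex$gene_id %in% disease_genes
  with_seed(seed, {
    draws <- vapply(seq_len(n_resamples), function(i) {
      sum(in_set[sample.int(nrow(ex), n_mut, replace = TRUE, prob = w)])
    }, numeric(1))
    mu <- mean(draws); s <- sd(draws)
    z <- if (s > 0) (observed - mu) / s else NA_real_
    structure(list(
      observed = observed, n_mutations = n_mut,
      null_mean = mu, null_sd = s, z_score = z,
      p = if (is.na(z)) NA_real_ else pnorm(z, lower.tail = FALSE),
      p_empirical = (sum(draws >= observed) + 1) / (n_resamples + 1),
      draws = draws
    ), class = "geneset_null")
  })
}

#' @export
print.geneset_null <- function(x, ...) {
  cat("<geneset_null> observed ", x$observed, " of ", x$n_mutations,
      " mutations in set; null ", signif(x$null_mean, 4), " +/- ",
      signif(x$null_sd, 4), "; Z = ", signif(x$z_score, 4), ", p = ",
      signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Non-synonymous / synonymous ratio of coding SNVs
#'
#' Maps coding SNVs to codons using the gene model (concatenated coding
#' exon sequence, strand-aware, frame from the coding start), classifies
#' each substitution as synonymous or non-synonymous under the standard
#' genetic code (stop-gains count as non-synonymous), and reports the
#' per-clone NS/S ratio. When young/old groups are supplied the ratios are
#' compared with a two-sided Mann-Whitney test.
#'
#' @param catalog SNV tibble with `clone`, `chrom`, `pos`, `ref`, `alt`.
#' @param reference A `"sim_reference"` (sequence + gene model).
#' @param metadata Optional metadata with `clone`, `group` for the group
#'   comparison.
#' @return A list of class `"nss_result"`: `per_variant` (classified coding
#'   SNVs), `per_clone` (NS, S, `ratio`; `NA` when S = 0), `test`
#'   (Mann-Whitney htest or `NULL`).
#' @export
ns_s_ratio <- function(catalog, reference, metadata = NULL) {
  cds <- cds_table(reference)
  x <- catalog
  if ("class" %in% names(x)) x <- dplyr::filter(x, .data$class == "SNV")
  x <- dplyr::filter(x, nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  hit <- dplyr::inner_join(x, cds, by = "chrom",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$pos > .data$start, .data$pos <= .data$end)
  if (nrow(hit) == 0) {
    per_clone <- tibble(clone = character(), NS = integer(), S = integer(),
                        ratio = double())
    return(structure(list(per_variant = hit, per_clone = per_clone,
                          test = NULL), class = "nss_result"))
  }
  code <- Biostrings::GENETIC_CODE
  cls <- purrr::pmap_chr(hit, function(...) {
    v <- list(...)
    cdspos <- if (v$strand == "+") v$cds_offset + (v$pos - v$start)
              else v$cds_offset + (v$end - v$pos + 1L)
    codon_i <- (cdspos - 1L) %/% 3L
    frame <- (cdspos - 1L) %% 3L
    cds_seq <- v$cds_seq
    if ((codon_i + 1L) * 3L > nchar(cds_seq)) return(NA_character_)
    codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    base <- if (v$strand == "+") v$alt else comp_base(v$alt)
    mut <- codon
    substr(mut, frame + 1L, frame + 1L) <- base
    aa0 <- code[[codon]]; aa1 <- code[[mut]]
    if (is.null(aa0) || is.null(aa1)) return(NA_character_)
    if (aa0 == aa1) "synonymous" else "non-synonymous"
  })
  hit$consequence <- cls
  hit <- dplyr::filter(hit, !is.na(.data$consequence))
  per_clone <- hit |>
    dplyr::count(.data$clone, .data$consequence) |>
    tidyr::pivot_wider(names_from = "consequence", values_from = "n",
                       values_fill = 0L)
  for (col in c("non-synonymous", "synonymous")) {
    if (!col %in% names(per_clone)) per_clone[[col]] <- 0L
  }
  per_clone <- per_clone |>
    dplyr::rename(NS = "non-synonymous", S = "synonymous") |>
    dplyr::mutate(ratio = ifelse(.data$S > 0, .data$NS / .data$S, NA_real_))
  test <- NULL
  if (!is.null(metadata)) {
    d <- dplyr::inner_join(per_clone, metadata, by = "clone") |>
      dplyr::filter(!is.na(.data$ratio))
    if (length(unique(d$group)) == 2) {
      test <- suppressWarnings(wilcox.test(ratio ~ group, data = d))
    }
  }
  structure(list(per_variant = hit, per_clone = per_clone, test = test),
            class = "nss_result")
}

# Coding-exon table with per-exon CDS offsets and the full CDS sequence.
cds_table <- function(reference) {
  genes <- reference$genes
  coding_ids <- if ("coding" %in% names(genes)) {
    genes$gene_id[genes$coding]
  } else genes$gene_id
  utr <- dplyr::bind_rows(reference$utr5 %||% genes[0, ],
                          reference$utr3 %||% genes[0, ])
  out <- list()
  for (g in coding_ids) {
    ex <- dplyr::filter(reference$exons, .data$gene_id == g)
    cds <- subtract_regions(ex, dplyr::filter(utr, .data$gene_id == g))
    if (nrow(cds) == 0) next
    strand <- ex$strand[1]
    cds <- dplyr::arrange(cds, .data$start)
    if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
    seqs <- substring(reference$sequence[cds$chrom], cds$start + 1L,
                      cds$end)
    if (strand == "-") seqs <- revcomp(seqs)
    full <- paste(seqs, collapse = "")
    widths <- cds$end - cds$start
    cds$cds_offset <- cumsum(dplyr::lag(widths, default = 0L))
    cds$strand <- strand
    cds$gene_id <- g
    cds$cds_seq <- full
    out[[g]] <- cds
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), strand = character(),
                  cds_offset = integer(), cds_seq = character()))
  }
  dplyr::bind_rows(out)
}
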