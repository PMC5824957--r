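test_that("annotation assigns classes by precedence and partitions", {
  ref <- small_reference(seed = 71)
  g <- ref$genes[1, ]
  ex <- ref$exons[ref$exons$gene_id == g$gene_id, ]
  mid_exon <- as.integer((ex$start[2] + ex$end[2]) / 2)  # non-UTR exon

  cat0 <- tibble::tibble(
    clone = "c1", chrom = "chr1",
    pos = c(mid_exon + 1L,                      # coding exon
            as.integer(ex$end[2] + 400L),       # intron interior
            as.integer(if (g$strand == "+") g$start - 3000L
                       else g$end + 3000L),     # 3 kb 5' of the gene
            5L))                                # far intergenic
  ann <- annotate_catalog(cat0, ref)
  expect_equal(ann$annotation[1], "exon")
  expect_equal(ann$annotation[2], "intron")
  expect_equal(ann$annotation[3], "upstream gene")
  expect_equal(ann$gene[1], g$gene_id)

  # percentages partition the catalog per clone
  cfg <- small_config(seed = 71)
  coh <- simulate_cohort(ref, cfg)
  acc <- accepted_catalog(filter_somatic(coh$callsets, filter_params()))
  anns <- annotate_catalog(acc, ref)
  expect_false(any(is.na(anns$annotation)))
  sums <- annotation_summary(anns) |>
    dplyr::group_by(clone) |>
    dplyr::summarise(total = sum(percent))
  expect_equal(sums$total, rep(100, nrow(sums)))
})

test_that("enrichment test matches the exact binomial worked example", {
  # 100 mutations, region 8% of callable genome, 2 observed
  catalog <- tibble::tibble(chrom = "chr1",
                            pos = c(1:2, 8001:8098 + 1L))
  region <- tibble::tibble(chrom = "chr1", start = 0L, end = 8000L)
  r <- enrichment_depletion(catalog, region, callable_length = 1e5)
  expect_equal(r$observed, 2)
  expect_equal(r$expected, 8)
  p_exact <- sum(choose(100, 0:2) * 0.08^(0:2) * 0.92^(100 - 0:2))
  expect_equal(r$p, p_exact, tolerance = 1e-10)
  expect_equal(r$p, 0.01127, tolerance = 1e-3)
  expect_equal(r$direction, "less")
})

test_that("whole-callable-genome region gives ratio 0; zero observed -Inf", {
  catalog <- tibble::tibble(chrom = "chr1", pos = sample.int(1000, 50))
  whole <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  r <- enrichment_depletion(catalog, whole, callable_length = 1000)
  expect_equal(r$observed, 50)
  expect_equal(r$expected, 50)
  expect_equal(r$log2_ratio, 0)

  off <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2500L)
  r0 <- enrichment_depletion(catalog, off, callable_length = 1e4)
  expect_equal(r0$observed, 0)
  expect_identical(r0$log2_ratio, -Inf)
  expect_error(enrichment_depletion(catalog, whole, 0), "callable")
})

test_that("fixed-direction p-values are uniform under uniform placement", {
  set.seed(19)
  L <- 1e5
  region <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  ps <- vapply(1:200, function(i) {
    cat_i <- tibble::tibble(chrom = "chr1", pos = sample.int(L, 2000))
    enrichment_depletion(cat_i, region, L, direction = "less")$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fantom region construction applies the published windows", {
  ref <- small_reference(seed = 73)
  lens <- ref$contig_lengths
  base <- tibble::tibble(
    region_id = c("e1", "p1", "p2"),
    type = c("enhancer", "promoter", "promoter"),
    gene = c(NA, ref$genes$gene_id[1], ref$genes$gene_id[2]),
    chrom = "chr1",
    start = c(1000L, 5000L, 20000L), end = c(1200L, 5100L, 20100L),
    strand = c(".", "+", "+"))
  expr <- tidyr::expand_grid(base, timepoint = 0:1, replicate = 1:2) |>
    dplyr::mutate(score = dplyr::case_when(
      region_id == "e1" ~ 1,       # at threshold: included
      region_id == "p1" ~ 35,      # expressed promoter
      region_id == "p2" ~ 29))     # below promoter threshold: excluded
  built <- build_fantom_regions(expr, fantom_thresholds(), ref)
  enh <- dplyr::filter(built, type == "enhancer", set == "basal")
  expect_equal(enh$start, 900L)   # +/- 100 bp padding
  expect_equal(enh$end, 1300L)
  prom <- dplyr::filter(built, type == "promoter", set == "basal")
  expect_equal(prom$start, 5000L - 860L)  # 860 upstream / 100 downstream
  expect_equal(prom$end, 5100L + 100L)
  expect_equal(nrow(prom), 1)  # p2 excluded at score 29
  # exons of the expressed promoter's gene are included
  exb <- dplyr::filter(built, type == "exon", set == "basal")
  expect_equal(sum(exb$end - exb$start),
               sum(with(subset(ref$exons, gene_id == ref$genes$gene_id[1]),
                        end - start)))

  # missing promoter strand is an error
  bad <- dplyr::mutate(expr, strand = ifelse(region_id == "p1", ".",
                                             strand))
  expect_error(build_fantom_regions(bad, fantom_thresholds(), ref),
               "strand")
})

test_that("basal and upon-differentiation sets are disjoint", {
  ref <- small_reference(seed = 74)
  cfg <- small_config(seed = 74)
  expr <- simulate_expression_table(ref, cfg, seed = 74)
  built <- build_fantom_regions(expr, fantom_thresholds(), ref)
  for (ty in unique(built$type)) {
    a <- dplyr::filter(built, type == ty, set == "basal")
    b <- dplyr::filter(built, type == ty, set == "upon_differentiation")
    if (nrow(a) == 0 || nrow(b) == 0) next
    pts <- unlist(Map(seq, b$start + 1L, b$end))
    expect_false(any(clonesoma:::pos_in_regions("chr1"[rep(1, length(pts))],
                                                pts, a)))
  }
  # a region expressed at day 0 and day 6 stays basal only
  one <- tibble::tibble(region_id = "e1", type = "enhancer",
                        gene = NA_character_, chrom = "chr1",
                        start = 1000L, end = 1200L, strand = ".")
  expr2 <- tidyr::expand_grid(one, timepoint = c(0L, 6L), replicate = 1L) |>
    dplyr::mutate(score = 5)
  built2 <- build_fantom_regions(expr2, fantom_thresholds(), ref)
  expect_equal(unique(built2$set[built2$type == "enhancer"]), "basal")
})

test_that("regional load reports group means and fold changes", {
  fantom <- tibble::tibble(set = "basal", type = "exon", chrom = "chr1",
                           start = 0L, end = 1000L)
  md <- tibble::tibble(clone = c("y1", "o1"), group = c("young", "old"))
  catalog <- tibble::tibble(
    clone = rep(c("y1", "o1"), c(10, 24)),
    chrom = "chr1", pos = c(1:10, 1:24))
  rl <- regional_mutation_load(catalog, fantom, md)
  expect_equal(rl$fold$fold_old_young, 2.4)
  expect_equal(sort(rl$per_clone$n), c(10, 24))

  none <- regional_mutation_load(catalog[0, ], fantom, md)
  expect_true(all(none$per_clone$n == 0))

  shuffled <- regional_mutation_load(catalog[sample(nrow(catalog)), ],
                                     fantom, md)
  expect_equal(dplyr::arrange(shuffled$per_clone, clone),
               dplyr::arrange(rl$per_clone, clone))
})

test_that("gene-set load divides hits by clones and genes", {
  catalog <- tibble::tibble(gene = rep("mybpc1", 13))
  r <- gene_set_load(catalog, c(paste0("GENE", 1:99), "MYBPC1"),
                     n_clones = 13)
  expect_equal(r$n_hits, 13)         # case-normalized match
  expect_equal(r$avg_per_gene_per_clone, 0.01)
  expect_equal(gene_set_load(tibble::tibble(gene = "ABC"), "XYZ", 5)$n_hits,
               0)
  expect_error(gene_set_load(catalog, character(0), 13), "empty")
})

test_that("disease-gene null matches the analytic enumeration oracle", {
  exons <- tibble::tibble(gene_id = c("A", "B", "C", "D"),
                          start = 0L, end = c(100L, 200L, 300L, 400L))
  disease <- c("B", "D")           # length fraction 0.6
  hits <- rep(c("B", "A"), c(9, 1))  # 9 of 10 mutations in the set
  r <- disease_gene_null(hits, exons, disease, n_resamples = 1e5, seed = 31)
  p <- 0.6
  z_exact <- (9 - 10 * p) / sqrt(10 * p * (1 - p))
  p_exact <- 1 - pbinom(8, 10, p)
  expect_lt(abs(r$z_score - z_exact), 0.02)
  expect_lt(abs(r$p_empirical - p_exact), 0.02)

  r2 <- disease_gene_null(hits, exons, disease, n_resamples = 100,
                          seed = 31)
  r3 <- disease_gene_null(hits, exons, disease, n_resamples = 100,
                          seed = 31)
  expect_identical(r2$draws, r3$draws)

  # saturated set: every draw hits, excess is never observed
  sat <- disease_gene_null(rep("A", 5), exons, c("A", "B", "C", "D"),
                           n_resamples = 500, seed = 1)
  expect_equal(sat$observed, 5)
  expect_equal(sat$null_mean, 5)
  expect_equal(sat$p_empirical, 1, tolerance = 1e-6)
})

test_that("the null procedure applied to its own draws is centred", {
  set.seed(33)
  exons <- tibble::tibble(gene_id = paste0("g", 1:50), start = 0L,
                          end = sample(50:500, 50, replace = TRUE))
  w <- exons$end / sum(exons$end)
  null_set <- unique(exons$gene_id[sample.int(50, 20, replace = TRUE,
                                              prob = w)])
  p_set <- sum(exons$end[exons$gene_id %in% null_set]) / sum(exons$end)
  n_mut <- 200
  hits <- exons$gene_id[sample.int(50, n_mut, replace = TRUE, prob = w)]
  r <- disease_gene_null(hits, exons, null_set, n_resamples = 1e5,
                         seed = 34)
  z_of_truth <- (n_mut * p_set - r$null_mean) / r$null_sd
  expect_lt(abs(z_of_truth), 0.1)
})

test_that("minus-strand coding SNVs are classified on the coding strand", {
  # CDS on the minus strand over genomic [4, 10): revcomp("ACGTAT") =
  # "ATACGT", codons ATA (Ile), CGT (Arg)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", start = 4L,
                          end = 10L, strand = "-", coding = TRUE)
  refobj <- list(sequence = c(chr1 = "TTTTACGTATTTTT"),
                 contig_lengths = c(chr1 = 14L),
                 genes = genes,
                 exons = dplyr::mutate(genes, rank = 1L),
                 utr5 = genes[0, ], utr3 = genes[0, ])
  x <- tibble::tibble(clone = "c1", chrom = "chr1",
                      pos = c(10L, 8L), ref = c("T", "T"),
                      alt = c("G", "G"))
  res <- ns_s_ratio(x, refobj)
  # pos 10 is CDS base 1: ATA -> CTA (Ile -> Leu), non-synonymous;
  # pos 8 is CDS base 3: ATA -> ATC (Ile -> Ile), synonymous
  expect_equal(res$per_variant$consequence[res$per_variant$pos == 10],
               "non-synonymous")
  expect_equal(res$per_variant$consequence[res$per_variant$pos == 8],
               "synonymous")
})

test_that("NS/S ratios follow the counts, with S = 0 undefined", {
  # direct worked cases on a hand-built reference: TTT>TTC synonymous,
  # TAC>TAA stop-gain (non-synonymous)
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", start = 2L,
                          end = 14L, strand = "+", coding = TRUE)
  exons <- tibble::tibble(gene_id = "G1", chrom = "chr1", start = 2L,
                          end = 14L, strand = "+", rank = 1L)
  refobj <- list(sequence = c(chr1 = "AATTTTACGGGCCCA"),
                 contig_lengths = c(chr1 = 15L),
                 genes = genes, exons = exons,
                 utr5 = genes[0, ], utr3 = genes[0, ])
  # CDS (1-based genomic 3..14): TTT TAC GGG CCC
  x <- tibble::tibble(clone = "c1", chrom = "chr1",
                      pos = c(5L, 8L),
                      ref = c("T", "C"), alt = c("C", "A"))
  res <- ns_s_ratio(x, refobj)
  expect_setequal(res$per_variant$consequence,
                  c("synonymous", "non-synonymous"))
  expect_equal(res$per_clone$ratio, 1)

  only_ns <- ns_s_ratio(x[2, ], refobj)
  expect_true(is.na(only_ns$per_clone$ratio))

  four_two <- tibble::tibble(clone = "c1", chrom = "chr1",
                             pos = c(5L, 11L, 8L, 8L, 6L, 7L),
                             ref = c("T", "G", "C", "C", "T", "A"),
                             alt = c("C", "A", "A", "G", "G", "G"))
  # 2 synonymous (TTT>TTC, GGG>GGA), 2 stop-gains and 2 missense at TAC
  r2 <- ns_s_ratio(four_two, refobj)
  expect_equal(r2$per_clone$ratio, 2)
})
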