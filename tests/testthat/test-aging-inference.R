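test_that("fit_rate recovers an exact linear burden", {
  md <- tibble::tibble(individual = paste0("d", 1:6),
                       age = c(21, 30, 42, 58, 70, 78))
  md$mutation_count <- 100 + 13.1 * md$age
  fit <- fit_rate(md)
  expect_equal(fit$slope, 13.1, tolerance = 1e-6)
  expect_equal(fit$intercept, 100, tolerance = 1e-4)
  expect_equal(fit$method, "robust_mixed")
  expect_error(fit_rate(dplyr::mutate(md, age = 50)), "single age")
})

test_that("fit_rate slope is equivariant under count scaling", {
  set.seed(51)
  md <- tibble::tibble(individual = rep(paste0("d", 1:5), each = 3),
                       age = rep(c(25, 35, 50, 65, 75), each = 3))
  md$mutation_count <- rpois(15, 50 + 10 * md$age)
  f1 <- fit_rate(md)
  f3 <- fit_rate(dplyr::mutate(md, mutation_count = 3 * mutation_count))
  expect_equal(f3$slope, 3 * f1$slope, tolerance = 1e-6)
})

test_that("a single donor falls back to robust simple regression", {
  md <- tibble::tibble(individual = "d1", age = c(20, 40, 60, 80),
                       mutation_count = c(300, 550, 800, 1100))
  expect_warning(fit <- fit_rate(md), "robust simple")
  expect_equal(fit$method, "robust_simple")
  expect_equal(fit$slope, 13.3, tolerance = 0.2)
})

test_that("robust fitting resists an extreme outlier better than OLS", {
  set.seed(53)
  ages <- rep(c(25, 40, 55, 70), each = 2)
  errs <- replicate(100, {
    y <- 50 + 2 * ages + rnorm(8, 0, 5)
    y[3] <- y[3] + 500
    d <- tibble::tibble(individual = paste0("d", seq_along(ages)),
                        age = ages, mutation_count = y)
    rob <- fit_rate(d, method = "robust_simple")$slope
    ols <- unname(coef(lm(mutation_count ~ age, d))["age"])
    c(abs(rob - 2), abs(ols - 2))
  })
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
})

test_that("rate fits expose broom-style tidy and glance", {
  md <- tibble::tibble(individual = paste0("d", 1:6),
                       age = c(21, 30, 42, 58, 70, 78))
  md$mutation_count <- 100 + 13.1 * md$age
  fit <- fit_rate(md)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "age"], 13.1, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$n_donors, 6)
})

test_that("divisions per year follow the published arithmetic", {
  expect_equal(divisions_per_year(13.1, 2.5), 5.24)
  expect_equal(divisions_per_year(100, 2.5), 40)
  expect_equal(divisions_per_year(0, 2.5), 0)
  expect_error(divisions_per_year(10, 0), "positive")
})

test_that("threshold derivation matches the algebraic oracle", {
  md <- tibble::tibble(
    clone = c("y1", "y2", "y3", "o1", "o2", "o3"),
    group = c("young", "young", "young", "old", "old", "old"),
    days_in_culture = c(50, 52, 54, 40 + 0.01 * 500, 40 + 0.01 * 1000,
                        40 + 0.01 * 1500),
    mutation_count = c(300, 320, 310, 500, 1000, 1500))
  r <- derive_threshold(md)
  expect_equal(r$young_mean, 52)
  expect_equal(r$young_sd, 2)
  expect_equal(r$band, c(50, 54))
  expect_equal(r$old_slope, 0.01, tolerance = 1e-10)
  expect_equal(r$threshold, 1400, tolerance = 1e-8)
  expect_equal(r$old_clones$status, c("healthy", "healthy", "diseased"))
})

test_that("a non-positive old slope leaves the threshold undefined", {
  md <- tibble::tibble(
    clone = c("y1", "y2", "o1", "o2"),
    group = c("young", "young", "old", "old"),
    days_in_culture = c(50, 54, 48, 48),
    mutation_count = c(300, 320, 500, 1500))
  r <- derive_threshold(md)
  expect_true(is.na(r$threshold))
  expect_true(all(is.na(r$old_clones$status)))
})

test_that("threshold is order-invariant and decreases with the slope", {
  md <- tibble::tibble(
    clone = c("y1", "y2", "o1", "o2", "o3"),
    group = c("young", "young", "old", "old", "old"),
    days_in_culture = c(50, 54, 45, 50, 55),
    mutation_count = c(300, 320, 500, 1000, 1500))
  r1 <- derive_threshold(md)
  r2 <- derive_threshold(md[c(2, 5, 3, 1, 4), ])
  expect_equal(r1$threshold, r2$threshold)
  # steeper old regression through the same centre crosses the band sooner
  md_steep <- dplyr::mutate(md, days_in_culture = ifelse(
    group == "old", 50 + 2 * (days_in_culture - 50), days_in_culture))
  expect_lt(derive_threshold(md_steep)$threshold, r1$threshold)
  # all old clones below the threshold: no diseased set
  md_low <- dplyr::mutate(md, days_in_culture = ifelse(
    group == "old", 40 + 0.001 * mutation_count, days_in_culture))
  rl <- derive_threshold(md_low)
  expect_equal(sum(rl$old_clones$status == "diseased"), 0)
})

test_that("deleteriousness scores sum per clone and per scope", {
  catalog <- tibble::tibble(clone = c("c1", "c1", "c1", "c2"),
                            chrom = "chr1", pos = c(10L, 20L, 30L, 10L),
                            ref = "C", alt = "T")
  scores <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
                           ref = "C", alt = "T", score = c(10.5, 20.3))
  r <- aggregate_deleteriousness(catalog, scores)
  expect_equal(r$global_score[r$clone == "c1"], 30.8)
  expect_equal(r$n_unscored[r$clone == "c1"], 1)

  scope <- tibble::tibble(chrom = "chr1", start = 15L, end = 25L)
  rs <- aggregate_deleteriousness(catalog, scores, scope = scope)
  expect_equal(rs$global_score[rs$clone == "c1"], 20.3)
  # scope restriction can only reduce the score
  expect_true(all(rs$global_score <=
                    r$global_score[match(rs$clone, r$clone)]))

  empty_scope <- tibble::tibble(chrom = "chr1", start = 900L, end = 950L)
  re <- aggregate_deleteriousness(catalog, scores, scope = empty_scope)
  expect_equal(nrow(re), 0)
})

test_that("deleteriousness is additive over catalog partitions", {
  set.seed(57)
  catalog <- tibble::tibble(clone = "c1", chrom = "chr1", pos = 1:40,
                            ref = "C", alt = "T")
  scores <- tibble::tibble(chrom = "chr1", pos = 1:40, ref = "C",
                           alt = "T", score = runif(40, 0, 30))
  whole <- aggregate_deleteriousness(catalog, scores)$global_score
  parts <- sum(aggregate_deleteriousness(catalog[1:15, ], scores)$global_score,
               aggregate_deleteriousness(catalog[16:40, ], scores)$global_score)
  expect_equal(whole, parts)
})

test_that("allele fractions convert to cell fractions with a cap", {
  expect_equal(allele_to_cell_fraction(0.013), 0.026)
  expect_equal(allele_to_cell_fraction(0.5), 1)
  expect_equal(allele_to_cell_fraction(0.6), 1)
  expect_error(allele_to_cell_fraction(1.2), "vaf")
})

test_that("the pipeline recovers the generative rate end to end", {
  # simulate -> filter -> FNR-correct -> fit, checked for 2 SE coverage
  cfg <- sim_config(genome_length = 1e6, n_genes = 4, seed = 61)
  ref <- simulate_reference(cfg)
  hits <- vapply(1:20, function(i) {
    coh <- simulate_cohort(ref, cfg, seed = 6000 + i)
    catalog <- filter_somatic(coh$callsets,
                              filter_params(blacklist = ref$blacklist))
    fnr <- estimate_fnr(germline_controls(coh))
    counts <- dplyr::count(
      dplyr::filter(accepted_catalog(catalog), class == "SNV"), clone)
    md <- dplyr::left_join(coh$metadata, counts, by = "clone") |>
      dplyr::mutate(mutation_count = correct_for_fnr(
        dplyr::coalesce(n, 0L), fnr$fnr))
    f <- fit_rate(md)
    abs(f$slope - 13.1) <= 2 * f$slope_se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
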