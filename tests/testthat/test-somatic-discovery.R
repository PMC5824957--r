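test_that("union_callsets merges variants and retains caller provenance", {
  v1 <- candidate(pos = 10L, callers = "HaplotypeCaller")
  v2 <- candidate(pos = 20L, callers = "HaplotypeCaller")
  v2b <- candidate(pos = 20L, callers = "MuTect2")
  v3 <- candidate(pos = 30L, callers = "MuTect2")
  u <- union_callsets(list(dplyr::bind_rows(v1, v2), dplyr::bind_rows(v2b, v3)))
  expect_equal(nrow(u), 3)
  expect_equal(u$callers[u$pos == 20], "HaplotypeCaller;MuTect2")

  expect_identical(nrow(union_callsets(list(v1))), 1L)
  empty <- v1[0, ]
  expect_equal(nrow(union_callsets(list(empty, empty))), 0)

  conflicted <- candidate(pos = 10L, ref = "G", alt = "A")
  expect_error(union_callsets(list(v1, conflicted)), "conflicting ref")
})

test_that("the filter chain accepts and rejects the worked cases", {
  p <- filter_params()
  ok <- filter_somatic(candidate(), p)
  expect_true(ok$accepted)
  expect_true(is.na(ok$reason))

  low <- filter_somatic(candidate(clone_alt_fwd = 3L, clone_alt_rev = 2L),
                        p)  # VAF 0.25: culture-acquired, below window
  expect_false(low$accepted)
  expect_equal(low$reason, "vaf_window")

  blood <- filter_somatic(candidate(blood_alt = 5L), p)  # 5/30 = 0.167
  expect_equal(blood$reason, "blood_vaf")

  shallow <- filter_somatic(candidate(clone_depth = 14L,
                                      clone_alt_fwd = 3L,
                                      clone_alt_rev = 3L), p)
  expect_equal(shallow$reason, "min_depth")

  deep <- filter_somatic(candidate(clone_depth = 1200L,
                                   clone_alt_fwd = 300L,
                                   clone_alt_rev = 300L), p)
  expect_equal(deep$reason, "max_depth")

  onestrand <- filter_somatic(candidate(clone_alt_fwd = 10L,
                                        clone_alt_rev = 0L), p)
  expect_equal(onestrand$reason, "strand")

  sex <- filter_somatic(candidate(chrom = "chrX"), p)
  expect_equal(sex$reason, "sex_chrom")

  bl <- filter_params(blacklist = tibble::tibble(chrom = "chr1",
                                                 start = 90L, end = 110L))
  expect_equal(filter_somatic(candidate(), bl)$reason, "blacklist")

  # a window-edge het: depth 20 with exactly 8 alt reads passes (closed)
  edge <- filter_somatic(candidate(clone_alt_fwd = 4L, clone_alt_rev = 4L),
                         p)
  expect_true(edge$accepted)
})

test_that("variants recurring across individuals are rejected in both", {
  two <- dplyr::bind_rows(candidate(individual = "D1"),
                          candidate(individual = "D2", clone = "c2"))
  res <- filter_somatic(two, filter_params())
  expect_true(all(!res$accepted))
  expect_true(all(res$reason == "recurrent"))

  same_ind <- dplyr::bind_rows(candidate(clone = "c1"),
                               candidate(clone = "c2"))
  expect_true(all(filter_somatic(same_ind, filter_params())$accepted))
})

test_that("a missing blood sample is a hard error", {
  x <- candidate(blood_depth = NA_integer_)
  expect_error(filter_somatic(x, filter_params()), "blood")
})

test_that("tightening any threshold never adds accepted variants", {
  set.seed(42)
  sites <- simulated_sites(500, 0.5)
  base <- filter_somatic(sites, filter_params())
  tighter <- list(
    filter_params(vaf_window = c(0.45, 0.55)),
    filter_params(blood_vaf_max = 0.05),
    filter_params(min_depth = 20),
    filter_params(max_depth = 40)
  )
  for (p in tighter) {
    res <- filter_somatic(sites, p)
    expect_true(all(res$pos[res$accepted] %in% base$pos[base$accepted]))
  }
})

test_that("rejection reasons partition the rejected candidates", {
  cfg <- small_config(seed = 55)
  coh <- simulate_cohort(small_reference(seed = 55), cfg)
  res <- filter_somatic(coh$callsets,
                        filter_params(blacklist = small_reference(55)$blacklist))
  expect_equal(sum(rejection_summary(res)$n_rejected),
               sum(!res$accepted))
  expect_true(all(is.na(res$reason) == res$accepted))
})

test_that("filter acceptance matches the analytic binomial oracle", {
  set.seed(77)
  n <- 5000
  hets <- simulated_sites(n, 0.5)
  acc <- mean(filter_somatic(hets, filter_params())$accepted)
  p_oracle <- analytic_accept_prob(0.5, 30)
  expect_lt(abs(acc - p_oracle), 3 * sqrt(p_oracle * (1 - p_oracle) / n))

  cult <- simulated_sites(n, 0.25)
  acc_c <- mean(filter_somatic(cult, filter_params())$accepted)
  p_c <- analytic_accept_prob(0.25, 30)
  expect_lt(abs(acc_c - p_c), 3 * sqrt(p_c * (1 - p_c) / n) + 1e-3)
})

test_that("germline variants fail the blood criterion almost surely", {
  set.seed(88)
  n <- 2000
  g <- simulated_sites(n, 0.5)
  g$blood_depth <- pmax(15L, rpois(n, 30))
  g$blood_alt <- rbinom(n, g$blood_depth, 0.5)
  res <- filter_somatic(g, filter_params())
  rejected_blood <- mean(res$blood_alt / res$blood_depth >= 0.1)
  expect_gte(rejected_blood, 0.99)
  expect_lte(mean(res$accepted), 0.01)
})

test_that("estimate_fnr reproduces the published arithmetic", {
  het <- tibble::tibble(detected = rep(c(TRUE, FALSE), c(59, 41)),
                        clone_alt = c(rep(15L, 59), rep(2L, 41)),
                        clone_depth = 30L)
  r <- estimate_fnr(het)
  expect_equal(r$fnr, 0.41)
  expect_equal(r$positive_prediction_rate, 0.59)
  expect_equal(r$n_control_sites, 100)

  allpass <- tibble::tibble(detected = TRUE, clone_alt = rep(15L, 50),
                            clone_depth = 30L)
  expect_equal(estimate_fnr(allpass)$fnr, 0)

  expect_error(estimate_fnr(allpass[0, ]), "control sites")
})

test_that("estimate_fnr combines het and hom control components", {
  het <- tibble::tibble(detected = rep(c(TRUE, FALSE), c(40, 10)),
                        clone_alt = rep(15L, 50), clone_depth = 30L)
  hom <- tibble::tibble(blood_minor = rep(c(0L, 10L), c(45, 5)),
                        blood_depth = 30L)
  r <- estimate_fnr(het, hom)
  expect_equal(r$n_het_pass, 40)
  expect_equal(r$n_hom_pass, 45)
  expect_equal(r$positive_prediction_rate, 85 / 100)
  expect_equal(r$het_rate, 0.8)
  expect_equal(r$hom_rate, 0.9)
})

test_that("estimate_fnr recovers injected caller drop-out on simulation", {
  set.seed(123)
  n <- 2000
  drop <- 0.2
  het <- simulated_sites(n, 0.5) |>
    dplyr::mutate(clone_alt = clone_alt_fwd + clone_alt_rev,
                  detected = runif(n) > drop)
  r <- estimate_fnr(het)
  # analytic: PPR = (1 - drop) * P(VAF in window | depth >= 15)
  p_win <- analytic_accept_prob(0.5, 30, strand = FALSE,
                                blood_depth_term = FALSE) /
    (1 - ppois(14, 30))
  expect_lt(abs(r$fnr - (1 - (1 - drop) * p_win)), 0.03)
})

test_that("FNR burden correction matches the published worked examples", {
  expect_equal(correct_for_fnr(209, 0.41), 354)
  expect_equal(correct_for_fnr(1371, 0.41), 2323)
  expect_equal(correct_for_fnr(100, 0), 100)
  expect_error(correct_for_fnr(10, 1), "undefined")
})

test_that("burden normalization divides by the callable fraction", {
  expect_equal(normalize_burden(500, 1), 500)
  expect_equal(normalize_burden(500, 0.95), 526.3158, tolerance = 1e-6)
  expect_equal(normalize_burden(0, 0.9), 0)
  expect_error(normalize_burden(10, 0), "positive")
})
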