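# Shared in-code fixtures: a small simulated reference and a hand-built
# candidate row factory.

small_config <- function(seed = 101, ...) {
  args <- utils::modifyList(
    list(genome_length = 5e4, n_genes = 4, n_germline_het = 50,
         n_culture_mutations = 10, seed = seed),
    list(...))
  do.call(sim_config, args)
}

small_reference <- local({
  cache <- new.env()
  function(seed = 101, ...) {
    key <- paste(seed, paste(c(...), collapse = "_"))
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_reference(small_config(seed, ...))
    }
    cache[[key]]
  }
})

# A passing mid-window candidate; override fields to construct failures.
candidate <- function(...) {
  base <- tibble::tibble(
    individual = "D1", clone = "c1", chrom = "chr1", pos = 100L,
    ref = "C", alt = "T", class = "SNV",
    clone_alt_fwd = 5L, clone_alt_rev = 5L, clone_depth = 20L,
    blood_alt = 0L, blood_depth = 30L, callers = "HaplotypeCaller"
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# Analytic probability that a true-VAF `v` site passes the read-level filter
# criteria (VAF window, depths, strand) at Poisson depth `depth_mean`;
# independent oracle used against the simulator + filter path.
analytic_accept_prob <- function(v, depth_mean, vaf_window = c(0.4, 0.6),
                                 min_depth = 15, max_depth = 1000,
                                 strand = TRUE, blood_depth_term = TRUE) {
  ds <- 0:ceiling(depth_mean + 10 * sqrt(depth_mean))
  p_blood <- if (blood_depth_term) {
    sum(dpois(ds[ds >= min_depth], depth_mean)) +
      ppois(max(ds), depth_mean, lower.tail = FALSE)
  } else 1
  tot <- 0
  for (d in ds[ds >= min_depth & ds <= max_depth]) {
    as <- 0:d
    in_win <- as / d >= vaf_window[1] & as / d <= vaf_window[2]
    p_strand <- if (strand) {
      ifelse(as == 0, 0, 1 - 2 * 0.5^as)
    } else rep(1, length(as))
    tot <- tot + dpois(d, depth_mean) *
      sum(dbinom(as[in_win], d, v) * p_strand[in_win])
  }
  tot * p_blood
}

# Draw `n` read-level candidates at a common true VAF (blood clean).
simulated_sites <- function(n, vaf, depth_mean = 30) {
  d <- rpois(n, depth_mean)
  a <- rbinom(n, d, vaf)
  af <- rbinom(n, a, 0.5)
  tibble::tibble(
    individual = "D1", clone = "c1", chrom = "chr1", pos = seq_len(n),
    ref = "C", alt = "T", class = "SNV",
    clone_alt_fwd = af, clone_alt_rev = a - af, clone_depth = d,
    blood_alt = 0L, blood_depth = rpois(n, depth_mean),
    callers = "HaplotypeCaller"
  )
}
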