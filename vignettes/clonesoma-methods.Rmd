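---
title: "Methods: clone-based somatic mutation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-based somatic mutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesoma)
```

## The measurement problem

A somatic mutation private to one stem cell is invisible in bulk
sequencing of its tissue. Expanding a single sorted cell into a clone
turns that private genome into a clonal population: every founder-cell
variant is heterozygous in all cells (allele fraction ≈ 0.5 at a diploid
site), while the donor's blood provides the germline reference. Three
variant classes must be separated:

* **germline heterozygotes** — VAF ≈ 0.5 in both clone and blood;
* **in-vivo somatic variants** — VAF ≈ 0.5 in the clone, absent from
  blood;
* **culture-acquired variants** — arising during the in-vitro expansion.
  Under a neutral synchronous binary expansion, a mutation in one
  daughter cell at division $k$ is carried by cell fraction $2^{-k}$ and
  seen at VAF $2^{-(k+1)}$; even a first-division event reaches only
  0.25 (`culture_vaf(1)`).

The discovery filter exploits exactly this geometry: a closed clone-VAF
window $[0.4, 0.6]$ admits clonal heterozygotes and excludes the culture
tail, the blood criterion (alt fraction $< 0.1$) removes germline
variants, and depth/strand/blacklist/recurrence criteria remove
artifacts. The window's price is a substantial false negative rate: at
30× coverage a true VAF-0.5 site falls outside the window with
probability given by the binomial tail, and `estimate_fnr()` measures
precisely this (plus caller drop-out) on germline control sites.

## What the simulator generates, and why those defaults

`sim_config()` fixes the study conditions; `simulate_reference()`,
`simulate_clone_trio()`, `simulate_cohort()` and
`simulate_expression_table()` generate data with the statistical
structure the analysis assumes.

| parameter | default | rationale |
|---|---|---|
| `yearly_rate` | 13.1 SNVs/genome/yr | the adult-life accumulation rate the analysis is designed to recover |
| `intercept` | 50 SNVs | small positive burden at age 0, consistent with observed clone burdens of a few hundred at age 21 |
| `donor_sd` | 50 SNVs | donor-level Gaussian random effect on the Poisson mean (truncated at 0), mirroring the mixed model fitted downstream |
| `ages`, `clones_per_donor` | 7 donors, 21–78 yr, 29 clones | the young (13 clones)/old (16 clones) cohort design |
| `depth_mean` | 30 reads | Poisson per-site depths around 30×, independent in clone and blood |
| `indel_fraction` | 0.07 | indels ride on top of the SNV rate so they are ~7% of events, matching observed indel/SNV ratios; the SNV rate itself stays 13.1 |
| `caller_sensitivity` | 0.8 | probability a true variant reaches the union callset; combined with the window loss at 30× this yields an FNR near 0.41 |
| `n_culture_mutations` | 30/clone | culture variants with division-of-origin $k \sim 1 + \mathrm{Geom}(0.5)$, VAF $2^{-(k+1)}$ |
| `blood_contamination` | 0 | no clone-lineage cells in blood; configurable |

Read evidence is binomial given depth and true VAF, with strand counts
split binomially — the simplest model consistent with whole-genome shot
noise. In-vivo SNV contexts are drawn from a mixture of three generative
signature profiles (`generative_signatures()`): a clock-like CpG C>T
profile, a flat profile, and a C>A-rich profile; positions are sampled
from a precomputed trinucleotide index of the synthetic reference so the
spectrum of the truth set follows the configured mixture.

Culture times are generated so the proliferation-threshold analysis has
signal: young clones draw days in culture from Normal(52, 2); old clones
from $40 + 0.012 \times \text{burden}$ plus Normal(0, 1) noise.

**What the simulator does not emulate**: sequencing error and false
positive calls (off by default; the filter chain, not caller error, is the
subject), mapping artifacts, GC-dependent coverage, structural variants,
sex chromosomes, and real genome composition (a uniform-composition
synthetic autosome of 0.05–1 Mb stands in for 2.9 Gb of autosomes).
Passing tests therefore certify the statistical machinery — filter
operating characteristics, estimator calibration, recovery of generative
parameters — not robustness to alignment artifacts or real mutational
context biases. One desk-scale artifact is worth naming: on a small
genome, independent clones collide at the same positions far more often
than on a real genome, so the cross-individual recurrence criterion
removes a visible fraction of true somatic variants (about 1% at 1 Mb,
~8% at 100 kb); tests that quantify filter sensitivity either use a 1 Mb
genome or constructed candidates.

## Estimators and numerical choices

**Filter evaluation order.** VAF window, blood fraction, minimum depth,
sex chromosome, strand support, maximum depth, blacklist, recurrence.
Each rejected candidate records the *first* failing criterion, making the
audit deterministic and the reason counts an exact partition of the
rejections. The window is closed — a depth-20 het with exactly 8 alt
reads (VAF 0.40) passes — and the blood criterion is strict (< 0.1).
"Both strands" means ≥ 1 alt read on each; recurrence is keyed on
(chrom, pos, ref, alt) across individuals. Indels pass through the same
criteria as SNVs.

**FNR.** The positive prediction rate combines the two published control
counts — heterozygotes detected by ≥ 1 caller with in-window clone VAF,
and homozygotes with blood minor fraction < 0.1 — as sites passing over
total control sites; both component rates are also reported since their
relative weighting is a design choice. Burden correction floors
`observed / (1 − FNR)`.

**NMF.** De novo extraction minimizes generalized KL divergence with
multiplicative updates, the canonical formulation for mutational
signatures. Defaults: 20 random restarts (uniform [0.1, 1] inits), up to
500 iterations, relative objective tolerance $10^{-8}$, best restart by
final objective; the per-iteration objective is non-increasing and
tested as such. Profiles are column-normalized with scale moved into the
contributions. Refitting to reference profiles is non-negative least
squares (`pracma::lsqnonneg`), whose residual is zero whenever the
spectrum lies in the cone of the profiles.

**Clustering.** Contributions are normalized per clone by row sum before
PCA (the alternative z-scaling is exposed via `normalize`), and k-means
on the first 3 components keeps the best of `n_starts` random
initializations by within-cluster sum of squares — the "permutations" of
the reference procedure are read as random restarts. Labels follow a
stable convention (cluster 1 = larger cluster, ties broken by smallest
clone id) and the input is canonically ordered first, so clone order
cannot change the result. All-identical input is flagged degenerate
rather than clustered.

**Enrichment/depletion.** Expected counts assume uniform mutation
opportunity over the callable genome (no trinucleotide adjustment,
matching the construction of the reference test). The one-sided exact
binomial tail follows the observed direction by default; note that a
direction-conditional p-value is *not* uniform under the null (it is
bounded near 0.6), so calibration checks use the fixed `direction =
"less"` tail, which is uniform up to binomial discreteness. Zero
observed mutations report a `-Inf` log2 ratio sentinel.

**Expressed-region construction.** Enhancers need score ≥ 1 in ≥ 1
replicate and are padded ±100 bp; promoters need score ≥ 30 and a
strand-aware window of 860 bp upstream / 100 bp downstream (an absent
strand is an error, since the window is undefined); exons are all exons
of genes owning an expressed promoter. "Basal" is day 0; "upon
differentiation" is the union over all timepoints minus the basal
genomic space — a genomic set difference, so the two sets are disjoint
by construction. Overlapping promoter/enhancer space is resolved by a
deterministic rule (promoter wins), replacing manual curation.

**Disease-gene null.** Mutations attributed to extended gene regions
(exons + introns + 5 kb flanks) are compared against a null that
resamples the same number of exons with replacement, probability
proportional to exon length. Sampling *with* replacement is chosen
because draws model independent mutations; the toy-model oracle is then
exactly binomial. Z-score uses the null draws' moments; both a
normal-approximation p and an empirical resampling p (with the +1
continuity correction) are reported.

**Robust mixed model.** "Robust mixed" is implemented as iteratively
reweighted `lmer` (random donor intercept) with Huber weights at tuning
constant 1.345 computed from MAD-scaled residuals, up to 20 reweighting
iterations; a plain mixed model and `MASS::rlm` simple regression are
selectable, and the fit reports which method was actually used. Fewer
than two donors falls back to robust simple regression with a warning.
Exactly singular (noiseless) fits, where the mixed-model covariance is
unavailable, take their dispersion from the weighted fixed-effect
regression instead. P-values are Satterthwaite (`lmerTest`) where
available. Signature age trends apply Bonferroni over the number of
signatures tested (3 in the default analysis).

**Threshold.** The healthy band is the young clones' mean ± sample SD of
days in culture (population SD selectable); the old-clone fit is
ordinary least squares of days on *raw* mutation counts (SNVs + indels,
uncorrected — the corrected scale is a flag away), unweighted across
donors. The threshold is the band's upper border intersected with that
line, undefined (`NA`) when the old slope is not positive — mirroring
the absence of correlation in young clones. Slopes below $10^{-10}$
count as non-positive to keep the degenerate case stable under floating
point.

**FNR correction before rate fitting** is off by default (the headline
rate is fitted on observed counts) and available as a flag in
`pipeline_config()`.

## Problem sizes used by the tests

The suite exercises everything at desk scale, chosen so the full run
stays within a few minutes: 50 kb–1 Mb genomes, 29-clone cohorts, 50
replicates for rate-recovery coverage (within 2 SE of 13.1 in ≥ 90% of
replicates), 10⁴ simulated read-level sites against the analytic
binomial filter oracle, 200 catalogs of 2000 mutations for p-value
calibration (KS at α = 0.01), 10⁵ resamples against the enumeration
oracle of the disease-gene null, and 20 end-to-end
simulate→filter→correct→fit replicates at 1 Mb. The acceptance script
reports the mean recovered slope over 50 simulated cohorts.

## Known limitations

* The synthetic reference-signature matrix shipped with the package is a
  labelled stand-in; refitting results are structurally, not
  biologically, comparable to refits against published compendia.
* The interval annotator replaces a full effect predictor: one class per
  variant by fixed precedence, no transcript isoforms, no splice-site
  distinction beyond ±2 bp.
* The expected-count model for enrichment ignores trinucleotide
  composition; regions with atypical composition will show spurious
  enrichment against it on real data.
* Published surveyed region sizes of the external expression atlas are
  not reproduced; the region builder is validated on synthetic tables.
* The VAF model assumes diploid autosomes throughout; copy-number
  alterations would shift both the window and the cell-fraction
  conversion.
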