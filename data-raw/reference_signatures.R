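# Builds inst/extdata/reference_signatures_synthetic.tsv: a synthetic
# 96 x 30 reference-signature compendium (NOT the published COSMIC
# signatures, which cannot be redistributed here). Profiles 1-3 reuse the
# simulator's generative profiles (clock-like CpG C>T, flat, C>A-rich);
# the rest are sparse random probability vectors.
devtools::load_all(".")
set.seed(961L)
cls <- sbs96_classes()
gen <- generative_signatures()
rand <- sapply(1:27, function(i) {
  w <- rgamma(96, shape = 0.3)
  hot <- sample(96, 4)
  w[hot] <- w[hot] + rgamma(4, shape = 8)
  w / sum(w)
})
m <- cbind(gen, rand)
colnames(m) <- sprintf("RS%02d", seq_len(ncol(m)))
tab <- tibble::tibble(context = cls)
tab <- cbind(tab, round(m, 6))
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(tab, "inst/extdata/reference_signatures_synthetic.tsv")
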