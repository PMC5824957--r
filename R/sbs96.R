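#' The 96 trinucleotide substitution classes
#'
#' Canonical ordering of the pyrimidine-collapsed single-base-substitution
#' classes: the six substitution types `C>A, C>G, C>T, T>A, T>C, T>G` (outer),
#' each combined with the 16 flanking-base contexts ordered by 5' base then
#' 3' base (`A, C, G, T`). Labels have the form `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_classes())
sbs96_classes <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(f) paste0(f, "[", s, "]", bases)))
  }))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Collapse a (ref, alt, 5' base, 3' base) substitution onto the pyrimidine
# strand and return its 96-class label. Vectorised.
sbs96_label <- function(ref, alt, up, down) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp_base(ref), ref)
  a <- ifelse(pur, comp_base(alt), alt)
  u <- ifelse(pur, comp_base(down), up)
  d <- ifelse(pur, comp_base(up), down)
  paste0(u, "[", r, ">", a, "]", d)
}

# The 32 pyrimidine-centred trinucleotide contexts, in class order.
sbs32_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(c("C", "T"), function(m) {
    unlist(lapply(bases, function(f) paste0(f, m, bases)))
  }))
}

# Pyrimidine-collapse a trinucleotide string (central base any of ACGT).
collapse_context <- function(tri) {
  mid <- substr(tri, 2, 2)
  ifelse(mid %in% c("C", "T"), tri, revcomp(tri))
}
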