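#' Read a clone/blood candidate callset from a multi-sample VCF
#'
#' Parses per-sample `AD`/`DP` and the strand-count FORMAT field `SAC`
#' (ref-forward, ref-reverse, alt-forward, alt-reverse) into the candidate
#' tibble the filter operates on. Multi-allelic records are decomposed into
#' one biallelic observation per alternative allele. Positions stay
#' 1-based. When `SAC` is absent the strand columns are `NA` and a warning
#' is raised (the strand criterion is then skipped by the filter only if
#' disabled in [filter_params()]).
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param clone,blood Sample column names.
#' @param individual Individual id to attach (defaults to the file name).
#' @return Candidate tibble (see [filter_somatic()]).
#' @export
read_callset <- function(path, clone, blood, individual = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    return(tibble(individual = character(), clone = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), class = character(),
                  clone_alt_fwd = integer(), clone_alt_rev = integer(),
                  clone_depth = integer(), blood_alt = integer(),
                  blood_depth = integer(), callers = character()))
  }
  samples <- colnames(v@gt)[-1]
  for (s in c(clone, blood)) {
    if (!s %in% samples) stop("sample '", s, "' not found in ", path,
                              call. = FALSE)
  }
  fix <- as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  ad_c <- vcfR::extract.gt(v, "AD")[, clone]
  ad_b <- vcfR::extract.gt(v, "AD")[, blood]
  dp_c <- as.integer(vcfR::extract.gt(v, "DP")[, clone])
  dp_b <- as.integer(vcfR::extract.gt(v, "DP")[, blood])
  has_sac <- any(grepl("SAC", v@gt[, "FORMAT"]))
  sac_c <- if (has_sac) vcfR::extract.gt(v, "SAC")[, clone] else
    rep(NA_character_, nrow(fix))
  if (!has_sac) warning("FORMAT field SAC absent: strand counts are NA")

  ind <- individual %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  caller_info <- sub(".*CALLERS=([^;]*).*", "\\1", fix$INFO)
  caller_info[!grepl("CALLERS=", fix$INFO)] <- NA_character_

  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    adc <- as.integer(strsplit(ad_c[i] %||% NA_character_, ",")[[1]])
    adb <- as.integer(strsplit(ad_b[i] %||% NA_character_, ",")[[1]])
    sac <- if (!is.na(sac_c[i])) {
      as.integer(strsplit(sac_c[i], ",")[[1]])
    } else NULL
    purrr::map_dfr(seq_along(alts), function(j) {
      af <- if (!is.null(sac) && length(sac) >= 2 * j + 2) {
        sac[2 * j + 1]
      } else NA_integer_
      ar <- if (!is.null(sac) && length(sac) >= 2 * j + 2) {
        sac[2 * j + 2]
      } else NA_integer_
      tibble(
        individual = ind, clone = clone, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[j],
        class = if (nchar(fix$REF[i]) == 1 && nchar(alts[j]) == 1) "SNV"
                else "indel",
        clone_alt_fwd = af, clone_alt_rev = ar,
        clone_alt = if (length(adc) > j) adc[j + 1] else NA_integer_,
        clone_depth = dp_c[i],
        blood_alt = if (length(adb) > j) adb[j + 1] else NA_integer_,
        blood_depth = dp_b[i],
        callers = caller_info[i]
      )
    })
  })
  # when SAC was present it carries the split; otherwise keep totals only
  rows <- dplyr::mutate(rows,
    clone_alt_fwd = dplyr::coalesce(.data$clone_alt_fwd, .data$clone_alt),
    clone_alt_rev = dplyr::coalesce(.data$clone_alt_rev,
                                    .data$clone_alt - .data$clone_alt_fwd))
  dplyr::select(rows, -"clone_alt")
}

#' Write a candidate callset (or accepted catalog) as a multi-sample VCF
#'
#' Emits a VCF v4.2 with clone and blood sample columns carrying
#' `AD`, `DP` and the strand-count field `SAC`
#' (ref-fwd, ref-rev, alt-fwd, alt-rev), and caller provenance in
#' `INFO/CALLERS`. Output is bgzip-agnostic gzip (`.vcf.gz`).
#'
#' @param candidates Candidate tibble for a single clone.
#' @param path Output path ending in `.vcf.gz`.
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_callset <- function(candidates, path, contig_lengths = NULL) {
  x <- dplyr::arrange(candidates, .data$chrom, .data$pos)
  clone <- unique(x$clone)
  stopifnot(length(clone) == 1)
  meta <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Union callset caller provenance\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=SAC,Number=.,Type=Integer,Description=\"Strand allele counts: ref-fwd,ref-rev,alt-fwd,alt-rev\">"
  )
  clone_alt <- x$clone_alt_fwd + x$clone_alt_rev
  clone_ref <- x$clone_depth - clone_alt
  ref_fwd <- if ("clone_ref_fwd" %in% names(x)) x$clone_ref_fwd
             else floor(clone_ref / 2)
  ref_rev <- clone_ref - ref_fwd
  fix <- cbind(
    CHROM = x$chrom, POS = as.character(x$pos), ID = ".",
    REF = x$ref, ALT = x$alt, QUAL = ".", FILTER = ".",
    INFO = ifelse(is.na(x$callers) | x$callers == "", ".",
                  paste0("CALLERS=", gsub(";", "|", x$callers)))
  )
  gt <- cbind(
    FORMAT = "AD:DP:SAC",
    clone = sprintf("%d,%d:%d:%d,%d,%d,%d", clone_ref, clone_alt,
                    x$clone_depth, ref_fwd, ref_rev, x$clone_alt_fwd,
                    x$clone_alt_rev),
    blood = sprintf("%d,%d:%d:.", x$blood_depth - x$blood_alt, x$blood_alt,
                    x$blood_depth)
  )
  colnames(gt) <- c("FORMAT", clone, paste0(unique(x$individual)[1],
                                            "_blood"))
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a BED file into a region tibble
#'
#' @param path BED path (0-based half-open; 3+ columns).
#' @return Tibble `chrom`, `start`, `end` (plus `name`, `strand` when
#'   present).
#' @export
read_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_tibble(gr)
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- nm
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write a region tibble to BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name`, `strand`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  gr <- regions_to_granges(regions)
  if ("name" %in% names(regions)) gr$name <- regions$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read a filtered catalog audit table
#'
#' The audit TSV has one row per candidate with the acceptance flag and
#' first-failing rejection reason; `read_catalog()` restores it.
#'
#' @param catalog A [filter_somatic()] result.
#' @param path TSV path.
#' @return `path` / the catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(as_tibble(catalog), path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = "c", ref = "c", alt = "c",
                         reason = "c"))
  class(x) <- c("somatic_catalog", class(x))
  x
}
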