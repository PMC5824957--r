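#' De novo mutational-signature extraction by NMF
#'
#' Factorizes a 96 x n spectrum matrix `V` into non-negative profiles `W`
#' (96 x rank) and contributions `H` (rank x n) by minimizing the
#' generalized Kullback-Leibler divergence with multiplicative updates,
#' the canonical formulation for mutational-signature extraction. The best
#' of `n_restarts` random initializations (by final objective) is kept;
#' profile columns are normalized to probability vectors with the scale
#' moved into the contributions.
#'
#' @param spectra 96 x n non-negative matrix (or a [build_spectrum()]
#'   tibble, converted via [spectrum_matrix()]).
#' @param rank Number of signatures to extract (default 3).
#' @param n_restarts Random restarts (default 20).
#' @param max_iter,tol Update iterations per restart and relative
#'   objective-change stopping tolerance.
#' @param seed Seed making the extraction deterministic.
#' @return A list of class `"signature_set"`: `profiles` (96 x rank, columns
#'   sum to 1), `contributions` (rank x n), `kind = "de-novo"`, `objective`
#'   (best final KL divergence) and `objective_trace` (per-iteration
#'   objective of the best restart; non-increasing).
#' @export
extract_signatures <- function(spectra, rank = 3, n_restarts = 20,
                               max_iter = 500, tol = 1e-8, seed = NULL) {
  V <- if (is.matrix(spectra)) spectra else spectrum_matrix(spectra)
  stopifnot(all(V >= 0), rank >= 1, ncol(V) >= rank)
  if (sum(V) == 0) stop("all-zero spectrum matrix", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- nmf_kl(V, rank, max_iter, tol)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    s <- colSums(best$W)
    W <- sweep(best$W, 2, s, "/")
    H <- best$H * s
    colnames(W) <- rownames(H) <- paste0("S", seq_len(rank))
    rownames(W) <- rownames(V)
    colnames(H) <- colnames(V)
    structure(list(profiles = W, contributions = H, kind = "de-novo",
                   objective = best$objective,
                   objective_trace = best$trace),
              class = "signature_set")
  })
}

# Multiplicative-update NMF under generalized KL divergence.
nmf_kl <- function(V, rank, max_iter, tol) {
  eps <- .Machine$double.eps
  n <- ncol(V); m <- nrow(V)
  W <- matrix(runif(m * rank, 0.1, 1), m, rank)
  H <- matrix(runif(rank * n, 0.1, 1), rank, n)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H) + eps, each = m)
    P <- W %*% H + eps
    obj <- sum(ifelse(V > 0, V * log(V / P), 0) - V + P)
    trace <- c(trace, obj)
    if (is.finite(prev) && prev - obj < tol * max(1, abs(prev))) break
    prev <- obj
  }
  list(W = W, H = H, objective = trace[length(trace)], trace = trace)
}

#' Refit a spectrum to fixed reference signatures
#'
#' Finds the non-negative contribution vector `c` minimizing
#' `|| spectrum - P c ||_2` for column-normalized reference profiles `P`
#' (non-negative least squares), assessing how well a mutational catalog
#' can be expressed as a combination of known signatures. Absolute
#' contributions are in mutation counts; relative contributions divide by
#' the total reconstructed count per clone.
#'
#' @param spectrum A [build_spectrum()] tibble, or 96 x n matrix (one
#'   column per clone), or a length-96 vector.
#' @param reference_profiles 96 x M matrix with columns summing to 1, e.g.
#'   [read_reference_signatures()].
#' @return A `"signature_set"` with `kind = "reference-refit"`,
#'   `contributions` (M x n) and `residuals` (per-clone L2 residual).
#' @export
refit_to_reference <- function(spectrum, reference_profiles) {
  V <- if (is.matrix(spectrum)) spectrum
       else if (is.numeric(spectrum)) matrix(spectrum, ncol = 1)
       else spectrum_matrix(spectrum)
  P <- as.matrix(reference_profiles)
  if (nrow(V) != nrow(P)) {
    stop("spectrum and reference profiles disagree in class dimension (",
         nrow(V), " vs ", nrow(P), ")", call. = FALSE)
  }
  fit1 <- function(v) {
    if (all(v == 0)) return(list(x = rep(0, ncol(P)), resid = 0))
    f <- pracma::lsqnonneg(P, v)
    list(x = f$x, resid = sqrt(f$resid.norm))
  }
  fits <- apply(V, 2, fit1, simplify = FALSE)
  H <- vapply(fits, `[[`, numeric(ncol(P)), "x")
  H <- matrix(H, nrow = ncol(P),
              dimnames = list(colnames(P), colnames(V)))
  structure(list(profiles = P, contributions = H, kind = "reference-refit",
                 residuals = vapply(fits, `[[`, numeric(1), "resid")),
            class = "signature_set")
}

#' Relative signature contributions
#'
#' @param x A `"signature_set"`.
#' @return Matrix of per-clone contribution fractions (columns sum to 1
#'   where the total is positive).
#' @export
relative_contributions <- function(x) {
  stopifnot(inherits(x, "signature_set"))
  tot <- colSums(x$contributions)
  sweep(x$contributions, 2, ifelse(tot > 0, tot, 1), "/")
}

#' Packaged synthetic reference-signature profiles
#'
#' Loads the 96 x 30 reference-signature profile matrix shipped with the
#' package. These profiles are a synthetic stand-in constructed with the
#' structure of a cancer-signature compendium (one clock-like CpG C>T
#' profile, one flat profile, one C>A-rich profile, and 27 random sparse
#' profiles); they are not the published COSMIC signatures.
#'
#' @param path Optional alternative TSV (96 rows, one column per profile).
#' @return 96 x M numeric matrix, columns summing to 1.
#' @export
read_reference_signatures <- function(path = NULL) {
  path <- path %||% system.file("extdata",
                                "reference_signatures_synthetic.tsv",
                                package = "clonesoma", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m <- m[match(sbs96_classes(), rownames(m)), , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Per-signature age trends
#'
#' Fits, for every signature, the contribution-versus-age relationship with
#' the robust mixed model of [fit_rate()] (donor as random effect) and
#' applies a Bonferroni correction over the number of signatures tested
#' (3 in the reference analysis).
#'
#' @param contributions Signature x clone matrix (e.g. from a
#'   `"signature_set"`), or a tidy tibble with `clone`, `signature`,
#'   `contribution`.
#' @param metadata Clone metadata tibble with `clone`, `individual`, `age`.
#' @param m Bonferroni multiplier; default the number of signatures.
#' @param method Passed to [fit_rate()].
#' @return Tibble with one row per signature: `slope` (contribution/year),
#'   `intercept`, `se`, `p_raw`, `p_adj = min(1, m * p_raw)`, `method`.
#' @export
signature_age_trend <- function(contributions, metadata, m = NULL,
                                method = "robust_mixed") {
  if (inherits(contributions, "signature_set")) {
    contributions <- contributions$contributions
  }
  if (is.matrix(contributions)) {
    contributions <- as_tibble(contributions, rownames = "signature") |>
      tidyr::pivot_longer(-"signature", names_to = "clone",
                          values_to = "contribution")
  }
  sigs <- unique(contributions$signature)
  m <- m %||% length(sigs)
  purrr::map_dfr(sigs, function(s) {
    d <- contributions |>
      dplyr::filter(.data$signature == s) |>
      dplyr::inner_join(metadata, by = "clone")
    fit <- fit_rate(d, response = "contribution", method = method)
    tibble(signature = s, slope = fit$slope, intercept = fit$intercept,
           se = fit$slope_se, p_raw = fit$p_value,
           p_adj = pmin(1, m * fit$p_value), method = fit$method)
  })
}

#' Cluster clones on signature contributions
#'
#' Normalizes contributions per clone (rows sum to 1 by default), projects
#' onto principal components, and k-means-clusters the clones on the first
#' `n_pcs` components, keeping the best of `n_starts` random
#' initializations by within-cluster sum of squares. Labels follow a
#' stable convention: cluster 1 is the larger cluster (ties broken by the
#' lexicographically smallest clone id), and the input order of clones does
#' not affect the labelling.
#'
#' @param contributions Signature x clone matrix or `"signature_set"`.
#' @param n_pcs Principal components retained (default 3).
#' @param k Number of clusters (default 2).
#' @param n_starts Random k-means initializations (default 1e5 to mirror
#'   the reference analysis; reduce for speed).
#' @param normalize `"row_sum"` (per-clone fractions) or `"zscale"`.
#' @param seed Seed.
#' @return A list of class `"clone_clusters"`: tibble `clusters` (`clone`,
#'   `cluster`, PC coordinates), `tot_withinss`, `degenerate` flag.
#' @export
cluster_clones <- function(contributions, n_pcs = 3, k = 2,
                           n_starts = 1e5, normalize = c("row_sum", "zscale"),
                           seed = NULL) {
  if (inherits(contributions, "signature_set")) {
    contributions <- contributions$contributions
  }
  normalize <- match.arg(normalize)
  X <- t(as.matrix(contributions))        # clones x signatures
  if (nrow(X) < k) stop("k exceeds the number of clones", call. = FALSE)
  ord <- order(rownames(X))
  X <- X[ord, , drop = FALSE]             # canonical order: stable labels
  if (normalize == "row_sum") {
    rs <- rowSums(X)
    X <- sweep(X, 1, ifelse(rs > 0, rs, 1), "/")
  } else {
    X <- scale(X)
    X[is.nan(X)] <- 0
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  npc <- min(n_pcs, ncol(pc$x))
  Y <- pc$x[, seq_len(npc), drop = FALSE]
  degenerate <- nrow(unique(round(Y, 12))) < k
  with_seed(seed, {
    if (degenerate) {
      cl <- rep(1L, nrow(Y)); wss <- 0
    } else {
      km <- kmeans(Y, centers = k, nstart = n_starts, iter.max = 100)
      cl <- km$cluster; wss <- km$tot.withinss
    }
    sizes <- table(cl)
    first <- tapply(rownames(Y), cl, min)
    lab_order <- order(-as.vector(sizes), as.vector(first))
    relabel <- match(seq_along(sizes), lab_order)
    cl <- relabel[cl]
    out <- tibble(clone = rownames(Y), cluster = as.integer(cl)) |>
      dplyr::bind_cols(as_tibble(Y))
    structure(list(clusters = out, tot_withinss = wss,
                   degenerate = degenerate, n_pcs = npc, k = k),
              class = "clone_clusters")
  })
}
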