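# Expression filtering, between-sample normalization factors, normalized
# abundances, and sample-level diagnostics.

#' Filter features with low expression
#'
#' Keeps feature i iff it has at least `min_count` counts in at least
#' `min_samples` samples. The defaults reproduce the standard "at least 4
#' counts in two or more samples" rule applied before normalization.
#' Filtering is idempotent and preserves feature order.
#'
#' @param x a [count_matrix()] or plain count matrix.
#' @param min_count,min_samples the filter rule.
#' @return object of the same kind with failing features removed (possibly
#'   zero rows).
#' @export
filter_low_expression <- function(x, min_count = 4, min_samples = 2) {
  counts <- as_counts(x)
  if (nrow(counts) == 0L) stopf("empty count matrix")
  keep <- rowSums(counts >= min_count) >= min_samples
  if (inherits(x, "count_matrix"))
    count_matrix(counts[keep, , drop = FALSE],
                 if (is.null(x$feature_type)) NULL else x$feature_type[keep])
  else counts[keep, , drop = FALSE]
}

new_norm_factors <- function(samples, lib_size, factor, method) {
  structure(data.frame(sample = samples, lib_size = lib_size,
                       factor = factor, stringsAsFactors = FALSE,
                       row.names = NULL),
            method = method, class = c("norm_factors", "data.frame"))
}

#' Upper-quartile normalization factors
#'
#' Per sample j, the raw factor is the 75th percentile of `count / N_j` over
#' features that are nonzero in at least one sample, where `N_j` is the
#' column sum. Factors are rescaled to geometric mean 1. Standard choice for
#' small-RNA libraries, whose count distribution is dominated by a few very
#' abundant species.
#'
#' @param x filtered [count_matrix()] or matrix; every sample must have at
#'   least one nonzero count.
#' @param p quantile used (default 0.75), linearly interpolated (type 7).
#' @return a `norm_factors` data frame with columns `sample`, `lib_size`,
#'   `factor`.
#' @export
upper_quartile_factors <- function(x, p = 0.75) {
  counts <- as_counts(x)
  n <- colSums(counts)
  zero <- n == 0 | colSums(counts > 0) == 0
  if (any(zero)) stopf("sample '%s' has no nonzero counts", colnames(counts)[zero][1])
  expressed <- rowSums(counts > 0) >= 1
  f <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[expressed, j] / n[j], p, names = FALSE, type = 7),
    numeric(1))
  if (any(f == 0)) stopf("upper-quartile factor is zero for sample '%s'",
                         colnames(counts)[f == 0][1])
  new_norm_factors(colnames(counts), n, rescale_geomean(f), "uq")
}

# trimmed, precision-weighted mean of M-values for one sample against the
# reference; returns the factor on the linear scale
tmm_one <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  shared <- obs > 0 & ref > 0
  if (!any(shared)) {
    warnf("no shared expressed features with reference; factor set to 1")
    return(1)
  }
  obs <- obs[shared]; ref <- ref[shared]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- 1 / (1 / obs - 1 / n_obs + 1 / ref - 1 / n_ref)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (sum(keep) < 10) {
    warnf("fewer than 10 features retained after TMM trimming; using untrimmed mean")
    keep <- rep(TRUE, n)
  }
  f <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' For each sample against a reference sample, M (log2 abundance ratio) and A
#' (average log2 abundance) values are computed over features nonzero in
#' both; the upper and lower `logratio_trim` fraction of M and `sum_trim`
#' fraction of A are trimmed; the factor is 2 to the precision-weighted mean
#' of the retained M values, with inverse asymptotic binomial variances as
#' weights. Factors are rescaled to geometric mean 1. Robust to a minority of
#' differentially expressed features; standard for mRNA libraries.
#'
#' @param x filtered [count_matrix()] or matrix.
#' @param reference reference sample id; default is the sample whose 75th
#'   percentile of `count / N` is closest to the across-sample mean.
#' @param logratio_trim,sum_trim trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @return a `norm_factors` data frame.
#' @export
tmm_factors <- function(x, reference = NULL, logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- as_counts(x)
  n <- colSums(counts)
  zero <- n == 0
  if (any(zero)) stopf("sample '%s' has no nonzero counts", colnames(counts)[zero][1])
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / n[j], 0.75, names = FALSE, type = 7), numeric(1))
  if (is.null(reference)) {
    ref_j <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_j <- match(reference, colnames(counts))
    if (is.na(ref_j)) stopf("reference sample '%s' not found", reference)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_j) return(1)
    tmm_one(counts[, j], counts[, ref_j], n[j], n[ref_j], logratio_trim, sum_trim)
  }, numeric(1))
  new_norm_factors(colnames(counts), n, rescale_geomean(f), "tmm")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors (%s): %d samples, factor range [%.4f, %.4f]\n",
              attr(x, "method"), nrow(x), min(x$factor), max(x$factor)))
  invisible(x)
}

#' Normalized abundances (counts per million)
#'
#' `value_ij = counts_ij / (N_j * f_j) * 1e6`, optionally log2-transformed
#' with a pseudo-count.
#'
#' @param x [count_matrix()] or matrix.
#' @param factors matching `norm_factors`; `NULL` uses factors of 1.
#' @param log return `log2(cpm + prior)` instead of cpm.
#' @param prior pseudo-count for the log transform.
#' @return numeric matrix, same shape as the input counts.
#' @export
normalize_counts <- function(x, factors = NULL, log = FALSE, prior = 0.5) {
  counts <- as_counts(x)
  if (is.null(factors)) {
    eff <- colSums(counts)
  } else {
    idx <- match(colnames(counts), factors$sample)
    if (anyNA(idx)) stopf("no normalization factor for sample '%s'",
                          colnames(counts)[is.na(idx)][1])
    eff <- factors$lib_size[idx] * factors$factor[idx]
  }
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  if (log) log2(cpm + prior) else cpm
}

#' Sample-by-sample Spearman correlation matrix
#'
#' Rank correlation between sample columns; ties get mean ranks. A standard
#' between-sample variability diagnostic.
#'
#' @param normalized matrix of (normalized) abundances, samples in columns.
#' @return symmetric sample x sample correlation matrix with unit diagonal.
#' @export
sample_spearman_matrix <- function(normalized) {
  rho <- stats::cor(normalized, method = "spearman")
  diag(rho) <- 1
  rho
}

#' PCA embedding of samples
#'
#' Principal components of the centered feature-by-sample matrix (samples as
#' observations). Typically run on log-normalized abundances.
#'
#' @param normalized matrix, features in rows and samples in columns.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components) and
#'   `explained_variance` (fraction per returned component; non-increasing,
#'   summing to at most 1 over all components).
#' @export
pca_embed <- function(normalized, n_components = 2) {
  if (ncol(normalized) < 2) stopf("PCA needs at least 2 samples")
  pc <- stats::prcomp(t(normalized), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)])
}
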