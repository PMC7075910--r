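# Negative binomial GLM likelihood-ratio differential expression at the
# common-dispersion level: IRLS fitting, Cox-Reid adjusted profile likelihood
# for the dispersion, chi-square LRT, Benjamini-Hochberg correction.

nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi < 1e-12) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit a negative binomial log-linear GLM to one feature
#'
#' Coefficients are estimated by iteratively reweighted least squares with
#' working weights `mu / (1 + phi * mu)`; the linear predictor is
#' `offset + X beta` on the natural log scale. Convergence when the largest
#' coefficient change falls below `tol`.
#'
#' @param y counts for one feature.
#' @param design design matrix (full rank, observations in rows).
#' @param offset per-observation offset, normally `log(N_j * f_j)`.
#' @param phi NB dispersion (0 gives a Poisson fit).
#' @param tol,max_iter IRLS stopping rule.
#' @return list with `coefficients`, `fitted`, `loglik`, `info` (the Fisher
#'   information `X' W X` at the fit), `converged`, and `degenerate` (TRUE
#'   for all-zero features, whose intercept is pinned at a floor).
#' @export
fit_nb_glm <- function(y, design, offset, phi, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(design)
  p <- ncol(X)
  if (all(y == 0)) {
    beta <- c(-30, rep(0, p - 1))
    mu <- exp(pmin(offset + drop(X %*% beta), 700))
    return(list(coefficients = beta, fitted = mu, loglik = nb_loglik(y, mu, phi),
                info = crossprod(X, X * (mu / (1 + phi * mu))),
                converged = TRUE, degenerate = TRUE))
  }
  mu0 <- pmax(y, mean(y) / 8)
  beta <- qr.coef(qr(X), log(mu0) - offset)
  beta[is.na(beta)] <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta_lin <- pmin(pmax(drop(X %*% beta), -40), 40)
    mu <- pmax(exp(offset + eta_lin), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- eta_lin + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    beta_new <- tryCatch(
      drop(solve(xtwx, crossprod(X, w * z))),
      error = function(e) drop(solve(xtwx + diag(1e-8, p), crossprod(X, w * z))))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta_lin <- pmin(pmax(drop(X %*% beta), -40), 40)
  mu <- pmax(exp(offset + eta_lin), 1e-10)
  w <- mu / (1 + phi * mu)
  list(coefficients = beta, fitted = mu, loglik = nb_loglik(y, mu, phi),
       info = crossprod(X, X * w), converged = converged, degenerate = FALSE)
}

#' Estimate the common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' Maximizes, over all features jointly, the sum of per-feature NB
#' log-likelihoods at the fitted means of the full design minus the Cox-Reid
#' adjustment (half the log-determinant of the per-feature Fisher
#' information). The search runs by golden section on
#' `log10(phi)` in `[-6, 1]`.
#'
#' @param counts [count_matrix()] or matrix.
#' @param factors `norm_factors` for the effective library sizes (`NULL` for
#'   raw column totals).
#' @param design full design matrix.
#' @param tol golden-section tolerance on the log10 scale.
#' @return the dispersion estimate (>= 0); a warning and a `boundary`
#'   attribute flag an estimate pinned at the upper search bound.
#' @export
estimate_common_dispersion <- function(counts, factors = NULL, design,
                                       tol = 0.01) {
  y <- as_counts(counts)
  X <- as.matrix(design)
  if (nrow(X) != ncol(y)) stopf("design rows must match samples")
  rank <- qr(X)$rank
  if (rank < ncol(X)) stopf("design matrix is not full rank")
  if (ncol(y) - rank < 1) stopf("no residual degrees of freedom")
  offsets <- log(effective_lib_sizes(y, factors))

  objective <- function(log10_phi) {
    phi <- 10^log10_phi
    total <- 0
    for (i in seq_len(nrow(y))) {
      fit <- fit_nb_glm(y[i, ], X, offsets, phi)
      total <- total + fit$loglik -
        0.5 * determinant(fit$info, logarithm = TRUE)$modulus
    }
    as.numeric(total)
  }

  lo <- -6; hi <- 1
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- objective(x1); f2 <- objective(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- objective(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- objective(x1)
    }
  }
  est <- 10^((lo + hi) / 2)
  boundary <- (1 - (lo + hi) / 2) < 2 * tol
  if (boundary)
    warnf("common dispersion estimate is at the upper search bound (%.3g)", est)
  structure(max(est, 0), boundary = boundary)
}

effective_lib_sizes <- function(counts, factors = NULL) {
  if (is.null(factors)) return(colSums(counts))
  idx <- match(colnames(counts), factors$sample)
  if (anyNA(idx)) stopf("no normalization factor for sample '%s'",
                        colnames(counts)[is.na(idx)][1])
  factors$lib_size[idx] * factors$factor[idx]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control:
#' `q_(i) = min over k >= i of min(1, p_(k) * m / k)` on the sorted p-values.
#'
#' @param p vector of p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Likelihood-ratio test between nested NB GLMs
#'
#' Fits the full and reduced design per feature at a shared common
#' dispersion; `LR = 2 (ll_full - ll_reduced)` is referred to a chi-square
#' distribution with the rank difference as degrees of freedom, and BH
#' correction is applied across features.
#'
#' @param counts [count_matrix()] or matrix.
#' @param design_full,design_reduced design matrices; the reduced design must
#'   be nested in the full one.
#' @param phi common NB dispersion.
#' @param factors `norm_factors` for the offsets (`NULL` for column totals).
#' @param coef column of `design_full` whose estimate is reported as the
#'   log2 fold change; defaults to the last column absent from the reduced
#'   design (by name), else the last column.
#' @param alpha significance level for the up/down/ns status call (on q).
#' @return a `de_result` data frame: `feature`, `logFC` (log2), `LR`, `p`,
#'   `q`, `mean_cpm`, `status`.
#' @export
lrt_test <- function(counts, design_full, design_reduced, phi, factors = NULL,
                     coef = NULL, alpha = 0.05) {
  y <- as_counts(counts)
  Xf <- as.matrix(design_full)
  Xr <- as.matrix(design_reduced)
  rank_f <- qr(Xf)$rank
  rank_r <- qr(Xr)$rank
  if (qr(cbind(Xr, Xf))$rank > rank_f || rank_r >= rank_f)
    stopf("reduced design is not nested in the full design")
  df <- rank_f - rank_r
  if (is.null(coef)) {
    cand <- setdiff(colnames(Xf), colnames(Xr))
    coef <- if (length(cand)) cand[length(cand)] else ncol(Xf)
  }
  coef_j <- if (is.character(coef)) match(coef, colnames(Xf)) else coef
  if (is.na(coef_j)) stopf("coefficient '%s' not found in the full design", coef)

  offsets <- log(effective_lib_sizes(y, factors))
  n <- nrow(y)
  lr <- logfc <- numeric(n)
  for (i in seq_len(n)) {
    ff <- fit_nb_glm(y[i, ], Xf, offsets, phi)
    fr <- fit_nb_glm(y[i, ], Xr, offsets, phi)
    lr[i] <- max(0, 2 * (ff$loglik - fr$loglik))
    logfc[i] <- ff$coefficients[coef_j] / log(2)
  }
  p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  q <- bh_adjust(p)
  cpm <- sweep(y, 2, exp(offsets), "/") * 1e6
  out <- data.frame(
    feature = rownames(y), logFC = logfc, LR = lr, p = p, q = q,
    mean_cpm = rowMeans(cpm),
    status = ifelse(q < alpha, ifelse(logfc > 0, "up", "down"), "ns"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df") <- df
  attr(out, "phi") <- phi
  class(out) <- c("de_result", "data.frame")
  out
}

#' Differential expression between two stages
#'
#' Convenience wrapper reproducing the standard stage-contrast analysis:
#' subsets the samples to the two stages, builds the full design
#' `~ cell_line + stage` (cell line dropped automatically when only one line
#' is present) against the reduced design without stage, estimates the
#' common dispersion if not supplied, and runs [lrt_test()].
#'
#' @param counts [count_matrix()] or matrix for one library type.
#' @param samples sample table covering the matrix columns.
#' @param stage_a,stage_b the contrast (fold changes are b vs a).
#' @param factors `norm_factors` computed on the full matrix.
#' @param phi common dispersion; estimated from the contrast samples when
#'   `NULL`.
#' @param use_cell_line include cell line as an additive covariate.
#' @param alpha significance level for the status call.
#' @return a `de_result` (see [lrt_test()]); the dispersion used is in
#'   `attr(, "phi")`.
#' @export
de_between_stages <- function(counts, samples, stage_a = "0", stage_b = "3",
                              factors = NULL, phi = NULL, use_cell_line = TRUE,
                              alpha = 0.05) {
  y <- as_counts(counts)
  meta <- samples[match(colnames(y), samples$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stopf("sample table does not cover all columns")
  keep <- meta$stage %in% c(stage_a, stage_b)
  if (!any(meta$stage == stage_a) || !any(meta$stage == stage_b))
    stopf("contrast stages %s/%s not both present", stage_a, stage_b)
  y <- y[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  stage <- factor(meta$stage, levels = c(stage_a, stage_b))
  use_cl <- use_cell_line && length(unique(meta$cell_line)) > 1
  if (use_cl) {
    line <- factor(meta$cell_line)
    full <- stats::model.matrix(~ line + stage)
    reduced <- stats::model.matrix(~ line)
  } else {
    full <- stats::model.matrix(~ stage)
    reduced <- stats::model.matrix(~ 1, data = data.frame(row.names = seq_len(ncol(y))))
  }
  rownames(full) <- rownames(reduced) <- colnames(y)
  if (is.null(phi))
    phi <- estimate_common_dispersion(y, factors, full)
  out <- lrt_test(y, full, reduced, phi = as.numeric(phi), factors = factors,
                  coef = paste0("stage", stage_b), alpha = alpha)
  attr(out, "contrast") <- c(stage_a, stage_b)
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d features tested, %d up / %d down at q < 0.05 (phi = %.4g)\n",
              nrow(x), sum(x$status == "up"), sum(x$status == "down"),
              attr(x, "phi")))
  invisible(x)
}
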