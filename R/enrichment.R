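# Regulator-target databases and Fisher exact enrichment of targets within
# co-expression clusters; generic gene-set (GO-style) enrichment on the same
# engine.

new_interaction_db <- function(pairs, regulator_class) {
  pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]  # no self-targeting
  key <- paste(pairs$regulator, pairs$target, sep = "\r")
  sources <- vapply(split(pairs$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  dedup <- pairs[!duplicated(key), c("regulator", "target"), drop = FALSE]
  dedup$sources <- unname(sources[paste(dedup$regulator, dedup$target, sep = "\r")])
  rownames(dedup) <- NULL
  if (nrow(dedup) == 0L) warnf("interaction database is empty")
  structure(list(pairs = dedup,
                 targets = lapply(split(dedup$target, dedup$regulator), unique),
                 regulator_class = regulator_class),
            class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db (%s): %d regulators, %d pairs\n",
              x$regulator_class, length(x$targets), nrow(x$pairs)))
  invisible(x)
}

#' Build the high-confidence miRNA-target database
#'
#' Combines predicted interactions passing a strict total context score
#' cutoff (TargetScan dialect; more negative = stronger predicted
#' repression) with experimentally validated interactions whose evidence
#' mentions a luciferase reporter assay (miRTarBase dialect,
#' case-insensitive substring match). The union is deduplicated with
#' per-pair provenance; self-targeting pairs are dropped.
#'
#' @param targetscan_records,mirtarbase_records record data frames from
#'   [read_interaction_table()].
#' @param score_threshold keep TargetScan pairs with score strictly below
#'   this (default -0.3; the boundary value is excluded).
#' @param evidence_token substring identifying accepted evidence.
#' @return an `interaction_db` with `regulator_class = "mirna"`.
#' @export
build_mirna_target_db <- function(targetscan_records, mirtarbase_records,
                                  score_threshold = -0.3,
                                  evidence_token = "luciferase") {
  ts <- targetscan_records[!is.na(targetscan_records$score) &
                             targetscan_records$score < score_threshold, ,
                           drop = FALSE]
  mtb <- mirtarbase_records[grepl(evidence_token, mirtarbase_records$evidence,
                                  ignore.case = TRUE), , drop = FALSE]
  new_interaction_db(rbind(ts, mtb), "mirna")
}

#' Build the TF-target database
#'
#' Union of curated (TRRUST dialect), co-expression derived (FANTOM5
#' dialect) and ChIP-seq derived (ENCODE dialect) TF-target pairs,
#' deduplicated with provenance retained.
#'
#' @param trrust_records,fantom5_records,encode_records record data frames
#'   from [read_interaction_table()]; any may be empty.
#' @return an `interaction_db` with `regulator_class = "tf"`.
#' @export
build_tf_target_db <- function(trrust_records, fantom5_records, encode_records) {
  new_interaction_db(rbind(trrust_records, fantom5_records, encode_records), "tf")
}

# one-sided (greater) hypergeometric tail P(X >= a) for a 2x2 table with
# margins K = a+c (targets), n = a+b (cluster), N total; log-space sum
hyper_tail_p <- function(a, K, n, N) {
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  if (a <= lo) return(1)
  if (a > hi) return(0)
  k <- a:hi
  logp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

# two-sided p in the usual exact-test sense: sum of all outcome
# probabilities no larger than the observed one (with a small tolerance)
hyper_two_sided_p <- function(a, K, n, N) {
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  k <- lo:hi
  logp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  obs <- logp[k == a]
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

#' Fisher exact enrichment of a target set within a cluster
#'
#' Builds the 2x2 table (a = targets in cluster, b = non-targets in cluster,
#' c = targets outside, d = non-targets outside) over a background universe,
#' intersecting the target set with the background first. The odds ratio is
#' `ad / (bc)`; the default p-value is the one-sided (greater) exact
#' hypergeometric tail. A zero-denominator odds ratio is reported as `Inf`
#' when the numerator is positive; a degenerate margin (no targets in
#' background, or empty cluster/complement margin making enrichment
#' meaningless) gives an `NA` odds ratio with p = 1.
#'
#' @param targets character vector of target ids.
#' @param cluster character vector of cluster member ids; must be a subset
#'   of `background`.
#' @param background character vector, the background universe.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return list with `table` (named counts a, b, c, d), `odds_ratio`,
#'   `p_value`, `fold_enrichment`.
#' @export
fisher_enrichment <- function(targets, cluster, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  cluster <- unique(cluster)
  if (length(setdiff(cluster, background)))
    stopf("cluster contains %d id(s) outside the background",
          length(setdiff(cluster, background)))
  targets <- intersect(unique(targets), background)
  a <- length(intersect(targets, cluster))
  b <- length(cluster) - a
  cc <- length(targets) - a
  d <- length(background) - a - b - cc
  N <- a + b + cc + d
  K <- a + cc  # targets in background
  n <- a + b   # cluster size
  degenerate <- K == 0 || n == 0 || K == N || n == N
  odds_ratio <- if (degenerate) NA_real_
                else if (b * cc == 0) { if (a * d > 0) Inf else NA_real_ }
                else (a * d) / (b * cc)
  p <- if (degenerate) 1
       else if (alternative == "greater") hyper_tail_p(a, K, n, N)
       else hyper_two_sided_p(a, K, n, N)
  fold <- if (n == 0 || K == 0) 0 else (a / n) / (K / N)
  list(table = c(a = a, b = b, c = cc, d = d),
       odds_ratio = odds_ratio, p_value = p, fold_enrichment = fold)
}

as_cluster_list <- function(clusters) {
  if (inherits(clusters, "cluster_assignment"))
    return(split(names(clusters$membership), clusters$membership))
  if (is.list(clusters)) return(clusters)
  split(names(clusters), clusters)  # named membership vector
}

#' Per-regulator Fisher enrichment against every cluster
#'
#' One exact test per (regulator, cluster) pair with BH correction across
#' all tests of the regulator class. Default significance rules follow the
#' class conventions: TFs at raw `p < 0.001` and odds ratio > 1, miRNAs at
#' `q < 0.05` and odds ratio > 1; both are configurable. When a DE table is
#' given and a regulator is itself a measured feature, its own
#' differential-expression status is joined in.
#'
#' @param db an `interaction_db`.
#' @param clusters a `cluster_assignment`, a named membership vector, or a
#'   list of member id vectors.
#' @param background background universe (features considered expressed).
#' @param de_table optional `de_result` for regulator DE status.
#' @param p_threshold,q_threshold,or_threshold significance rule; defaults
#'   depend on `db$regulator_class` (tf: p < 0.001; mirna: q < 0.05; both
#'   with OR > `or_threshold`).
#' @param alternative test sidedness, as in [fisher_enrichment()].
#' @return an `enrichment_result` data frame: `regulator`, `cluster`, `a`,
#'   `b`, `c`, `d`, `odds_ratio`, `p`, `q`, `significant`,
#'   `regulator_de_status`.
#' @export
enrich_regulators <- function(db, clusters, background, de_table = NULL,
                              p_threshold = NULL, q_threshold = NULL,
                              or_threshold = 1,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  cl <- as_cluster_list(clusters)
  if (length(cl) == 0L || all(lengths(cl) == 0L)) stopf("empty clusters")
  cl <- lapply(cl, intersect, x = background)
  if (is.null(p_threshold) && is.null(q_threshold)) {
    if (db$regulator_class == "tf") p_threshold <- 0.001 else q_threshold <- 0.05
  }
  regs <- names(db$targets)
  grid <- expand.grid(regulator = regs, cluster = names(cl),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(r, k)
    fisher_enrichment(db$targets[[r]], cl[[k]], background, alternative),
    grid$regulator, grid$cluster, SIMPLIFY = FALSE)
  tab <- do.call(rbind, lapply(res, function(x) x$table))
  out <- data.frame(grid, tab,
                    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
                    p = vapply(res, `[[`, numeric(1), "p_value"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- bh_adjust(out$p)
  sig <- out$odds_ratio > or_threshold & !is.na(out$odds_ratio)
  if (!is.null(p_threshold)) sig <- sig & out$p < p_threshold
  if (!is.null(q_threshold)) sig <- sig & out$q < q_threshold
  out$significant <- sig
  out$regulator_de_status <- if (is.null(de_table)) NA_character_ else
    de_table$status[match(out$regulator, de_table$feature)]
  attr(out, "regulator_class") <- db$regulator_class
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Gene-set enrichment of a query list
#'
#' Runs the same exact-test engine per gene set, treating the set members as
#' "targets" and the query list as the "cluster": fold enrichment is
#' `(a / |query|) / (|set in background| / N)`. BH correction across sets.
#'
#' @param sets a `gene_set_collection` or named list of member vectors.
#' @param query character vector of query ids (must lie in the background).
#' @param background background universe.
#' @param alternative test sidedness.
#' @return an `enrichment_result` data frame with columns `set`, `a`-`d`,
#'   `odds_ratio`, `fold_enrichment`, `p`, `q`.
#' @export
gene_set_enrichment <- function(sets, query, background,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  query <- intersect(unique(query), background)
  res <- lapply(sets, function(s)
    fisher_enrichment(s, query, background, alternative))
  tab <- do.call(rbind, lapply(res, function(x) x$table))
  out <- data.frame(set = names(sets), tab,
                    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
                    fold_enrichment = vapply(res, `[[`, numeric(1), "fold_enrichment"),
                    p = vapply(res, `[[`, numeric(1), "p_value"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- bh_adjust(out$p)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cls <- attr(x, "regulator_class")
  cat(sprintf("enrichment_result%s: %d tests, %d significant\n",
              if (is.null(cls)) "" else sprintf(" (%s)", cls), nrow(x),
              if ("significant" %in% names(x)) sum(x$significant) else sum(x$q < 0.05)))
  invisible(x)
}
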