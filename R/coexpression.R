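# Joint mRNA + miRNA co-expression: Pearson correlation graph at a high
# threshold, clustered with a from-scratch Markov Cluster (MCL)
# implementation, plus per-cluster stage profile summaries.

#' Combine normalized mRNA and miRNA tables over shared biological samples
#'
#' The two library types are sequenced from the same biological samples;
#' columns are matched on (stage, cell_line, replicate) and renamed to a
#' common biological sample id so that correlations can be computed across
#' the combined table. mRNA features can be restricted to protein-coding.
#'
#' @param norm_mrna,norm_mirna normalized matrices (e.g. log2 CPM) whose
#'   columns are library sample ids present in `samples`.
#' @param samples the sample table.
#' @param coding_only restrict mRNA rows to `mRNA_coding` features
#'   (requires `feature_type`).
#' @param feature_type named type vector (needed when `coding_only = TRUE`).
#' @return combined matrix, rows = mRNA then miRNA features, columns =
#'   biological samples present in both library types.
#' @export
combine_expression <- function(norm_mrna, norm_mirna, samples,
                               coding_only = TRUE, feature_type = NULL) {
  bio_id <- function(meta) sprintf("s%s_%s_r%s", meta$stage, meta$cell_line,
                                   meta$replicate)
  meta_mrna <- samples[match(colnames(norm_mrna), samples$sample_id), ]
  meta_mirna <- samples[match(colnames(norm_mirna), samples$sample_id), ]
  if (anyNA(meta_mrna$sample_id) || anyNA(meta_mirna$sample_id))
    stopf("sample table does not cover all matrix columns")
  shared <- intersect(bio_id(meta_mrna), bio_id(meta_mirna))
  if (length(shared) < 3) stopf("fewer than 3 shared biological samples")
  a <- norm_mrna[, match(shared, bio_id(meta_mrna)), drop = FALSE]
  b <- norm_mirna[, match(shared, bio_id(meta_mirna)), drop = FALSE]
  colnames(a) <- colnames(b) <- shared
  if (coding_only) {
    if (is.null(feature_type)) stopf("'feature_type' needed for coding_only")
    a <- a[rownames(a) %in% names(feature_type)[feature_type == "mRNA_coding"], ,
           drop = FALSE]
  }
  rbind(a, b)
}

#' Feature-by-feature Pearson correlation matrix
#'
#' Correlations are computed across all samples (columns). Constant-valued
#' features carry no correlation signal and are removed with a warning,
#' recorded in the `"dropped_constant"` attribute.
#'
#' @param x matrix of normalized abundances, features in rows.
#' @param features optional feature id subset.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x, features = NULL) {
  if (!is.null(features)) x <- x[rownames(x) %in% features, , drop = FALSE]
  if (ncol(x) < 3) stopf("need at least 3 samples for correlation")
  constant <- apply(x, 1, function(v) max(v) - min(v) < .Machine$double.eps * 100)
  if (any(constant)) {
    warnf("dropping %d constant feature(s) from the correlation", sum(constant))
    x <- x[!constant, , drop = FALSE]
  }
  r <- stats::cor(t(x), method = "pearson")
  diag(r) <- 1
  attr(r, "dropped_constant") <- names(constant)[constant]
  r
}

#' Threshold a correlation matrix into a co-expression graph
#'
#' Keeps edges whose statistic strictly exceeds the threshold; isolated
#' nodes are dropped. The statistic is the Pearson r by default; `"r2"`
#' thresholds the squared correlation instead (sign ignored).
#'
#' @param r correlation matrix from [pearson_matrix()].
#' @param threshold edge threshold (default 0.98).
#' @param statistic `"r"` or `"r2"`.
#' @return a `correlation_graph`: list with `nodes`, `edges` (data frame
#'   `a`, `b`, `weight` = r), `threshold`, `statistic`.
#' @export
threshold_graph <- function(r, threshold = 0.98, statistic = c("r", "r2")) {
  statistic <- match.arg(statistic)
  stat <- if (statistic == "r2") r^2 else r
  hit <- which(upper.tri(stat) & stat > threshold, arr.ind = TRUE)
  edges <- data.frame(a = rownames(r)[hit[, 1]], b = colnames(r)[hit[, 2]],
                      weight = r[hit], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$a, edges$b)))
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 statistic = statistic),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("correlation_graph: %d nodes, %d edges (%s > %g)\n",
              length(x$nodes), nrow(x$edges), x$statistic, x$threshold))
  invisible(x)
}

# one MCL expansion (matrix square) and one inflation (entrywise power then
# column renormalization with pruning); exposed internally for invariants
mcl_expand <- function(m) m %*% m
mcl_inflate <- function(m, inflation, prune = 1e-6) {
  m <- m^inflation
  m[m < prune] <- 0
  sweep(m, 2, pmax(colSums(m), .Machine$double.xmin), "/")
}

#' Markov Cluster (MCL) graph clustering
#'
#' Builds a column-stochastic transition matrix from the edge weights with
#' self-loops (each node's self-loop weight is its maximum incident edge
#' weight), then alternates expansion (matrix squaring) and inflation
#' (entrywise power with column renormalization, pruning entries below
#' `prune`) until the matrix stops changing. Clusters are the connected
#' components of the converged attractor structure; components smaller than
#' `min_cluster_size` are reported as unclustered. The algorithm is fully
#' deterministic.
#'
#' @param graph a `correlation_graph` (or any list with `nodes` and `edges`).
#' @param inflation inflation exponent (default 2.0).
#' @param min_cluster_size smallest reported cluster.
#' @param max_iter,tol,prune iteration controls; non-convergence after
#'   `max_iter` iterations yields a warning and a flagged result.
#' @return a `cluster_assignment`: list with `membership` (named cluster
#'   label per clustered feature, labels `C1`, `C2`, ... ordered by
#'   decreasing size), `unclustered` (node ids in dropped small components),
#'   `sizes`, `converged`, `iterations`, and the call parameters.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, min_cluster_size = 3,
                        max_iter = 200, tol = 1e-8, prune = 1e-6) {
  nodes <- graph$nodes
  edges <- graph$edges
  if (length(nodes) == 0L) stopf("empty graph")
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
  adj[cbind(ia, ib)] <- edges$weight
  adj[cbind(ib, ia)] <- edges$weight
  loop <- apply(adj, 1, max)
  loop[loop <= 0] <- 1
  diag(adj) <- loop
  m <- sweep(adj, 2, colSums(adj), "/")
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    m_new <- mcl_inflate(mcl_expand(m), inflation, prune)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("MCL did not converge in %d iterations (last change %.2e)", max_iter, delta)
  keep <- which(m > prune & row(m) != col(m), arr.ind = TRUE)
  comp <- graph_components(nodes, nodes[keep[, 1]], nodes[keep[, 2]])
  comp_sizes <- table(comp)
  big <- as.integer(names(comp_sizes)[comp_sizes >= min_cluster_size])
  big <- big[order(-comp_sizes[as.character(big)])]
  membership <- stats::setNames(rep(NA_character_, n), nodes)
  for (i in seq_along(big))
    membership[comp == big[i]] <- sprintf("C%d", i)
  structure(list(
    membership = membership[!is.na(membership)],
    unclustered = nodes[is.na(membership)],
    sizes = if (length(big)) table(membership[!is.na(membership)]) else table(character()),
    converged = converged, iterations = it,
    inflation = inflation, min_cluster_size = min_cluster_size),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d clusters over %d features (+%d unclustered)\n",
              length(x$sizes), length(x$membership), length(x$unclustered)))
  if (length(x$sizes))
    cat("  sizes:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster stage expression profiles
#'
#' For each cluster and stage, the mean normalized abundance of the member
#' features over all samples of that stage (averaging cell lines and
#' replicates); also reports each clustered feature's stage of highest mean
#' expression.
#'
#' @param assignment a `cluster_assignment`.
#' @param normalized combined normalized matrix (columns = biological
#'   samples, as from [combine_expression()]).
#' @param samples sample table; stage is looked up per column by matching
#'   either `sample_id` or the biological id `s<stage>_<line>_r<rep>`.
#' @return list with `profile` (cluster x stage matrix of means) and
#'   `peak_stage` (named character, per clustered feature).
#' @export
cluster_profiles <- function(assignment, normalized, samples) {
  bio <- sprintf("s%s_%s_r%s", samples$stage, samples$cell_line, samples$replicate)
  idx <- match(colnames(normalized), samples$sample_id)
  idx2 <- match(colnames(normalized), bio)
  stage <- ifelse(!is.na(idx), samples$stage[idx], samples$stage[idx2])
  if (anyNA(stage)) stopf("cannot resolve stage for column '%s'",
                          colnames(normalized)[is.na(stage)][1])
  stages <- unique(samples$stage)
  feats <- intersect(names(assignment$membership), rownames(normalized))
  stage_means <- vapply(stages, function(s)
    rowMeans(normalized[feats, stage == s, drop = FALSE]),
    numeric(length(feats)))
  if (is.null(dim(stage_means)))
    stage_means <- matrix(stage_means, nrow = length(feats),
                          dimnames = list(feats, stages))
  labels <- assignment$membership[feats]
  profile <- do.call(rbind, lapply(split(feats, labels), function(members)
    colMeans(stage_means[members, , drop = FALSE])))
  peak <- stats::setNames(stages[max.col(stage_means, ties.method = "first")], feats)
  list(profile = profile, peak_stage = peak)
}
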