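# STRING-dialect protein-protein interaction network handling: confidence
# filtering, induced subnetworks, subnetwork edge-enrichment, hubs.

ppi_nodes <- function(network) unique(c(network$protein_a, network$protein_b))

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n", length(ppi_nodes(x)), nrow(x)))
  invisible(x)
}

#' Keep only high-confidence interactions
#'
#' Retains edges whose combined score, on the 0-1 scale, strictly exceeds
#' `min_score` (default 0.7, the usual "high confidence" cutoff).
#'
#' @param network a `ppi_network`.
#' @param min_score threshold on score / 1000.
#' @return filtered `ppi_network`.
#' @export
filter_high_confidence <- function(network, min_score = 0.7) {
  out <- network[network$combined_score / 1000 > min_score, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppi_network", "data.frame")
  out
}

#' Subnetwork induced by a gene set
#'
#' Nodes are the intersection of the set with the network's nodes; edges are
#' those with both endpoints inside.
#'
#' @param network a `ppi_network`.
#' @param genes character vector of node ids.
#' @return induced `ppi_network`.
#' @export
induced_subnetwork <- function(network, genes) {
  out <- network[network$protein_a %in% genes & network$protein_b %in% genes, ,
                 drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppi_network", "data.frame")
  out
}

#' Edge enrichment of a node set within a background network
#'
#' Tests whether the subnetwork induced by `genes` has more edges than
#' expected for a random set of nodes of the same size. The analytic method
#' uses the degree-preserving Chung-Lu expectation
#' `lambda = sum over pairs {u,v} in S of min(1, k_u k_v / (2M))` with a
#' Poisson upper tail for the p-value; the permutation method draws `n_perm`
#' uniform node sets of the same size and uses the empirical tail
#' `(1 + #{m_perm >= m}) / (n_perm + 1)`.
#'
#' @param genes the node set (ids outside the network are ignored).
#' @param network background `ppi_network`; typically already
#'   confidence-filtered.
#' @param method `"analytic"` or `"permutation"`.
#' @param n_perm permutations for the permutation method.
#' @return list with `observed` (edge count m), `expected` (lambda, or the
#'   permutation mean), `p_value`, `n_nodes`, `method`.
#' @export
edge_enrichment_test <- function(genes, network,
                                 method = c("analytic", "permutation"),
                                 n_perm = 2000) {
  method <- match.arg(method)
  nodes <- ppi_nodes(network)
  s <- intersect(unique(genes), nodes)
  if (length(s) < 2) stopf("need at least 2 set nodes present in the network")
  m <- nrow(induced_subnetwork(network, s))
  if (method == "analytic") {
    deg <- table(factor(c(network$protein_a, network$protein_b), levels = nodes))
    k <- as.numeric(deg[s])
    two_m <- 2 * nrow(network)
    pk <- outer(k, k) / two_m
    pk[pk > 1] <- 1
    lambda <- sum(pk[upper.tri(pk)])
    p <- stats::ppois(m - 1, lambda, lower.tail = FALSE)
    return(list(observed = m, expected = lambda, p_value = p,
                n_nodes = length(s), method = "analytic"))
  }
  perm <- vapply(seq_len(n_perm), function(i)
    nrow(induced_subnetwork(network, sample(nodes, length(s)))), numeric(1))
  list(observed = m, expected = mean(perm),
       p_value = (1 + sum(perm >= m)) / (n_perm + 1),
       n_nodes = length(s), method = "permutation")
}

#' Top-k hub nodes by degree
#'
#' Ties are broken lexically by node id, making the ranking deterministic.
#'
#' @param network a `ppi_network`.
#' @param k how many hubs to return.
#' @return data frame with columns `node` and `degree`, at most `k` rows.
#' @export
hub_nodes <- function(network, k = 10) {
  nodes <- ppi_nodes(network)
  deg <- table(factor(c(network$protein_a, network$protein_b), levels = nodes))
  ord <- order(-as.numeric(deg), names(deg))
  utils::head(data.frame(node = names(deg)[ord],
                         degree = as.numeric(deg)[ord],
                         stringsAsFactors = FALSE, row.names = NULL), k)
}
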