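# shared internal helpers

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1

# rescale positive factors so their geometric mean is exactly 1
rescale_geomean <- function(f) {
  if (any(!is.finite(f) | f <= 0)) stopf("normalization factors must be finite and > 0")
  f / exp(mean(log(f)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#' Used throughout to quantify recovery of planted cluster structure.
#'
#' @param labels_a,labels_b vectors of equal length giving the two partitions.
#'   Label values are arbitrary; only the induced partitions matter.
#' @return a single number, 1 for identical partitions, ~0 for independent ones.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("partitions have different lengths (%d vs %d)",
          length(labels_a), length(labels_b))
  if (length(labels_a) < 2L) return(1)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(labels_a), 2)
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < .Machine$double.eps^0.5) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# connected components of an undirected graph given as an edge list over
# `nodes`; returns an integer component id per node
graph_components <- function(nodes, from, to) {
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(from, nodes)
  ib <- match(to, nodes)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
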