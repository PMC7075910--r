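test_that("Pearson matrix matches the direct formula and flags degenerate input", {
  set.seed(50)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("f%d", 1:10),
                                                sprintf("s%d", 1:6)))
  x["f2", ] <- x["f1", ]                 # duplicate
  x["f3", ] <- -x["f1", ] + 2           # negated after centering
  r <- pearson_matrix(x)
  expect_equal(r["f1", "f2"], 1)
  expect_equal(r["f1", "f3"], -1)
  # independent covariance-based computation for one pair
  a <- x["f4", ]; b <- x["f5", ]
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r["f4", "f5"], oracle)

  expect_error(pearson_matrix(x[, 1:2]), "at least 3 samples")
  x2 <- rbind(x, const = rep(5, 6))
  expect_warning(r2 <- pearson_matrix(x2), "constant")
  expect_false("const" %in% rownames(r2))
})

test_that("graph thresholding is strict and drops isolated nodes", {
  r <- diag(4)
  rownames(r) <- colnames(r) <- c("a", "b", "c", "d")
  r["a", "b"] <- r["b", "a"] <- 0.99
  r["a", "c"] <- r["c", "a"] <- 0.98
  r["b", "c"] <- r["c", "b"] <- 0.97
  g <- threshold_graph(r, 0.98)
  expect_equal(nrow(g$edges), 1)          # only 0.99 passes strictly
  expect_setequal(g$nodes, c("a", "b"))   # c and d isolated -> dropped

  # duplicates (r exactly 1) connect just below a threshold of 1
  r2 <- diag(3); rownames(r2) <- colnames(r2) <- c("x", "y", "z")
  r2["x", "y"] <- r2["y", "x"] <- 1
  r2["x", "z"] <- r2["z", "x"] <- 0.9999
  g2 <- threshold_graph(r2, 1 - 1e-9)
  expect_equal(nrow(g2$edges), 1)
  expect_setequal(g2$nodes, c("x", "y"))

  # r2 statistic ignores the sign
  r3 <- diag(2); rownames(r3) <- colnames(r3) <- c("p", "q")
  r3["p", "q"] <- r3["q", "p"] <- -0.995
  expect_equal(nrow(threshold_graph(r3, 0.98, statistic = "r2")$edges), 1)
  expect_equal(nrow(threshold_graph(r3, 0.98, statistic = "r")$edges), 0)
})

test_that("MCL resolves disconnected and complete graphs", {
  tri2 <- structure(list(
    nodes = c("a", "b", "c", "d", "e", "f"),
    edges = data.frame(a = c("a", "b", "c", "d", "e", "f"),
                       b = c("b", "c", "a", "e", "f", "d"),
                       weight = 1, stringsAsFactors = FALSE)),
    class = "correlation_graph")
  cl <- mcl_cluster(tri2)
  expect_equal(length(cl$sizes), 2)
  expect_true(all(cl$sizes == 3))
  expect_equal(cl$membership[["a"]], cl$membership[["b"]])
  expect_false(cl$membership[["a"]] == cl$membership[["d"]])

  n8 <- sprintf("k%d", 1:8)
  pairs <- t(combn(8, 2))
  complete <- structure(list(
    nodes = n8, edges = data.frame(a = n8[pairs[, 1]], b = n8[pairs[, 2]],
                                   weight = 1, stringsAsFactors = FALSE)),
    class = "correlation_graph")
  cl8 <- mcl_cluster(complete)
  expect_equal(length(cl8$sizes), 1)
  expect_equal(unname(cl8$sizes[1]), 8)
})

test_that("MCL recovers a planted 6-block partition deterministically", {
  bg <- make_block_graph(rep(30, 6), 0.9, 0.01, seed = 99)
  cl <- mcl_cluster(bg$graph)
  got <- cl$membership[names(bg$truth)]
  keep <- !is.na(got)
  ari <- adjusted_rand_index(bg$truth[keep], got[keep])
  expect_gte(ari, 0.9)
  # determinism across runs
  cl2 <- mcl_cluster(bg$graph)
  expect_identical(cl$membership, cl2$membership)
  # the package ARI agrees with the established oracle
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(bg$truth[keep], got[keep]))
})

test_that("node order permutation changes labels but not the partition", {
  bg <- make_block_graph(rep(12, 3), 0.95, 0.02, seed = 5)
  g <- bg$graph
  set.seed(1)
  perm <- sample(length(g$nodes))
  g2 <- g
  g2$nodes <- g$nodes[perm]
  cl1 <- mcl_cluster(g)
  cl2 <- mcl_cluster(g2)
  shared <- intersect(names(cl1$membership), names(cl2$membership))
  expect_equal(adjusted_rand_index(cl1$membership[shared], cl2$membership[shared]), 1)
})

test_that("transition matrix stays column-stochastic through the iterations", {
  bg <- make_block_graph(rep(10, 2), 0.9, 0.05, seed = 3)
  g <- bg$graph
  n <- length(g$nodes)
  adj <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  ia <- match(g$edges$a, g$nodes); ib <- match(g$edges$b, g$nodes)
  adj[cbind(ia, ib)] <- adj[cbind(ib, ia)] <- g$edges$weight
  diag(adj) <- apply(adj, 1, max)
  m <- sweep(adj, 2, colSums(adj), "/")
  for (i in 1:15) {
    m <- chondronet:::mcl_inflate(chondronet:::mcl_expand(m), 2)
    expect_lt(max(abs(colSums(m) - 1)), 1e-9)
  }
})

test_that("cluster stage profiles average members and replicates correctly", {
  samples <- data.frame(sample_id = sprintf("m_%d", 1:6),
                        stage = rep(c("0", "3"), each = 3),
                        cell_line = "L", replicate = rep(1:3, 2),
                        batch = "b1", library = "mrna",
                        stringsAsFactors = FALSE)
  x <- rbind(f1 = c(1, 2, 3, 10, 11, 12),
             f2 = c(2, 3, 4, 20, 21, 22),
             f3 = c(9, 9, 9, 1, 1, 1))
  colnames(x) <- samples$sample_id
  asg <- structure(list(membership = c(f1 = "C1", f2 = "C1", f3 = "C2"),
                        unclustered = character(), sizes = table(c("C1", "C1", "C2"))),
                   class = "cluster_assignment")
  prof <- cluster_profiles(asg, x, samples)
  expect_equal(prof$profile["C1", "0"], mean(c(1, 2, 3, 2, 3, 4)))
  expect_equal(prof$profile["C1", "3"], mean(c(10, 11, 12, 20, 21, 22)))
  expect_equal(prof$profile["C2", ], c("0" = 9, "3" = 1))  # single member
  expect_equal(unname(prof$peak_stage[c("f1", "f2", "f3")]), c("3", "3", "0"))

  # cluster of identical features reproduces the common profile
  x2 <- rbind(f1 = c(1, 1, 1, 5, 5, 5), f2 = c(1, 1, 1, 5, 5, 5))
  colnames(x2) <- samples$sample_id
  asg2 <- structure(list(membership = c(f1 = "C1", f2 = "C1")),
                    class = "cluster_assignment")
  expect_equal(cluster_profiles(asg2, x2, samples)$profile["C1", ],
               c("0" = 1, "3" = 5))
})

test_that("planted clusters give dense within and sparse between edges", {
  ds <- generate_dataset(small_config(seed = 7))
  fm <- filter_low_expression(ds$mrna)
  fmir <- filter_low_expression(ds$mirna)
  nm <- normalize_counts(fm, tmm_factors(fm), log = TRUE)
  nmir <- normalize_counts(fmir, upper_quartile_factors(fmir), log = TRUE)
  comb <- combine_expression(nm, nmir, ds$samples, coding_only = TRUE,
                             feature_type = c(fm$feature_type, fmir$feature_type))
  g <- threshold_graph(pearson_matrix(comb), 0.98)
  cl <- ds$truth$cluster_of
  same <- !is.na(cl[g$edges$a]) & !is.na(cl[g$edges$b]) &
    cl[g$edges$a] == cl[g$edges$b]
  n_planted <- sum(!is.na(cl))
  within_pairs <- sum(sapply(ds$truth$cluster_members, function(m) choose(length(m), 2)))
  between_pairs <- choose(n_planted, 2) - within_pairs
  dens_within <- sum(same) / within_pairs
  dens_between <- sum(!same) / between_pairs  # generous upper bound
  expect_gt(dens_within, 50 * max(dens_between, 1e-6))
})
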