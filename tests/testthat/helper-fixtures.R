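# Shared fixtures: everything is generated in code at test time.

# compact study configuration used by most module tests (fast but carries
# the full planted structure)
small_config <- function(seed = 7, ...) {
  defaults <- list(n_mrna = 600, n_mirna = 80, cluster_size_mrna = 25,
                   cluster_size_mirna = 4, mean_lib_size_mrna = 1e6,
                   mean_lib_size_mirna = 2e5, n_regulators_tf = 12,
                   n_regulators_mirna = 12, targets_per_regulator = 40,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

toy_counts <- function(values, n_features, n_samples,
                       features = sprintf("f%02d", seq_len(n_features)),
                       samples = sprintf("s%d", seq_len(n_samples))) {
  matrix(values, n_features, n_samples, byrow = TRUE,
         dimnames = list(features, samples))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# construct explicit id sets realizing a given 2x2 enrichment table
sets_from_table <- function(a, b, c, d) {
  n <- a + b + c + d
  ids <- sprintf("g%04d", seq_len(n))
  cluster <- ids[seq_len(a + b)]
  targets <- c(ids[seq_len(a)], ids[seq.int(a + b + 1, length.out = c)])
  list(targets = targets, cluster = cluster, background = ids)
}

# planted-partition random graph for clustering recovery tests
make_block_graph <- function(block_sizes, p_in, p_out, seed = 1) {
  set.seed(seed)
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(n, 2))
  p <- ifelse(labels[pairs[, 1]] == labels[pairs[, 2]], p_in, p_out)
  keep <- runif(nrow(pairs)) < p
  list(graph = structure(list(
    nodes = nodes,
    edges = data.frame(a = nodes[pairs[keep, 1]], b = nodes[pairs[keep, 2]],
                       weight = 1, stringsAsFactors = FALSE),
    threshold = NA, statistic = "r"), class = "correlation_graph"),
    truth = stats::setNames(labels, nodes))
}

# align recovered cluster labels with planted ones by majority vote
map_planted_clusters <- function(truth, membership) {
  vapply(names(truth$cluster_members), function(k) {
    got <- membership[intersect(truth$cluster_members[[k]], names(membership))]
    if (!length(got)) return(NA_character_)
    names(which.max(table(got)))
  }, character(1))
}
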