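# Synthetic joint miRome/transcriptome study generator.
#
# The generator plants three kinds of structure whose recovery the rest of
# the package is tested against: (i) co-expression clusters of mRNAs and
# miRNAs sharing a stage profile, (ii) differential expression between the
# first and last stage, and (iii) regulators (TFs, miRNAs) whose target sets
# concentrate in one cluster.

#' Draw negative binomial counts around a matrix of expected means
#'
#' Variance is `mu + phi * mu^2`; `phi = 0` gives Poisson counts.
#'
#' @param mu matrix (or vector) of expected counts.
#' @param phi common NB dispersion, >= 0.
#' @return integer-valued matrix shaped like `mu`.
#' @export
simulate_nb_counts <- function(mu, phi) {
  if (phi < 0) stopf("dispersion must be >= 0")
  y <- if (phi == 0) stats::rpois(length(mu), lambda = mu)
       else stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
  if (is.matrix(mu))
    y <- matrix(y, nrow = nrow(mu), dimnames = dimnames(mu))
  y
}

#' Generate a synthetic dataset with planted structure
#'
#' Produces mRNA and small-RNA count matrices over the configured
#' stage x cell-line x replicate design, a sample table, and the planted
#' truth. Counts for feature i in library j are negative binomial with mean
#' `lib_size_j * relative_abundance_ij` where the relative abundance combines
#' a per-feature baseline, the feature's cluster stage profile (flat for
#' non-cluster features), and a per-biological-sample cluster activity shared
#' by all members of a cluster. The two library types are generated as
#' separate matrices over the same biological samples, mirroring separate
#' library preparations from the same RNA.
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset` list with elements `mrna` and `mirna`
#'   ([count_matrix()]), `samples` (data frame, one row per library), `truth`
#'   (`synthetic_truth`), and `config`.
#' @export
generate_dataset <- function(config) {
  config <- validate_sim_config(unclass(config))
  set.seed(as.integer(config$seed))

  stages <- config$stages
  bio <- expand.grid(replicate = seq_len(config$replicates_per_condition),
                     cell_line = config$cell_lines, stage = stages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bio$bio_id <- sprintf("s%s_%s_r%d", bio$stage, bio$cell_line, bio$replicate)
  n_bio <- nrow(bio)

  n_coding <- floor(config$frac_coding * config$n_mrna)
  mrna_ids <- sprintf("gene%04d", seq_len(config$n_mrna))
  mirna_ids <- sprintf("mir%03d", seq_len(config$n_mirna))
  feature_type <- c(
    stats::setNames(rep(c("mRNA_coding", "mRNA_noncoding"),
                        c(n_coding, config$n_mrna - n_coding)), mrna_ids),
    stats::setNames(rep("miRNA", config$n_mirna), mirna_ids))

  k <- config$n_clusters
  cluster_names <- sprintf("cluster%d", seq_len(k))
  members_mrna <- sample(mrna_ids[seq_len(n_coding)], k * config$cluster_size_mrna)
  members_mirna <- sample(mirna_ids, k * config$cluster_size_mirna)
  cluster_members <- stats::setNames(vector("list", k), cluster_names)
  for (i in seq_len(k)) {
    cluster_members[[i]] <- c(
      members_mrna[seq.int((i - 1) * config$cluster_size_mrna + 1,
                           i * config$cluster_size_mrna)],
      members_mirna[seq.int((i - 1) * config$cluster_size_mirna + 1,
                            i * config$cluster_size_mirna)])
  }
  all_ids <- c(mrna_ids, mirna_ids)
  cluster_of <- stats::setNames(rep(NA_character_, length(all_ids)), all_ids)
  for (nm in cluster_names) cluster_of[cluster_members[[nm]]] <- nm

  # per-feature stage multipliers: cluster profile, flat, or idiosyncratic DE
  mult <- matrix(1, length(all_ids), length(stages),
                 dimnames = list(all_ids, stages))
  for (i in seq_len(k))
    mult[cluster_members[[i]], ] <- rep(config$cluster_profiles[i, ],
                                        each = length(cluster_members[[i]]))
  free <- all_ids[is.na(cluster_of)]
  n_free_de <- round(config$frac_de * length(free))
  if (n_free_de > 0 && length(stages) >= 2) {
    de_feats <- sample(free, n_free_de)
    direction <- sample(c(-1, 1), n_free_de, replace = TRUE)
    lfc <- direction * (log(4) + stats::rnorm(n_free_de, 0, 0.25))
    mult[de_feats, length(stages)] <- exp(lfc)
    if (length(stages) > 2) {
      for (s in 2:(length(stages) - 1))
        mult[de_feats, s] <- exp(lfc * (s - 1) / (length(stages) - 1) +
                                   stats::rnorm(n_free_de, 0, 0.4))
    }
  }

  # baseline relative abundance; planted members drawn well-expressed so the
  # co-expression analysis operates on quantifiable features
  baseline <- stats::setNames(stats::rlnorm(length(all_ids), 0, 1.2), all_ids)
  planted <- all_ids[!is.na(cluster_of)]
  baseline[planted] <- stats::rlnorm(length(planted), 1.5, 0.8)

  # shared per-biological-sample cluster activity (coherent biology)
  activity <- matrix(stats::rnorm(k * n_bio, 0, config$cluster_sample_sd),
                     k, n_bio, dimnames = list(cluster_names, bio$bio_id))

  sdlog <- sqrt(log(1 + config$lib_size_cv^2))
  make_library <- function(ids, lib, mean_lib) {
    u <- baseline[ids] * mult[ids, as.character(bio$stage), drop = FALSE]
    in_cl <- ids[!is.na(cluster_of[ids])]
    if (length(in_cl))
      u[in_cl, ] <- u[in_cl, ] * exp(activity[cluster_of[in_cl], , drop = FALSE])
    if (config$batch_effect_sd > 0) {
      for (b in unique(bio$replicate)) {
        off <- exp(stats::rnorm(length(ids), 0, config$batch_effect_sd))
        u[, bio$replicate == b] <- u[, bio$replicate == b] * off
      }
    }
    lib_sizes <- stats::rlnorm(n_bio, log(mean_lib) - sdlog^2 / 2, sdlog)
    mu <- sweep(sweep(u, 2, colSums(u), "/"), 2, lib_sizes, "*")
    counts <- simulate_nb_counts(mu, config$dispersion)
    colnames(counts) <- sprintf("%s_%s", lib, bio$bio_id)
    list(counts = counts,
         samples = data.frame(sample_id = colnames(counts), stage = bio$stage,
                              cell_line = bio$cell_line,
                              replicate = as.character(bio$replicate),
                              batch = sprintf("b%d", bio$replicate),
                              library = lib, stringsAsFactors = FALSE))
  }
  mrna <- make_library(mrna_ids, "mrna", config$mean_lib_size_mrna)
  mirna <- make_library(mirna_ids, "mirna", config$mean_lib_size_mirna)

  ratio <- mult[, length(stages)] / mult[, 1]
  de_status <- stats::setNames(
    ifelse(ratio >= 2, "up", ifelse(ratio <= 0.5, "down", "null")), all_ids)

  truth <- structure(list(
    features = list(mrna_coding = mrna_ids[seq_len(n_coding)],
                    mrna_noncoding = mrna_ids[seq.int(n_coding + 1,
                                                      length.out = config$n_mrna - n_coding)],
                    mirna = mirna_ids),
    cluster_of = cluster_of,
    cluster_members = cluster_members,
    de_status = de_status,
    stage_multipliers = mult),
    class = "synthetic_truth")

  structure(list(
    mrna = count_matrix(mrna$counts, feature_type[mrna_ids]),
    mirna = count_matrix(mirna$counts, feature_type[mirna_ids]),
    samples = rbind(mrna$samples, mirna$samples),
    truth = truth, config = config),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_dataset: %d mRNA x %d libraries, %d miRNA x %d libraries\n",
    "  %d planted clusters, dispersion %.3g\n"),
    nrow(x$mrna$counts), ncol(x$mrna$counts),
    nrow(x$mirna$counts), ncol(x$mirna$counts),
    length(x$truth$cluster_members), x$config$dispersion))
  invisible(x)
}

#' Generate annotation resources with planted regulator structure
#'
#' Builds regulator-target interaction records (TargetScan-, miRTarBase-,
#' TRRUST-, FANTOM5- and ENCODE-dialect), a gene-set collection, and a PPI
#' edge table, all consistent with a generated dataset. The first
#' `n_clusters` regulators of each class are planted: each is itself a member
#' of its cluster and its targets are drawn with sampling weight
#' `target_enrichment_factor` inside that cluster. Remaining regulators are
#' decoys drawing targets uniformly. miRNA-target records are split between
#' the TargetScan dialect (passing scores drawn below -0.3) and the
#' miRTarBase dialect (luciferase evidence); chaff records that the database
#' filters must remove (scores above -0.3, non-luciferase evidence) are
#' added on top. PPI edges are dense inside the `ppi_module_cluster` cluster.
#'
#' @param truth `synthetic_truth` from [generate_dataset()].
#' @param config the same [sim_config()] used to generate it.
#' @return a list with `mirna_records`, `tf_records` (interaction record data
#'   frames), `gene_sets` (`gene_set_collection`), `ppi` (`ppi_network`), and
#'   `truth` (the input truth augmented with `regulator_cluster`,
#'   `regulator_class` and `target_sets`).
#' @export
generate_annotation <- function(truth, config) {
  config <- validate_sim_config(unclass(config))
  if (!inherits(truth, "synthetic_truth"))
    stopf("truth must come from generate_dataset()")
  coding <- truth$features$mrna_coding
  if (length(coding) != floor(config$frac_coding * config$n_mrna) ||
      length(truth$features$mirna) != config$n_mirna)
    stopf("truth/config mismatch in feature universe")
  set.seed(as.integer(config$seed) + 1L)

  k <- config$n_clusters
  cluster_names <- names(truth$cluster_members)
  coding_members <- lapply(truth$cluster_members, intersect, x = coding)
  mirna_members <- lapply(truth$cluster_members, intersect, x = truth$features$mirna)
  free_coding <- setdiff(coding, unlist(coding_members))
  free_mirna <- setdiff(truth$features$mirna, unlist(mirna_members))

  planted_tf <- vapply(coding_members, `[`, character(1), 1L)
  decoy_tf <- sample(free_coding, config$n_regulators_tf - k)
  planted_mir <- vapply(mirna_members, `[`, character(1), 1L)
  decoy_mir <- sample(free_mirna, config$n_regulators_mirna - k)

  draw_targets <- function(regulator, cluster) {
    pool <- setdiff(coding, regulator)
    w <- rep(1, length(pool))
    if (!is.na(cluster))
      w[pool %in% coding_members[[cluster]]] <- config$target_enrichment_factor
    sample(pool, config$targets_per_regulator, prob = w)
  }
  regulators <- c(planted_tf, decoy_tf, planted_mir, decoy_mir)
  reg_class <- stats::setNames(
    rep(c("tf", "mirna"), c(config$n_regulators_tf, config$n_regulators_mirna)),
    regulators)
  reg_cluster <- stats::setNames(
    c(cluster_names, rep(NA_character_, config$n_regulators_tf - k),
      cluster_names, rep(NA_character_, config$n_regulators_mirna - k)),
    regulators)
  target_sets <- stats::setNames(
    lapply(regulators, function(r) sort(draw_targets(r, reg_cluster[[r]]))),
    regulators)

  # TF records: union across TRRUST/FANTOM5/ENCODE dialects, pairs assigned
  # to one or two sources at random
  tf_regs <- regulators[reg_class == "tf"]
  tf_pairs <- data.frame(
    regulator = rep(tf_regs, lengths(target_sets[tf_regs])),
    target = unlist(target_sets[tf_regs], use.names = FALSE),
    stringsAsFactors = FALSE)
  src3 <- c("trrust", "fantom5", "encode")
  first <- sample(src3, nrow(tf_pairs), replace = TRUE)
  second_mask <- stats::runif(nrow(tf_pairs)) < 0.15
  second <- vapply(first[second_mask],
                   function(s) sample(setdiff(src3, s), 1), character(1))
  tf_records <- data.frame(
    regulator = c(tf_pairs$regulator, tf_pairs$regulator[second_mask]),
    target = c(tf_pairs$target, tf_pairs$target[second_mask]),
    source = c(first, second),
    score = NA_real_, evidence = NA_character_, stringsAsFactors = FALSE)

  # miRNA records: true pairs pass the database filters; chaff does not
  mir_regs <- regulators[reg_class == "mirna"]
  mir_pairs <- data.frame(
    regulator = rep(mir_regs, lengths(target_sets[mir_regs])),
    target = unlist(target_sets[mir_regs], use.names = FALSE),
    stringsAsFactors = FALSE)
  in_ts <- stats::runif(nrow(mir_pairs)) < 0.85
  in_mtb <- !in_ts | stats::runif(nrow(mir_pairs)) < 0.1  # some pairs in both
  ts_true <- mir_pairs[in_ts, ]
  ts_true$score <- round(stats::runif(nrow(ts_true), -0.9, -0.31), 3)
  mtb_true <- mir_pairs[in_mtb, ]
  n_chaff <- max(50L, nrow(mir_pairs) %/% 5L)
  chaff_reg <- sample(mir_regs, 2L * n_chaff, replace = TRUE)
  chaff_tgt <- sample(coding, 2L * n_chaff, replace = TRUE)
  chaff_key <- paste(chaff_reg, chaff_tgt)
  true_key <- paste(mir_pairs$regulator, mir_pairs$target)
  ok <- !(chaff_key %in% true_key) & !duplicated(chaff_key) & chaff_reg != chaff_tgt
  chaff_reg <- chaff_reg[ok]; chaff_tgt <- chaff_tgt[ok]
  half <- length(chaff_reg) %/% 2L
  mirna_records <- rbind(
    data.frame(regulator = ts_true$regulator, target = ts_true$target,
               source = "targetscan", score = ts_true$score,
               evidence = NA_character_, stringsAsFactors = FALSE),
    data.frame(regulator = mtb_true$regulator, target = mtb_true$target,
               source = "mirtarbase", score = NA_real_,
               evidence = "Luciferase reporter assay", stringsAsFactors = FALSE),
    data.frame(regulator = chaff_reg[seq_len(half)],
               target = chaff_tgt[seq_len(half)], source = "targetscan",
               score = round(stats::runif(half, -0.29, -0.01), 3),
               evidence = NA_character_, stringsAsFactors = FALSE),
    data.frame(regulator = chaff_reg[seq.int(half + 1, length(chaff_reg))],
               target = chaff_tgt[seq.int(half + 1, length(chaff_tgt))],
               source = "mirtarbase", score = NA_real_,
               evidence = sample(c("Western blot", "qRT-PCR", "Microarray"),
                                 length(chaff_reg) - half, replace = TRUE),
               stringsAsFactors = FALSE))

  # gene sets: one noisy set per planted cluster plus random decoys
  sets <- list()
  for (i in seq_len(k)) {
    mem <- coding_members[[i]]
    keep <- sample(mem, ceiling(0.8 * length(mem)))
    sets[[sprintf("set_%s", cluster_names[i])]] <-
      unique(c(keep, sample(free_coding, 10)))
  }
  for (i in seq_len(k))
    sets[[sprintf("decoy_set%d", i)]] <- sample(coding, 60)
  gene_sets <- structure(
    list(sets = sets,
         description = stats::setNames(rep("synthetic", length(sets)), names(sets))),
    class = "gene_set_collection")

  # PPI: dense module inside one designated cluster over a sparse background
  module <- coding_members[[config$ppi_module_cluster]]
  universe <- unique(c(module, sample(coding, min(800L, length(coding)))))
  bg_pairs <- t(utils::combn(universe, 2L))
  keep_bg <- stats::runif(nrow(bg_pairs)) < 0.004
  mod_pairs <- t(utils::combn(module, 2L))
  keep_mod <- stats::runif(nrow(mod_pairs)) < 0.25
  pa <- c(bg_pairs[keep_bg, 1L], mod_pairs[keep_mod, 1L])
  pb <- c(bg_pairs[keep_bg, 2L], mod_pairs[keep_mod, 2L])
  score <- c(sample(150:1000, sum(keep_bg), replace = TRUE),
             sample(750:999, sum(keep_mod), replace = TRUE))
  ppi <- ppi_network(pa, pb, score)

  truth$regulator_cluster <- reg_cluster
  truth$regulator_class <- reg_class
  truth$target_sets <- target_sets
  list(mirna_records = mirna_records, tf_records = tf_records,
       gene_sets = gene_sets, ppi = ppi, truth = truth)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits every table the pipeline can consume, in the dialects understood by
#' the package readers, plus a JSON truth sidecar; the round trip through the
#' readers is lossless.
#'
#' @param dataset a `sim_dataset` from [generate_dataset()].
#' @param annotation the matching [generate_annotation()] result.
#' @param dir output directory (created if absent).
#' @return named character vector of emitted file paths (the manifest).
#' @export
write_fixture_bundle <- function(dataset, annotation, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory '%s'", dir)
  if (file.access(dir, 2) != 0) stopf("directory '%s' is not writable", dir)
  p <- function(f) file.path(dir, f)
  manifest <- c(
    counts_mrna = p("counts_mrna.tsv"), counts_mirna = p("counts_mirna.tsv"),
    feature_types = p("feature_types.tsv"), samples = p("samples.tsv"),
    targetscan = p("interactions_targetscan.tsv"),
    mirtarbase = p("interactions_mirtarbase.tsv"),
    trrust = p("interactions_trrust.tsv"),
    fantom5 = p("interactions_fantom5.tsv"),
    encode = p("interactions_encode.tsv"),
    gene_sets = p("gene_sets.gmt"), ppi = p("ppi_edges.tsv"),
    truth = p("truth.json"))
  write_count_table(dataset$mrna, manifest[["counts_mrna"]])
  write_count_table(dataset$mirna, manifest[["counts_mirna"]])
  types <- c(dataset$mrna$feature_type, dataset$mirna$feature_type)
  utils::write.table(
    data.frame(feature = names(types), type = unname(types)),
    manifest[["feature_types"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_sample_table(dataset$samples, manifest[["samples"]])
  for (d in c("targetscan", "mirtarbase"))
    write_interaction_table(
      annotation$mirna_records[annotation$mirna_records$source == d, ],
      manifest[[d]], d)
  for (d in c("trrust", "fantom5", "encode"))
    write_interaction_table(
      annotation$tf_records[annotation$tf_records$source == d, ],
      manifest[[d]], d)
  write_gene_sets(annotation$gene_sets, manifest[["gene_sets"]])
  write_ppi_edges(annotation$ppi, manifest[["ppi"]])
  write_truth(annotation$truth, manifest[["truth"]])
  manifest
}

#' Serialize the planted truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  clustered <- truth$cluster_of[!is.na(truth$cluster_of)]
  m <- truth$stage_multipliers
  payload <- list(
    features = truth$features,
    cluster_of = as.list(clustered),
    cluster_members = truth$cluster_members,
    de_status = as.list(truth$de_status),
    stage_multipliers = list(
      feature = rownames(m), stage = colnames(m),
      values = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))),
    regulator_cluster = as.list(truth$regulator_cluster),
    regulator_class = as.list(truth$regulator_class),
    target_sets = truth$target_sets)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Reload a truth sidecar written by [write_truth()]
#' @param path JSON path.
#' @return a `synthetic_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  all_ids <- unlist(x$features, use.names = FALSE)
  cluster_of <- stats::setNames(rep(NA_character_, length(all_ids)), all_ids)
  cluster_of[names(x$cluster_of)] <- unlist(x$cluster_of)
  v <- x$stage_multipliers$values  # simplifies to a matrix when rectangular
  mult <- if (is.matrix(v)) v else do.call(rbind, v)
  dimnames(mult) <- list(x$stage_multipliers$feature, x$stage_multipliers$stage)
  structure(list(
    features = x$features,
    cluster_of = cluster_of,
    cluster_members = lapply(x$cluster_members, as.character),
    de_status = stats::setNames(unlist(x$de_status), names(x$de_status)),
    stage_multipliers = mult,
    regulator_cluster = stats::setNames(
      vapply(x$regulator_cluster,
             function(v) if (is.null(v) || is.na(v)) NA_character_ else v,
             character(1)),
      names(x$regulator_cluster)),
    regulator_class = stats::setNames(unlist(x$regulator_class),
                                      names(x$regulator_class)),
    target_sets = lapply(x$target_sets, as.character)),
    class = "synthetic_truth")
}
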