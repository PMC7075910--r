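# End-to-end orchestration: filter -> normalize -> DE -> combine ->
# correlate -> threshold -> MCL -> enrichment (gene sets, TFs, miRNAs) ->
# PPI, with every intermediate table written out and a summary report.

#' Pipeline configuration
#'
#' @param input either a [sim_config()] (the pipeline then simulates its own
#'   input) or a named list of file paths with elements `counts_mrna`,
#'   `samples`, `feature_types`, and optionally `counts_mirna`,
#'   `targetscan`, `mirtarbase`, `trrust`, `fantom5`, `encode`, `gene_sets`,
#'   `ppi` (as produced by [write_fixture_bundle()]).
#' @param out_dir directory for result tables (`NULL` keeps everything in
#'   memory).
#' @param contrast two stage labels for the differential expression contrast.
#' @param correlation_threshold,correlation_statistic co-expression edge rule
#'   (see [threshold_graph()]).
#' @param inflation,min_cluster_size MCL parameters.
#' @param tf_p_threshold,mirna_q_threshold,or_threshold regulator
#'   significance rules per class.
#' @param min_ppi_score high-confidence PPI cutoff on the 0-1 scale.
#' @param log_cpm correlate log2(CPM + 0.5) (default) instead of raw CPM.
#' @param seed seed consumed by any stochastic stage of the run.
#' @param verbose emit progress messages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir = NULL, contrast = c("0", "3"),
                            correlation_threshold = 0.98,
                            correlation_statistic = "r",
                            inflation = 2.0, min_cluster_size = 3,
                            tf_p_threshold = 0.001, mirna_q_threshold = 0.05,
                            or_threshold = 1, min_ppi_score = 0.7,
                            log_cpm = TRUE, seed = 1, verbose = TRUE) {
  if (!inherits(input, "sim_config") && !is.list(input))
    stopf("input must be a sim_config or a list of paths")
  if (!inherits(input, "sim_config")) {
    needed <- c("counts_mrna", "samples")
    missing <- setdiff(needed, names(input))
    if (length(missing)) stopf("input paths missing '%s'", missing[1])
    for (p in unlist(input)) if (!file.exists(p)) stopf("input file not found: %s", p)
  }
  if (!is_prob(correlation_threshold) || correlation_threshold <= 0)
    stopf("correlation_threshold must be in (0, 1]")
  if (!correlation_statistic %in% c("r", "r2"))
    stopf("correlation_statistic must be 'r' or 'r2'")
  if (inflation <= 1) stopf("inflation must be > 1")
  if (!is_prob(min_ppi_score)) stopf("min_ppi_score must be in [0, 1]")
  structure(list(input = input, out_dir = out_dir,
                 contrast = as.character(contrast),
                 correlation_threshold = correlation_threshold,
                 correlation_statistic = correlation_statistic,
                 inflation = inflation, min_cluster_size = min_cluster_size,
                 tf_p_threshold = tf_p_threshold,
                 mirna_q_threshold = mirna_q_threshold,
                 or_threshold = or_threshold, min_ppi_score = min_ppi_score,
                 log_cpm = log_cpm, seed = seed, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full integrative analysis
#'
#' Executes the whole pipeline from a single configuration: low-count
#' filtering, upper-quartile (miRNA) and TMM (mRNA) normalization, NB GLM
#' likelihood-ratio differential expression for the configured stage
#' contrast, joint log-CPM co-expression graph at the configured Pearson
#' threshold, MCL clustering, per-cluster gene-set and regulator (TF and
#' miRNA) Fisher enrichment, and PPI subnetwork edge enrichment. Branches
#' whose inputs are absent (e.g. no miRNA counts, no PPI table) are skipped
#' with a notice. The run is fully reproducible from the configuration and
#' seed. When the input is synthetic, recovery statistics against the
#' planted truth are included in the summary.
#'
#' @param config a [pipeline_config()], or a [sim_config()] (wrapped with
#'   default pipeline settings).
#' @return a `chondronet_run` list: `tables` (all result data frames /
#'   matrices), `summary` (named scalars), `manifest` (paths written),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "sim_config")) config <- pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stopf("not a pipeline_config")
  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  set.seed(as.integer(config$seed))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  tables <- list()
  truth <- NULL
  synthetic <- inherits(config$input, "sim_config")
  if (synthetic) {
    log_msg("stage simulate: generating synthetic dataset (seed %d)",
            as.integer(config$input$seed))
    dataset <- run_stage("simulate", generate_dataset(config$input))
    annotation <- run_stage("simulate", generate_annotation(dataset$truth, config$input))
    truth <- annotation$truth
    mrna <- dataset$mrna
    mirna <- dataset$mirna
    samples <- dataset$samples
    mirna_records <- annotation$mirna_records
    tf_records <- annotation$tf_records
    gene_sets <- annotation$gene_sets
    ppi <- annotation$ppi
  } else {
    paths <- config$input
    log_msg("stage load: reading input tables")
    mrna <- run_stage("load", read_count_table(paths$counts_mrna))
    samples <- run_stage("load", read_sample_table(paths$samples))
    if (!is.null(paths$feature_types)) {
      types <- utils::read.delim(paths$feature_types, colClasses = "character")
      mrna <- attach_feature_types(mrna, types)
    }
    mirna <- if (!is.null(paths$counts_mirna)) {
      m <- run_stage("load", read_count_table(paths$counts_mirna))
      if (!is.null(paths$feature_types)) attach_feature_types(m, types) else m
    }
    read_if <- function(nm, dialect) if (!is.null(paths[[nm]]))
      run_stage("load", read_interaction_table(paths[[nm]], dialect))
    mirna_records <- rbind(read_if("targetscan", "targetscan"),
                           read_if("mirtarbase", "mirtarbase"))
    tf_records <- rbind(read_if("trrust", "trrust"),
                        read_if("fantom5", "fantom5"),
                        read_if("encode", "encode"))
    gene_sets <- if (!is.null(paths$gene_sets))
      run_stage("load", read_gene_sets(paths$gene_sets))
    ppi <- if (!is.null(paths$ppi)) run_stage("load", read_ppi_edges(paths$ppi))
  }
  has_mirna <- !is.null(mirna)
  if (!has_mirna) log_msg("notice: no miRNA counts; miRNA branch skipped")

  log_msg("stage filter: low-expression filtering")
  mrna_f <- run_stage("filter", filter_low_expression(mrna))
  mirna_f <- if (has_mirna) run_stage("filter", filter_low_expression(mirna))
  log_msg("  mRNA %d -> %d features%s", nrow(mrna$counts), nrow(mrna_f$counts),
          if (has_mirna) sprintf("; miRNA %d -> %d", nrow(mirna$counts),
                                 nrow(mirna_f$counts)) else "")

  log_msg("stage normalize: TMM (mRNA), upper-quartile (miRNA)")
  fac_mrna <- run_stage("normalize", tmm_factors(mrna_f))
  fac_mirna <- if (has_mirna) run_stage("normalize", upper_quartile_factors(mirna_f))
  tables$factors_mrna <- as.data.frame(fac_mrna)
  norm_mrna <- normalize_counts(mrna_f, fac_mrna, log = config$log_cpm)
  norm_mirna <- if (has_mirna) normalize_counts(mirna_f, fac_mirna, log = config$log_cpm)

  log_msg("stage de: NB GLM LRT, stage %s vs %s", config$contrast[1], config$contrast[2])
  de_mrna <- run_stage("de", de_between_stages(
    mrna_f, samples, config$contrast[1], config$contrast[2], fac_mrna))
  de_mirna <- if (has_mirna) run_stage("de", de_between_stages(
    mirna_f, samples, config$contrast[1], config$contrast[2], fac_mirna))
  tables$de_mrna <- de_mrna
  de_all <- de_mrna
  if (has_mirna) {
    tables$factors_mirna <- as.data.frame(fac_mirna)
    tables$de_mirna <- de_mirna
    de_all <- rbind(as.data.frame(de_mrna), as.data.frame(de_mirna))
  }

  log_msg("stage coexpress: Pearson graph (%s > %g) + MCL (inflation %g)",
          config$correlation_statistic, config$correlation_threshold,
          config$inflation)
  feature_type <- c(mrna_f$feature_type, if (has_mirna) mirna_f$feature_type)
  combined <- run_stage("coexpress", if (has_mirna)
    combine_expression(norm_mrna, norm_mirna, samples, coding_only = TRUE,
                       feature_type = feature_type)
    else {
      meta <- samples[match(colnames(norm_mrna), samples$sample_id), ]
      out <- norm_mrna[rownames(norm_mrna) %in%
                         names(feature_type)[feature_type == "mRNA_coding"], ,
                       drop = FALSE]
      colnames(out) <- sprintf("s%s_%s_r%s", meta$stage, meta$cell_line,
                               meta$replicate)
      out
    })
  rmat <- run_stage("coexpress", pearson_matrix(combined))
  graph <- run_stage("coexpress", threshold_graph(
    rmat, config$correlation_threshold, config$correlation_statistic))
  clustering <- run_stage("coexpress", mcl_cluster(
    graph, inflation = config$inflation,
    min_cluster_size = config$min_cluster_size))
  profiles <- run_stage("coexpress", cluster_profiles(clustering, combined, samples))
  tables$clusters <- data.frame(feature = names(clustering$membership),
                                cluster = unname(clustering$membership),
                                stringsAsFactors = FALSE)
  tables$cluster_profiles <- profiles$profile
  log_msg("  %d nodes, %d edges, %d clusters",
          length(graph$nodes), nrow(graph$edges), length(clustering$sizes))

  background <- rownames(mrna_f$counts)[mrna_f$feature_type[rownames(mrna_f$counts)] ==
                                          "mRNA_coding"]
  cluster_sets <- split(names(clustering$membership), clustering$membership)
  cluster_sets_bg <- lapply(cluster_sets, intersect, x = background)

  if (!is.null(gene_sets)) {
    log_msg("stage geneset: per-cluster gene-set enrichment")
    tables$gene_set_enrichment <- run_stage("geneset", do.call(rbind, lapply(
      names(cluster_sets_bg), function(k) {
        if (length(cluster_sets_bg[[k]]) == 0) return(NULL)
        res <- gene_set_enrichment(gene_sets, cluster_sets_bg[[k]], background)
        cbind(cluster = k, as.data.frame(res))
      })))
  }

  if (!is.null(tf_records) && nrow(tf_records)) {
    log_msg("stage enrich_tf: TF target enrichment per cluster")
    tf_db <- run_stage("enrich_tf", build_tf_target_db(
      tf_records[tf_records$source == "trrust", ],
      tf_records[tf_records$source == "fantom5", ],
      tf_records[tf_records$source == "encode", ]))
    tables$enrichment_tf <- run_stage("enrich_tf", enrich_regulators(
      tf_db, cluster_sets, background, de_table = de_all,
      p_threshold = config$tf_p_threshold, or_threshold = config$or_threshold))
  }
  if (has_mirna && !is.null(mirna_records) && nrow(mirna_records)) {
    log_msg("stage enrich_mirna: miRNA target enrichment per cluster")
    mirna_db <- run_stage("enrich_mirna", build_mirna_target_db(
      mirna_records[mirna_records$source == "targetscan", ],
      mirna_records[mirna_records$source == "mirtarbase", ]))
    tables$enrichment_mirna <- run_stage("enrich_mirna", enrich_regulators(
      mirna_db, cluster_sets, background, de_table = de_all,
      q_threshold = config$mirna_q_threshold, or_threshold = config$or_threshold))
  }

  if (!is.null(ppi) && nrow(ppi)) {
    log_msg("stage ppi: high-confidence subnetwork enrichment")
    ppi_hc <- run_stage("ppi", filter_high_confidence(ppi, config$min_ppi_score))
    ppi_rows <- lapply(names(cluster_sets_bg), function(k) {
      s <- intersect(cluster_sets_bg[[k]], ppi_nodes(ppi_hc))
      if (length(s) < 2) return(NULL)
      t <- edge_enrichment_test(s, ppi_hc, method = "analytic")
      data.frame(cluster = k, n_nodes = t$n_nodes, observed_edges = t$observed,
                 expected_edges = t$expected, p = t$p_value,
                 stringsAsFactors = FALSE)
    })
    tables$ppi_enrichment <- do.call(rbind, ppi_rows)
    if (!is.null(tables$ppi_enrichment) && nrow(tables$ppi_enrichment)) {
      best <- tables$ppi_enrichment$cluster[which.min(tables$ppi_enrichment$p)]
      tables$ppi_hubs <- hub_nodes(
        induced_subnetwork(ppi_hc, cluster_sets_bg[[best]]), k = 10)
    }
  }

  summary <- c(
    n_mrna_filtered = nrow(mrna_f$counts),
    n_mirna_filtered = if (has_mirna) nrow(mirna_f$counts) else 0,
    n_de_mrna = sum(de_mrna$status != "ns"),
    n_de_mirna = if (has_mirna) sum(de_mirna$status != "ns") else 0,
    n_graph_nodes = length(graph$nodes),
    n_graph_edges = nrow(graph$edges),
    n_clusters = length(clustering$sizes),
    n_clustered_features = length(clustering$membership),
    phi_mrna = as.numeric(attr(de_mrna, "phi")),
    n_tf_significant = if (!is.null(tables$enrichment_tf))
      sum(tables$enrichment_tf$significant) else NA,
    n_mirna_significant = if (!is.null(tables$enrichment_mirna))
      sum(tables$enrichment_mirna$significant) else NA,
    min_ppi_p = if (!is.null(tables$ppi_enrichment))
      min(tables$ppi_enrichment$p) else NA)

  if (synthetic) {
    planted <- truth$cluster_of[names(clustering$membership)]
    eval_feats <- names(planted)[!is.na(planted)]
    summary <- c(summary,
      cluster_ari = if (length(eval_feats) > 1)
        adjusted_rand_index(truth$cluster_of[eval_feats],
                            clustering$membership[eval_feats]) else NA,
      frac_clustered_planted = mean(!is.na(planted)))
  }

  manifest <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      path <- file.path(config$out_dir, paste0(name, ".tsv"))
      if (is.matrix(obj))
        utils::write.table(data.frame(id = rownames(obj), obj, check.names = FALSE),
                           path, sep = "\t", quote = FALSE, row.names = FALSE)
      else utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
      path
    }
    for (nm in names(tables))
      manifest[nm] <- wr(as.data.frame(tables[[nm]]), nm)
  }

  run <- structure(list(tables = tables, summary = summary,
                        manifest = manifest, config = config, truth = truth),
                   class = "chondronet_run")
  if (!is.null(config$out_dir)) {
    report_path <- file.path(config$out_dir, "report.txt")
    writeLines(make_report(run), report_path)
    run$manifest["report"] <- report_path
  }
  run
}

#' Human-readable run report
#'
#' Summarizes a pipeline run: feature and DE counts, cluster sizes with
#' their stage of peak expression, top regulator enrichments per cluster,
#' and PPI statistics. Regenerating the report from the same run is
#' idempotent.
#'
#' @param run a `chondronet_run`.
#' @return character vector of report lines.
#' @export
make_report <- function(run) {
  s <- run$summary
  tb <- run$tables
  lines <- c("chondronet run report",
             "=====================",
             sprintf("features after filtering: %d mRNA, %d miRNA",
                     s[["n_mrna_filtered"]], s[["n_mirna_filtered"]]),
             sprintf("differentially expressed (q < 0.05): %d mRNA, %d miRNA",
                     s[["n_de_mrna"]], s[["n_de_mirna"]]),
             sprintf("co-expression graph: %d nodes, %d edges",
                     s[["n_graph_nodes"]], s[["n_graph_edges"]]),
             sprintf("clusters: %d (over %d features)",
                     s[["n_clusters"]], s[["n_clustered_features"]]))
  if (!is.null(tb$cluster_profiles) && nrow(tb$cluster_profiles)) {
    peak <- colnames(tb$cluster_profiles)[max.col(tb$cluster_profiles,
                                                  ties.method = "first")]
    counts <- table(tb$clusters$cluster)[rownames(tb$cluster_profiles)]
    lines <- c(lines, "cluster sizes and stage of peak mean expression:",
               sprintf("  %s: %d features, peak at stage %s",
                       rownames(tb$cluster_profiles), as.integer(counts), peak))
  }
  top_enr <- function(df, label) {
    if (is.null(df)) return(sprintf("%s enrichment: none", label))
    sig <- df[df$significant, , drop = FALSE]
    if (nrow(sig) == 0) return(sprintf("%s enrichment: none", label))
    sig <- sig[order(sig$p), , drop = FALSE]
    c(sprintf("top %s enrichments:", label),
      sprintf("  %s -> %s (OR %.2f, p %.3g, %s)",
              utils::head(sig$regulator, 5), utils::head(sig$cluster, 5),
              utils::head(sig$odds_ratio, 5), utils::head(sig$p, 5),
              utils::head(sig$regulator_de_status, 5)))
  }
  lines <- c(lines, top_enr(tb$enrichment_tf, "TF"),
             top_enr(tb$enrichment_mirna, "miRNA"))
  if (!is.null(tb$ppi_enrichment) && nrow(tb$ppi_enrichment)) {
    best <- tb$ppi_enrichment[which.min(tb$ppi_enrichment$p), ]
    lines <- c(lines, sprintf(
      "PPI: densest cluster %s with %d edges (expected %.1f, p %.3g)",
      best$cluster, best$observed_edges, best$expected_edges, best$p))
  } else lines <- c(lines, "PPI enrichment: none")
  if ("cluster_ari" %in% names(s))
    lines <- c(lines, sprintf("planted-truth recovery: ARI %.3f", s[["cluster_ari"]]))
  lines
}

#' @export
print.chondronet_run <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}
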