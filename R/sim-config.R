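# Simulation configuration for the synthetic study generator.

default_cluster_profiles <- function() {
  # Stage multipliers (stages 0 / 2 / 3) for the six planted co-expression
  # programs. Shapes mimic a staged differentiation time course: pluripotency
  # genes collapse by two-plus orders of magnitude, primitive-streak genes
  # spike transiently at the intermediate stage, and matrix/limb programs
  # switch on late. Magnitudes are deliberately large: graph clustering at
  # Pearson r > 0.98 only connects features whose shared signal dwarfs
  # counting noise, which is the regime the method is designed for.
  matrix(c(
    1,     0.05, 0.004,   # pluripotency, down
    0.01,  1,    0.02,    # primitive streak, transient peak
    0.01,  0.6,  1,       # transcription regulation, up from mid
    0.002, 0.05, 1,       # ECM organisation, up late
    0.01,  0.04, 1,       # limb development, up late (delayed)
    1,     0.8,  0.01     # late-silenced program
  ), nrow = 6, byrow = TRUE,
  dimnames = list(c("pluripotency_down", "primitive_streak", "transcription_mid",
                    "ecm_late", "limb_late", "down_late"),
                  NULL))
}

#' Configuration for the synthetic joint miRome/transcriptome study
#'
#' Defines the simulated study design: three differentiation stages sampled in
#' two cell lines with replicate mRNA and small-RNA libraries, negative
#' binomial counts with library-size variation, planted co-expression clusters
#' with stage-specific profiles, and planted regulators whose target sets
#' concentrate in one cluster.
#'
#' @param n_mrna,n_mirna number of mRNA and miRNA features.
#' @param n_clusters number of planted co-expression clusters.
#' @param stages ordered stage labels.
#' @param cell_lines cell line labels.
#' @param replicates_per_condition replicate libraries per stage x line.
#' @param mean_lib_size_mrna,mean_lib_size_mirna mean sequencing depth (reads)
#'   per library type; realized depths are log-normal around the mean.
#' @param lib_size_cv coefficient of variation of library sizes.
#' @param dispersion negative binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param cluster_profiles `n_clusters` x `length(stages)` matrix of positive
#'   stage multipliers, one row per planted cluster.
#' @param cluster_size_mrna,cluster_size_mirna planted members per cluster.
#' @param cluster_sample_sd standard deviation (natural log scale) of the
#'   per-biological-sample activity shared by all members of a cluster;
#'   models coherent condition-level biological variation.
#' @param frac_de fraction of non-cluster features given an idiosyncratic
#'   differential profile between first and last stage.
#' @param frac_coding fraction of mRNA features annotated protein-coding.
#' @param n_regulators_tf,n_regulators_mirna total regulators per class; the
#'   first `n_clusters` of each class are planted (one per cluster), the rest
#'   are decoys.
#' @param targets_per_regulator targets drawn per regulator.
#' @param target_enrichment_factor sampling weight multiplier for a planted
#'   regulator's targets inside its own cluster (1 = no planted signal).
#' @param batch_effect_sd standard deviation (natural log) of a multiplicative
#'   per-batch offset; 0 (default) disables batch effects.
#' @param ppi_module_cluster index of the cluster given a dense PPI module;
#'   defaults to the fourth cluster (the late-matrix program) or the last
#'   cluster if fewer exist.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_mrna = 3000, n_mirna = 300, n_clusters = 6,
                       stages = c("0", "2", "3"), cell_lines = c("lineA", "lineB"),
                       replicates_per_condition = 3,
                       mean_lib_size_mrna = 5e6, mean_lib_size_mirna = 1e6,
                       lib_size_cv = 0.2, dispersion = 0.05,
                       cluster_profiles = NULL,
                       cluster_size_mrna = 60, cluster_size_mirna = 8,
                       cluster_sample_sd = 0.5,
                       frac_de = 0.1, frac_coding = 0.9,
                       n_regulators_tf = 30, n_regulators_mirna = 30,
                       targets_per_regulator = 100,
                       target_enrichment_factor = 10,
                       batch_effect_sd = 0, ppi_module_cluster = NULL,
                       seed = 1) {
  cfg <- list(n_mrna = n_mrna, n_mirna = n_mirna, n_clusters = n_clusters,
              stages = as.character(stages), cell_lines = as.character(cell_lines),
              replicates_per_condition = replicates_per_condition,
              mean_lib_size_mrna = mean_lib_size_mrna,
              mean_lib_size_mirna = mean_lib_size_mirna,
              lib_size_cv = lib_size_cv, dispersion = dispersion,
              cluster_profiles = cluster_profiles,
              cluster_size_mrna = cluster_size_mrna,
              cluster_size_mirna = cluster_size_mirna,
              cluster_sample_sd = cluster_sample_sd,
              frac_de = frac_de, frac_coding = frac_coding,
              n_regulators_tf = n_regulators_tf,
              n_regulators_mirna = n_regulators_mirna,
              targets_per_regulator = targets_per_regulator,
              target_enrichment_factor = target_enrichment_factor,
              batch_effect_sd = batch_effect_sd,
              ppi_module_cluster = ppi_module_cluster,
              seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (fld in c("n_mrna", "n_mirna", "n_clusters", "replicates_per_condition",
                "cluster_size_mrna", "cluster_size_mirna", "n_regulators_tf",
                "n_regulators_mirna", "targets_per_regulator"))
    if (!is_count(cfg[[fld]])) stopf("sim_config: '%s' must be a positive integer", fld)
  for (fld in c("mean_lib_size_mrna", "mean_lib_size_mirna"))
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] <= 0)
      stopf("sim_config: '%s' must be > 0", fld)
  if (!is.numeric(cfg$dispersion) || cfg$dispersion < 0)
    stopf("sim_config: 'dispersion' must be >= 0")
  for (fld in c("frac_de", "frac_coding"))
    if (!is_prob(cfg[[fld]])) stopf("sim_config: '%s' must be in [0, 1]", fld)
  for (fld in c("lib_size_cv", "cluster_sample_sd", "batch_effect_sd"))
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] < 0)
      stopf("sim_config: '%s' must be >= 0", fld)
  if (cfg$target_enrichment_factor < 1)
    stopf("sim_config: 'target_enrichment_factor' must be >= 1")
  if (length(cfg$stages) < 2) stopf("sim_config: need at least 2 stages")
  if (is.null(cfg$cluster_profiles)) {
    base <- default_cluster_profiles()
    if (cfg$n_clusters > nrow(base) && length(cfg$stages) == 3) {
      extra <- base[rep_len(seq_len(nrow(base)), cfg$n_clusters - nrow(base)), ,
                    drop = FALSE] * exp(0.5)
      base <- rbind(base, extra)
    }
    if (length(cfg$stages) != ncol(base))
      stopf("sim_config: supply 'cluster_profiles' for %d stages", length(cfg$stages))
    cfg$cluster_profiles <- base[seq_len(cfg$n_clusters), , drop = FALSE]
  }
  if (!is.matrix(cfg$cluster_profiles) ||
      nrow(cfg$cluster_profiles) != cfg$n_clusters ||
      ncol(cfg$cluster_profiles) != length(cfg$stages))
    stopf("sim_config: 'cluster_profiles' must be %d x %d",
          cfg$n_clusters, length(cfg$stages))
  if (any(cfg$cluster_profiles <= 0))
    stopf("sim_config: 'cluster_profiles' multipliers must be > 0")
  if (cfg$n_clusters * cfg$cluster_size_mrna > floor(cfg$frac_coding * cfg$n_mrna))
    stopf("sim_config: planted mRNA cluster members exceed coding features")
  if (cfg$n_clusters * cfg$cluster_size_mirna > cfg$n_mirna)
    stopf("sim_config: planted miRNA cluster members exceed 'n_mirna'")
  if (cfg$n_regulators_tf < cfg$n_clusters || cfg$n_regulators_mirna < cfg$n_clusters)
    stopf("sim_config: need at least one regulator per cluster (n_clusters = %d)",
          cfg$n_clusters)
  if (is.null(cfg$ppi_module_cluster))
    cfg$ppi_module_cluster <- min(4, cfg$n_clusters)
  if (!is_count(cfg$ppi_module_cluster) || cfg$ppi_module_cluster > cfg$n_clusters)
    stopf("sim_config: 'ppi_module_cluster' must index a cluster")
  if (!is.numeric(cfg$seed) || !is.finite(cfg$seed))
    stopf("sim_config: 'seed' must be an integer")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d mRNA + %d miRNA features, %d clusters\n",
    "  %d stages x %d lines x %d replicates, dispersion %.3g, seed %d\n"),
    x$n_mrna, x$n_mirna, x$n_clusters, length(x$stages), length(x$cell_lines),
    x$replicates_per_condition, x$dispersion, as.integer(x$seed)))
  invisible(x)
}
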