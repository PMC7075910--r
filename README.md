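# chondronet

Integrative analysis of paired small-RNA and whole-transcriptome
sequencing over a staged differentiation time course — built for studies
like hESC-directed chondrogenesis, where pluripotent cells (stage 0) pass
through mesoderm (stage 2) to chondroprogenitors (stage 3) in multiple
cell lines with replicate mRNA and miRNA libraries per condition. The
package is aimed at computational biologists who want the whole chain —
normalization, differential expression, co-expression clustering,
regulator enrichment, PPI analysis — as plain, testable R functions
rather than a collection of web tools.

## What it computes

* **Filtering and normalization** — features kept with ≥ 4 counts in ≥ 2
  samples; upper-quartile factors for small-RNA libraries, trimmed mean of
  M-values (TMM) for mRNA libraries (30% M-trim, 5% A-trim,
  precision-weighted), factors rescaled to geometric mean 1; CPM and
  log2(CPM + 0.5) abundances; Spearman sample correlation and PCA
  diagnostics.
* **Differential expression** — per-feature negative binomial GLM
  (log link, offsets log(N·f)) with a single common dispersion φ
  maximizing the Cox–Reid adjusted profile likelihood; likelihood-ratio
  test 2(ℓ_full − ℓ_reduced) ~ χ², BH correction, calls at q < 0.05.
* **Co-expression clustering** — Pearson correlations of the combined
  coding-mRNA + miRNA log-CPM table across shared biological samples;
  edges at r > 0.98 (strict); a from-scratch Markov Cluster algorithm
  (expansion/inflation on the column-stochastic matrix, inflation 2.0)
  yields deterministic clusters with per-stage expression profiles.
* **Regulator enrichment** — miRNA target database from TargetScan-style
  records (total context score < −0.3) plus luciferase-validated
  miRTarBase-style records; TF database as the TRRUST ∪ FANTOM5 ∪ ENCODE
  union. Per regulator × cluster, the 2×2 table (a,b,c,d) over the
  expressed protein-coding background gives OR = ad/(bc) and a one-sided
  exact hypergeometric p; BH within regulator class; defaults p < 0.001 &
  OR > 1 (TFs), q < 0.05 & OR > 1 (miRNAs). Gene-set (GO-style)
  enrichment with fold enrichment uses the same engine.
* **PPI subnetworks** — STRING-style edges, high confidence at
  score/1000 > 0.7; cluster-induced subnetworks tested against a
  degree-preserving Chung–Lu null, λ = Σ min(1, k_u·k_v / 2M), Poisson
  upper-tail p, with a uniform-permutation cross-check and degree-ranked
  hubs.
* **Synthetic studies** — `generate_dataset()` / `generate_annotation()`
  plant known clusters, DE, regulator targeting, gene sets and a dense
  PPI module under the same study design, so every stage of the pipeline
  is testable end to end; `write_fixture_bundle()` serializes a full
  study in the dialects the readers understand.

## Worked example

A complete run on a compact synthetic study (600 mRNAs, 80 miRNAs, six
planted clusters, 18 + 18 libraries):

```r
library(chondronet)

cfg <- sim_config(n_mrna = 600, n_mirna = 80, cluster_size_mrna = 25,
                  cluster_size_mirna = 4, mean_lib_size_mrna = 1e6,
                  mean_lib_size_mirna = 2e5, n_regulators_tf = 12,
                  n_regulators_mirna = 12, seed = 7)
run <- run_pipeline(pipeline_config(cfg, seed = 1, verbose = FALSE))
print(run)
```

```
chondronet run report
=====================
features after filtering: 600 mRNA, 80 miRNA
differentially expressed (q < 0.05): 195 mRNA, 26 miRNA
co-expression graph: 172 nodes, 1835 edges
clusters: 6 (over 172 features)
cluster sizes and stage of peak mean expression:
  C1: 29 features, peak at stage 3
  C2: 29 features, peak at stage 0
  C3: 29 features, peak at stage 2
  C4: 29 features, peak at stage 0
  C5: 28 features, peak at stage 3
  C6: 28 features, peak at stage 3
top TF enrichments:
  gene0018 -> C1 (OR 65.42, p 3.26e-16, up)
  gene0031 -> C3 (OR 65.42, p 3.26e-16, up)
  gene0075 -> C4 (OR 28.97, p 4.34e-13, down)
  gene0006 -> C5 (OR 21.75, p 1.01e-11, up)
  gene0022 -> C2 (OR 13.58, p 2.66e-09, down)
top miRNA enrichments:
  mir001 -> C6 (OR 65.42, p 3.26e-16, up)
  mir023 -> C5 (OR 41.09, p 1.41e-14, up)
  mir043 -> C1 (OR 21.75, p 1.01e-11, up)
  mir007 -> C4 (OR 21.75, p 1.01e-11, down)
  mir010 -> C2 (OR 16.97, p 1.82e-10, down)
PPI: densest cluster C5 with 66 edges (expected 20.2, p 6.51e-16)
planted-truth recovery: ARI 1.000
```

Reading it: 195 transcripts and 26 miRNAs change significantly between
the first and last stage; the 0.98-correlation graph retains the 172
strongly co-expressed features, which MCL partitions into the six planted
programs (adjusted Rand index 1.0 against the planted truth); each
cluster's peak stage reflects its planted profile; for every cluster, the
planted TF and miRNA rank first among its enrichments with large odds
ratios, and their own differential-expression direction is joined in
(`up`/`down`); the designated matrix-like cluster carries a dense PPI
module (66 observed edges against 20.2 expected under the
degree-preserving null). All result tables are in `run$tables`, and
`pipeline_config(..., out_dir = ...)` writes each as TSV plus the report.

Individual stages are ordinary functions — `filter_low_expression()`,
`tmm_factors()`, `de_between_stages()`, `pearson_matrix()`,
`threshold_graph()`, `mcl_cluster()`, `build_mirna_target_db()`,
`enrich_regulators()`, `edge_enrichment_test()` — and accept data read
from files via `read_count_table()`, `read_sample_table()`,
`read_interaction_table()`, `read_gene_sets()` and `read_ppi_edges()`.

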