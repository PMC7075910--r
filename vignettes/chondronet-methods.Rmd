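---
title: "Methods: integrative miRNA-mRNA co-expression network analysis"
author: "chondronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA-mRNA co-expression network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondronet)
```

# The analysis

`chondronet` implements an integrative analysis of paired small-RNA and
whole-transcriptome sequencing over a staged differentiation time course
(here phrased for hESC-directed chondrogenesis: pluripotent stage 0,
mesodermal stage 2, chondroprogenitor stage 3, sampled in two cell lines
with replicate libraries of each type per condition). The pipeline is:

1. low-count filtering and between-sample normalization, per library type;
2. negative binomial (NB) GLM likelihood-ratio differential expression
   between stages;
3. a joint mRNA + miRNA Pearson co-expression graph at a high correlation
   threshold, partitioned with the Markov Cluster algorithm (MCL);
4. Fisher exact enrichment of transcription-factor (TF) and miRNA target
   sets within each co-expression cluster, plus generic gene-set
   enrichment;
5. protein-protein interaction (PPI) subnetwork edge enrichment for the
   clusters.

Every step is exposed as a plain function; `run_pipeline()` chains them
from one configuration. A synthetic-data module generates complete studies
with planted structure so that the whole chain is testable without
external data.

# Filtering and normalization

Features are retained when they have **at least 4 counts in 2 or more
samples** (`filter_low_expression()`), applied per count matrix *before*
normalization. The rule is deliberately permissive: downstream models
handle low counts, the filter only removes features with no usable signal.

Two normalization factor methods are provided, matching the common choice
per library type:

* **Upper quartile** (`upper_quartile_factors()`, used for small-RNA
  libraries): the raw factor of sample $j$ is the 75th percentile of
  $x_{ij} / N_j$ over features expressed in at least one sample, where
  $N_j$ is the column total. Small-RNA count distributions are dominated
  by a few extremely abundant species, which makes quantile-based factors
  more stable than means. Quantiles use linear interpolation between order
  statistics (R type 7); the quantile is configurable.
* **TMM** (`tmm_factors()`, used for mRNA libraries): for sample $k$
  against reference $r$, over features nonzero in both,
  $M_g = \log_2\frac{x_{gk}/N_k}{x_{gr}/N_r}$ and
  $A_g = \tfrac12 \log_2\left(\frac{x_{gk}}{N_k}\cdot\frac{x_{gr}}{N_r}\right)$;
  the upper and lower 30% of $M$ and 5% of $A$ are trimmed, and the factor
  is $2$ to the precision-weighted mean of the retained $M_g$, with
  weights $\left(1/x_{gk} - 1/N_k + 1/x_{gr} - 1/N_r\right)^{-1}$
  (inverse asymptotic binomial variance). The reference is the sample
  whose 75th percentile of $x/N$ is closest to the across-sample mean.
  If fewer than 10 features survive trimming the untrimmed weighted mean
  is used, with a warning.

Both factor sets are rescaled to geometric mean 1. Normalized abundance is
CPM-style, $x_{ij} / (N_j f_j) \times 10^6$, optionally
$\log_2(\mathrm{CPM} + 0.5)$.

One caveat worth stating: because the TMM precision weights involve
absolute counts, rescaling a *single* column's counts perturbs the factors
very slightly (order $10^{-3}$ on realistic matrices) even though the
$M/A$ values and the trimming are exactly invariant; a global rescale is
exactly invariant. The upper-quartile factors are exactly invariant in
both senses.

# Differential expression

Counts are modelled as NB with a **single common dispersion** $\phi$
(variance $\mu + \phi\mu^2$): the synthetic data are generated under the
same model, which keeps the test surface self-consistent, and the
trended/tagwise empirical-Bayes refinements of mature DE packages are
deliberately out of scope here.

Per feature, a log-linear GLM
$\log \mu_j = o_j + \mathbf{x}_j^\top \beta$ with offsets
$o_j = \log(N_j f_j)$ is fitted by IRLS with working weights
$\mu/(1+\phi\mu)$, converging when the largest coefficient change drops
below $10^{-8}$ (at most 100 iterations; the linear predictor is clamped
to $\pm 40$ and all-zero features get an intercept pinned at a floor and a
`degenerate` flag).

The common dispersion maximizes the summed **Cox-Reid adjusted profile
likelihood**: per feature, the NB log-likelihood at the fitted means minus
$\tfrac12 \log\det(X^\top W X)$, searched by golden section on
$\log_{10}\phi \in [-6, 1]$ (tolerance 0.01; an estimate pinned at the
upper bound is flagged). On simulated data the estimate tracks the truth
closely and agrees with the standard reference implementation to a few
percent. Note that the estimate absorbs *all* extra-Poisson variation: on
synthetic data with coherent per-sample cluster activity it is biased
upward relative to the pure counting dispersion, which is the correct
behaviour for a marginal NB model.

The test is the likelihood ratio between nested designs
($2(\ell_{full}-\ell_{reduced})$ against $\chi^2$ with the rank
difference as df), with Benjamini-Hochberg correction across features and
calls at $q < 0.05$. The default stage contrast fits
`~ cell_line + stage` against `~ cell_line` when both lines are present
(the additive design pools lines; per-line analyses are run by
subsetting the sample table). Log2 fold changes are the stage coefficient
divided by $\log 2$.

# Co-expression graph and MCL

Pearson correlations are computed on the combined table of
$\log_2(\mathrm{CPM}+0.5)$ values — protein-coding mRNAs plus miRNAs —
across the biological samples shared by both library types (the two
library preparations come from the same RNA, so columns are matched on
stage x line x replicate). The log transform tempers count
heteroscedasticity; raw CPM is available behind a flag. Constant features
are dropped with a warning.

Edges keep pairs with $r$ strictly above the threshold, default
**0.98**; a `statistic = "r2"` switch thresholds $r^2$ instead (sign
ignored). The threshold is strict at the boundary, so $r = 0.98$ exactly
is excluded, as is $r = 1$ at a threshold of 1. Isolated nodes are
dropped. At such thresholds only features sharing strong coherent
profiles connect, which is exactly the regime in which the clusters are
interpretable.

`mcl_cluster()` is a from-scratch MCL: edge weights ($r$, not binarized)
form a symmetric adjacency; each node receives a self-loop equal to its
maximum incident weight (standard practice, keeps the chain aperiodic);
columns are normalized to a stochastic matrix; then expansion (matrix
squaring) alternates with inflation (entrywise power, default 2.0, then
column renormalization), pruning entries below $10^{-6}$, until the
maximum entry change falls below $10^{-8}$ or 200 iterations
(non-convergence warns and flags the result). Clusters are the connected
components of the converged attractor structure; components smaller than
`min_cluster_size` (default 3) are reported separately as unclustered.
The procedure is fully deterministic and invariant to node order up to
label names.

Cluster stage profiles average member abundances over the replicates and
cell lines of each stage, and record each feature's stage of peak
expression.

# Regulator and gene-set enrichment

Interaction databases are built with strict provenance-preserving filters:

* miRNA targets: TargetScan-dialect records with total context score
  **strictly below -0.3** (more negative = stronger predicted
  repression; the boundary value is excluded) unioned with
  miRTarBase-dialect records whose evidence contains `"luciferase"`
  case-insensitively (reporter-assay validation treated as
  high-confidence). Duplicated pairs keep both source tags.
* TF targets: the union of TRRUST-, FANTOM5- and ENCODE-dialect records.

Self-targeting pairs are dropped. Readers never filter; all thresholds
live in the builders, so the same files can be re-filtered differently.

For each regulator and cluster, `fisher_enrichment()` forms the 2x2 table
over a background universe (features that survived the expression filter;
for target tests, restricted to protein-coding mRNAs, since targets are
genes): $a$ targets in cluster, $b$ non-targets in cluster, $c$ targets
outside, $d$ non-targets outside. The odds ratio is $ad/(bc)$, reported
as $\infty$ when $bc = 0$ with $ad > 0$ and as undefined (p = 1) for a
degenerate margin. The p-value is the one-sided (greater) hypergeometric
tail, computed in log space from `lchoose` and verified against
exhaustive enumeration; enrichment pairs naturally with a one-sided test
and OR > 1, and a two-sided mode exists behind a flag. Targets are
intersected with the background before tabulation, so annotation entries
outside the measured universe cannot influence the result.

Multiple testing is BH **within regulator class across all
regulator x cluster tests**. Default significance rules follow the
per-class conventions: TFs at raw $p < 0.001$ with OR > 1 (large curated
TF target sets make raw-p thresholds customary), miRNAs at $q < 0.05$
with OR > 1; both are configurable. When a DE table is supplied each
regulator's own expression status (up/down/ns) is joined in, supporting
the "enriched and itself regulated" intersection logic.

Gene-set (GO-style) enrichment reuses the same engine with the set as
"targets" and the query as "cluster", additionally reporting fold
enrichment $\frac{a/(a+b)}{(a+c)/N}$.

# PPI subnetwork enrichment

STRING-dialect edges carry combined scores on 0-1000 (a 0-1 scale is
auto-detected); high confidence keeps scores strictly above 0.7x1000.
For a node set $S$ within a background network with $M$ edges and degrees
$k_u$, the expected number of induced edges under a degree-preserving
(Chung-Lu) null is
$\lambda = \sum_{\{u,v\}\subset S}\min(1, k_u k_v / 2M)$, and the
p-value is the Poisson upper tail $P(X \ge m;\lambda)$ for the observed
$m$ ($m = 0$ gives p = 1). A permutation mode draws uniform node sets of
size $|S|$ and reports $(1 + \#\{m_{perm} \ge m\})/(R+1)$. The two nulls
answer slightly different questions: $\lambda$ conditions on the set's
own degrees while the permutation draws uniform sets, so on
degree-heterogeneous networks they are compared on matched uniform sets
in the tests. STRING's own background-corrected model is proprietary and
not reproduced; this explicit null is the package's documented
substitute. Hubs are ranked by degree with lexical tie-breaks.

# The synthetic study generator

`generate_dataset()` emulates the study design: 3 stages x 2 cell lines
x 3 replicates (replicates per condition are configurable; two or more
is realistic for this design, three is the default) of paired mRNA and
small-RNA libraries drawn from the same biological samples. Counts are
NB (`variance = mu + phi mu^2`, common `phi = 0.05` by default,
`phi = 0` giving Poisson) around
`lib_size x relative abundance x stage profile`, with:

* log-normal library sizes (CV 0.2) around 5e6 (mRNA) and 1e6 (miRNA)
  reads — scaled-down but depth-realistic libraries for the default
  3,000 + 300 feature universe, keeping a full run on one CPU under a
  minute;
* six planted cluster programs whose stage-multiplier profiles span two
  to three orders of magnitude (pluripotency collapse, transient
  primitive-streak peak, mid and late activation, late silencing). The
  magnitudes are deliberately strong: differentiation time courses do
  move master regulators by 100-fold and more, and a Pearson threshold
  of 0.98 only makes sense for such programs;
* a shared per-biological-sample cluster activity (log-normal, sd 0.5 on
  the natural scale) capturing coherent condition-level biology; this is
  what lifts within-cluster correlations above the threshold at finite
  counting noise, and it inflates the marginal dispersion estimate above
  the generative `phi`, as real biological replication does;
* flat profiles for non-cluster features, a configurable fraction
  (default 10%) of which get idiosyncratic ~4-fold stage ramps with
  per-feature jitter (differential but not co-expressed);
* planted regulators (one TF and one miRNA per cluster, themselves
  members of their cluster, echoing regulators that are co-expressed
  with their targets), whose target sets are drawn without replacement
  with weight `target_enrichment_factor` (default 10) inside their
  cluster; decoy regulators draw uniformly. Sampling without replacement
  depletes the in-cluster pool, so realized in-cluster counts sit below
  the naive binomial expectation — the default study scale keeps planted
  regulators clearly above both class thresholds regardless;
* annotation chaff that the database filters must remove (TargetScan
  scores above -0.3, non-luciferase evidence), gene sets that noisily
  shadow each cluster plus random decoys, and a PPI network with a dense
  module inside one designated cluster over a sparse background;
* an optional multiplicative per-batch offset (default off) to mimic
  batch-sensitive small-RNA libraries.

Identical seeds give bit-identical bundles, and `write_fixture_bundle()`
serializes everything in the dialects the readers understand, with a JSON
truth sidecar.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: mean-dependent (trended) dispersion,
gene length and GC effects, isoform structure, unannotated features,
identifier ambiguity, correlated decoy regulators (real TF families share
targets), dependence between annotation databases and expression, and
library-preparation artefacts beyond a scalar batch offset. Recovery
statistics on synthetic data are a correctness check of the machinery,
not an estimate of sensitivity on real studies.

# Numerical and design choices

* Strict inequalities at every quoted boundary: correlation > 0.98,
  context score < -0.3, PPI score > 0.7.
* Quantile type 7 for the upper quartile; configurable.
* `log2(x + 0.5)` pseudo-count for log transforms; configurable.
* IRLS: tolerance 1e-8 on coefficients, 100 iterations, linear predictor
  clamped to [-40, 40]; dispersion search on log10 phi in [-6, 1],
  golden-section tolerance 0.01.
* MCL: inflation 2.0 (the common default), pruning 1e-6, convergence
  1e-8, self-loops at the maximum incident weight, edges weighted by r.
* Tie-breaks are deterministic everywhere (lexical hub ordering, stable
  cluster size ordering, first-maximum peak stage).
* The correlation statistic defaults to Pearson r (the operational
  reading of a ">0.98" co-expression cutoff); an r-squared mode is
  provided because the two conventions coexist in the literature.
* Problem sizes in the test-suite simulations (600-3,000 mRNA features,
  small planted graphs) were chosen as the smallest scales at which the
  statistical properties under test are stable; they are package
  choices, not statements about real study sizes.

# Known limitations

Common dispersion only (no empirical-Bayes moderation); additive
stage + line designs (no interactions); hard clustering only; the
Chung-Lu expectation treats edges as independent Poisson events, which
is an approximation for very dense subnetworks; no identifier mapping
between annotation dialects and expression tables (ids are opaque
strings and must already agree).
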