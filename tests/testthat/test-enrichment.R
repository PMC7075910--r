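rec <- function(regulator, target, source, score = NA_real_,
                evidence = NA_character_) {
  data.frame(regulator = regulator, target = target, source = source,
             score = score, evidence = evidence, stringsAsFactors = FALSE)
}

test_that("miRNA database filters are strict on score and evidence", {
  ts <- rec(c("m1", "m1", "m1"), c("g1", "g2", "g3"), "targetscan",
            score = c(-0.5, -0.3, -0.1))
  mtb <- rec(c("m2", "m2"), c("g4", "g5"), "mirtarbase",
             evidence = c("Luciferase reporter assay//Western blot", "qRT-PCR"))
  db <- build_mirna_target_db(ts, mtb)
  expect_equal(db$targets$m1, "g1")          # -0.3 boundary excluded
  expect_equal(db$targets$m2, "g4")          # luciferase substring only
  expect_equal(db$regulator_class, "mirna")

  # the same pair from both sources collapses with two provenance tags
  ts2 <- rec("m1", "g1", "targetscan", score = -0.6)
  mtb2 <- rec("m1", "g1", "mirtarbase", evidence = "Luciferase reporter assay")
  db2 <- build_mirna_target_db(ts2, mtb2)
  expect_equal(nrow(db2$pairs), 1)
  expect_equal(db2$pairs$sources, "mirtarbase;targetscan")
})

test_that("TF database is the provenance-tagged union of three sources", {
  a <- rec(c("t1", "t1"), c("g1", "g2"), "trrust")
  b <- rec(c("t2", "t2"), c("g3", "g4"), "fantom5")
  c_ <- rec(c("t3", "t3"), c("g5", "g6"), "encode")
  db <- build_tf_target_db(a, b, c_)
  expect_equal(nrow(db$pairs), 6)

  same <- rec(c("t1", "t1"), c("g1", "g2"), "trrust")
  db2 <- build_tf_target_db(same,
                            rec(c("t1", "t1"), c("g1", "g2"), "fantom5"),
                            rec(c("t1", "t1"), c("g1", "g2"), "encode"))
  expect_equal(nrow(db2$pairs), 2)
  expect_true(all(db2$pairs$sources == "encode;fantom5;trrust"))

  db3 <- build_tf_target_db(a, b, c_[0, ])
  expect_equal(nrow(db3$pairs), 4)

  # self-targeting pairs are dropped
  expect_warning(expect_equal(nrow(build_tf_target_db(
    rec("t1", "t1", "trrust"), a[0, ], a[0, ])$pairs), 0), "empty")
})

test_that("Fisher engine reproduces hand-enumerated exact results", {
  s <- sets_from_table(1, 1, 1, 1)
  res <- fisher_enrichment(s$targets, s$cluster, s$background)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 5 / 6, tolerance = 1e-12)

  s2 <- sets_from_table(20, 30, 80, 870)
  res2 <- fisher_enrichment(s2$targets, s2$cluster, s2$background)
  expect_equal(res2$odds_ratio, 20 * 870 / (30 * 80))
  oracle <- sum(dhyper(20:50, 100, 900, 50))   # brute-force tail sum
  expect_equal(res2$p_value, oracle, tolerance = 1e-12)

  # degenerate margin: no targets in background
  res3 <- fisher_enrichment("absent_gene", s$cluster, s$background)
  expect_true(is.na(res3$odds_ratio))
  expect_equal(res3$p_value, 1)

  expect_error(fisher_enrichment("g1", "not_in_bg", s$background),
               "outside the background")
})

test_that("Fisher engine agrees with fisher.test across random tables", {
  set.seed(60)
  for (i in 1:40) {
    tab <- rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1))
    s <- sets_from_table(tab[1], tab[2], tab[3], tab[4])
    mine <- fisher_enrichment(s$targets, s$cluster, s$background)
    ref <- fisher.test(matrix(tab, 2), alternative = "greater")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    two <- fisher_enrichment(s$targets, s$cluster, s$background,
                             alternative = "two.sided")
    ref2 <- fisher.test(matrix(tab, 2))
    expect_equal(two$p_value, ref2$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher engine satisfies symmetry, monotonicity and background discipline", {
  # relabelling targets as non-targets inverts the odds ratio and maps the
  # one-sided greater test onto the complementary tail P(X <= a)
  s0 <- sets_from_table(12, 8, 20, 60)
  r1 <- fisher_enrichment(s0$targets, s0$cluster, s0$background)
  r2 <- fisher_enrichment(setdiff(s0$background, s0$targets), s0$cluster,
                          s0$background)
  expect_equal(r2$odds_ratio, 1 / r1$odds_ratio)
  expect_equal(r2$p_value, sum(dhyper(0:12, 32, 68, 20)), tolerance = 1e-12)

  # increasing a with margins fixed never increases p
  prev <- 1
  for (a in 5:15) {
    s <- sets_from_table(a, 20 - a, 30 - a, 50 + a)
    p <- fisher_enrichment(s$targets, s$cluster, s$background)$p_value
    expect_lte(p, prev + 1e-12)
    prev <- p
  }

  # target ids outside the background cannot change the result
  s <- sets_from_table(5, 10, 15, 70)
  base <- fisher_enrichment(s$targets, s$cluster, s$background)
  noisy <- fisher_enrichment(c(s$targets, "alien1", "alien2"), s$cluster,
                             s$background)
  expect_identical(base, noisy)
})

test_that("regulator enrichment recovers planted structure and rejects decoys", {
  # compact fixture: fewer background genes than the default study, so the
  # planted signal is strengthened to keep every planted regulator clearly
  # above the stringent TF threshold
  cfg <- small_config(seed = 41, targets_per_regulator = 60,
                      target_enrichment_factor = 15)
  ds <- generate_dataset(cfg)
  ann <- generate_annotation(ds$truth, cfg)
  truth <- ann$truth
  background <- truth$features$mrna_coding
  clusters <- lapply(truth$cluster_members, intersect, x = background)

  tfr <- ann$tf_records
  db <- build_tf_target_db(tfr[tfr$source == "trrust", ],
                           tfr[tfr$source == "fantom5", ],
                           tfr[tfr$source == "encode", ])
  res <- enrich_regulators(db, clusters, background)
  planted <- names(truth$regulator_cluster)[!is.na(truth$regulator_cluster) &
                                              truth$regulator_class == "tf"]
  for (r in planted) {
    row <- res[res$regulator == r & res$cluster == truth$regulator_cluster[[r]], ]
    expect_true(row$significant)
    expect_gt(row$odds_ratio, 1)
  }
  decoys <- setdiff(names(db$targets), planted)
  decoy_rows <- res[res$regulator %in% decoys, ]
  expect_gte(mean(!decoy_rows$significant), 0.95)

  # permuting cluster memberships destroys the planted significance
  set.seed(1)
  perm_members <- split(sample(unlist(clusters)),
                        rep(names(clusters), lengths(clusters)))
  res_perm <- enrich_regulators(db, perm_members, background)
  p_planted <- vapply(planted, function(r)
    res_perm$p[res_perm$regulator == r &
                 res_perm$cluster == truth$regulator_cluster[[r]]], numeric(1))
  expect_gt(median(p_planted), 0.1)
})

test_that("gene-set enrichment reports fold enrichment on the shared engine", {
  set_a <- sprintf("a%d", 1:30)
  decoy <- sprintf("b%d", 1:30)
  res <- gene_set_enrichment(list(A = set_a), query = set_a,
                             background = c(set_a, decoy))
  expect_equal(res$fold_enrichment, 2)

  res2 <- gene_set_enrichment(list(A = set_a[1:5]), query = decoy[1:10],
                              background = c(set_a, decoy))
  expect_equal(res2$a, 0)
  expect_equal(res2$fold_enrichment, 0)
  expect_equal(res2$p, 1)

  # identity with a direct engine call
  direct <- fisher_enrichment(set_a, set_a[1:12], c(set_a, decoy))
  viaset <- gene_set_enrichment(list(A = set_a), set_a[1:12], c(set_a, decoy))
  expect_equal(viaset$p, direct$p_value)
  expect_equal(viaset$odds_ratio, direct$odds_ratio)
  expect_equal(viaset$fold_enrichment, direct$fold_enrichment)
})
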