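test_that("generators are pure functions of their seed", {
  a <- simulate_genome_and_cnvs(n_genes = 15, n_lof_recurrent = 4,
                                n_lof_single = 2, n_benign = 2,
                                n_individuals = 8, seed = 5)
  b <- simulate_genome_and_cnvs(n_genes = 15, n_lof_recurrent = 4,
                                n_lof_single = 2, n_benign = 2,
                                n_individuals = 8, seed = 5)
  expect_equal(a$cnvs, b$cnvs)
  expect_equal(a$truth, b$truth)
  expect_equal(gene_spans(a$models), gene_spans(b$models))

  f1 <- simulate_feature_classes(n_hi = 50, n_hs = 50, seed = 5)
  f2 <- simulate_feature_classes(n_hi = 50, n_hs = 50, seed = 5)
  expect_equal(f1$features, f2$features)

  n1 <- simulate_network(n_genes = 40, n_seeds = 8, seed = 5)
  n2 <- simulate_network(n_genes = 40, n_seeds = 8, seed = 5)
  expect_equal(n1$network$edges, n2$network$edges)

  # byte-identical files across runs
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_gene_models_bed12(a$models, t1)
  write_gene_models_bed12(b$models, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("planted deletions evaluate to exactly the requested criterion", {
  set.seed(6)
  for (strand in c("+", "-")) for (shift in c(0, 30, 60)) {
    tx <- toy_transcript("t", "g", "chr1", 5000, strand, cds_shift = shift)
    for (crit in c("over_half_cds", "start_codon", "first_exon",
                   "splice_signal", "frameshift", "none")) {
      d <- plant_deletion(tx, crit)
      expect_identical(transcript_lof(tx, d)$criterion, crit)
      expect_identical(oracle_lof_criterion(tx, d), crit)
    }
  }
  # frameshift deletions remove a non-multiple-of-3 stretch of CDS
  sim <- simulate_genome_and_cnvs(n_genes = 30, n_lof_recurrent = 10,
                                  n_lof_single = 0, n_benign = 0,
                                  n_individuals = 10,
                                  criteria_mix = c(over_half_cds = 0,
                                                   start_codon = 0,
                                                   first_exon = 0,
                                                   splice_signal = 0,
                                                   frameshift = 1),
                                  seed = 8)
  expect_true(all(sim$truth$events$criterion == "frameshift"))
  for (i in seq_len(nrow(sim$truth$events))) {
    ev <- sim$truth$events[i, ]
    tx <- Find(function(t) t$id == ev$transcript_id, sim$models[[ev$gene_id]])
    cut <- sum(pmax(0, pmin(ev$end, tx$cds$end) - pmax(ev$start, tx$cds$start)))
    expect_true(cut %% 3 != 0)
  }
})

test_that("an infeasible planting request names the conflict", {
  single_exon <- transcript("se", "gse", "chr1", "+",
                            exons = data.frame(start = 0, end = 600),
                            cds = data.frame(start = 100, end = 400))
  expect_error(plant_deletion(single_exon, "splice_signal"), "infeasible")
  expect_error(plant_deletion(single_exon, "first_exon"), "infeasible")
})

test_that("planted recurrence is recovered exactly by the catalog", {
  sim <- simulate_genome_and_cnvs(n_genes = 50, n_lof_recurrent = 20,
                                  n_lof_single = 10, n_benign = 5,
                                  n_individuals = 30, seed = 14)
  cat2 <- build_hs_catalog(sim$cnvs, sim$models, min_individuals = 2)
  truth <- sim$truth$gene_status
  expect_setequal(cat2$catalog, truth$gene_id[truth$status == "recurrent"])
  expect_setequal(cat2$putative,
                  truth$gene_id[truth$status %in% c("recurrent", "single")])
  # the planted carrier count is reproduced per gene
  for (g in cat2$catalog)
    expect_equal(unname(cat2$counts[g]),
                 truth$n_carriers[truth$gene_id == g])
  # same individual with several LOF deletions of one gene counts once
  expect_true(all(cat2$counts <= 30))
})

test_that("generated fixtures pass the genomic_io validators", {
  sim <- simulate_genome_and_cnvs(n_genes = 12, n_lof_recurrent = 3,
                                  n_lof_single = 2, n_benign = 2,
                                  n_individuals = 6, seed = 15)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_models_bed12(sim$models, bed)
  expect_no_error(read_gene_models(bed, "bed12"))
  cnv <- withr::local_tempfile(fileext = ".bed")
  write.table(sim$cnvs, cnv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_no_error(read_cnvs(cnv))
  nw <- simulate_network(n_genes = 30, n_seeds = 5, seed = 15)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(nw$network, tsv)
  expect_equal(read_network(tsv)$edges$weight, nw$network$edges$weight,
               tolerance = 1e-6)
})

test_that("the feature generator records the analytic optimum", {
  f <- simulate_feature_classes(n_hi = 30, n_hs = 30, target_auc = 0.5,
                                seed = 16)
  expect_equal(f$optimal_auc, 0.5)
  expect_equal(f$delta, 0)
  f81 <- simulate_feature_classes(n_hi = 30, n_hs = 30, target_auc = 0.81,
                                  seed = 16)
  expect_equal(f81$optimal_auc, 0.81, tolerance = 1e-12)
  # Mahalanobis distance of the class means matches the reported delta
  d <- f81$mu_hi - f81$mu_hs
  expect_equal(sqrt(drop(t(d) %*% solve(f81$sigma, d))), f81$delta,
               tolerance = 1e-12)
  expect_false(anyNA(simulate_feature_classes(n_hi = 20, n_hs = 20,
                                              seed = 17)$features))
  holey <- simulate_feature_classes(n_hi = 200, n_hs = 200,
                                    missingness = 0.2, seed = 18)$features
  expect_lt(abs(mean(is.na(as.matrix(holey))) - 0.2), 0.03)
})

test_that("zero planted network excess yields statistically indistinguishable classes", {
  ps <- vapply(1:8, function(i) {
    nw <- simulate_network(n_genes = 80, n_seeds = 10, excess_edges = 0,
                           p_background = 0.05, seed = 100 + i)
    pr <- proximity_to_seeds(nw$network, nw$seeds, c(nw$class1, nw$class0))
    w <- setNames(pr$seed_weight, pr$gene_id)
    w1 <- w[nw$class1]; w0 <- w[nw$class0]
    mann_whitney(w1[!is.na(w1)], w0[!is.na(w0)])$p_value
  }, numeric(1))
  expect_gt(min(ps), 0.001)     # no systematic separation
  expect_gt(mean(ps > 0.1), 0.5)
})
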