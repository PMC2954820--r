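test_that("promoter window is [-100,100) about the TSS, reflected on the minus strand, clipped at 0", {
  txp <- transcript("tp", "gp", "chr1", "+",
                    exons = data.frame(start = 1000, end = 2000),
                    cds = data.frame(start = 1100, end = 1900))
  w <- promoter_interval(txp)
  expect_equal(c(w$start, w$end), c(900, 1100))

  txm <- transcript("tm", "gm", "chr1", "-",
                    exons = data.frame(start = 1000, end = 2000),
                    cds = data.frame(start = 1100, end = 1900))
  wm <- promoter_interval(txm)  # 5' end at coordinate 2000
  expect_equal(c(wm$start, wm$end), c(1900, 2100))

  tx0 <- transcript("t0", "g0", "chr1", "+",
                    exons = data.frame(start = 40, end = 400),
                    cds = data.frame(start = 100, end = 301))
  expect_warning(w0 <- promoter_interval(tx0), "clipped")
  expect_equal(c(w0$start, w0$end), c(0, 140))
})

test_that("per-gene summarization is the median over transcripts", {
  expect_equal(summarize_by_gene(3), 3)
  expect_equal(summarize_by_gene(c(1, 2, 10)), 2)
  expect_equal(summarize_by_gene(c(1, 2, 3, 10)), 2.5)
  expect_error(summarize_by_gene(numeric(0)), "at least one")
})

test_that("promoter conservation sums the track over the window and medians over transcripts", {
  tx1 <- transcript("t1", "g", "chr1", "+",
                    exons = data.frame(start = 1000, end = 2000),
                    cds = data.frame(start = 1100, end = 1900))
  tx2 <- transcript("t2", "g", "chr1", "+",
                    exons = data.frame(start = 1200, end = 2000),
                    cds = data.frame(start = 1300, end = 1900))
  models <- gene_model_set(list(tx1, tx2))
  track <- data.frame(chrom = "chr1", pos = c(950, 1099, 1100, 1150, 1250),
                      score = c(2, 3, 7, 1, 5))
  # t1 window [900,1100): 2+3 = 5 ; t2 window [1100,1300): 7+1+5 = 13
  expect_equal(unname(promoter_conservation(models, track)), median(c(5, 13)))
})

test_that("tissue specificity normalizes each gene's profile before taking the n-1 SD", {
  m <- rbind(uniform = c(5, 5, 5, 5),
             a = c(8, 4, 2, 2),
             b = c(80, 40, 20, 20),   # proportional to a
             solo = c(9, 0, 0, 0))
  ts <- tissue_specificity(m)
  expect_equal(unname(ts["uniform"]), 0)
  expect_equal(ts[["a"]], ts[["b"]])  # magnitude cancels
  # oracle: normalized solo profile is (1,0,0,0) regardless of level
  expect_equal(unname(ts["solo"]), sd(c(1, 0, 0, 0)))
  expect_error(tissue_specificity(m[, 1, drop = FALSE]), "single tissue")
})

test_that("embryonic flag is an 8-fold union rule with zero-reference handling", {
  expect_identical(embryonic_flag(80, 10), 1L)
  expect_identical(embryonic_flag(79, 10), 0L)
  expect_identical(embryonic_flag(c(5, 80), c(10, 10)), 1L)  # union over datasets
  expect_identical(embryonic_flag(3, 0), 1L)   # ratio infinite
  expect_identical(embryonic_flag(0, 0), 0L)
})

test_that("z-transform maps the genome mean to 0, keeps missing missing, and is idempotent", {
  df <- data.frame(x = c(1, 2, 3, NA, 10), y = c(0, 0, 1, 1, 0))
  z <- zscore_vs_genome(df)
  expect_equal(mean(z$x, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_true(is.na(z$x[4]))
  z2 <- zscore_vs_genome(z)
  expect_equal(z2$x, z$x, tolerance = 1e-10)
  expect_error(zscore_vs_genome(data.frame(k = rep(2, 5))), "constant")
})

test_that("Mann-Whitney agrees with exhaustive permutation enumeration for small samples", {
  set.seed(101)
  for (i in 1:20) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = sample(c(0, 1.5), 1))
    got <- mann_whitney(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, oracle_mw_p(x, y), tolerance = 1e-9)
  }
  # complete separation at 3 vs 3: 2 extreme assignments of 20
  expect_equal(mann_whitney(c(10, 11, 12), c(1, 2, 3))$p_value, 0.1)
  # all tied across both groups -> p = 1
  expect_equal(mann_whitney(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
})

test_that("property comparison uses the right test per kind and reports z-scores vs the genome", {
  cmp <- compare_property(c(10, 11, 12), c(1, 2, 3), "continuous",
                          genome_values = c(1:12), property = "demo")
  expect_identical(cmp$test, "mann_whitney_two_tailed")
  expect_equal(cmp$p_value, 0.1)
  expect_gt(cmp$z_hi, cmp$z_hs)

  bin <- compare_property(c(1, 1, 1, 1, 1), c(0, 0, 0, 0, 0), "binary")
  expect_identical(bin$test, "fisher_exact")
  expect_equal(bin$p_value, oracle_fisher_p(5, 0, 0, 5), tolerance = 1e-9)

  tied <- compare_property(c(2, 2), c(2, 2, 2), "continuous")
  expect_equal(tied$p_value, 1)
})

test_that("feature selection screens coverage and Spearman correlation and ranks by CV AUC", {
  set.seed(202)
  # independent within-class features keep the pooled rank correlation low
  sim <- simulate_feature_classes(n_hi = 150, n_hs = 150, target_auc = 0.85,
                                  sigma = diag(4), seed = 303)
  feats <- sim$features
  feats$noise <- rnorm(nrow(feats))
  labels <- sim$labels

  sel <- select_features(feats, labels, max_size = 4, folds = 5, repeats = 2,
                         seed = 7)
  expect_identical(sel$status, "ok")
  # the four generative features carry the separation; noise displaces none
  expect_setequal(sel$chosen, c("f1", "f2", "f3", "f4"))

  # perfectly rank-correlated features are never co-selected
  feats2 <- data.frame(a = rnorm(300), lab = labels)
  feats2$b <- feats2$a * 2 + 1  # Spearman rho = 1
  sel2 <- select_features(feats2[, c("a", "b")], labels, folds = 5,
                          repeats = 2, seed = 7)
  both <- grepl("a\\+b", sel2$report$features)
  expect_false(any(sel2$report$feasible[both]))

  # single candidate at 60% coverage is selected trivially
  one <- data.frame(a = c(rnorm(180), rep(NA, 120)))
  lab3 <- rep(c("HI", "HS"), 150)
  sel3 <- select_features(one, lab3, folds = 5, repeats = 2, seed = 7)
  expect_identical(sel3$chosen, "a")

  # order of candidate columns does not change the choice
  sel_rev <- select_features(feats[, rev(names(feats))], labels, max_size = 4,
                             folds = 5, repeats = 2, seed = 7)
  expect_setequal(sel_rev$chosen, sel$chosen)

  # nothing feasible -> explicit status
  allna <- data.frame(a = c(rnorm(30), rep(NA, 270)))
  sel4 <- select_features(allna, labels, folds = 5, repeats = 2, seed = 7)
  expect_identical(sel4$status, "no_feasible_subset")
  expect_null(sel4$chosen)
})
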