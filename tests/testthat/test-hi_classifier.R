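test_that("the discriminant points toward the HI mean and degenerate data warns", {
  set.seed(1)
  x <- data.frame(f = c(rnorm(50, 5), rnorm(50, 0)))
  lab <- rep(c("HI", "HS"), each = 50)
  m <- fit_lda(x, lab)
  expect_gt(m$w[["f"]], 0)

  # equal class means with within-class spread: w collapses to 0
  same <- data.frame(f = rep(c(1, 3, 1, 3), 5))
  expect_warning(fit_lda(same, rep(c("HI", "HI", "HS", "HS"), 5)),
                 "identical class means")
})

test_that("rows with missing features are dropped and counted; collinearity is diagnosed", {
  set.seed(2)
  x <- data.frame(a = rnorm(40), b = rnorm(40))
  x$a[1:4] <- NA
  m <- fit_lda(x, rep(c("HI", "HS"), 20))
  expect_equal(m$n_dropped, 4L)
  bad <- data.frame(a = rnorm(40))
  bad$b <- 2 * bad$a
  expect_error(fit_lda(bad, rep(c("HI", "HS"), 20)), "collinearity")
})

test_that("posterior equals the brute-force Gaussian-Bayes oracle", {
  set.seed(3)
  for (i in 1:20) {
    p <- sample(2:4, 1)
    n <- 60
    sim <- simulate_feature_classes(n_hi = n, n_hs = n, n_features = p,
                                    target_auc = runif(1, 0.6, 0.95),
                                    seed = 1000 + i)
    m <- fit_lda(sim$features, sim$labels,
                 priors = sample(list("empirical", "equal"), 1)[[1]])
    X <- as.matrix(sim$features)
    phi <- predict_phi(m, sim$features)
    for (j in sample(nrow(X), 5)) {
      expect_equal(phi$phi[j], oracle_posterior(m, X[j, ]), tolerance = 1e-9)
    }
  }
})

test_that("x at the midpoint of class means gives p(HI) = 0.5 under equal priors", {
  sim <- simulate_feature_classes(n_hi = 200, n_hs = 200, seed = 12)
  m <- fit_lda(sim$features, sim$labels, priors = "equal")
  mid <- (m$mu_hi + m$mu_hs) / 2 * m$scale  # back to raw units
  ph <- predict_phi(m, as.data.frame(t(mid)))
  expect_equal(ph$phi, 0.5, tolerance = 1e-12)
  # far beyond the HI mean the posterior saturates toward 1
  far <- m$mu_hi * m$scale * 50
  expect_gt(predict_phi(m, as.data.frame(t(far)))$phi, 0.999)
})

test_that("recovered discriminant is parallel to the analytic direction and to MASS::lda", {
  sim <- simulate_feature_classes(n_hi = 2000, n_hs = 2000, seed = 21)
  m <- fit_lda(sim$features, sim$labels)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_gte(cosine(m$w_raw, sim$optimal_w), 0.95)
  ref <- MASS::lda(as.matrix(sim$features), grouping = sim$labels)
  # MASS orders groups alphabetically (HI first); LD1 is defined up to sign
  expect_gte(abs(cosine(m$w_raw, ref$scaling[, 1])), 0.999)
})

test_that("unit-variance scaling absorbs any positive rescaling of a raw feature", {
  sim <- simulate_feature_classes(n_hi = 150, n_hs = 150, seed = 31)
  m1 <- fit_lda(sim$features, sim$labels)
  p1 <- predict_phi(m1, sim$features)$phi
  scaled <- sim$features
  scaled$f2 <- scaled$f2 * 1000
  m2 <- fit_lda(scaled, sim$labels)
  p2 <- predict_phi(m2, scaled)$phi
  expect_equal(p2, p1, tolerance = 1e-9)
})

test_that("AUC equals the Mann-Whitney identity and the pair-enumeration oracle", {
  set.seed(41)
  for (i in 1:25) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    s <- c(rnorm(n1, 0.5), rnorm(n2))
    if (i %% 3 == 0) s <- round(s)  # force ties
    y <- c(rep(TRUE, n1), rep(FALSE, n2))
    a <- auc(s, y)
    expect_equal(a, oracle_auc_pairs(s, y), tolerance = 1e-12)
    expect_equal(a, mann_whitney(s[y], s[!y])$U / (n1 * n2), tolerance = 1e-12)
  }
  # positives score {3, 1}, negative scores 2: one concordant pair of two
  expect_equal(auc(c(3, 1, 2), c(TRUE, TRUE, FALSE)),
               oracle_auc_pairs(c(3, 1, 2), c(TRUE, TRUE, FALSE)))
  expect_equal(auc(c(3, 1, 2), c(TRUE, TRUE, FALSE)), 0.5)
  expect_equal(auc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("MCC follows the closed form with the zero-denominator convention", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(5, 0, 5, 0), 0)
  expect_equal(mcc(4, 3, 2, 1),
               (4 * 3 - 2 * 1) / sqrt((4 + 2) * (4 + 1) * (3 + 2) * (3 + 1)))
  expect_equal(mcc(0, 0, 0, 0), 0)
})

test_that("cross-validation is deterministic under a fixed seed and honest under the null", {
  sim <- simulate_feature_classes(n_hi = 100, n_hs = 100, seed = 51)
  cv1 <- cross_validate(sim$features, sim$labels, repeats = 1, seed = 99)
  cv30 <- cross_validate(sim$features, sim$labels, repeats = 5, seed = 99)
  expect_equal(cv30$auc[1], cv1$auc[1])
  expect_equal(cross_validate(sim$features, sim$labels, repeats = 1, seed = 99)$auc,
               cv1$auc)

  # labels independent of features: CV AUC stays near 0.5
  null <- simulate_feature_classes(n_hi = 500, n_hs = 500, target_auc = 0.5,
                                   seed = 61)
  cvn <- cross_validate(null$features, null$labels, repeats = 3, seed = 7)
  expect_gt(cvn$mean_auc, 0.45)
  expect_lt(cvn$mean_auc, 0.55)
})

test_that("PMM imputation is identity without missingness and copies the nearest donor at k=1", {
  df <- data.frame(a = rnorm(30), b = rnorm(30))
  out <- impute_pmm(df, seed = 1)
  expect_equal(out$completed, df)

  df2 <- df
  df2$a[5] <- NA
  out2 <- impute_pmm(df2, seed = 1, donors = 1)
  fit <- lm(a ~ b, data = df2[-5, ])
  pred <- predict(fit, newdata = df2[5, , drop = FALSE])
  donor <- which.min(abs(fitted(fit) - pred))
  expect_equal(out2$completed$a[5], df2$a[-5][donor])
  expect_true(out2$imputed[5, "a"])
})

test_that("PMM under 20% MCAR keeps feature means within 3 SE of the complete data", {
  sim <- simulate_feature_classes(n_hi = 400, n_hs = 400, seed = 71)
  full <- sim$features
  holey <- simulate_feature_classes(n_hi = 400, n_hs = 400, missingness = 0.2,
                                    seed = 71)$features
  out <- impute_pmm(holey, seed = 5)
  for (v in names(full)) {
    se <- sd(full[[v]]) / sqrt(nrow(full))
    expect_lt(abs(mean(out$completed[[v]]) - mean(full[[v]])), 3 * se)
  }
  expect_false(anyNA(out$completed))
})

test_that("enrichment on a set matching the background composition is near fold 1", {
  set.seed(81)
  phi <- data.frame(gene_id = sprintf("G%04d", 1:2000), phi = runif(2000))
  random_set <- sample(phi$gene_id, 400)
  e <- enrichment_test(phi, random_set)
  expect_identical(e$definition_used, "proportion_ratio_vs_baseline")
  expect_lt(abs(e$fold_enrichment - 1), 0.35)
  expect_gt(e$p_value, 0.01)

  # two-set mode reduces to the sample odds ratio of the 2x2 table
  top <- phi$gene_id[order(-phi$phi)][1:200]
  set_a <- c(top[1:40], sample(setdiff(phi$gene_id, top), 160))
  set_b <- sample(setdiff(phi$gene_id, set_a), 300)
  e2 <- enrichment_test(phi, set_a, set_b)
  expect_identical(e2$definition_used, "odds_ratio")
  expect_equal(e2$fold_enrichment, (e2$a * e2$d) / (e2$b * e2$c))
  expect_warning(enrichment_test(phi, set_a, training_genes = set_a[1]),
                 "training")
})

test_that("LDA models survive a JSON round-trip", {
  sim <- simulate_feature_classes(n_hi = 80, n_hs = 80, seed = 91)
  m <- fit_lda(sim$features, sim$labels)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_lda_model(m, tmp)
  m2 <- read_lda_model(tmp)
  expect_equal(m2$w, m$w)
  expect_equal(m2$scale, m$scale)
  expect_equal(m2$priors, m$priors)
  expect_equal(predict_phi(m2, sim$features)$phi,
               predict_phi(m, sim$features)$phi, tolerance = 1e-12)
})
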