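#' Fit the linear discriminant model for haploinsufficiency
#'
#' Two-class LDA with a shared (pooled within-class) covariance. Each
#' feature is first divided by its training standard deviation so that all
#' enter on the same variance scale; the absolute values of the resulting
#' discriminant coefficients are then directly comparable as per-feature
#' contributions. The discriminant is `w = S_pooled^{-1} (mu_HI - mu_HS)`
#' in scaled space. Rows with any missing feature are dropped (and
#' counted); class priors default to the training class frequencies.
#'
#' @param features data.frame or matrix of numeric predictors (rows =
#'   genes).
#' @param labels Vector with exactly two kinds of values; the positive
#'   (HI) class is `positive`, everything else is HS.
#' @param positive Label value treated as the HI class (default `"HI"`).
#' @param priors `"empirical"` (training frequencies) or `"equal"`, or a
#'   numeric vector `c(p_HI, p_HS)` summing to 1.
#' @return An `lda_model`: list with `features`, `scale`, `mu_hi`, `mu_hs`
#'   (scaled space), `cov_pooled`, `w` (scaled space), `w_raw` (original
#'   units), `coefficients_abs`, `priors`, `n_hi`, `n_hs`, `n_dropped`.
#' @export
fit_lda <- function(features, labels, positive = "HI", priors = "empirical") {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  complete <- stats::complete.cases(X) & !is.na(labels)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  y <- labels[complete] == positive
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 genes per class with complete features")

  scale <- apply(X, 2L, stats::sd)
  if (any(scale == 0)) stop("constant feature; cannot scale to unit variance")
  Xs <- sweep(X, 2L, scale, "/")

  mu_hi <- colMeans(Xs[y, , drop = FALSE])
  mu_hs <- colMeans(Xs[!y, , drop = FALSE])
  n1 <- sum(y); n0 <- sum(!y)
  S1 <- stats::cov(Xs[y, , drop = FALSE])
  S0 <- stats::cov(Xs[!y, , drop = FALSE])
  Sp <- ((n1 - 1) * S1 + (n0 - 1) * S0) / (n1 + n0 - 2)

  w <- tryCatch(solve(Sp, mu_hi - mu_hs),
                error = function(e)
                  stop("singular pooled covariance; check features for collinearity"))
  if (all(abs(mu_hi - mu_hs) < sqrt(.Machine$double.eps)))
    warning("identical class means; degenerate model (w = 0)")

  pr <- if (identical(priors, "empirical")) c(n1, n0) / (n1 + n0)
        else if (identical(priors, "equal")) c(0.5, 0.5)
        else {
          stopifnot(is.numeric(priors), length(priors) == 2L,
                    abs(sum(priors) - 1) < 1e-8)
          priors
        }

  structure(list(features = colnames(X), scale = scale,
                 mu_hi = mu_hi, mu_hs = mu_hs, cov_pooled = Sp,
                 w = w, w_raw = w / scale,
                 coefficients_abs = abs(w),
                 priors = stats::setNames(pr, c("HI", "HS")),
                 n_hi = n1, n_hs = n0, n_dropped = n_dropped),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d features, trained on %d HI / %d HS (%d rows dropped)\n",
              length(x$features), x$n_hi, x$n_hs, x$n_dropped))
  print(round(stats::setNames(x$coefficients_abs, x$features), 4))
  invisible(x)
}

#' Posterior probability of haploinsufficiency
#'
#' Under the equal-covariance two-Gaussian model the posterior is logistic
#' in the discriminant score:
#' `logit p(HI) = w' (x - (mu_HI + mu_HS)/2) + log(pi_HI / pi_HS)`
#' (in scaled feature space). Genes with any missing model feature are
#' excluded and reported, never scored.
#'
#' @param model An [fit_lda()] model.
#' @param features data.frame/matrix with (at least) the model's feature
#'   columns; rownames are gene ids.
#' @param provenance Provenance flag stored per gene
#'   (`"observed_features"` or `"imputed_features"`).
#' @return A `phi_table` data.frame: `gene_id`, `phi`, `provenance`, with
#'   attribute `n_excluded` (genes with missing features).
#' @export
predict_phi <- function(model, features, provenance = "observed_features") {
  X <- as.matrix(as.data.frame(features)[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X) & !is.na(X))) stop("non-finite feature value")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  complete <- stats::complete.cases(X)
  Xs <- sweep(X[complete, , drop = FALSE], 2L, model$scale, "/")
  mid <- (model$mu_hi + model$mu_hs) / 2
  logit <- drop(sweep(Xs, 2L, mid, "-") %*% model$w) +
    log(model$priors[["HI"]] / model$priors[["HS"]])
  out <- data.frame(gene_id = ids[complete], phi = stats::plogis(logit),
                    provenance = provenance, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!complete)
  class(out) <- c("phi_table", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Rank-based: equals `U / (n1 * n2)` where U is the Mann-Whitney statistic
#' of the positive-class scores, with ties counted 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or two-valued vector; `positive` marks the
#'   positive class.
#' @param positive Positive label (default `TRUE`).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels, positive = TRUE) {
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; 0 by convention
#' when any denominator factor is zero.
#'
#' @param tp,tn,fp,fn Confusion-matrix counts (>= 0).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Repeated stratified k-fold cross-validation of the LDA model
#'
#' Per repeat: a stratified random partition into `folds` folds; the model
#' is fit on the training folds and scores the held-out fold; held-out
#' scores are pooled over folds to give one AUC and one MCC (posterior
#' threshold `threshold`) per repeat. Means over repeats are reported.
#'
#' @param features,labels As in [fit_lda()] (complete cases required).
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 30).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param positive Positive-class label.
#' @param threshold Posterior threshold for the MCC confusion matrix
#'   (default 0.5).
#' @param priors Passed to [fit_lda()].
#' @return A `cv_result`: list with `auc` and `mcc` (per-repeat vectors),
#'   `mean_auc`, `mean_mcc`, `folds`, `repeats`, `seed`.
#' @export
cross_validate <- function(features, labels, folds = 10, repeats = 30,
                           seed, positive = "HI", threshold = 0.5,
                           priors = "empirical") {
  if (missing(seed)) stop("seed is required")
  X <- as.data.frame(features)
  stopifnot(all(stats::complete.cases(X)))
  y <- labels == positive
  if (min(sum(y), sum(!y)) < folds)
    stop("need at least `folds` genes per class")
  rownames(X) <- NULL
  set.seed(seed)
  auc_rep <- numeric(repeats); mcc_rep <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold_of <- integer(nrow(X))
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    scores <- numeric(nrow(X))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      m <- fit_lda(X[!test, , drop = FALSE],
                   ifelse(y[!test], "HI", "HS"), priors = priors)
      scores[test] <- predict_phi(m, X[test, , drop = FALSE])$phi
    }
    auc_rep[r] <- auc(scores, y)
    pred <- scores >= threshold
    mcc_rep[r] <- mcc(tp = sum(pred & y), tn = sum(!pred & !y),
                      fp = sum(pred & !y), fn = sum(!pred & y))
  }
  structure(list(auc = auc_rep, mcc = mcc_rep,
                 mean_auc = mean(auc_rep), mean_mcc = mean(mcc_rep),
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d repeats  mean AUC %.3f, mean MCC %.3f\n",
              x$folds, x$repeats, x$mean_auc, x$mean_mcc))
  invisible(x)
}

#' Predictive-mean-matching imputation
#'
#' For each feature with missing values: a linear regression of that
#' feature on the other features is fit over complete cases; each missing
#' cell receives the observed value of one of the `donors` complete cases
#' whose regression-predicted values are nearest the cell's own predicted
#' value (chosen uniformly at random among the `donors` nearest). Features
#' are processed in order of increasing missingness; a recipient row whose
#' other features are themselves missing uses the complete-case means of
#' those predictors for the prediction step only.
#'
#' @param features data.frame of numeric features with missing values.
#' @param seed RNG seed.
#' @param donors Number of nearest donors to sample from (default 5).
#' @return List with `completed` (data.frame, no missing values in
#'   processed columns) and `imputed` (logical matrix marking imputed
#'   cells).
#' @export
impute_pmm <- function(features, seed, donors = 5) {
  if (missing(seed)) stop("seed is required")
  X <- as.data.frame(features)
  num <- vapply(X, is.numeric, logical(1))
  stopifnot(all(num))
  if (!any(stats::complete.cases(X))) stop("no complete cases; cannot impute")
  miss <- is.na(as.matrix(X))
  if (any(colMeans(miss) == 1)) stop("feature missing in all rows")
  set.seed(seed)
  order_feats <- names(X)[order(colSums(miss[, names(X), drop = FALSE]))]
  complete_rows <- stats::complete.cases(X)
  for (v in order_feats) {
    mi <- which(is.na(X[[v]]))
    if (!length(mi)) next
    others <- setdiff(names(X), v)
    don <- which(complete_rows)
    fml <- stats::reformulate(others, response = v)
    fit <- stats::lm(fml, data = X[don, , drop = FALSE])
    pred_don <- stats::fitted(fit)
    newd <- X[mi, others, drop = FALSE]
    for (o in others) {  # prediction-only fill of missing predictors
      nao <- is.na(newd[[o]])
      if (any(nao)) newd[[o]][nao] <- mean(X[don, o])
    }
    pred_mi <- stats::predict(fit, newdata = newd)
    k <- min(donors, length(don))
    for (j in seq_along(mi)) {
      nearest <- don[order(abs(pred_don - pred_mi[j]))[seq_len(k)]]
      X[[v]][mi[j]] <- X[sample(rep(nearest, 2), 1L), v]
    }
  }
  list(completed = X, imputed = miss)
}

#' Enrichment of predicted-HI genes in a gene set
#'
#' Genes in the top `top_fraction` of p(HI) among all scored genes are
#' labeled predicted-HI. Two modes:
#' * two-set (`set_b` given): 2x2 table of predicted-HI status in set A vs
#'   set B; `fold_enrichment` is the sample odds ratio and the p-value a
#'   two-sided Fisher's exact test;
#' * baseline (`set_b = NULL`): `fold_enrichment` is the fraction of set A
#'   predicted HI divided by `top_fraction`, with a two-sided binomial
#'   test against `top_fraction`.
#'
#' Sets should be disjoint from the training labels; a warning is emitted
#' if `training_genes` is supplied and overlaps.
#'
#' @param phi A `phi_table` (or data.frame with `gene_id`, `phi`).
#' @param set_a Character vector of gene ids (scored genes only counted).
#' @param set_b Optional second gene set.
#' @param top_fraction Fraction of top-ranked genes labeled predicted-HI
#'   (default 0.10).
#' @param training_genes Optional ids used in training, for the overlap
#'   warning.
#' @return An `enrichment_result`: list with the 2x2 counts `a`, `b`, `c`,
#'   `d` (two-set mode), `fold_enrichment`, `p_value`, `definition_used`,
#'   `n_predicted_hi`, `threshold`.
#' @export
enrichment_test <- function(phi, set_a, set_b = NULL, top_fraction = 0.10,
                            training_genes = NULL) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  if (!length(set_a)) stop("empty gene set")
  if (!is.null(training_genes) &&
      length(intersect(c(set_a, set_b), training_genes)))
    warning("test set overlaps training genes; enrichment may be circular")
  p <- stats::setNames(phi$phi, phi$gene_id)
  n_top <- max(1L, floor(length(p) * top_fraction))
  predicted_hi <- names(sort(p, decreasing = TRUE))[seq_len(n_top)]
  threshold <- min(p[predicted_hi])
  a_in <- intersect(set_a, names(p))
  if (!length(a_in)) stop("no scored genes in set A")
  a <- sum(a_in %in% predicted_hi); b <- length(a_in) - a
  if (!is.null(set_b)) {
    b_in <- intersect(set_b, names(p))
    if (!length(b_in)) stop("no scored genes in set B")
    cc <- sum(b_in %in% predicted_hi); d <- length(b_in) - cc
    fold <- (a * d) / (b * cc)
    pv <- stats::fisher.test(rbind(c(a, b), c(cc, d)))$p.value
    res <- list(a = a, b = b, c = cc, d = d, fold_enrichment = fold,
                p_value = pv, definition_used = "odds_ratio")
  } else {
    fold <- (a / length(a_in)) / top_fraction
    pv <- stats::binom.test(a, length(a_in), p = top_fraction)$p.value
    res <- list(a = a, b = b, c = NA_integer_, d = NA_integer_,
                fold_enrichment = fold, p_value = pv,
                definition_used = "proportion_ratio_vs_baseline")
  }
  structure(c(res, list(n_predicted_hi = n_top, threshold = threshold)),
            class = "enrichment_result")
}

#' Enrichment arithmetic from pre-tabulated counts
#'
#' The same two fold-enrichment definitions as [enrichment_test()], applied
#' directly to counts (e.g. published tables): `odds_ratio` mode takes the
#' 2x2 table `a`,`b`,`c`,`d`; `proportion_ratio_vs_baseline` mode takes `a`
#' predicted-HI of `n` genes against a `baseline` fraction.
#'
#' @param a,b,c,d 2x2 counts (predicted-HI / not x set A / set B).
#' @param n Set size for baseline mode.
#' @param baseline Baseline fraction for baseline mode (default 0.10).
#' @return An `enrichment_result`.
#' @export
enrichment_from_counts <- function(a, b = NULL, c = NULL, d = NULL,
                                   n = NULL, baseline = 0.10) {
  if (!is.null(b) && !is.null(c) && !is.null(d)) {
    fold <- (a * d) / (b * c)
    pv <- stats::fisher.test(rbind(c(a, b), c(c, d)))$p.value
    structure(list(a = a, b = b, c = c, d = d, fold_enrichment = fold,
                   p_value = pv, definition_used = "odds_ratio",
                   n_predicted_hi = a + c, threshold = NA_real_),
              class = "enrichment_result")
  } else {
    stopifnot(!is.null(n))
    fold <- (a / n) / baseline
    pv <- stats::binom.test(a, n, p = baseline)$p.value
    structure(list(a = a, b = n - a, c = NA_integer_, d = NA_integer_,
                   fold_enrichment = fold, p_value = pv,
                   definition_used = "proportion_ratio_vs_baseline",
                   n_predicted_hi = a, threshold = NA_real_),
              class = "enrichment_result")
  }
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result (%s): fold %.3f, p = %.3g\n",
              x$definition_used, x$fold_enrichment, x$p_value))
  invisible(x)
}

#' Serialize an LDA model to JSON
#' @param model An `lda_model`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_lda_model <- function(model, path) {
  obj <- list(features = model$features, scale = unname(model$scale),
              mu_hi = unname(model$mu_hi), mu_hs = unname(model$mu_hs),
              cov_pooled = model$cov_pooled, w = unname(model$w),
              w_raw = unname(model$w_raw),
              priors = unname(model$priors),
              n_hi = model$n_hi, n_hs = model$n_hs,
              n_dropped = model$n_dropped)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an LDA model from JSON
#' @param path Path to a model written by [write_lda_model()].
#' @return An `lda_model`.
#' @export
read_lda_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- o$features
  structure(list(features = nm, scale = stats::setNames(o$scale, nm),
                 mu_hi = stats::setNames(o$mu_hi, nm),
                 mu_hs = stats::setNames(o$mu_hs, nm),
                 cov_pooled = matrix(unlist(o$cov_pooled), length(nm), length(nm),
                                     dimnames = list(nm, nm)),
                 w = stats::setNames(o$w, nm),
                 w_raw = stats::setNames(o$w_raw, nm),
                 coefficients_abs = abs(stats::setNames(o$w, nm)),
                 priors = stats::setNames(o$priors, c("HI", "HS")),
                 n_hi = o$n_hi, n_hs = o$n_hs, n_dropped = o$n_dropped),
            class = "lda_model")
}
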