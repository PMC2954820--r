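#' Promoter window of a transcript
#'
#' The promoter is the `[-100, 100)` window (bp, half-open) centered at the
#' transcription start site, the 5' end of the transcript. On the minus
#' strand the window is reflected about the 5' end so that offset -100 is
#' upstream in transcription direction; genomically, both strands yield a
#' symmetric 200-bp window about the TSS. Windows extending below position
#' 0 are clipped at 0 with a warning.
#'
#' @param tx A [transcript()].
#' @param upstream,downstream Window half-widths in bp (defaults 100/100).
#' @return A [genome_interval()].
#' @export
promoter_interval <- function(tx, upstream = 100, downstream = 100) {
  center <- if (tx$strand == "+") tx$start else tx$end
  s <- center - upstream
  e <- center + downstream
  if (tx$strand == "-") { s <- center - downstream; e <- center + upstream }
  if (s < 0) {
    warning(sprintf("promoter window of %s clipped at position 0", tx$id))
    s <- 0
  }
  genome_interval(tx$chrom, s, e, tx$strand)
}

#' Read a per-base conservation track
#'
#' TSV with columns chrom, pos (0-based), score.
#'
#' @param path Path to the track file.
#' @return data.frame with `chrom`, `pos`, `score`.
#' @export
read_conservation_track <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "pos", "score"),
                    colClasses = c("character", "numeric", "numeric"))
}

#' Summed promoter conservation per gene
#'
#' Sums the per-base conservation score over each transcript's promoter
#' window, then summarizes transcripts by gene using the median.
#'
#' @param models A [gene_model_set()].
#' @param track Conservation track as from [read_conservation_track()].
#' @param ... Passed to [promoter_interval()].
#' @return Named numeric vector, one value per gene.
#' @export
promoter_conservation <- function(models, track, ...) {
  per_gene <- vapply(names(models), function(g) {
    sums <- vapply(models[[g]], function(tx) {
      w <- promoter_interval(tx, ...)
      sum(track$score[track$chrom == w$chrom &
                      track$pos >= w$start & track$pos < w$end])
    }, numeric(1))
    summarize_by_gene(sums)
  }, numeric(1))
  per_gene
}

#' Summarize per-transcript values by gene
#'
#' The gene-level value is the median over its transcripts (mean of the
#' central pair for an even count).
#'
#' @param values Numeric vector of per-transcript values (length >= 1).
#' @return The median.
#' @export
summarize_by_gene <- function(values) {
  if (length(values) < 1L) stop("at least one transcript value required")
  stats::median(values)
}

#' Tissue specificity of expression
#'
#' Each gene's expression profile is normalized to total 1 across tissues
#' (so that specificity is not confounded with expression magnitude), then
#' the sample standard deviation (n-1 denominator) across tissues is taken
#' as the specificity measure.
#'
#' @param expr Numeric matrix, genes x tissues, non-negative, with
#'   rownames.
#' @return Named numeric vector of per-gene SDs.
#' @export
tissue_specificity <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("tissue specificity undefined for a single tissue")
  if (any(expr < 0, na.rm = TRUE)) stop("expression must be non-negative")
  tot <- rowSums(expr)
  norm <- expr / ifelse(tot > 0, tot, 1)
  apply(norm, 1L, stats::sd)
}

#' Embryonic over-expression flag
#'
#' A gene is flagged as embryonically expressed (1) if its embryonic
#' expression level is at least `fold` times its reference level in any of
#' the supplied embryonic datasets (union rule). A zero reference with
#' positive embryonic expression counts as satisfying the fold; both zero
#' does not.
#'
#' @param embryonic Numeric vector of embryonic-stage levels, one per
#'   dataset.
#' @param reference Numeric vector of matching reference (adult) levels.
#' @param fold Fold-change threshold (default 8).
#' @return 0 or 1.
#' @export
embryonic_flag <- function(embryonic, reference, fold = 8) {
  if (length(embryonic) != length(reference))
    stop("embryonic and reference must have equal length")
  if (any(embryonic < 0 | reference < 0)) stop("levels must be >= 0")
  pass <- ifelse(reference == 0, embryonic > 0, embryonic / reference >= fold)
  as.integer(any(pass))
}

#' Transform feature columns to z-scores vs the genome average
#'
#' Each numeric column is centered and scaled by its own (genome-wide)
#' mean and SD over non-missing values; missing values stay missing. The
#' transform is idempotent up to floating error.
#'
#' @param features data.frame of per-gene numeric features.
#' @return data.frame of the same shape.
#' @export
zscore_vs_genome <- function(features) {
  out <- features
  for (nm in names(out)) {
    x <- out[[nm]]
    if (!is.numeric(x)) next
    ok <- !is.na(x)
    if (sum(ok) < 2L) stop(sprintf("column %s: fewer than 2 non-missing values", nm))
    s <- stats::sd(x[ok])
    if (s == 0) stop(sprintf("column %s is constant; z-score undefined", nm))
    out[[nm]] <- (x - mean(x[ok])) / s
  }
  out
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-based two-sample location test. For small samples without ties
#' (`n1 + n2 <= exact_max`) the p-value is computed by exhaustive
#' enumeration of all group assignments (two-tailed: twice the smaller tail
#' probability of U, capped at 1). Otherwise the normal approximation with
#' tie correction is used. When all values are tied across both groups the
#' p-value is 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Maximum combined size for the exact-enumeration path
#'   (default 16).
#' @return List with `U` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 16) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0L
  if (!has_ties && (n1 + n2) <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(us <= U), mean(us >= U))
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  t <- table(all_v)
  tie_term <- sum(t^3 - t) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Compare one gene property between HI and HS genes
#'
#' Continuous properties are compared by the two-tailed Mann-Whitney U
#' test, binary ones by a two-sided Fisher's exact test on the 2x2 table.
#' Group means are also expressed as z-scores relative to the genome
#' average (supplied via `genome_values`; the pooled groups are used as the
#' reference when absent), with standard errors of the mean (error bars in
#' the comparison report are 2 x SEM).
#'
#' @param values_hi,values_hs Numeric vectors of the property in the HI and
#'   HS training genes (missing values dropped).
#' @param kind `"continuous"` or `"binary"`.
#' @param genome_values Optional numeric vector of genome-wide values used
#'   as the z-score reference.
#' @param property Optional property name carried into the result.
#' @return A `property_comparison`: list with `property`, `test`,
#'   `p_value`, `mean_hi`, `mean_hs`, `sem_hi`, `sem_hs`, `z_hi`, `z_hs`,
#'   `z_sem_hi`, `z_sem_hs`.
#' @export
compare_property <- function(values_hi, values_hs,
                             kind = c("continuous", "binary"),
                             genome_values = NULL, property = NA_character_) {
  kind <- match.arg(kind)
  values_hi <- values_hi[!is.na(values_hi)]
  values_hs <- values_hs[!is.na(values_hs)]
  if (!length(values_hi) || !length(values_hs))
    stop("both groups must be non-empty")
  if (kind == "continuous") {
    test <- "mann_whitney_two_tailed"
    p <- mann_whitney(values_hi, values_hs)$p_value
  } else {
    test <- "fisher_exact"
    tab <- rbind(c(sum(values_hi == 1), sum(values_hi == 0)),
                 c(sum(values_hs == 1), sum(values_hs == 0)))
    p <- stats::fisher.test(tab)$p.value
  }
  ref <- if (is.null(genome_values)) c(values_hi, values_hs)
         else genome_values[!is.na(genome_values)]
  gm <- mean(ref); gs <- stats::sd(ref)
  zt <- function(v) if (gs > 0) (v - gm) / gs else NA_real_
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(property = property, test = test, p_value = p,
                 mean_hi = mean(values_hi), mean_hs = mean(values_hs),
                 sem_hi = sem(values_hi), sem_hs = sem(values_hs),
                 z_hi = zt(mean(values_hi)), z_hs = zt(mean(values_hs)),
                 z_sem_hi = sem(values_hi) / gs, z_sem_hs = sem(values_hs) / gs),
            class = "property_comparison")
}

#' Constrained feature-subset selection
#'
#' Enumerates subsets of candidate predictors and retains those that
#' (i) jointly cover at least `coverage_min` of all genes (non-missing in
#' every subset member), and (ii) have all pairwise Spearman rank
#' correlations below `rho_max` in absolute value (computed on jointly
#' non-missing genes, average ranks for ties). Surviving subsets are ranked
#' by mean cross-validated AUC of the LDA model fit on complete cases;
#' category diversity (number of distinct feature categories) is reported.
#'
#' @param features data.frame of candidate predictor columns (rows =
#'   genes; missing allowed).
#' @param labels Factor/character vector with levels HI/HS aligned to rows;
#'   `NA` for unlabeled genes (they count toward coverage only).
#' @param categories Optional named character vector mapping feature name
#'   to its broad category (genomic/evolutionary/functional/network).
#' @param coverage_min Minimum joint coverage fraction (default 0.5).
#' @param rho_max Spearman correlation ceiling (default 0.3).
#' @param max_size Largest subset size to consider (default all).
#' @param folds,repeats,seed Cross-validation settings (see
#'   [cross_validate()]).
#' @return List with `chosen` (character vector of feature names, or `NULL`
#'   when no subset is feasible), `report` (data.frame over all evaluated
#'   subsets), `status` (`"ok"` or `"no_feasible_subset"`).
#' @export
select_features <- function(features, labels, categories = NULL,
                            coverage_min = 0.5, rho_max = 0.3,
                            max_size = ncol(features),
                            folds = 10, repeats = 3, seed = 1) {
  stopifnot(ncol(features) >= 1L)
  cand <- sort(names(features))
  n_genes <- nrow(features)
  subsets <- unlist(lapply(seq_len(min(max_size, length(cand))),
                           function(k) utils::combn(cand, k, simplify = FALSE)),
                    recursive = FALSE)
  rows <- list()
  for (ss in subsets) {
    sub <- features[, ss, drop = FALSE]
    complete <- stats::complete.cases(sub)
    coverage <- mean(complete)
    max_rho <- 0
    if (length(ss) > 1L) {
      cm <- stats::cor(sub[complete, , drop = FALSE], method = "spearman")
      max_rho <- max(abs(cm[upper.tri(cm)]))
    }
    feasible <- coverage >= coverage_min && max_rho < rho_max
    auc_cv <- NA_real_; mcc_cv <- NA_real_
    if (feasible) {
      keep <- complete & !is.na(labels)
      cv <- cross_validate(sub[keep, , drop = FALSE], labels[keep],
                           folds = folds, repeats = repeats, seed = seed)
      auc_cv <- cv$mean_auc; mcc_cv <- cv$mean_mcc
    }
    n_cat <- if (is.null(categories)) NA_integer_
             else length(unique(categories[ss]))
    rows[[length(rows) + 1L]] <-
      data.frame(features = paste(ss, collapse = "+"), size = length(ss),
                 coverage = coverage, max_abs_rho = max_rho,
                 n_categories = n_cat, feasible = feasible,
                 cv_auc = auc_cv, cv_mcc = mcc_cv)
  }
  report <- do.call(rbind, rows)
  ok <- report$feasible
  if (!any(ok))
    return(list(chosen = NULL, report = report, status = "no_feasible_subset"))
  best <- report[ok, ][order(-report$cv_auc[ok]), ][1L, ]
  list(chosen = strsplit(best$features, "+", fixed = TRUE)[[1L]],
       report = report[order(-report$cv_auc, na.last = TRUE), ],
       status = "ok")
}
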