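#' Deletion haploinsufficiency LOD score
#'
#' The log10 odds that at least one gene in the deletion causes
#' haploinsufficiency versus none of them doing so, assuming no statistical
#' interaction between genes: with `q = prod(1 - p_i)`,
#' `LOD = log10((1 - q) / q)`. Each probability is clamped into
#' `[eps, 1 - eps]` first so the score stays finite when a gene's p(HI)
#' saturates at 0 or 1.
#'
#' @param p Numeric vector of per-gene p(HI) in \[0, 1\] (non-empty).
#' @param clamp_eps Clamping epsilon (default 1e-6).
#' @return The LOD score (finite numeric).
#' @export
lod_score <- function(p, clamp_eps = 1e-6) {
  if (length(p) == 0L) stop("undefined LOD: no gene probabilities supplied")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  p <- pmin(pmax(p, clamp_eps), 1 - clamp_eps)
  q <- prod(1 - p)
  log10((1 - q) / q)
}

#' LOD scores for a set of deletions
#'
#' Maps each deletion to the genes it renders loss-of-function (default) or
#' merely overlaps (`overlap_mode = TRUE`), looks up their p(HI), and
#' computes the LOD score. Genes without a p(HI) are skipped and counted,
#' never treated as p = 0; deletions with no scorable gene get `NA`.
#'
#' @param deletions data.frame with `chrom`, `start`, `end` (and optionally
#'   `sample_id`).
#' @param phi A `phi_table` (columns `gene_id`, `phi`).
#' @param models A [gene_model_set()].
#' @param overlap_mode If `TRUE`, any gene whose span overlaps the deletion
#'   is included; if `FALSE` (default) only genes whose every coding
#'   transcript is disrupted by the deletion under the LOF rules.
#' @param clamp_eps Passed to [lod_score()].
#' @return data.frame: one row per deletion with `chrom`, `start`, `end`,
#'   `sample_id` (if present), `genes` (comma-joined), `n_genes_scored`,
#'   `n_genes_skipped_missing_phi`, `lod`.
#' @export
score_deletions <- function(deletions, phi, models, overlap_mode = FALSE,
                            clamp_eps = 1e-6) {
  p <- stats::setNames(phi$phi, phi$gene_id)
  spans <- gene_spans(models)
  out <- deletions[, intersect(c("chrom", "start", "end", "sample_id"),
                               names(deletions)), drop = FALSE]
  out$genes <- NA_character_
  out$n_genes_scored <- 0L
  out$n_genes_skipped_missing_phi <- 0L
  out$lod <- NA_real_
  for (i in seq_len(nrow(deletions))) {
    del <- genome_interval(deletions$chrom[i], deletions$start[i],
                           deletions$end[i])
    touch <- spans$gene_id[spans$chrom == del$chrom &
                           spans$end > del$start & spans$start < del$end]
    if (overlap_mode) {
      genes <- touch
    } else {
      genes <- Filter(function(g) {
        coding <- Filter(is_coding, models[[g]])
        length(coding) > 0L &&
          all(vapply(coding, function(tx) transcript_lof(tx, del)$is_lof,
                     logical(1)))
      }, touch)
    }
    genes <- unlist(genes)
    scored <- intersect(genes, names(p))
    out$genes[i] <- paste(genes, collapse = ",")
    out$n_genes_scored[i] <- length(scored)
    out$n_genes_skipped_missing_phi[i] <- length(genes) - length(scored)
    if (length(scored) > 0L)
      out$lod[i] <- lod_score(p[scored], clamp_eps = clamp_eps)
  }
  out
}

#' Maximal deletion LOD per individual
#'
#' Each individual is summarized by the largest LOD among their scored
#' deletions; individuals whose deletions are all unscorable are excluded
#' and counted.
#'
#' @param scored Output of [score_deletions()] including `sample_id`.
#' @return List with `max_lod` (named numeric vector per sample) and
#'   `n_excluded` (samples with no scorable deletion).
#' @export
max_lod_per_individual <- function(scored) {
  stopifnot("sample_id" %in% names(scored))
  by_sample <- split(scored$lod, scored$sample_id)
  vals <- vapply(by_sample, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  list(max_lod = vals[!is.na(vals)], n_excluded = sum(is.na(vals)))
}

#' Genome-wide haploinsufficiency burden
#'
#' Pools the unique genes hit across all of one genome's deletions
#' (deduplicated, so a gene hit by two deletions counts once) and computes
#' a single LOD score over the pooled set.
#'
#' @param scored Output of [score_deletions()] for one genome's deletions.
#' @param phi A `phi_table`.
#' @param clamp_eps Passed to [lod_score()].
#' @return The genome burden LOD (NA when no gene is scorable).
#' @export
genome_burden_lod <- function(scored, phi, clamp_eps = 1e-6) {
  p <- stats::setNames(phi$phi, phi$gene_id)
  genes <- unique(unlist(strsplit(scored$genes[nzchar(scored$genes)], ",")))
  scored_genes <- intersect(genes, names(p))
  if (!length(scored_genes)) return(NA_real_)
  lod_score(p[scored_genes], clamp_eps = clamp_eps)
}

#' Empirical control distribution of maximal LOD scores
#'
#' Either raw per-individual maximal LOD values or a percentile summary
#' table (percentile -> LOD, monotone non-decreasing).
#'
#' @param values Numeric vector of per-individual maximal LODs.
#' @param percentiles data.frame with columns `percentile` (0-100) and
#'   `lod`.
#' @param population Optional population label.
#' @return A `control_distribution`.
#' @export
control_distribution <- function(values = NULL, percentiles = NULL,
                                 population = "") {
  if (is.null(values) && is.null(percentiles))
    stop("control distribution needs values or a percentile table")
  if (!is.null(values)) values <- sort(values)
  if (!is.null(percentiles)) {
    percentiles <- percentiles[order(percentiles$percentile), ]
    if (is.unsorted(percentiles$lod))
      stop("percentile table must be monotone non-decreasing in LOD")
  }
  structure(list(values = values, percentiles = percentiles,
                 population = population),
            class = "control_distribution")
}

#' @export
print.control_distribution <- function(x, ...) {
  if (!is.null(x$values))
    cat(sprintf("control_distribution '%s': %d individuals\n",
                x$population, length(x$values)))
  else
    cat(sprintf("control_distribution '%s': percentile table (%s)\n",
                x$population,
                paste(sprintf("%g%%=%g", x$percentiles$percentile,
                              x$percentiles$lod), collapse = ", ")))
  invisible(x)
}

#' Empirical probability of drawing an equally pathogenic control
#'
#' The proportion of control individuals whose maximal LOD is greater than
#' or equal to the query LOD. With raw values this is an exact proportion
#' (resolution 1/N; a LOD above every control returns 0 with a
#' `resolution_limit` attribute). With a percentile table, the survival
#' probability `1 - pct/100` is linearly interpolated between tabulated
#' LODs and clamped to the outermost tabulated percentiles beyond the
#' table.
#'
#' @param lod Query LOD score.
#' @param control A [control_distribution()].
#' @return Probability in \[0, 1\].
#' @export
empirical_p <- function(lod, control) {
  stopifnot(inherits(control, "control_distribution"))
  if (!is.null(control$values)) {
    n <- length(control$values)
    pr <- sum(control$values >= lod) / n
    if (pr == 0) attr(pr, "resolution_limit") <- 1 / n
    return(pr)
  }
  tab <- control$percentiles
  surv <- 1 - tab$percentile / 100
  if (lod <= tab$lod[1L]) return(surv[1L])
  if (lod >= tab$lod[nrow(tab)]) return(surv[nrow(tab)])
  stats::approx(tab$lod, surv, xout = lod, ties = "ordered")$y
}

#' Load the packaged control LOD percentile tables
#'
#' Percentiles (50/90/95/99) of the distribution of per-individual maximal
#' deletion LOD scores in published healthy GWAS control cohorts
#' (African-American and European-American), shipped as reference data for
#' percentile-lookup mode.
#'
#' @param population `"AA"` (African-American) or `"EA"`
#'   (European-American).
#' @return A [control_distribution()] in percentile-table mode.
#' @export
load_control_percentiles <- function(population = c("AA", "EA")) {
  population <- match.arg(population)
  path <- system.file("extdata", "control_lod_percentiles.tsv",
                      package = "hipred", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab <- tab[tab$population == population, c("percentile", "lod")]
  control_distribution(percentiles = tab, population = population)
}

#' Read a control distribution from TSV
#'
#' A two-column `percentile<TAB>lod` table (with header) is read as a
#' percentile summary; a single column of numbers as raw per-individual
#' maximal LODs.
#'
#' @param path Path to the TSV.
#' @param population Optional label.
#' @return A [control_distribution()].
#' @export
read_control_distribution <- function(path, population = "") {
  first <- readLines(path, n = 1L)
  if (grepl("percentile", first, ignore.case = TRUE)) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE)
    control_distribution(percentiles = tab[, c("percentile", "lod")],
                         population = population)
  } else {
    vals <- utils::read.table(path, header = FALSE)[[1L]]
    control_distribution(values = as.numeric(vals), population = population)
  }
}

#' Compare pathogenicity metrics by ROC
#'
#' For each metric (e.g. LOD, deletion length, gene count), computes the
#' ROC AUC for discriminating case deletions from the per-individual
#' representative control deletions (the control representative is the
#' maximum of the metric within each individual, matching how a clinician
#' would flag the most suspicious deletion per genome).
#'
#' @param cases data.frame of case deletions with metric columns.
#' @param controls data.frame of control deletions with the same metric
#'   columns plus `sample_id`.
#' @param metrics Character vector of metric column names.
#' @return data.frame with `metric` and `auc`.
#' @export
roc_compare <- function(cases, controls, metrics = c("lod", "length_bp", "n_genes")) {
  stopifnot("sample_id" %in% names(controls))
  rows <- lapply(metrics, function(m) {
    stopifnot(m %in% names(cases), m %in% names(controls))
    ctrl_rep <- tapply(controls[[m]], controls$sample_id,
                       function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    ctrl_rep <- ctrl_rep[!is.na(ctrl_rep)]
    case_v <- cases[[m]][!is.na(cases[[m]])]
    if (!length(case_v) || !length(ctrl_rep))
      stop(sprintf("metric %s: empty group", m))
    data.frame(metric = m,
               auc = auc(c(case_v, ctrl_rep),
                         c(rep(TRUE, length(case_v)),
                           rep(FALSE, length(ctrl_rep)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
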