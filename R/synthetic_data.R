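# Sub-seed offsets per generator: the master seed plus a fixed offset per
# generator, so adding a generator never perturbs the streams of the others.
.SEED_GENOME <- 101L
.SEED_FEATURES <- 202L
.SEED_NETWORK <- 303L
.SEED_CONTROLS <- 404L

#' Toy transcript template
#'
#' Three exons with the 5'-most exon fully untranslated (so that every LOF
#' criterion, including first-exon deletion, is plantable without another
#' rule firing first). The CDS lies in the two 3' exons; its start within
#' the middle exon is adjustable so that multiple transcripts of one gene
#' differ.
#'
#' @param id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param base Genomic offset of the transcript (>= 120).
#' @param strand `"+"` or `"-"`.
#' @param cds_shift Shift of the CDS start within the middle exon
#'   (0, 30 or 60).
#' @return A [transcript()].
#' @export
toy_transcript <- function(id, gene_id, chrom, base, strand = "+",
                           cds_shift = 0) {
  stopifnot(cds_shift %in% c(0, 30, 60))
  G <- base
  exons <- data.frame(start = G + c(0, 200, 400), end = G + c(100, 320, 500))
  if (strand == "+") {
    # exon1 is UTR; CDS from inside exon2 through part of exon3
    thick <- c(G + 230 + cds_shift, G + 470)
  } else {
    # mirrored: exon3 is the 5'-most exon (UTR); CDS in exons 1-2
    thick <- c(G + 30, G + 270 - cds_shift)
  }
  cds <- local({
    cs <- pmax(exons$start, thick[1]); ce <- pmin(exons$end, thick[2])
    keep <- ce > cs
    data.frame(start = cs[keep], end = ce[keep])
  })
  transcript(id, gene_id, chrom, strand, exons, cds)
}

#' Construct a deletion guaranteed to satisfy one LOF criterion
#'
#' Engineers a deletion interval over `tx` whose first satisfied criterion
#' (in the fixed rule order) is `criterion`; `"none"` yields a benign
#' intronic deletion. The construction is verified by [transcript_lof()]
#' and an error naming the conflict is raised if the transcript geometry
#' makes the request infeasible (e.g. a splice-signal deletion of a
#' single-exon transcript).
#'
#' @param tx A coding [transcript()].
#' @param criterion One of `over_half_cds`, `start_codon`, `first_exon`,
#'   `splice_signal`, `frameshift`, `none`.
#' @return A [genome_interval()].
#' @export
plant_deletion <- function(tx, criterion = c("over_half_cds", "start_codon",
                                             "first_exon", "splice_signal",
                                             "frameshift", "none")) {
  criterion <- match.arg(criterion)
  ex <- tx$exons
  del <- switch(criterion,
    over_half_cds = c(tx$start - 10, tx$end + 10),
    start_codon = {
      sc <- .start_codon(tx)
      c(min(sc$start), max(sc$end))
    },
    first_exon = {
      fe <- .first_exon(tx)
      c(max(0, fe$start - 5), fe$end + 5)
    },
    splice_signal = {
      if (nrow(ex) < 2L)
        stop(sprintf("infeasible: splice_signal needs an intron (transcript %s has one exon)",
                     tx$id))
      c(ex$end[1L], ex$end[1L] + 2)
    },
    frameshift = {
      w <- tx$cds$end - tx$cds$start
      i <- which.max(w)
      if (w[i] < 12)
        stop(sprintf("infeasible: frameshift needs an internal CDS stretch (transcript %s)",
                     tx$id))
      mid <- floor((tx$cds$start[i] + tx$cds$end[i]) / 2)
      c(mid, mid + 4)
    },
    none = {
      if (nrow(ex) < 2L)
        stop(sprintf("infeasible: benign intronic deletion needs an intron (transcript %s)",
                     tx$id))
      c(ex$end[1L] + 4, ex$end[1L] + 14)
    })
  out <- genome_interval(tx$chrom, del[1], del[2])
  got <- transcript_lof(tx, out)$criterion
  if (!identical(got, criterion))
    stop(sprintf("infeasible request: %s deletion on transcript %s evaluates as %s",
                 criterion, tx$id, got))
  out
}

#' Simulate toy gene models and planted LOF deletions
#'
#' Generates `n_genes` toy genes (random strand, 1 to `max_transcripts`
#' transcripts each, spaced well apart) and deletion CNVs planted so that a
#' known subset of genes is loss-of-function in a known set of
#' individuals: `n_lof_recurrent` genes are LOF in >= 2 individuals (each in
#' 2 to `max_carriers`), `n_lof_single` in exactly one, and `n_benign`
#' genes carry an intronic deletion that disrupts nothing. Each planted
#' gene-individual event deletes every coding transcript, one deletion per
#' transcript, with the per-transcript criterion drawn from
#' `criteria_mix`.
#'
#' @param n_genes Total genes (default 200).
#' @param n_lof_recurrent Genes LOF in two or more individuals (default 40).
#' @param n_lof_single Genes LOF in exactly one individual (default 20).
#' @param n_benign Genes with a benign deletion only (default 20).
#' @param n_individuals Cohort size (default 100).
#' @param max_transcripts Max transcripts per gene (default 2).
#' @param max_carriers Max carriers of a recurrent LOF gene (default 4).
#' @param criteria_mix Probability weights over the five criteria used to
#'   draw each planted event's criterion.
#' @param seed Master seed (mandatory).
#' @return List with `models` (a [gene_model_set()]), `cnvs` (a `cnv_set`
#'   data.frame), `truth` (list with `gene_status` data.frame and `events`
#'   data.frame of planted per-transcript criteria).
#' @export
simulate_genome_and_cnvs <- function(n_genes = 200, n_lof_recurrent = 40,
                                     n_lof_single = 20, n_benign = 20,
                                     n_individuals = 100,
                                     max_transcripts = 2, max_carriers = 4,
                                     criteria_mix = c(over_half_cds = 1,
                                                      start_codon = 1,
                                                      first_exon = 1,
                                                      splice_signal = 1,
                                                      frameshift = 1),
                                     seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_lof_recurrent + n_lof_single + n_benign <= n_genes,
            n_individuals >= 2, max_carriers >= 2)
  set.seed(seed + .SEED_GENOME)

  samples <- sprintf("S%03d", seq_len(n_individuals))
  criteria <- names(criteria_mix)

  txs <- list()
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  for (i in seq_len(n_genes)) {
    g <- gene_ids[i]
    chrom <- sprintf("chr%d", 1 + (i - 1) %% 4)
    base <- 1000 + 10000 * ((i - 1) %/% 4)
    strand <- sample(c("+", "-"), 1L)
    n_tx <- sample.int(max_transcripts, 1L)
    shifts <- c(0, 30, 60)[seq_len(n_tx)]
    for (k in seq_len(n_tx))
      txs[[length(txs) + 1L]] <-
        toy_transcript(sprintf("%s.t%d", g, k), g, chrom, base, strand,
                       cds_shift = shifts[k])
  }
  models <- gene_model_set(txs)

  status <- rep("untouched", n_genes)
  pick <- sample(n_genes, n_lof_recurrent + n_lof_single + n_benign)
  status[pick[seq_len(n_lof_recurrent)]] <- "recurrent"
  status[pick[n_lof_recurrent + seq_len(n_lof_single)]] <- "single"
  if (n_benign > 0)
    status[pick[n_lof_recurrent + n_lof_single + seq_len(n_benign)]] <- "benign"

  cnv_rows <- list(); event_rows <- list(); carrier_of <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g <- gene_ids[i]
    if (status[i] == "untouched") next
    if (status[i] == "benign") {
      sid <- sample(samples, 1L)
      tx <- models[[g]][[1L]]
      del <- plant_deletion(tx, "none")
      cnv_rows[[length(cnv_rows) + 1L]] <-
        data.frame(chrom = del$chrom, start = del$start, end = del$end,
                   sample_id = sid)
      next
    }
    n_car <- if (status[i] == "recurrent") sample(2:max_carriers, 1L) else 1L
    carriers <- sample(samples, n_car)
    carrier_of[[i]] <- carriers
    for (sid in carriers) for (tx in models[[g]]) {
      crit <- sample(criteria, 1L, prob = criteria_mix)
      del <- plant_deletion(tx, crit)
      cnv_rows[[length(cnv_rows) + 1L]] <-
        data.frame(chrom = del$chrom, start = del$start, end = del$end,
                   sample_id = sid)
      event_rows[[length(event_rows) + 1L]] <-
        data.frame(gene_id = g, transcript_id = tx$id, sample_id = sid,
                   criterion = crit, start = del$start, end = del$end)
    }
  }
  cnvs <- unique(do.call(rbind, cnv_rows))
  rownames(cnvs) <- NULL
  class(cnvs) <- c("cnv_set", "data.frame")

  truth <- list(
    gene_status = data.frame(
      gene_id = gene_ids, status = status,
      n_carriers = vapply(carrier_of, length, integer(1)),
      carriers = vapply(carrier_of, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE),
    events = if (length(event_rows)) do.call(rbind, event_rows)
             else data.frame())
  list(models = models, cnvs = cnvs, truth = truth)
}

#' Simulate two-class Gaussian gene features
#'
#' The generative twin of the LDA model: class-conditional multivariate
#' normal draws with a shared covariance. The class-mean separation is set
#' so that the analytically optimal classifier attains a chosen AUC:
#' for Mahalanobis distance `Delta` between class means, the optimal AUC
#' is `pnorm(Delta / sqrt(2))`. Optional MCAR missingness.
#'
#' @param n_hi,n_hs Genes per class (defaults 1000/1000).
#' @param n_features Number of predictors (default 4, mirroring a model of
#'   dN/dS, promoter conservation, embryonic expression and network
#'   proximity).
#' @param target_auc Optimal AUC of the generating model (default 0.81).
#' @param sigma Shared covariance matrix (default: unit variances with
#'   0.2 off-diagonal correlation).
#' @param missingness MCAR missingness rate in \[0, 1) (default 0).
#' @param seed Master seed (mandatory).
#' @return List with `features` (data.frame, rownames = gene ids),
#'   `labels` (`"HI"`/`"HS"`), `mu_hi`, `mu_hs`, `sigma`, `delta`
#'   (Mahalanobis separation), `optimal_auc`, `optimal_w` (the analytic
#'   discriminant `sigma^{-1} (mu_hi - mu_hs)`).
#' @export
simulate_feature_classes <- function(n_hi = 1000, n_hs = 1000,
                                     n_features = 4, target_auc = 0.81,
                                     sigma = NULL, missingness = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(missingness >= 0, missingness < 1, target_auc >= 0.5,
            target_auc < 1)
  set.seed(seed + .SEED_FEATURES)
  if (is.null(sigma)) {
    sigma <- matrix(0.2, n_features, n_features)
    diag(sigma) <- 1
  }
  stopifnot(nrow(sigma) == n_features, isSymmetric(sigma))

  delta <- stats::qnorm(target_auc) * sqrt(2)
  dirn <- rep(1, n_features)
  m <- dirn * delta / sqrt(drop(t(dirn) %*% solve(sigma, dirn)))
  mu_hs <- rep(0, n_features)
  mu_hi <- m

  X <- rbind(MASS::mvrnorm(n_hi, mu_hi, sigma),
             MASS::mvrnorm(n_hs, mu_hs, sigma))
  labels <- c(rep("HI", n_hi), rep("HS", n_hs))
  if (missingness > 0)
    X[matrix(stats::runif(length(X)) < missingness, nrow(X))] <- NA
  features <- as.data.frame(X)
  names(features) <- sprintf("f%d", seq_len(n_features))
  rownames(features) <- sprintf("G%05d", seq_len(n_hi + n_hs))

  list(features = features, labels = labels, mu_hi = mu_hi, mu_hs = mu_hs,
       sigma = sigma, delta = delta,
       optimal_auc = stats::pnorm(delta / sqrt(2)),
       optimal_w = solve(sigma, mu_hi - mu_hs))
}

#' Simulate a weighted functional network with planted seed proximity
#'
#' A random background graph (Erdos-Renyi over genes plus seed genes, with
#' Gamma-distributed positive log-likelihood weights) in which each
#' designated class-1 gene receives `excess_edges` extra edges to randomly
#' chosen seed genes. Class-1 genes thereby carry a known expected excess
#' of direct seed weight over class-0 genes.
#'
#' @param n_genes Non-seed genes (default 200).
#' @param n_seeds Seed genes (default 30).
#' @param class1_fraction Fraction of non-seed genes given planted seed
#'   edges (default 0.5).
#' @param p_background Background edge probability (default 0.02).
#' @param excess_edges Planted seed edges per class-1 gene (default 3; 0
#'   plants nothing).
#' @param weight_shape,weight_rate Gamma parameters of edge weights
#'   (defaults 2 and 1, mean 2).
#' @param seed Master seed (mandatory).
#' @return List with `network` (a [gene_network()]), `seeds`, `class1`,
#'   `class0` (gene id vectors), `expected_excess` (expected extra seed
#'   weight per class-1 gene, `excess_edges * shape / rate`).
#' @export
simulate_network <- function(n_genes = 200, n_seeds = 30,
                             class1_fraction = 0.5, p_background = 0.02,
                             excess_edges = 3, weight_shape = 2,
                             weight_rate = 1, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed + .SEED_NETWORK)
  genes <- sprintf("N%04d", seq_len(n_genes))
  seeds <- sprintf("SEED%03d", seq_len(n_seeds))
  nodes <- c(genes, seeds)
  n <- length(nodes)
  pairs <- utils::combn(n, 2L)
  take <- stats::runif(ncol(pairs)) < p_background
  ed <- data.frame(gene_a = nodes[pairs[1L, take]],
                   gene_b = nodes[pairs[2L, take]],
                   weight = stats::rgamma(sum(take), weight_shape,
                                          weight_rate))
  class1 <- sort(sample(genes, round(n_genes * class1_fraction)))
  class0 <- setdiff(genes, class1)
  if (excess_edges > 0) {
    extra <- lapply(class1, function(g) {
      tgt <- sample(seeds, min(excess_edges, n_seeds))
      data.frame(gene_a = g, gene_b = tgt,
                 weight = stats::rgamma(length(tgt), weight_shape,
                                        weight_rate))
    })
    ed <- rbind(ed, do.call(rbind, extra))
  }
  net <- suppressWarnings(gene_network(ed))
  list(network = net, seeds = seeds, class1 = class1, class0 = class0,
       expected_excess = excess_edges * weight_shape / weight_rate)
}

#' Simulate a control cohort's maximal LOD distribution
#'
#' Per-individual maximal deletion LOD scores drawn from a right-skewed
#' distribution (shifted Gamma) whose median sits slightly below 0 and
#' whose upper percentiles reach into the low single digits, the shape
#' seen for the most pathogenic deletion per healthy genome.
#'
#' @param n Cohort size (default 1000).
#' @param shift,shape,scale Shifted-Gamma parameters (defaults -1, 2,
#'   0.45).
#' @param seed Master seed (mandatory).
#' @return A [control_distribution()] in raw-value mode.
#' @export
simulate_control_lods <- function(n = 1000, shift = -1, shape = 2,
                                  scale = 0.45, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed + .SEED_CONTROLS)
  control_distribution(values = shift + stats::rgamma(n, shape, scale = scale),
                       population = "synthetic")
}
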