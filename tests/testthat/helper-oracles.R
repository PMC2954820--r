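# Independent brute-force oracles used to check the package's
# implementations. These deliberately use a different computational route
# (explicit base sets, density ratios, pair enumeration) than the code
# they verify.

# literal base-set evaluator of the five LOF criteria, in order
oracle_lof_criterion <- function(tx, del) {
  if (!identical(tx$chrom, del$chrom)) return("none")
  bases <- function(s, e) if (e > s) seq(s, e - 1) else numeric(0)
  del_b <- bases(del$start, del$end)
  cds_b <- sort(unlist(Map(bases, tx$cds$start, tx$cds$end)))
  hit_cds <- intersect(del_b, cds_b)

  if (length(hit_cds) > length(cds_b) / 2) return("over_half_cds")

  start_b <- if (tx$strand == "+") utils::head(cds_b, 3) else utils::tail(cds_b, 3)
  if (length(intersect(del_b, start_b)) > 0) return("start_codon")

  ex <- tx$exons[order(tx$exons$start), ]
  fe <- if (tx$strand == "+") ex[1, ] else ex[nrow(ex), ]
  if (all(bases(fe$start, fe$end) %in% del_b)) return("first_exon")

  if (nrow(ex) > 1) {
    splice_b <- unlist(lapply(seq_len(nrow(ex) - 1), function(i) {
      c(bases(ex$end[i], ex$end[i] + 2),
        bases(ex$start[i + 1] - 2, ex$start[i + 1]))
    }))
    if (length(intersect(del_b, splice_b)) > 0) return("splice_signal")
  }

  n <- length(hit_cds)
  if (n > 0 && n < length(cds_b) && n %% 3 != 0) return("frameshift")
  "none"
}

# posterior P(HI | x) from explicit Gaussian density evaluation
oracle_posterior <- function(model, x_raw) {
  xs <- x_raw / model$scale
  S <- model$cov_pooled
  p <- length(xs)
  dens <- function(mu) {
    z <- xs - mu
    exp(-0.5 * drop(t(z) %*% solve(S) %*% z)) /
      sqrt((2 * pi)^p * det(S))
  }
  d1 <- dens(model$mu_hi) * model$priors[["HI"]]
  d0 <- dens(model$mu_hs) * model$priors[["HS"]]
  d1 / (d1 + d0)
}

# AUC by explicit enumeration of all positive-negative pairs
oracle_auc_pairs <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-tailed Mann-Whitney p by exhaustive combination enumeration
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(all_v), n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= U_obs), mean(us >= U_obs)))
}

# product-form recomputation of the deletion LOD score
oracle_lod <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log_q <- sum(log10(1 - p))
  log10(1 - 10^log_q) - log_q
}

# a single-CDS-exon toy transcript: exons [0,1000), CDS [100,400)
simple_tx <- function(id = "tx1", strand = "+") {
  transcript(id, paste0("gene_", id), "chr1", strand,
             exons = data.frame(start = 0, end = 1000),
             cds = data.frame(start = 100, end = 400))
}

# three-exon transcript with a 70-bp internal coding exon
three_exon_tx <- function(strand = "+") {
  transcript("tx3e", "gene3e", "chr1", strand,
             exons = data.frame(start = c(0, 200, 400),
                                end = c(100, 270, 500)),
             cds = data.frame(start = c(50, 200, 400),
                              end = c(100, 270, 450)))
}

del <- function(start, end, chrom = "chr1") genome_interval(chrom, start, end)
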