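#' Loss-of-function call for a deletion against one transcript
#'
#' Applies the five transcript-disruption criteria, in this fixed order,
#' and reports the first one satisfied:
#'
#' 1. `over_half_cds` — the deletion removes strictly more than 50% of the
#'    coding sequence;
#' 2. `start_codon` — the deletion overlaps any of the three 5'-most CDS
#'    bases (strand-aware);
#' 3. `first_exon` — the deletion fully contains the transcript's 5'-most
#'    exon;
#' 4. `splice_signal` — the deletion overlaps any of the 2-bp intronic
#'    windows flanking an exon boundary (donor and acceptor, all introns);
#' 5. `frameshift` — the deletion overlaps the CDS partially and the number
#'    of deleted coding bases is not a multiple of 3.
#'
#' A deletion on a different chromosome is not LOF. Exactly half of the CDS
#' is not "over half". Splice windows are positional; no sequence content is
#' checked.
#'
#' @param tx A coding [transcript()].
#' @param deletion A [genome_interval()] (strand ignored).
#' @param sample_id Optional sample identifier carried into the call.
#' @return A `lof_call`: list with `transcript_id`, `sample_id`, `is_lof`,
#'   `criterion` (one of the five names, or `"none"`).
#' @export
transcript_lof <- function(tx, deletion, sample_id = NA_character_) {
  if (!is_coding(tx))
    stop(sprintf("transcript %s is non-coding; filter before LOF calling", tx$id))
  call <- function(criterion) {
    structure(list(transcript_id = tx$id, sample_id = sample_id,
                   is_lof = criterion != "none", criterion = criterion),
              class = "lof_call")
  }
  if (!identical(tx$chrom, deletion$chrom)) return(call("none"))
  ds <- deletion$start; de <- deletion$end

  cds_total <- cds_length(tx)
  cds_del <- sum(overlap_bp(ds, de, tx$cds$start, tx$cds$end))
  if (cds_del > cds_total / 2) return(call("over_half_cds"))

  if (sum(overlap_bp(ds, de, .start_codon(tx)$start, .start_codon(tx)$end)) > 0)
    return(call("start_codon"))

  fe <- .first_exon(tx)
  if (ds <= fe$start && de >= fe$end) return(call("first_exon"))

  sw <- .splice_windows(tx)
  if (nrow(sw) > 0L && sum(overlap_bp(ds, de, sw$start, sw$end)) > 0)
    return(call("splice_signal"))

  if (cds_del > 0 && cds_del < cds_total && (cds_del %% 3) != 0)
    return(call("frameshift"))

  call("none")
}

# genomic interval(s) of the 3 5'-most CDS bases, walking CDS segments in
# transcription order (the start codon can straddle a CDS junction)
.start_codon <- function(tx) {
  cds <- tx$cds
  need <- 3
  segs <- list()
  if (tx$strand == "+") {
    for (i in seq_len(nrow(cds))) {
      take <- min(need, cds$end[i] - cds$start[i])
      segs[[length(segs) + 1L]] <- c(cds$start[i], cds$start[i] + take)
      need <- need - take
      if (need <= 0) break
    }
  } else {
    for (i in rev(seq_len(nrow(cds)))) {
      take <- min(need, cds$end[i] - cds$start[i])
      segs[[length(segs) + 1L]] <- c(cds$end[i] - take, cds$end[i])
      need <- need - take
      if (need <= 0) break
    }
  }
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1], end = m[, 2])
}

# 5'-most exon in transcription direction
.first_exon <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "+") ex[1L, ] else ex[nrow(ex), ]
}

# 2-bp intronic windows on both sides of every intron
.splice_windows <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = numeric(0), end = numeric(0)))
  donor_s <- ex$end[-n]           # [exon_end, exon_end + 2)
  acceptor_s <- ex$start[-1L] - 2 # [next_exon_start - 2, next_exon_start)
  data.frame(start = c(donor_s, acceptor_s),
             end = c(donor_s + 2, acceptor_s + 2))
}

#' Gene-level LOF status for one individual
#'
#' A gene is LOF in an individual iff every coding transcript of the gene
#' has at least one LOF call from that individual's deletions. Different
#' transcripts may be disrupted by different deletions of the same
#' individual. Non-coding transcripts of a coding gene are ignored.
#'
#' @param gene_transcripts List of [transcript()] objects for one gene.
#' @param deletions data.frame with `chrom`, `start`, `end` — the deletions
#'   carried by one individual.
#' @return `TRUE` if the gene is LOF in this individual.
#' @export
gene_lof_in_individual <- function(gene_transcripts, deletions) {
  coding <- Filter(is_coding, gene_transcripts)
  if (length(coding) == 0L)
    stop("gene has no coding transcript; LOF status undefined")
  for (tx in coding) {
    hit <- FALSE
    for (j in seq_len(nrow(deletions))) {
      del <- genome_interval(deletions$chrom[j], deletions$start[j],
                             deletions$end[j])
      if (transcript_lof(tx, del)$is_lof) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Build the haplosufficient gene catalog
#'
#' Evaluates gene-level LOF for every (gene, individual) pair and retains
#' genes that are LOF in at least `min_individuals` distinct individuals.
#' Also reports the `>= 1`-individual ("putative") set and a per-criterion
#' tally of transcript-level LOF events (one event = one transcript
#' disrupted by one deletion in one individual; the criterion recorded is
#' the first satisfied in the fixed rule order).
#'
#' @param cnvs A `cnv_set` as from [read_cnvs()].
#' @param models A [gene_model_set()].
#' @param min_individuals Minimum number of distinct individuals with
#'   gene-level LOF for catalog membership (default 2, i.e. recurrence).
#' @return An `hs_catalog`: list with `counts` (named integer vector of
#'   distinct LOF individuals per gene, all genes with >= 1), `catalog`
#'   (gene ids at >= min_individuals), `putative` (gene ids at >= 1),
#'   `criterion_tally` (named integer vector over the five criteria),
#'   `min_individuals`.
#' @export
build_hs_catalog <- function(cnvs, models, min_individuals = 2) {
  if (min_individuals < 1) stop("min_individuals must be >= 1")
  stopifnot(inherits(models, "gene_model_set"))
  criteria <- c("over_half_cds", "start_codon", "first_exon",
                "splice_signal", "frameshift")
  tally <- stats::setNames(integer(length(criteria)), criteria)
  counts <- integer(0)

  by_sample <- split(seq_len(nrow(cnvs)), cnvs$sample_id)
  spans <- gene_spans(models)
  for (g in names(models)) {
    coding <- Filter(is_coding, models[[g]])
    if (length(coding) == 0L) next
    span <- spans[spans$gene_id == g, ]
    n_lof <- 0L
    for (sid in names(by_sample)) {
      dels <- cnvs[by_sample[[sid]], , drop = FALSE]
      # cheap prefilter: only deletions touching the gene span matter
      dels <- dels[dels$chrom == span$chrom &
                   dels$end > span$start & dels$start < span$end, ,
                   drop = FALSE]
      if (nrow(dels) == 0L) next
      all_tx_hit <- TRUE
      for (tx in coding) {
        tx_hit <- FALSE
        for (j in seq_len(nrow(dels))) {
          del <- genome_interval(dels$chrom[j], dels$start[j], dels$end[j])
          lc <- transcript_lof(tx, del, sample_id = sid)
          if (lc$is_lof) {
            tally[lc$criterion] <- tally[lc$criterion] + 1L
            tx_hit <- TRUE
          }
        }
        if (!tx_hit) all_tx_hit <- FALSE
      }
      if (all_tx_hit) n_lof <- n_lof + 1L
    }
    if (n_lof >= 1L) counts[g] <- n_lof
  }
  structure(list(counts = counts,
                 catalog = names(counts)[counts >= min_individuals],
                 putative = names(counts),
                 criterion_tally = tally,
                 min_individuals = min_individuals),
            class = "hs_catalog")
}

#' @export
print.hs_catalog <- function(x, ...) {
  cat(sprintf("hs_catalog: %d genes at >= %d individuals (%d putative at >= 1)\n",
              length(x$catalog), x$min_individuals, length(x$putative)))
  ct <- x$criterion_tally
  cat("LOF events by criterion:",
      paste(sprintf("%s=%d", names(ct), ct), collapse = ", "), "\n")
  invisible(x)
}

#' Write an HS catalog as TSV
#'
#' Columns: gene_id, n_individuals, in_catalog.
#'
#' @param catalog An `hs_catalog`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hs_catalog <- function(catalog, path) {
  df <- data.frame(gene_id = names(catalog$counts),
                   n_individuals = unname(catalog$counts),
                   in_catalog = as.integer(catalog$counts >= catalog$min_individuals))
  utils::write.table(df[order(-df$n_individuals, df$gene_id), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
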