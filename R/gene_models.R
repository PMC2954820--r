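#' Construct a transcript model
#'
#' A transcript is an exon/CDS structure on a strand. Exons must be
#' non-overlapping and sorted by start; every CDS segment must lie within an
#' exon. A transcript with no CDS is non-coding.
#'
#' @param id Transcript identifier.
#' @param gene_id Identifier of the parent gene.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"` (required for transcripts).
#' @param exons data.frame with numeric columns `start`, `end` (0-based
#'   half-open), one row per exon.
#' @param cds Optional data.frame with the same layout delimiting coding
#'   segments; `NULL` or zero rows for non-coding transcripts.
#' @return A `transcript` object.
#' @export
transcript <- function(id, gene_id, chrom, strand, exons, cds = NULL) {
  if (!strand %in% c("+", "-"))
    stop(sprintf("transcript %s: strand must be '+' or '-'", id))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.numeric(exons$start); exons$end <- as.numeric(exons$end)
  if (nrow(exons) < 1L) stop(sprintf("transcript %s: no exons", id))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start))
    stop(sprintf("transcript %s: exon with end <= start", id))
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop(sprintf("transcript %s: overlapping exons", id))
  if (is.null(cds) || nrow(as.data.frame(cds)) == 0L) {
    cds <- data.frame(start = numeric(0), end = numeric(0))
  } else {
    cds <- as.data.frame(cds)[, c("start", "end")]
    cds$start <- as.numeric(cds$start); cds$end <- as.numeric(cds$end)
    cds <- cds[order(cds$start), , drop = FALSE]
    rownames(cds) <- NULL
    if (any(cds$end <= cds$start))
      stop(sprintf("transcript %s: CDS segment with end <= start", id))
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
    }, logical(1))
    if (!all(contained))
      stop(sprintf("transcript %s: CDS outside exons", id))
  }
  structure(list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(exons$start), end = max(exons$end),
                 exons = exons, cds = cds),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s (gene %s) %s:[%g,%g)%s  %d exons, %s\n",
              x$id, x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons),
              if (is_coding(x)) sprintf("CDS %g bp", cds_length(x)) else "non-coding"))
  invisible(x)
}

#' Is a transcript protein-coding?
#' @param tx A `transcript`.
#' @return `TRUE` if the transcript has CDS.
#' @export
is_coding <- function(tx) nrow(tx$cds) > 0L

#' Total CDS length of a transcript in bp
#' @param tx A `transcript`.
#' @return Numeric bp count (0 for non-coding).
#' @export
cds_length <- function(tx) sum(tx$cds$end - tx$cds$start)

#' Construct a gene model set
#'
#' @param transcripts List of `transcript` objects.
#' @return A `gene_model_set`: a named list mapping gene_id to its list of
#'   transcripts.
#' @export
gene_model_set <- function(transcripts) {
  if (length(transcripts) == 0L)
    return(structure(list(), class = "gene_model_set"))
  stopifnot(all(vapply(transcripts, inherits, logical(1), "transcript")))
  gid <- vapply(transcripts, `[[`, character(1), "gene_id")
  structure(split(transcripts, gid), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes, %d transcripts\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Gene spans of a model set
#'
#' @param models A `gene_model_set`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (union span over transcripts).
#' @export
gene_spans <- function(models) {
  if (length(models) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0)))
  rows <- lapply(names(models), function(g) {
    txs <- models[[g]]
    data.frame(gene_id = g, chrom = txs[[1L]]$chrom,
               start = min(vapply(txs, `[[`, numeric(1), "start")),
               end = max(vapply(txs, `[[`, numeric(1), "end")),
               strand = txs[[1L]]$strand)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
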