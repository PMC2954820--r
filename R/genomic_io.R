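#' Read gene models from BED12 or GFF3
#'
#' Parses transcript models into a [gene_model_set()]. BED12 blocks become
#' exons and the thickStart/thickEnd region, clipped to the exons, becomes
#' the CDS. GFF3 exon and CDS features are attached to their transcripts via
#' `Parent` attributes. All coordinates are normalized to 0-based half-open
#' on read (GFF3 input is 1-based closed).
#'
#' For BED12 the `name` field is the transcript id; a name of the form
#' `"geneID|txID"` assigns the transcript to gene `geneID`, otherwise the
#' transcript is its own single-transcript gene.
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` or `"gff3"`.
#' @param chrom_style Chromosome-name normalization passed to
#'   [normalize_chrom()].
#' @return A `gene_model_set`.
#' @export
read_gene_models <- function(path, format = c("bed12", "gff3"),
                             chrom_style = "asis") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  content <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(content) == 0L) {
    warning(sprintf("empty annotation file: %s", path))
    return(gene_model_set(list()))
  }
  if (format == "bed12") {
    .validate_bed12_lines(lines)
    gr <- rtracklayer::import(path, format = "bed")
    txs <- .bed12_to_transcripts(gr, chrom_style)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    txs <- .gff3_to_transcripts(gr, chrom_style)
  }
  gene_model_set(txs)
}

# field-count / numeric pre-check so malformed input fails with a line number
.validate_bed12_lines <- function(lines) {
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || grepl("^(#|track|browser)", ln)) next
    f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(f) < 12L)
      stop(sprintf("BED12 parse error at line %d: %d fields (12 required)",
                   i, length(f)))
    num <- suppressWarnings(as.numeric(f[c(2, 3, 7, 8, 10)]))
    if (anyNA(num))
      stop(sprintf("BED12 parse error at line %d: non-numeric coordinate", i))
  }
  invisible(TRUE)
}

.bed12_to_transcripts <- function(gr, chrom_style) {
  n <- length(gr)
  blocks <- rtracklayer::blocks(gr)  # absolute 1-based exon ranges
  out <- vector("list", n)
  for (i in seq_len(n)) {
    name <- gr$name[i]
    if (is.na(name) || !nzchar(name)) name <- sprintf("tx%d", i)
    parts <- strsplit(name, "|", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) { gid <- parts[1L]; txid <- parts[2L] }
    else { gid <- name; txid <- name }
    ex <- blocks[[i]]
    exons <- data.frame(start = BiocGenerics::start(ex) - 1,
                        end = BiocGenerics::end(ex))
    thick <- gr$thick[i]
    ts <- BiocGenerics::start(thick) - 1
    te <- BiocGenerics::end(thick)
    if (te > ts) {  # zero-width thick = non-coding
      cs <- pmax(exons$start, ts); ce <- pmin(exons$end, te)
      keep <- ce > cs
      cds <- data.frame(start = cs[keep], end = ce[keep])
    } else cds <- NULL
    out[[i]] <- transcript(
      id = txid, gene_id = gid,
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr)[i]),
                              chrom_style),
      strand = as.character(BiocGenerics::strand(gr)[i]),
      exons = exons, cds = cds)
  }
  out
}

.gff3_to_transcripts <- function(gr, chrom_style) {
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[[1L]]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  is_tx <- type %in% c("mRNA", "transcript")
  tx_idx <- which(is_tx)
  if (length(tx_idx) == 0L) stop("GFF3 contains no mRNA/transcript features")
  tx_ids <- id[tx_idx]
  if (anyNA(tx_ids)) stop("GFF3 transcript feature without ID attribute")

  child_parent <- parent[type %in% c("exon", "CDS")]
  orphan <- setdiff(child_parent[!is.na(child_parent)], tx_ids)
  if (anyNA(child_parent) || length(orphan) > 0L)
    stop(sprintf("GFF3 validation error: exon/CDS with absent Parent%s",
                 if (length(orphan)) paste0(" (", paste(orphan, collapse = ", "), ")")
                 else ""))

  out <- vector("list", length(tx_idx))
  for (k in seq_along(tx_idx)) {
    i <- tx_idx[k]
    txid <- id[i]
    gid <- if (!is.na(parent[i])) parent[i] else txid
    ex_i <- which(type == "exon" & parent == txid)
    cds_i <- which(type == "CDS" & parent == txid)
    if (length(ex_i) == 0L)
      stop(sprintf("GFF3 transcript %s has no exons", txid))
    exons <- data.frame(start = BiocGenerics::start(gr)[ex_i] - 1,
                        end = BiocGenerics::end(gr)[ex_i])
    cds <- if (length(cds_i))
      data.frame(start = BiocGenerics::start(gr)[cds_i] - 1,
                 end = BiocGenerics::end(gr)[cds_i]) else NULL
    out[[k]] <- transcript(
      id = txid, gene_id = gid,
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr)[i]),
                              chrom_style),
      strand = as.character(BiocGenerics::strand(gr)[i]),
      exons = exons, cds = cds)
  }
  out
}

#' Write gene models as BED12
#'
#' Inverse of [read_gene_models()] for the BED12 dialect; `name` is written
#' as `"geneID|txID"` when the gene id differs from the transcript id.
#'
#' @param models A `gene_model_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gene_models_bed12 <- function(models, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (g in names(models)) for (tx in models[[g]]) {
    ex <- tx$exons
    if (nrow(tx$cds)) { ts <- min(tx$cds$start); te <- max(tx$cds$end) }
    else { ts <- tx$start; te <- tx$start }
    name <- if (identical(tx$gene_id, tx$id)) tx$id
            else paste(tx$gene_id, tx$id, sep = "|")
    writeLines(paste(tx$chrom, format(tx$start, scientific = FALSE),
                     format(tx$end, scientific = FALSE), name, 0, tx$strand,
                     format(ts, scientific = FALSE),
                     format(te, scientific = FALSE), 0, nrow(ex),
                     paste0(paste(ex$end - ex$start, collapse = ","), ","),
                     paste0(paste(ex$start - tx$start, collapse = ","), ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read deletion CNV calls
#'
#' Expects a BED-like TSV with columns chrom, start, end, sample_id (an
#' optional header line is detected and skipped). Duplicate
#' (sample, interval) rows collapse to one call. Only deletions are modeled.
#'
#' @param path Path to the CNV file.
#' @param chrom_style Passed to [normalize_chrom()].
#' @return data.frame of class `cnv_set` with columns `chrom`, `start`,
#'   `end`, `sample_id`.
#' @export
read_cnvs <- function(path, chrom_style = "asis") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 4L)
    stop("CNV file format error: 4 columns required (chrom, start, end, sample_id)")
  if (is.na(suppressWarnings(as.numeric(raw[1, 2]))))
    raw <- raw[-1, , drop = FALSE]  # header line
  cnvs <- data.frame(chrom = normalize_chrom(raw[[1]], chrom_style),
                     start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
                     sample_id = raw[[4]], stringsAsFactors = FALSE)
  if (anyNA(cnvs$start) || anyNA(cnvs$end))
    stop("CNV file format error: non-numeric coordinates")
  bad <- which(cnvs$end <= cnvs$start)
  if (length(bad))
    stop(sprintf("CNV validation error: end <= start in %d row(s), first at data row %d",
                 length(bad), bad[1L]))
  if (any(!nzchar(cnvs$sample_id)))
    stop("CNV validation error: empty sample_id")
  cnvs <- unique(cnvs)
  rownames(cnvs) <- NULL
  class(cnvs) <- c("cnv_set", "data.frame")
  cnvs
}

#' Write per-gene p(HI) scores as BED5
#'
#' One line per scored gene: chrom, start, end, gene_id, p(HI) with 6
#' decimals. Genes without coordinates are skipped, with the skip count
#' reported as a warning.
#'
#' @param phi Named numeric vector of p(HI), or a data.frame with columns
#'   `gene_id` and `phi`.
#' @param spans data.frame of gene coordinates as from [gene_spans()].
#' @param path Output path.
#' @return Invisibly, the number of genes written.
#' @export
write_scores_bed <- function(phi, spans, path) {
  if (is.data.frame(phi)) {
    p <- stats::setNames(phi$phi, phi$gene_id)
  } else p <- phi
  idx <- match(names(p), spans$gene_id)
  miss <- sum(is.na(idx))
  if (miss > 0L)
    warning(sprintf("%d gene(s) without coordinates skipped", miss))
  keep <- which(!is.na(idx))
  con <- file(path, "w"); on.exit(close(con))
  for (k in keep) {
    s <- spans[idx[k], ]
    writeLines(sprintf("%s\t%s\t%s\t%s\t%.6f", s$chrom,
                       format(s$start, scientific = FALSE),
                       format(s$end, scientific = FALSE),
                       names(p)[k], p[[k]]), con)
  }
  invisible(length(keep))
}

#' Read a p(HI) BED5 score table
#'
#' @param path Path to a BED5 file as written by [write_scores_bed()].
#' @return data.frame with `chrom`, `start`, `end`, `gene_id`, `phi`.
#' @export
read_scores_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "gene_id", "phi"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric"))
  raw
}

#' Construct a weighted gene network
#'
#' Undirected, with one stored edge per unordered gene pair. Weights are the
#' log-likelihood scores of functional interaction and must be finite;
#' self-loops are rejected.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @return A `gene_network` object.
#' @export
gene_network <- function(edges) {
  edges <- as.data.frame(edges)
  names(edges)[1:3] <- c("gene_a", "gene_b", "weight")
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight))) stop("network weights must be finite")
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%d duplicate edge(s) collapsed (first weight kept)", sum(dup)))
  }
  out <- data.frame(gene_a = a[!dup], gene_b = b[!dup],
                    weight = edges$weight[!dup], stringsAsFactors = FALSE)
  structure(list(edges = out), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d edges among %d genes\n", nrow(x$edges),
              length(network_genes(x))))
  invisible(x)
}

#' Genes present in a network
#' @param network A `gene_network`.
#' @return Character vector of gene ids with at least one edge.
#' @export
network_genes <- function(network) {
  unique(c(network$edges$gene_a, network$edges$gene_b))
}

#' Read a weighted edge list
#'
#' TSV with three columns: geneA, geneB, log-likelihood weight.
#'
#' @param path Path to the edge-list file.
#' @return A [gene_network()].
#' @export
read_network <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "character", "numeric"),
                           comment.char = "#")
  gene_network(data.frame(gene_a = raw[[1]], gene_b = raw[[2]],
                          weight = raw[[3]]))
}

#' Write a weighted edge list
#' @param network A `gene_network`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !grepl("^#", x)])
}
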