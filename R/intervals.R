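#' Construct a genomic interval
#'
#' All coordinates in hipred are 0-based half-open (BED convention): `start`
#' is the first base included, `end` the first base excluded. GFF3 input is
#' converted on read.
#'
#' @param chrom Chromosome name (non-empty string). Names are compared as
#'   exact strings; see [normalize_chrom()] for optional "chr"-prefix
#'   normalization.
#' @param start 0-based inclusive start (>= 0).
#' @param end 0-based exclusive end (> start).
#' @param strand One of `"+"`, `"-"`, `"."` (unspecified). Deletions are
#'   strandless; transcripts require an explicit strand.
#' @return A `genome_interval` object (a named list).
#' @export
genome_interval <- function(chrom, start, end, strand = ".") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || start < 0) stop("start must be >= 0")
  if (is.na(end) || end <= start)
    stop(sprintf("end (%s) must be > start (%s)", format(end), format(start)))
  if (!strand %in% c("+", "-", ".")) stop("strand must be '+', '-' or '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("%s:[%g,%g)%s\n", x$chrom, x$start, x$end,
              if (x$strand == ".") "" else x$strand))
  invisible(x)
}

#' Width of an interval in bp
#' @param x A `genome_interval`.
#' @return Integer width.
#' @export
interval_width <- function(x) x$end - x$start

# bp overlap between interval [s1,e1) and each row of (s2,e2); vectorized
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Normalize chromosome naming
#'
#' Optionally strips or adds a leading "chr" so that "chr1" and "1" compare
#' equal. Disabled by default: chromosome names are exact strings.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"asis"` (default, no change), `"strip"` (drop leading
#'   "chr"), or `"add"` (ensure leading "chr").
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
         asis  = chrom,
         strip = sub("^chr", "", chrom),
         add   = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)))
}
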