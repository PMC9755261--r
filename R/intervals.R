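#' Genomic interval
#'
#' Constructs a half-open genomic interval. All coordinates inside the
#' package are 0-based half-open (`[start, end)`); GTF input/output converts
#' at the boundary, so a single convention holds everywhere else.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start, `>= 0`.
#' @param end 0-based exclusive end, `>= start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `genomic_interval` with fields `chrom`,
#'   `start`, `end`, `strand`.
#' @examples
#' gi <- genomic_interval("chr1", 10, 20)
#' interval_length(gi)  # 10
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end < start)
    stop("invalid interval: start=", start, " end=", end,
         " (need 0 <= start <= end)")
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) x$end - x$start

#' @rdname genomic_interval
#' @param a,b Two `genomic_interval`s.
#' @return `intervals_overlap()`: `TRUE` iff the two intervals share at
#'   least one base (half-open arithmetic: abutting intervals do not
#'   overlap).
#' @export
intervals_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%s-%s(%s)>\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand))
  invisible(x)
}

#' Transcript model
#'
#' A transcript with its exon structure and Cuffcompare-style class code;
#' the unit flowing through the lncRNA discovery cascade.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param interval `genomic_interval` spanning the whole transcript.
#' @param exons List of `genomic_interval`s; must be non-overlapping,
#'   sorted, within `interval`, and share its chrom/strand.
#' @param class_code Single character relating the transcript to the
#'   reference annotation (`u` intergenic, `x` antisense, `i` intronic,
#'   `o` exonic overlap, `=` exact match, ...).
#' @param source Free-text provenance label.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, interval, exons,
                             class_code = "=", source = "") {
  stopifnot(inherits(interval, "genomic_interval"), length(exons) >= 1L)
  prev_end <- -Inf
  for (ex in exons) {
    stopifnot(inherits(ex, "genomic_interval"))
    if (ex$chrom != interval$chrom || ex$strand != interval$strand)
      stop("exon chrom/strand differs from transcript for ", transcript_id)
    if (ex$start < interval$start || ex$end > interval$end)
      stop("exon outside transcript interval for ", transcript_id)
    if (ex$start < prev_end)
      stop("exons overlap or are unsorted for ", transcript_id)
    prev_end <- ex$end
  }
  if (!(is.character(class_code) && nchar(class_code) == 1L))
    stop("class_code must be a single character")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 interval = interval, exons = exons,
                 class_code = class_code, source = source),
            class = "transcript_model")
}

#' Spliced length of a transcript
#'
#' Sum of exon lengths — the mature transcript length used by the
#' `> 200` bp lncRNA length filter (not the genomic span).
#'
#' @param tx A `transcript_model`.
#' @return Numeric spliced length in bp.
#' @export
spliced_length <- function(tx) {
  sum(vapply(tx$exons, interval_length, numeric(1)))
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s [%s] %s:%s-%s(%s) %d exon(s), %d bp spliced>\n",
              x$transcript_id, x$class_code, x$interval$chrom,
              format(x$interval$start, scientific = FALSE),
              format(x$interval$end, scientific = FALSE),
              x$interval$strand, length(x$exons), spliced_length(x)))
  invisible(x)
}

## GRanges bridge: overlap-heavy operations delegate to GenomicRanges.
intervals_to_granges <- function(intervals) {
  if (length(intervals) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = vapply(intervals, function(x) x$chrom, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(intervals, function(x) x$start, numeric(1)) + 1,
      end = vapply(intervals, function(x) x$end, numeric(1))),
    strand = sub("^\\.$", "*", vapply(intervals, function(x) x$strand,
                                      character(1))))
}

transcripts_to_granges <- function(transcripts) {
  intervals_to_granges(lapply(transcripts, function(tx) tx$interval))
}
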