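#' Keep transcripts with lncRNA-compatible class codes
#'
#' Retains transcripts whose Cuffcompare class code is one of `i`
#' (entirely intronic), `x` (antisense overlap), `u` (intergenic) or `o`
#' (generic exonic overlap) — the codes compatible with non-coding
#' transcripts. Everything else (exact matches, fragments, unknown
#' codes) is silently excluded; input order is preserved.
#'
#' @param transcripts List of [transcript_model()].
#' @return Filtered list of `transcript_model`.
#' @export
filter_class_codes <- function(transcripts) {
  keep <- vapply(transcripts, function(tx) tx$class_code %in% c("i", "x", "u", "o"),
                 logical(1))
  transcripts[keep]
}

#' Keep transcripts expressed in at least two samples
#'
#' A transcript counts as expressed in a sample when its FPKM meets an
#' exon-dependent threshold: 0.5 for multi-exon transcripts, 2.0 for
#' single-exon ones (single-exon models are less reliable, so the bar is
#' higher). Transcripts reaching their threshold in fewer than two
#' samples are dropped. All boundaries are inclusive.
#'
#' @param matrix An [expression_matrix()] covering all transcripts.
#' @param transcripts List of `transcript_model`.
#' @param multi_exon_fpkm,single_exon_fpkm,min_samples Thresholds.
#' @return Filtered list of `transcript_model`.
#' @export
filter_expression <- function(transcripts, matrix,
                              multi_exon_fpkm = 0.5, single_exon_fpkm = 2.0,
                              min_samples = 2L) {
  keep <- vapply(transcripts, function(tx) {
    fpkm <- fpkm_row(matrix, tx$transcript_id)
    thr <- if (length(tx$exons) >= 2L) multi_exon_fpkm else single_exon_fpkm
    sum(fpkm >= thr) >= min_samples
  }, logical(1))
  transcripts[keep]
}

#' Remove transcripts overlapping annotated small RNAs
#'
#' Drops any transcript whose exons share at least one base with a
#' small-RNA annotation interval (snRNA, snoRNA, miRNA, ...). Overlap is
#' strand-agnostic by default, the strictest simple reading of
#' small-RNA contamination removal.
#'
#' @param transcripts List of `transcript_model`.
#' @param small_rnas List of [genomic_interval()].
#' @param ignore_strand Overlap regardless of strand (default `TRUE`).
#' @return Filtered list of `transcript_model`.
#' @export
remove_small_rna_overlaps <- function(transcripts, small_rnas,
                                      ignore_strand = TRUE) {
  if (length(small_rnas) == 0L || length(transcripts) == 0L)
    return(transcripts)
  srna <- intervals_to_granges(small_rnas)
  exon_grl <- lapply(transcripts, function(tx) intervals_to_granges(tx$exons))
  hit <- vapply(exon_grl, function(gr)
    any(GenomicRanges::countOverlaps(gr, srna,
                                     ignore.strand = ignore_strand) > 0),
    logical(1))
  transcripts[!hit]
}

#' Keep transcripts longer than a minimum spliced length
#'
#' Long non-coding RNAs are by definition longer than 200 nt; this
#' filter keeps transcripts whose spliced length (sum of exon lengths)
#' is strictly greater than `min_exclusive`.
#'
#' @param transcripts List of `transcript_model`.
#' @param min_exclusive Exclusive lower bound in bp (default 200).
#' @return Filtered list of `transcript_model`.
#' @export
filter_length <- function(transcripts, min_exclusive = 200) {
  keep <- vapply(transcripts, function(tx) spliced_length(tx) > min_exclusive,
                 logical(1))
  transcripts[keep]
}

#' Coding-potential evidence record
#'
#' Per-transcript verdicts of three independent coding filters: a
#' coding-potential classifier (CPC-style), a protein-domain search
#' (Pfam-style) and a protein-database hit (SwissProt-style). The
#' verdicts are consumed as input; the engines themselves are external.
#'
#' @param transcript_id Identifier.
#' @param cpc_coding `TRUE` if classified as coding.
#' @param pfam_hit,swissprot_hit `TRUE` if a protein domain / database
#'   hit was found.
#' @param heuristic `TRUE` when produced by [orf_heuristic_evidence()].
#' @return An object of class `coding_evidence`.
#' @export
coding_evidence <- function(transcript_id, cpc_coding, pfam_hit,
                            swissprot_hit, heuristic = FALSE) {
  structure(list(transcript_id = transcript_id,
                 cpc_coding = isTRUE(cpc_coding),
                 pfam_hit = isTRUE(pfam_hit),
                 swissprot_hit = isTRUE(swissprot_hit),
                 heuristic = isTRUE(heuristic)),
            class = "coding_evidence")
}

#' Keep transcripts that all three coding filters call non-coding
#'
#' A transcript survives iff it is non-coding by the classifier AND has
#' no protein-domain hit AND no protein-database hit — the intersection
#' of the three non-coding sets.
#'
#' @param transcripts List of `transcript_model`.
#' @param evidence List of [coding_evidence()] covering all transcripts.
#' @return Filtered list of `transcript_model`, order preserved.
#' @export
filter_coding_potential <- function(transcripts, evidence) {
  ev <- setNames(evidence,
                 vapply(evidence, function(e) e$transcript_id, character(1)))
  keep <- vapply(transcripts, function(tx) {
    e <- ev[[tx$transcript_id]]
    if (is.null(e)) stop("no coding evidence for transcript ",
                         tx$transcript_id)
    !e$cpc_coding && !e$pfam_hit && !e$swissprot_hit
  }, logical(1))
  transcripts[keep]
}

#' Built-in ORF-length stand-in for coding-potential evidence
#'
#' Classifies a transcript as coding when its spliced sequence (forward
#' strand of the transcript) contains an open reading frame of at least
#' `min_codons` codons in any of the three frames: an uninterrupted
#' ATG..stop stretch. This is a deliberately simple heuristic so the
#' discovery cascade can run without external coding-potential engines;
#' records are flagged `heuristic`. Domain/database hits are reported as
#' absent.
#'
#' @param transcripts List of `transcript_model`.
#' @param genome Named character vector of chromosome sequences.
#' @param min_codons Minimum ORF length in codons, including the start
#'   codon but not the stop (default 100).
#' @return List of [coding_evidence()].
#' @export
orf_heuristic_evidence <- function(transcripts, genome, min_codons = 100) {
  lapply(transcripts, function(tx) {
    seqs <- vapply(tx$exons, function(ex) {
      if (!ex$chrom %in% names(genome))
        stop("chromosome not in genome: ", ex$chrom)
      substr(genome[[ex$chrom]], ex$start + 1, ex$end)
    }, character(1))
    spliced <- paste(seqs, collapse = "")
    if (tx$interval$strand == "-") spliced <- revcomp(spliced)
    coding_evidence(tx$transcript_id,
                    cpc_coding = longest_orf_codons(spliced) >= min_codons,
                    pfam_hit = FALSE, swissprot_hit = FALSE,
                    heuristic = TRUE)
  })
}

# Longest ATG..stop ORF over the three forward frames, in codons
# (start codon counted, stop codon not).
longest_orf_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(0L)
  best <- 0L
  codons_at <- function(frame) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    substring(seq, starts, starts + 2L)
  }
  for (frame in 0:2) {
    if (n - frame < 6L) next
    cod <- codons_at(frame)
    is_start <- cod == "ATG"
    is_stop <- cod %in% c("TAA", "TAG", "TGA")
    open_at <- NA_integer_
    for (i in seq_along(cod)) {
      if (is.na(open_at) && is_start[i]) open_at <- i
      if (!is.na(open_at) && is_stop[i]) {
        best <- max(best, i - open_at)
        open_at <- NA_integer_
      }
    }
  }
  best
}

#' Assign a lncRNA category from the class code
#'
#' Fixed mapping: `u` (intergenic) -> lincRNA, `i` -> intronic,
#' `x` -> antisense, `o` (same-strand exonic overlap) -> sense.
#'
#' @param transcript A `transcript_model` with class code in
#'   `{u, i, x, o}`.
#' @return An object of class `lncrna_annotation` with fields
#'   `transcript` and `category`.
#' @export
classify_lncrna <- function(transcript) {
  map <- c(u = "lincRNA", i = "intronic", x = "antisense", o = "sense")
  category <- unname(map[transcript$class_code])
  if (is.na(category))
    stop("cannot classify class code '", transcript$class_code,
         "' (expected one of u, i, x, o)")
  structure(list(transcript = transcript, category = category),
            class = "lncrna_annotation")
}

#' Run the full lncRNA discovery cascade
#'
#' Applies, in order: class-code selection (which implicitly removes
#' transcripts matching protein-coding models), expression filter
#' (FPKM threshold met in >= 2 samples), small-RNA overlap removal,
#' spliced-length filter (> 200 bp) and the three-way coding-potential
#' intersection; survivors are classified into sense / antisense /
#' intronic / lincRNA.
#'
#' @param transcripts List of `transcript_model`.
#' @param matrix An [expression_matrix()].
#' @param small_rnas List of `genomic_interval` (may be empty).
#' @param evidence List of [coding_evidence()].
#' @param ... Passed to [filter_expression()] / [filter_length()].
#' @return List with `annotations` (list of `lncrna_annotation`) and
#'   `counts` (named integer vector of survivors after each stage,
#'   monotone non-increasing).
#' @export
run_discovery_cascade <- function(transcripts, matrix, small_rnas, evidence,
                                  ...) {
  counts <- c(input = length(transcripts))
  s <- filter_class_codes(transcripts)
  counts["class_code"] <- length(s)
  s <- filter_expression(s, matrix)
  counts["expression"] <- length(s)
  s <- remove_small_rna_overlaps(s, small_rnas)
  counts["small_rna"] <- length(s)
  s <- filter_length(s)
  counts["length"] <- length(s)
  s <- filter_coding_potential(s, evidence)
  counts["coding_potential"] <- length(s)
  list(annotations = lapply(s, classify_lncrna), counts = counts)
}
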