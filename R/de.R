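#' Log2 fold change of salt vs. control mean FPKM
#'
#' `log2((mean salt + eps) / (mean control + eps))` within one genotype.
#' The pseudocount keeps zero-expression transcripts finite; with both
#' means zero the fold change is exactly 0.
#'
#' @param matrix An [expression_matrix()].
#' @param transcript_id Transcript to evaluate.
#' @param genotype Genotype whose samples are used.
#' @param eps Pseudocount added to both means (default 0.01).
#' @return Numeric log2 fold change.
#' @export
compute_log2fc <- function(matrix, transcript_id, genotype, eps = 0.01) {
  fpkm <- fpkm_row(matrix, transcript_id)
  sm <- matrix$samples
  salt <- fpkm[sm$genotype == genotype & sm$condition == "salt"]
  ctrl <- fpkm[sm$genotype == genotype & sm$condition == "control"]
  if (length(salt) < 1L || length(ctrl) < 1L)
    stop("need at least one salt and one control sample for ", genotype)
  log2((mean(salt) + eps) / (mean(ctrl) + eps))
}

#' Call differential-expression direction
#'
#' A transcript is up-regulated iff `log2fc >= lfc_threshold` and
#' `qvalue <= q_threshold`, down-regulated iff
#' `log2fc <= -lfc_threshold` under the same q cut-off, otherwise
#' `none`. All boundaries inclusive. Vectorised over `log2fc`/`qvalue`.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param qvalue Numeric vector of adjusted p-values in `[0, 1]`.
#' @param lfc_threshold,q_threshold Cut-offs (defaults 1 and 0.05).
#' @return Character vector over `{"up", "down", "none"}`.
#' @export
call_de <- function(log2fc, qvalue, lfc_threshold = 1, q_threshold = 0.05) {
  stopifnot(length(log2fc) == length(qvalue),
            all(qvalue >= 0 & qvalue <= 1))
  ifelse(qvalue <= q_threshold & log2fc >= lfc_threshold, "up",
         ifelse(qvalue <= q_threshold & log2fc <= -lfc_threshold, "down",
                "none"))
}

#' Tally up- and down-regulated calls
#'
#' @param directions Character vector of direction labels from
#'   [call_de()].
#' @return Named integer vector `c(up = , down = )`.
#' @export
count_directions <- function(directions) {
  c(up = sum(directions == "up"), down = sum(directions == "down"))
}

#' Loci shared between two DE-lncRNA sets
#'
#' Finds all pairs of intervals, one from each set, with the same
#' chromosome and at least 1 bp overlap — e.g. DE-lncRNAs detected at
#' the same locus in two genotypes.
#'
#' @param list_a,list_b Lists of [genomic_interval()] (may carry names).
#' @return `data.frame` with columns `a` and `b` (indices into the two
#'   lists) and `a_name`/`b_name` when the lists are named; zero rows if
#'   nothing overlaps.
#' @export
shared_loci <- function(list_a, list_b) {
  if (length(list_a) == 0L || length(list_b) == 0L)
    return(data.frame(a = integer(0), b = integer(0)))
  gra <- intervals_to_granges(list_a)
  grb <- intervals_to_granges(list_b)
  # the two sets may legitimately cover different chromosomes
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb, ignore.strand = TRUE))
  out <- data.frame(a = S4Vectors::queryHits(ov),
                    b = S4Vectors::subjectHits(ov))
  if (!is.null(names(list_a))) out$a_name <- names(list_a)[out$a]
  if (!is.null(names(list_b))) out$b_name <- names(list_b)[out$b]
  out
}

#' Count distinct loci across genotypes
#'
#' Merges overlapping intervals from both sets (strand-agnostic) and
#' counts the merged loci, so a locus detected in both genotypes counts
#' once.
#'
#' @param list_a,list_b Lists of `genomic_interval`.
#' @return Integer count of distinct merged loci.
#' @export
count_distinct_loci <- function(list_a, list_b) {
  gr <- suppressWarnings(
    c(intervals_to_granges(list_a), intervals_to_granges(list_b)))
  if (length(gr) == 0L) return(0L)
  length(GenomicRanges::reduce(gr, ignore.strand = TRUE))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)`; relative expression is
#' `2^-ddCt`. Equal target/reference behaviour across conditions gives
#' exactly 1.
#'
#' @param ct_target_treated,ct_ref_treated Ct of target and reference
#'   gene under treatment.
#' @param ct_target_control,ct_ref_control Ct under control.
#' @return Positive relative-expression ratio.
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-dd)
}

#' Differential-expression table for one genotype
#'
#' Computes log2 fold changes for every transcript and joins q-values.
#' The upstream DE test's q-values are consumed as input; when `stats`
#' is `NULL`, a clearly-labelled stand-in is used instead: Welch t-test
#' on `log2(FPKM + eps)` across conditions with Benjamini-Hochberg
#' correction (attribute `qvalue_source = "welch_bh_standin"`).
#'
#' @param matrix An [expression_matrix()].
#' @param genotype Genotype to contrast (salt vs. control).
#' @param stats Optional `data.frame` with columns `transcript_id`,
#'   `qvalue`.
#' @param eps Pseudocount (default 0.01).
#' @inheritParams call_de
#' @return `data.frame` with columns `transcript_id`, `log2fc`,
#'   `qvalue`, `direction`.
#' @export
de_table <- function(matrix, genotype, stats = NULL,
                     lfc_threshold = 1, q_threshold = 0.05, eps = 0.01) {
  ids <- rownames(matrix$values)
  lfc <- vapply(ids, function(id)
    compute_log2fc(matrix, id, genotype, eps = eps), numeric(1))
  if (is.null(stats)) {
    sm <- matrix$samples
    sel <- sm$genotype == genotype
    cond <- sm$condition[sel]
    lv <- log2(matrix$values[, sel, drop = FALSE] + eps)
    pv <- apply(lv, 1, function(v) {
      a <- v[cond == "salt"]; b <- v[cond == "control"]
      if (sd(a) == 0 && sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      tryCatch(t.test(a, b)$p.value, error = function(e) 1)
    })
    qv <- p.adjust(pv, method = "BH")
    source <- "welch_bh_standin"
  } else {
    qv <- setNames(stats$qvalue, stats$transcript_id)[ids]
    if (any(is.na(qv))) stop("stats table missing q-values for some transcripts")
    source <- "supplied"
  }
  out <- data.frame(transcript_id = ids, log2fc = unname(lfc),
                    qvalue = unname(qv),
                    direction = call_de(unname(lfc), unname(qv),
                                        lfc_threshold, q_threshold),
                    stringsAsFactors = FALSE)
  attr(out, "qvalue_source") <- source
  out
}
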