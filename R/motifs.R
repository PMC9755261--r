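# Per-position log2-odds score matrix for a PWM (positions x ACGT),
# with a probability floor applied before the log so scores stay finite.
pwm_score_matrix <- function(pwm, floor = 1e-4) {
  p <- pmax(pwm$matrix, floor)
  bg <- matrix(pwm$background, nrow(pwm$matrix), 4, byrow = TRUE)
  log2(p / bg)
}

#' Log-odds score of a word against a PWM
#'
#' Sum over positions of `log2(p_position(base) / background(base))`,
#' with motif probabilities floored at `floor` before the log. An `N`
#' contributes 0 (the background-expected score).
#'
#' @param pwm A [pwm_motif()].
#' @param word Character string over `{A,C,G,T,N}` of motif length.
#' @param floor Probability floor (default 1e-4).
#' @return Numeric log2-odds score.
#' @export
log_odds <- function(pwm, word, floor = 1e-4) {
  m <- nrow(pwm$matrix)
  if (nchar(word) != m) stop("word length must equal motif length")
  sm <- pwm_score_matrix(pwm, floor)
  idx <- match(chars(word), c("A", "C", "G", "T"))
  contrib <- sm[cbind(seq_len(m), idx)]
  sum(contrib[!is.na(idx)])
}

# Discretized null distribution of the log-odds score under iid
# background: integer-bin pmf built by per-position convolution.
# Returns list(offset = first bin index, pmf = numeric vector).
pwm_score_distribution <- function(pwm, granularity = 1e-3, floor = 1e-4) {
  sm <- pwm_score_matrix(pwm, floor)
  bins <- round(sm / granularity)
  bg <- pwm$background
  offset <- 0L
  pmf <- 1
  for (j in seq_len(nrow(bins))) {
    bj <- bins[j, ]
    lo <- min(bj); hi <- max(bj)
    new <- numeric(length(pmf) + (hi - lo))
    for (b in 1:4) {
      sh <- bj[b] - lo
      idx <- seq_along(pmf) + sh
      new[idx] <- new[idx] + pmf * bg[b]
    }
    pmf <- new
    offset <- offset + lo
  }
  list(offset = offset, pmf = pmf, granularity = granularity)
}

#' Exact p-value of a PWM score
#'
#' Tail probability, under iid background, of a single position/strand
#' achieving a log-odds score at least as high as `score`. Computed by
#' exact dynamic programming over discretized per-position score
#' histograms (bin width `granularity`); matches exhaustive word
#' enumeration up to the discretization.
#'
#' @param pwm A [pwm_motif()].
#' @param score Observed log2-odds score.
#' @param granularity Discretization bin in log-odds units (default
#'   1e-3).
#' @param floor Probability floor (default 1e-4).
#' @return p-value in `(0, 1]`, monotone non-increasing in `score`.
#' @export
score_pvalue <- function(pwm, score, granularity = 1e-3, floor = 1e-4) {
  dist <- pwm_score_distribution(pwm, granularity, floor)
  score_pvalue_from_dist(dist, score)
}

score_pvalue_from_dist <- function(dist, score) {
  b <- round(score / dist$granularity)
  top <- dist$offset + length(dist$pmf) - 1L
  if (b <= dist$offset) return(1)
  b <- min(b, top)                      # above-maximum scores get the top bin
  sum(dist$pmf[(b - dist$offset + 1L):length(dist$pmf)])
}

#' Scan a sequence for PWM hits with exact p-values
#'
#' Scores every position on the requested strands and reports hits whose
#' per-position/per-strand p-value is at or below `p_threshold` (no
#' multiple-testing across positions, FIMO-style). Minus-strand windows
#' are scored on the reverse complement and reported in plus-strand
#' coordinates. By default the background is the scanned sequence's own
#' base composition.
#'
#' @param sequence Character string over `{A,C,G,T,N}`.
#' @param pwm A [pwm_motif()].
#' @param p_threshold Hit threshold (default 1e-10).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param background `"sequence"` (composition of `sequence`),
#'   `"motif"` (use `pwm$background`), or a length-4 probability vector.
#' @param granularity,floor See [score_pvalue()].
#' @param chrom,origin Chromosome name and 0-based genomic position of
#'   `sequence[1]`, used to place hit intervals (defaults `"seq"`, 0).
#' @return `data.frame` with columns `motif_id`, `chrom`, `start`,
#'   `end`, `strand`, `score`, `pvalue` (0-based half-open coordinates).
#' @export
scan_sequence <- function(sequence, pwm, p_threshold = 1e-10,
                          strands = "both", background = "sequence",
                          granularity = 1e-3, floor = 1e-4,
                          chrom = "seq", origin = 0) {
  m <- nrow(pwm$matrix)
  n <- nchar(sequence)
  if (n < m) stop("sequence shorter than motif")
  bg <- if (identical(background, "sequence")) {
    counts <- vapply(BASES, function(b)
      sum(chars(sequence) == b), numeric(1))
    comp <- pmax(counts, 1) / sum(pmax(counts, 1))
    comp / sum(comp)
  } else if (identical(background, "motif")) {
    pwm$background
  } else {
    as.numeric(background)
  }
  pwm_bg <- pwm_motif(pwm$motif_id, pwm$matrix, bg)
  dist <- pwm_score_distribution(pwm_bg, granularity, floor)
  sm <- pwm_score_matrix(pwm_bg, floor)

  scan_one <- function(seq, strand) {
    base_idx <- match(chars(seq), BASES)
    npos <- nchar(seq) - m + 1L
    scores <- numeric(npos)
    for (j in seq_len(m)) {
      contrib <- sm[j, base_idx[j:(j + npos - 1L)]]
      contrib[is.na(contrib)] <- 0
      scores <- scores + contrib
    }
    pv <- vapply(scores, function(s) score_pvalue_from_dist(dist, s),
                 numeric(1))
    hit <- which(pv <= p_threshold)
    if (length(hit) == 0L)
      return(NULL)
    start_rel <- if (strand == "+") hit - 1L else nchar(seq) - (hit - 1L) - m
    data.frame(motif_id = pwm$motif_id, chrom = chrom,
               start = origin + start_rel, end = origin + start_rel + m,
               strand = strand, score = scores[hit], pvalue = pv[hit],
               stringsAsFactors = FALSE)
  }

  out <- list()
  if (strands %in% c("both", "+")) out <- c(out, list(scan_one(sequence, "+")))
  if (strands %in% c("both", "-"))
    out <- c(out, list(scan_one(revcomp(sequence), "-")))
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(motif_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Motif hits overlapping significance peaks
#'
#' Keeps hits whose interval shares at least one base with any peak
#' (half-open arithmetic: a hit abutting a peak end is excluded).
#'
#' @param hits `data.frame` from [scan_sequence()].
#' @param peaks List of [genomic_interval()] in the same coordinate
#'   frame.
#' @return Subset of `hits`.
#' @export
hits_in_peaks <- function(hits, peaks) {
  if (nrow(hits) == 0L || length(peaks) == 0L)
    return(hits[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    hi <- genomic_interval(hits$chrom[i], hits$start[i], hits$end[i])
    any(vapply(peaks, intervals_overlap, logical(1), b = hi))
  }, logical(1))
  hits[keep, , drop = FALSE]
}
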