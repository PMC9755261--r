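#' Extract a fixed-length sequence window centered on a TSS
#'
#' Returns exactly `length` bases with the TSS at index
#' `floor(length / 2)` (0-based); positions beyond the chromosome ends
#' are filled with `N`. For minus-strand TSSs the plus-strand extraction
#' is reverse-complemented.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,position,strand TSS location (0-based position).
#' @param length Window length in bp.
#' @return Character string of `length` bases.
#' @export
extract_tss_window <- function(genome, chrom, position, strand = "+",
                               length = 196698) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  seq <- genome[[chrom]]
  n <- nchar(seq)
  start <- position - floor(length / 2)
  end <- start + length                     # half-open
  left_pad <- max(0, -start)
  right_pad <- max(0, end - n)
  core <- substr(seq, max(0, start) + 1, min(n, end))
  out <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  stopifnot(nchar(out) == length)
  if (strand == "-") out <- revcomp(out)
  out
}

#' Make a predictor object
#'
#' A predictor is the plug-in contract of the mutagenesis engine: a
#' deterministic function from a fixed-length sequence window to a
#' bounded scalar accessibility score at the window's TSS (center).
#'
#' @param predict Function taking one character string of
#'   `window_length` bases, returning a scalar.
#' @param window_length Required input length `L_in`.
#' @return An object of class `predictor`.
#' @seealso [toy_predictor()] for the built-in motif-based
#'   implementation.
#' @export
predictor <- function(predict, window_length) {
  stopifnot(is.function(predict), window_length >= 1)
  structure(list(predict = predict, window_length = as.integer(window_length)),
            class = "predictor")
}

predict_score <- function(pred, sequence) {
  if (nchar(sequence) != pred$window_length)
    stop("predictor expects windows of length ", pred$window_length,
         ", got ", nchar(sequence))
  pred$predict(sequence)
}

#' In-silico mutagenesis scan over a sequence
#'
#' Slides a window of `window` nucleotides across the sequence in steps
#' of `stride`; at each offset the window contents are swapped with one
#' seeded draw of uniform-random nucleotides and the score is
#' `ISMS = |f(modified) - f(reference)|`, where `f` is the predictor's
#' accessibility score at the TSS. Each offset's random draw is derived
#' from `(seed, offset)`, so changing the stride leaves the per-offset
#' draws unchanged (a stride-`s` profile is the stride-1 profile
#' subsampled). z-scores standardize the profile by its own mean/SD.
#'
#' @param sequence Character string of exactly the predictor's window
#'   length.
#' @param predictor A [predictor()].
#' @param window Swap-window size in nt (default 1000).
#' @param stride Step size in nt (default 1).
#' @param seed Integer seed.
#' @param replicates Random replacements averaged per offset
#'   (default 1).
#' @return An object of class `isms_profile`: list with `positions`
#'   (0-based window start offsets), `scores`, `reference_score`, `z`,
#'   `window`, `stride`, `seed`.
#' @export
isms_scan <- function(sequence, predictor, window = 1000, stride = 1,
                      seed = 1, replicates = 1) {
  n <- nchar(sequence)
  if (n != predictor$window_length)
    stop("sequence length ", n, " does not match predictor window_length ",
         predictor$window_length)
  if (window > n) stop("swap window larger than sequence")
  reference <- predict_score(predictor, sequence)
  offsets <- seq.int(0L, n - window, by = stride)
  scores <- vapply(offsets, function(off) {
    reps <- vapply(seq_len(replicates), function(r) {
      repl <- with_seed(derive_seed(derive_seed(seed, off), r),
                       random_dna(window))
      modified <- paste0(substr(sequence, 1, off),
                         repl,
                         substr(sequence, off + window + 1, n))
      abs(predict_score(predictor, modified) - reference)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  mu <- mean(scores)
  sdv <- sd(scores)
  z <- if (is.na(sdv) || sdv == 0) rep(NA_real_, length(scores))
       else (scores - mu) / sdv
  structure(list(positions = offsets, scores = scores,
                 reference_score = reference, z = z,
                 window = window, stride = stride, seed = seed),
            class = "isms_profile")
}

#' Call significant peaks in an ISMS profile
#'
#' Offsets whose z-score is at or above `z_threshold` are peak
#' positions; consecutive peak offsets (one stride apart) merge into
#' maximal runs, reported as half-open intervals in window-offset
#' coordinates. High scores mark the disruptive windows; a profile with
#' zero spread yields no peaks (with a warning).
#'
#' @param profile An `isms_profile` from [isms_scan()].
#' @param z_threshold Peak threshold on the z-score (default 3).
#' @return `data.frame` with columns `start`, `end` (offset
#'   coordinates), `max_z`.
#' @export
call_isms_peaks <- function(profile, z_threshold = 3) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      max_z = numeric(0))
  if (all(is.na(profile$z))) {
    warning("profile has zero spread; no peaks called")
    return(empty)
  }
  hot <- which(profile$z >= z_threshold)
  if (length(hot) == 0L) return(empty)
  runs <- split(hot, cumsum(c(1, diff(hot) != 1)))
  do.call(rbind, lapply(runs, function(idx) {
    data.frame(start = profile$positions[idx[1]],
               end = profile$positions[idx[length(idx)]] + profile$stride,
               max_z = max(profile$z[idx]))
  }))
}

#' Single-base saturation mutagenesis
#'
#' For every position in `region`, substitutes each of the three
#' alternative bases and records `f(mut) - f(ref)`; the per-position
#' maximum is the gain score and the minimum the loss score (both
#' signed, so `gain >= loss` always). Exhaustive and deterministic.
#'
#' @param sequence Character string of the predictor's window length.
#' @param predictor A [predictor()].
#' @param region [genomic_interval()]-like list with `start`/`end`
#'   offsets into `sequence` (0-based half-open), or a length-2 numeric
#'   vector `c(start, end)`.
#' @return `data.frame` with columns `position` (0-based offset),
#'   `ref_base`, `gain`, `loss`.
#' @export
single_base_mutagenesis <- function(sequence, predictor, region) {
  if (is.numeric(region)) region <- list(start = region[1], end = region[2])
  n <- nchar(sequence)
  if (region$start < 0 || region$end > n || region$end <= region$start)
    stop("region out of sequence bounds")
  reference <- predict_score(predictor, sequence)
  rows <- lapply(seq.int(region$start, region$end - 1), function(pos) {
    ref_base <- substr(sequence, pos + 1, pos + 1)
    deltas <- vapply(setdiff(BASES, ref_base), function(b) {
      mut <- sequence
      substr(mut, pos + 1, pos + 1) <- b
      predict_score(predictor, mut) - reference
    }, numeric(1))
    data.frame(position = pos, ref_base = ref_base,
               gain = max(deltas), loss = min(deltas),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate features intersecting a genomic window
#'
#' Collects all genes, transcription factors and lncRNAs that intersect
#' a report window, labels each by role, and clips features spanning
#' the window edge (flagged `clipped`). Used to draw the neighborhood
#' track around a mutagenesis profile.
#'
#' @param genes,tfs,lncrnas Named lists of [genomic_interval()].
#' @param window A `genomic_interval` to report on.
#' @return `data.frame` with columns `feature_id`, `role`, `start`,
#'   `end`, `clipped`.
#' @export
annotate_window <- function(genes = list(), tfs = list(), lncrnas = list(),
                            window) {
  collect <- function(features, role) {
    ids <- names(features)
    if (is.null(ids)) ids <- paste0(role, seq_along(features))
    rows <- lapply(seq_along(features), function(i) {
      f <- features[[i]]
      if (!intervals_overlap(f, window)) return(NULL)
      cs <- max(f$start, window$start)
      ce <- min(f$end, window$end)
      data.frame(feature_id = ids[i], role = role, start = cs, end = ce,
                 clipped = (cs != f$start || ce != f$end),
                 stringsAsFactors = FALSE)
    })
    rows[!vapply(rows, is.null, logical(1))]
  }
  rows <- c(collect(genes, "gene"), collect(tfs, "tf"),
            collect(lncrnas, "lncrna"))
  if (length(rows) == 0L)
    return(data.frame(feature_id = character(0), role = character(0),
                      start = numeric(0), end = numeric(0),
                      clipped = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}
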