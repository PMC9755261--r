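# Pair penalty between a miRNA base and a target-site base (both given
# as DNA, T for U): Watson-Crick 0, G:U wobble 0.5, mismatch 1.
pair_penalty <- function(mi, site) {
  wc <- (mi == "A" && site == "T") || (mi == "T" && site == "A") ||
    (mi == "C" && site == "G") || (mi == "G" && site == "C")
  if (wc) return(c(0, 0))                       # penalty, mismatch flag
  gu <- (mi == "G" && site == "T") || (mi == "T" && site == "G")
  if (gu) return(c(0.5, 0))
  c(1, 1)
}

# x2 multiplier at miRNA seed positions 2-13 (1-based from the 5' end).
seed_mult <- function(pos, seed_from = 2, seed_to = 13) {
  if (pos >= seed_from && pos <= seed_to) 2 else 1
}

normalize_rna <- function(seq) {
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  if (grepl("[^ACGT]", seq)) stop("non-nucleotide characters in sequence")
  seq
}

# Banded global alignment of a miRNA (5'->3') against the reverse of a
# candidate site (antiparallel pairing). Returns the DP matrix plus the
# inputs needed for traceback. Band allows at most `band` unpaired
# bases on either strand.
duplex_dp <- function(mi_chars, site_rev_chars, band = 2,
                      gap_penalty = 2, seed_from = 2, seed_to = 13) {
  m <- length(mi_chars); n <- length(site_rev_chars)
  D <- matrix(Inf, m + 1, n + 1)
  D[1, 1] <- 0
  for (j in seq_len(min(n, band)))
    D[1, j + 1] <- D[1, j] + gap_penalty * seed_mult(1, seed_from, seed_to)
  for (i in seq_len(m)) {
    mult_i <- seed_mult(i, seed_from, seed_to)
    jlo <- max(0, i - band); jhi <- min(n, i + band)
    for (j in jlo:jhi) {
      if (j == 0) {
        D[i + 1, 1] <- D[i, 1] + gap_penalty * mult_i
        next
      }
      best <- Inf
      if (abs(i - j) <= band) {
        pp <- pair_penalty(mi_chars[i], site_rev_chars[j])
        best <- min(best, D[i, j] + pp[1] * mult_i)
      }
      if (abs((i - 1) - j) <= band)              # gap in site, consume miRNA i
        best <- min(best, D[i, j + 1] + gap_penalty * mult_i)
      if (abs(i - (j - 1)) <= band) {            # gap in miRNA, consume site j
        mult_next <- seed_mult(min(i + 1, m), seed_from, seed_to)
        best <- min(best, D[i + 1, j] + gap_penalty * mult_next)
      }
      D[i + 1, j + 1] <- best
    }
  }
  D
}

# Traceback for the alignment string and mismatch count at end cell
# (m, n). Ties resolve pair > miRNA-gap > site-gap.
duplex_traceback <- function(D, mi_chars, site_rev_chars, band = 2,
                             gap_penalty = 2, seed_from = 2, seed_to = 13) {
  i <- length(mi_chars); j <- length(site_rev_chars)
  aln <- character(0)
  mismatches <- 0L
  while (i > 0 || j > 0) {
    here <- D[i + 1, j + 1]
    if (i > 0 && j > 0) {
      pp <- pair_penalty(mi_chars[i], site_rev_chars[j])
      step <- pp[1] * seed_mult(i, seed_from, seed_to)
      if (isTRUE(all.equal(D[i, j] + step, here))) {
        aln <- c(if (pp[1] == 0) "|" else if (pp[1] == 0.5) "o" else ".", aln)
        if (pp[2] == 1) mismatches <- mismatches + 1L
        i <- i - 1; j <- j - 1
        next
      }
    }
    if (i > 0 &&
        isTRUE(all.equal(D[i, j + 1] +
                           gap_penalty * seed_mult(i, seed_from, seed_to),
                         here))) {
      aln <- c("-", aln); i <- i - 1
      next
    }
    if (j > 0) {
      mult_next <- seed_mult(min(i + 1, length(mi_chars)),
                             seed_from, seed_to)
      if (isTRUE(all.equal(D[i + 1, j] + gap_penalty * mult_next, here))) {
        aln <- c("-", aln); j <- j - 1
        next
      }
    }
    stop("traceback failed")    # nocov
  }
  list(alignment = paste(aln, collapse = ""), n_mismatches = mismatches)
}

#' Score a miRNA / target-site duplex
#'
#' Best antiparallel pairing of a miRNA (5'->3') against a candidate
#' lncRNA site by banded global alignment (at most 2 unpaired bases per
#' strand). Penalties: Watson-Crick pair 0, G:U wobble 0.5, mismatch
#' 1.0, gap 2.0; all penalties double at miRNA seed positions 2-13.
#' The total penalty is the expectation score (0 = perfect
#' complementarity); G:U wobbles are scored but not counted as
#' mismatches.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param site Target-site subsequence of the lncRNA, 5'->3'; length
#'   within 2 nt of the miRNA length.
#' @return An object of class `mirna_duplex`: list with `expectation`,
#'   `n_mismatches`, `alignment` (one char per alignment column: `|`
#'   pair, `o` G:U, `.` mismatch, `-` gap), `mirna`, `site`.
#' @export
duplex_score <- function(mirna, site) {
  mirna <- normalize_rna(mirna); site <- normalize_rna(site)
  m <- nchar(mirna); n <- nchar(site)
  if (n < m - 2 || n > m + 2)
    stop("site length must be within 2 nt of the miRNA length")
  mi <- chars(mirna)
  sr <- rev(chars(site))
  D <- duplex_dp(mi, sr)
  tb <- duplex_traceback(D, mi, sr)
  structure(list(expectation = D[m + 1, n + 1],
                 n_mismatches = tb$n_mismatches,
                 alignment = tb$alignment, mirna = mirna, site = site),
            class = "mirna_duplex")
}

#' @export
print.mirna_duplex <- function(x, ...) {
  cat(sprintf("<mirna_duplex expectation=%.1f mismatches=%d %s>\n",
              x$expectation, x$n_mismatches, x$alignment))
  invisible(x)
}

# Expectation scores for all candidate sites of one miRNA along one
# lncRNA, vectorised across site positions. The scalar duplex DP aligns
# the miRNA against the reversed site, anchored at the site's 3' end;
# here the same DP runs once per miRNA with the site 3'-end position as
# the vectorised dimension, so every cell, band constraint and seed
# multiplier matches duplex_score exactly. Varying the end cell's site
# length yields the five banded site lengths per start offset.
# Returns a matrix [offset + 1, site length m-2..m+2] (Inf where a
# site does not fit).
screen_expectations <- function(mirna, lnc, band = 2, gap_penalty = 2,
                                seed_from = 2, seed_to = 13) {
  m <- nchar(mirna); L <- nchar(lnc)
  code <- function(s) match(chars(s), BASES)
  P <- matrix(1, 4, 4)
  P[1, 4] <- 0; P[4, 1] <- 0; P[2, 3] <- 0; P[3, 2] <- 0   # Watson-Crick
  P[3, 4] <- 0.5; P[4, 3] <- 0.5                           # G:U wobble
  mi <- code(mirna)
  nmax <- m + band
  es <- (m - band):L                    # candidate site 3' ends (1-based)
  n_e <- length(es)
  lcp <- c(rep(NA_integer_, nmax), code(lnc))
  sm <- vapply(1:m, function(i) seed_mult(i, seed_from, seed_to),
               numeric(1))
  gm <- vapply(0:m, function(i)
    seed_mult(min(i + 1, m), seed_from, seed_to), numeric(1))
  prev <- vector("list", nmax + 1)
  prev[[1]] <- rep(0, n_e)
  for (j in 1:nmax)
    prev[[j + 1]] <- if (j <= band)
      prev[[j]] + gap_penalty * gm[1] else rep(Inf, n_e)
  for (i in 1:m) {
    cur <- vector("list", nmax + 1)
    cur[[1]] <- if (i <= band) prev[[1]] + gap_penalty * sm[i]
                else rep(Inf, n_e)
    for (j in 1:nmax) {
      if (abs(i - j) > band) { cur[[j + 1]] <- rep(Inf, n_e); next }
      # reversed site position j at end e reads lnc[e - j + 1]
      sidx <- lcp[nmax + es - j + 1]
      pen <- P[cbind(rep(mi[i], n_e), sidx)]
      pen[is.na(pen)] <- Inf
      v <- prev[[j]] + pen * sm[i]                            # pair
      v <- pmin(v, prev[[j + 1]] + gap_penalty * sm[i])       # site gap
      v <- pmin(v, cur[[j]] + gap_penalty * gm[i + 1])        # miRNA gap
      cur[[j + 1]] <- v
    }
    prev <- cur
  }
  n_off <- L - (m - band) + 1
  out <- matrix(Inf, n_off, 2 * band + 1)
  for (nk in seq_len(2 * band + 1)) {
    n <- m - band + nk - 1
    off <- es - n                       # 0-based site starts
    valid <- off >= 0 & off <= n_off - 1
    out[off[valid] + 1, nk] <- prev[[n + 1]][valid]
  }
  out
}

#' Screen lncRNAs for miRNA target-mimicry sites
#'
#' Slides each miRNA along each lncRNA, scoring candidate sites of all
#' banded lengths at every offset with [duplex_score()], and reports
#' sites with `expectation <= max_expectation` and
#' `n_mismatches <= max_mismatches` (the classic "maximum expectation
#' 5, fewer than four mismatches" screen). At each offset only the
#' best-scoring site length is kept; the best site per (miRNA, lncRNA)
#' pair is flagged.
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param lncrnas Named character vector of lncRNA sequences.
#' @param max_expectation Maximum expectation score (default 5).
#' @param max_mismatches Maximum mismatch count (default 3).
#' @return `data.frame` with columns `mirna_id`, `lncrna_id`, `offset`
#'   (0-based site start), `site_length`, `expectation`,
#'   `n_mismatches`, `alignment`, `is_best`; sorted by miRNA, lncRNA,
#'   offset. Deterministic and independent of input order.
#' @export
screen_mimics <- function(mirnas, lncrnas, max_expectation = 5,
                          max_mismatches = 3) {
  rows <- list()
  for (mid in sort(names(mirnas))) {
    mirna <- normalize_rna(mirnas[[mid]])
    m <- nchar(mirna)
    for (lid in sort(names(lncrnas))) {
      lnc <- normalize_rna(lncrnas[[lid]])
      L <- nchar(lnc)
      if (L < m - 2) next
      exp_mat <- screen_expectations(mirna, lnc)   # offsets x site lengths
      cand <- which(apply(exp_mat, 1, min) <= max_expectation)
      for (ci in cand) {
        off <- ci - 1L
        ns <- (m - 2):(m + 2)
        ok <- which(exp_mat[ci, ] <= max_expectation)
        best <- NULL
        for (nk in ok) {
          n <- ns[nk]
          dup <- duplex_score(mirna, substr(lnc, off + 1, off + n))
          if (dup$n_mismatches > max_mismatches) next
          if (is.null(best) || dup$expectation < best$expectation)
            best <- list(n = n, expectation = dup$expectation,
                         n_mismatches = dup$n_mismatches,
                         alignment = dup$alignment)
        }
        if (!is.null(best))
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = mid, lncrna_id = lid, offset = off,
            site_length = best$n, expectation = best$expectation,
            n_mismatches = best$n_mismatches, alignment = best$alignment,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(mirna_id = character(0), lncrna_id = character(0),
                      offset = numeric(0), site_length = numeric(0),
                      expectation = numeric(0), n_mismatches = integer(0),
                      alignment = character(0), is_best = logical(0)))
  out <- do.call(rbind, rows)
  out$is_best <- FALSE
  for (key in unique(paste(out$mirna_id, out$lncrna_id))) {
    idx <- which(paste(out$mirna_id, out$lncrna_id) == key)
    out$is_best[idx[which.min(out$expectation[idx])]] <- TRUE
  }
  out[order(out$mirna_id, out$lncrna_id, out$offset), , drop = FALSE]
}
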