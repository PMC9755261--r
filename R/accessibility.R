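#' Mean signal over an interval
#'
#' Arithmetic mean of per-base coverage over `[start, end)`.
#'
#' @param track A [coverage_track()].
#' @param interval A [genomic_interval()] within chromosome bounds.
#' @return Numeric mean signal.
#' @export
mean_signal <- function(track, interval) {
  v <- track$values[[interval$chrom]]
  if (is.null(v)) stop("chromosome not in track: ", interval$chrom)
  if (interval$end > length(v) || interval$start < 0)
    stop("interval out of chromosome bounds: ", interval$chrom, ":",
         interval$start, "-", interval$end)
  if (interval_length(interval) == 0) stop("zero-length interval")
  mean(v[(interval$start + 1):interval$end])
}

#' Sample random equal-length null regions
#'
#' Draws `n` intervals of exactly `length` bp with start positions
#' uniform over all valid (chromosome, start) pairs — so chromosomes are
#' weighted by how many placements they can host — rejecting regions
#' that overlap `exclude`. Deterministic for a fixed seed.
#'
#' @param sizes Named numeric vector of chromosome sizes.
#' @param length Region length in bp.
#' @param n Number of regions (default 50).
#' @param seed Integer seed.
#' @param exclude Optional [genomic_interval()] that null regions must
#'   not overlap.
#' @return List of `n` [genomic_interval()].
#' @export
sample_null_regions <- function(sizes, length, n = 50, seed = 1,
                                exclude = NULL) {
  capacity <- pmax(sizes - length + 1, 0)
  if (sum(capacity) == 0)
    stop("no chromosome can host a region of length ", length)
  if (!is.null(exclude)) {
    # a single excluded interval can block at most part of one chromosome;
    # make sure at least one valid placement remains
    blocked <- 0
    if (exclude$chrom %in% names(sizes)) {
      lo <- max(0, exclude$start - length + 1)
      hi <- min(capacity[[exclude$chrom]], exclude$end)
      blocked <- max(0, hi - lo)
    }
    if (sum(capacity) - blocked <= 0)
      stop("exclusion leaves no valid placement for length ", length)
  }
  with_seed(seed, {
    out <- vector("list", n)
    filled <- 0L
    while (filled < n) {
      ch <- sample(names(sizes), 1, prob = capacity)
      start <- floor(runif(1, min = 0, max = capacity[[ch]]))
      cand <- genomic_interval(ch, start, start + length)
      if (!is.null(exclude) && intervals_overlap(cand, exclude)) next
      filled <- filled + 1L
      out[[filled]] <- cand
    }
    out
  })
}

#' Accessibility significance against a random-region null
#'
#' Compares the mean signal over a query interval with the mean signals
#' of `n_null` random regions of the same length ("is this locus more
#' accessible than random genome?"). Reports the observed mean, the
#' null means, a z-score against the null distribution, a plus-one
#' corrected one-sided empirical p-value
#' `(1 + #\{null >= observed\}) / (n_null + 1)` (never exactly 0), a
#' one-sample t-test p of the null means against the observed value
#' (one-sided, observed greater), and significance stars
#' (`*` p<0.05, `**` p<0.01, `***` p<0.001) from the empirical p.
#'
#' @param track A [coverage_track()].
#' @param interval Query [genomic_interval()].
#' @param n_null Number of null regions (default 50).
#' @param seed Integer seed for null sampling.
#' @return An object of class `accessibility_test`: list with fields
#'   `interval`, `observed_mean`, `null_means`, `z`, `empirical_p`,
#'   `t_p`, `stars`.
#' @export
accessibility_significance <- function(track, interval, n_null = 50,
                                       seed = 1) {
  observed <- mean_signal(track, interval)
  nulls <- sample_null_regions(track$sizes, interval_length(interval),
                               n = n_null, seed = seed, exclude = interval)
  null_means <- vapply(nulls, function(iv) mean_signal(track, iv),
                       numeric(1))
  null_sd <- sd(null_means)
  z <- if (null_sd > 0) (observed - mean(null_means)) / null_sd else NA_real_
  empirical_p <- (1 + sum(null_means >= observed)) / (n_null + 1)
  t_p <- if (null_sd > 0)
    t.test(null_means, mu = observed, alternative = "less")$p.value
  else NA_real_
  stars <- if (empirical_p < 0.001) "***"
           else if (empirical_p < 0.01) "**"
           else if (empirical_p < 0.05) "*"
           else ""
  structure(list(interval = interval, observed_mean = observed,
                 null_means = null_means, z = z,
                 empirical_p = empirical_p, t_p = t_p, stars = stars),
            class = "accessibility_test")
}

#' @export
print.accessibility_test <- function(x, ...) {
  cat(sprintf("<accessibility_test %s:%s-%s mean=%.4g z=%.3g p=%.4g %s>\n",
              x$interval$chrom,
              format(x$interval$start, scientific = FALSE),
              format(x$interval$end, scientific = FALSE),
              x$observed_mean, x$z, x$empirical_p, x$stars))
  invisible(x)
}
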