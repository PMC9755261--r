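#' Protein-coding genes within a window of a lncRNA
#'
#' Candidate cis-targets: genes on the same chromosome whose interval
#' lies within `window` bp upstream or downstream of the lncRNA's edges
#' (inclusive at exactly `window`). Distance is edge-to-edge, 0 for
#' overlap; orientation says whether the gene lies upstream (before the
#' lncRNA start in genome coordinates), downstream, or overlapping.
#'
#' @param lncrna A [genomic_interval()].
#' @param genes Named list of `genomic_interval` (names = gene ids).
#' @param window Window size in bp on each side (default 100000).
#' @return `data.frame` with columns `gene_id`, `distance`,
#'   `orientation`, `correlation` (`NA`, filled later).
#' @export
find_cis_neighbors <- function(lncrna, genes, window = 100000) {
  ids <- names(genes)
  if (is.null(ids)) ids <- paste0("gene", seq_along(genes))
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    if (g$chrom != lncrna$chrom) return(NULL)
    if (g$end <= lncrna$start) {          # gene entirely before lncRNA
      d <- lncrna$start - g$end
      orient <- "upstream"
    } else if (g$start >= lncrna$end) {   # gene entirely after
      d <- g$start - lncrna$end
      orient <- "downstream"
    } else {
      d <- 0
      orient <- "overlapping"
    }
    if (d > window) return(NULL)
    data.frame(gene_id = ids[i], distance = d, orientation = orient,
               correlation = NA_real_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), distance = numeric(0),
                      orientation = character(0), correlation = numeric(0)))
  do.call(rbind, rows)
}

#' Pearson correlation with precondition checks
#'
#' Standard product-moment correlation (delegates to [stats::cor()]),
#' erroring on short or constant vectors rather than returning `NA`.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, non-constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  cor(x, y)
}

#' Filter cis pairs by absolute correlation
#'
#' @param pairs Output of [find_cis_neighbors()] with `correlation`
#'   filled in.
#' @param min_abs_r Minimum `|r|` (default 0.8). Reported cis pairs in
#'   the field span a wide range of correlations; the cut-off is a
#'   user-facing knob, not a law.
#' @return Subset of `pairs` with `|correlation| >= min_abs_r`.
#' @export
call_cis_targets <- function(pairs, min_abs_r = 0.8) {
  stopifnot(!anyNA(pairs$correlation))
  pairs[abs(pairs$correlation) >= min_abs_r, , drop = FALSE]
}

#' Detect co-expression modules (simplified WGCNA-style)
#'
#' Builds an unsigned weighted network (`a_ij = |r_ij|^beta`), clusters
#' transcripts by average-linkage hierarchical clustering of the
#' dissimilarity `1 - a`, cuts the tree statically at `cut_height`, and
#' discards clusters smaller than `min_module_size` (members labelled
#' unassigned). Each module gets a summary profile ("eigengene"
#' analog): the first principal-axis projection of the members'
#' standardized expression, sign-oriented to correlate positively with
#' the members' mean profile.
#'
#' @param matrix An [expression_matrix()] (>= 4 samples).
#' @param beta Soft-threshold power, >= 1 (default 6).
#' @param min_module_size Minimum members per module (default 10).
#' @param cut_height Static tree-cut height on `1 - a` (default 0.9).
#'   With `beta = 6`, a module whose members correlate at `r` sits at
#'   dissimilarity `1 - r^6` (0.47 at r = 0.9), while uncorrelated
#'   transcripts sit near 1; the default separates the two regimes.
#' @return List of modules, each a list with `module_id`, `members`
#'   (transcript ids) and `summary_profile` (numeric, one value per
#'   sample); attribute `unassigned` carries leftover transcript ids.
#' @export
detect_modules <- function(matrix, beta = 6, min_module_size = 10,
                           cut_height = 0.9) {
  stopifnot(ncol(matrix$values) >= 4L, beta >= 1)
  vals <- matrix$values
  keep <- apply(vals, 1, sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant transcript row(s) dropped")
    vals <- vals[keep, , drop = FALSE]
  }
  if (nrow(vals) < 2L)
    return(structure(list(), unassigned = rownames(vals)))
  adj <- abs(cor(t(vals)))^beta
  hc <- hclust(as.dist(1 - adj), method = "average")
  cl <- cutree(hc, h = cut_height)
  ids <- rownames(vals)
  modules <- list()
  unassigned <- character(0)
  k <- 0L
  for (g in sort(unique(cl))) {
    members <- ids[cl == g]
    if (length(members) < min_module_size) {
      unassigned <- c(unassigned, members)
      next
    }
    k <- k + 1L
    modules[[k]] <- list(module_id = sprintf("M%02d", k),
                         members = members,
                         summary_profile = module_summary_profile(
                           vals[members, , drop = FALSE]))
  }
  structure(modules, unassigned = unassigned)
}

# First principal-axis projection of standardized member expression,
# oriented to correlate positively with the mean member profile.
module_summary_profile <- function(member_values) {
  z <- t(scale(t(member_values)))      # standardize each transcript
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  profile <- pc$x[, 1]
  ref <- colMeans(z)
  if (sum(profile * ref) < 0) profile <- -profile
  unname(profile)
}

#' Association between a lncRNA and a co-expression module
#'
#' Correlates the lncRNA's expression vector with the module summary
#' profile and attaches a permutation p-value: the lncRNA vector is
#' shuffled across samples `n_perm` times and p is the plus-one
#' corrected fraction of permutations with `|r|` at least as large as
#' observed.
#'
#' @param lncrna_expression Numeric vector, one value per sample.
#' @param module A module from [detect_modules()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for the permutation draw.
#' @return List with `r`, `r_squared`, `p`.
#' @export
lncrna_module_association <- function(lncrna_expression, module,
                                      n_perm = 10000, seed = NULL) {
  profile <- module$summary_profile
  r_obs <- pearson(lncrna_expression, profile)
  draw <- function() {
    perm_r <- vapply(seq_len(n_perm), function(i)
      cor(sample(lncrna_expression), profile), numeric(1))
    (1 + sum(abs(perm_r) >= abs(r_obs))) / (n_perm + 1)
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(r = r_obs, r_squared = r_obs^2, p = p)
}

#' Fisher (hypergeometric) term enrichment
#'
#' One-sided upper-tail hypergeometric test per term: probability of
#' drawing at least the observed number of term genes when sampling
#' `|member_set|` genes from the universe without replacement;
#' Benjamini-Hochberg correction across terms.
#'
#' @param member_set Character vector of gene ids (subset of
#'   `universe`).
#' @param term_annotation Named list: term -> character vector of gene
#'   ids.
#' @param universe Character vector of all eligible gene ids.
#' @return `data.frame` with columns `term`, `overlap`, `term_size`,
#'   `p`, `q`, sorted by `p`.
#' @export
fisher_enrichment <- function(member_set, term_annotation, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  member_set <- unique(member_set)
  if (!all(member_set %in% universe))
    stop("member_set must be a subset of universe")
  n_univ <- length(universe)
  n_mem <- length(member_set)
  rows <- lapply(names(term_annotation), function(term) {
    tg <- intersect(unique(term_annotation[[term]]), universe)
    k <- length(intersect(member_set, tg))
    # upper tail including the observed count
    p <- phyper(k - 1, length(tg), n_univ - length(tg), n_mem,
                lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = length(tg), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
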