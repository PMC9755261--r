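# Shared fixture builders and independent oracles.

mk_iv <- function(chrom, start, end, strand = ".") {
  genomic_interval(chrom, start, end, strand)
}

# Single- or multi-exon transcript on one chromosome.
mk_tx <- function(id, chrom = "chr1", start = 0, spliced = 400,
                  class_code = "u", strand = "+", n_exons = 1,
                  intron = 100) {
  if (n_exons == 1) {
    iv <- mk_iv(chrom, start, start + spliced, strand)
    exons <- list(iv)
  } else {
    e1 <- floor(spliced / 2)
    iv <- mk_iv(chrom, start, start + spliced + intron, strand)
    exons <- list(mk_iv(chrom, start, start + e1, strand),
                  mk_iv(chrom, start + e1 + intron,
                        start + spliced + intron, strand))
  }
  transcript_model(id, paste0("g_", id), iv, exons, class_code)
}

# Expression matrix with explicit per-sample values for a set of
# transcripts; 2 genotypes x 2 conditions x `reps` replicates.
mk_expr <- function(values, reps = 3) {
  samples <- expand.grid(replicate = seq_len(reps),
                         condition = c("control", "salt"),
                         genotype = c("tolerant", "sensitive"),
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_%d", samples$genotype,
                            samples$condition, samples$replicate)
  samples <- samples[, c("sample", "genotype", "condition", "replicate")]
  values <- as.matrix(values)
  colnames(values) <- samples$sample
  expression_matrix(values, samples)
}

# Intervals for the bundled rice DE-lncRNA table, split by genotype.
rice_intervals <- function(genotype) {
  tab <- rice_de_lncrnas()
  tab <- tab[tab$genotype == genotype, ]
  setNames(lapply(seq_len(nrow(tab)), function(i)
    mk_iv(tab$chrom[i], tab$start[i], tab$end[i])), tab$name)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# ---- independent oracles ---------------------------------------------------

# Brute-force six-frame-free ORF scan: longest ATG..stop run over the
# three forward frames, counted in codons.
oracle_longest_orf <- function(seq) {
  best <- 0L
  n <- nchar(seq)
  for (frame in 0:2) {
    i <- frame + 1L
    while (i + 2L <= n) {
      if (substr(seq, i, i + 2) == "ATG") {
        len <- 0L
        j <- i
        while (j + 2L <= n) {
          cod <- substr(seq, j, j + 2)
          if (cod %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, len)
            break
          }
          len <- len + 1L
          j <- j + 3L
        }
      }
      i <- i + 3L
    }
  }
  best
}

# Exhaustive hypergeometric upper tail by direct summation.
oracle_hyper_tail <- function(k, term_size, universe, n_draw) {
  sum(vapply(k:min(term_size, n_draw), function(x)
    dhyper(x, term_size, universe - term_size, n_draw), numeric(1)))
}

# All words of length L over ACGT.
all_words <- function(L) {
  if (L == 0) return("")
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L),
                              stringsAsFactors = FALSE))
}

# Brute-force duplex expectation: branch-and-bound enumeration of all
# banded antiparallel pairings under the declared penalty scheme,
# independent of the package's DP.
oracle_duplex_expectation <- function(mirna, site, band = 2) {
  mirna <- chartr("U", "T", toupper(mirna))
  site <- chartr("U", "T", toupper(site))
  mi <- strsplit(mirna, "")[[1]]
  sr <- rev(strsplit(site, "")[[1]])
  m <- length(mi); n <- length(sr)
  pen_pair <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "C" && b == "G") || (a == "G" && b == "C")) 0
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) 0.5
    else 1
  }
  smult <- function(p) if (p >= 2 && p <= 13) 2 else 1
  best <- Inf
  recurse <- function(i, j, cost) {
    if (cost >= best) return()
    if (abs(i - j) > band) return()
    if (i == m && j == n) {
      best <<- min(best, cost)
      return()
    }
    if (i < m && j < n)
      recurse(i + 1, j + 1, cost + pen_pair(mi[i + 1], sr[j + 1]) *
                smult(i + 1))
    if (i < m)
      recurse(i + 1, j, cost + 2 * smult(i + 1))
    if (j < n)
      recurse(i, j + 1, cost + 2 * smult(min(i + 1, m)))
  }
  recurse(0, 0, 0)
  best
}
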