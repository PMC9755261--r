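#' Configuration for the synthetic dataset generator
#'
#' Defines the toy study the generator emulates: a two-genotype
#' (tolerant/sensitive), two-condition (control/salt) design with three
#' biological replicates, a small two-chromosome genome, a mixture of
#' true lncRNAs and transcripts engineered to fail exactly one
#' discovery filter each, planted differential expression, a planted
#' co-expression module driven by one lncRNA, planted accessible
#' regions on lncRNA loci, planted motif instances in the genome, and
#' planted miRNA complementary sites in lncRNAs.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_chromosomes,chromosome_length Genome shape (default 2 x
#'   100 kb).
#' @param replicates Biological replicates per (genotype, condition)
#'   (default 3, i.e. 12 samples).
#' @param n_lncrna True lncRNAs passing every filter (default 30, class
#'   codes cycled over u, i, x, o).
#' @param n_coding_background Protein-coding (`=` class) transcripts,
#'   the expressed-transcript background and module-member pool
#'   (default 110).
#' @param n_short,n_small_rna_overlap,n_coding_potential,n_low_expression
#'   Spoiler transcripts failing, respectively, the length filter, the
#'   small-RNA overlap filter, the coding-potential intersection and
#'   the expression filter (defaults 20, 10, 20, 10).
#' @param noise_sd SD of the log-normal multiplicative FPKM noise
#'   (default 0.2; 0 gives exact planted values).
#' @param de_log2fc Planted salt-vs-control log2 fold changes for the
#'   first `length(de_log2fc)` lncRNAs (defaults to the four effect
#'   sizes reported for the tolerant rice genotype: 1.33505, -1.84777,
#'   1.3109, -1.84449).
#' @param de_genotype Genotype carrying the planted DE (default
#'   `"tolerant"`).
#' @param module_size,module_r,module_sd Planted co-expression module:
#'   member count (default 50 coding transcripts), target pairwise
#'   correlation induced by a shared latent factor with loading
#'   `sqrt(module_r)` (default 0.96), and log-scale signal SD (default
#'   0.5).
#' @param n_accessible,accessibility_amplitude,coverage_background
#'   Accessible regions planted on the first `n_accessible` lncRNA
#'   loci, their mean signal elevation over the background level
#'   (defaults 4, 10, 1).
#' @param n_motifs,motif_length,motif_instances,motif_spacing Planted
#'   PWMs (near-consensus, defaults 2 motifs of 18 bp, 3 genomic
#'   instances each, 2500 bp apart). 18 bp keeps the consensus word's
#'   exact p-value (0.25^18 under uniform background) below the 1e-10
#'   scanning threshold, and the spacing keeps instances from sharing
#'   a toy-predictor receptive field.
#' @param n_mirnas,mirna_length Mature miRNAs (default 3 of 21 nt);
#'   each gets one perfect complementary site planted inside a lncRNA.
#' @return An object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 2, chromosome_length = 100000,
                              replicates = 3,
                              n_lncrna = 30, n_coding_background = 110,
                              n_short = 20, n_small_rna_overlap = 10,
                              n_coding_potential = 20, n_low_expression = 10,
                              noise_sd = 0.2,
                              de_log2fc = c(1.33505, -1.84777, 1.3109,
                                            -1.84449),
                              de_genotype = "tolerant",
                              module_size = 50, module_r = 0.96,
                              module_sd = 0.5,
                              n_accessible = 4,
                              accessibility_amplitude = 10,
                              coverage_background = 1,
                              n_motifs = 2, motif_length = 18,
                              motif_instances = 3, motif_spacing = 2500,
                              n_mirnas = 3, mirna_length = 21) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chromosomes, cfg$chromosome_length, cfg$replicates,
              cfg$n_lncrna, cfg$n_coding_background, cfg$n_short,
              cfg$n_small_rna_overlap, cfg$n_coding_potential,
              cfg$n_low_expression, cfg$module_size, cfg$n_accessible,
              cfg$n_motifs, cfg$motif_instances, cfg$n_mirnas)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$module_r < -1 || cfg$module_r > 1)
    stop("module_r must lie in [-1, 1]")
  if (cfg$accessibility_amplitude < 0 || cfg$coverage_background < 0)
    stop("amplitudes must be >= 0")
  if (cfg$n_accessible > cfg$n_lncrna)
    stop("cannot plant more accessible regions than lncRNAs")
  if (cfg$module_size > cfg$n_coding_background)
    stop("module_size cannot exceed n_coding_background")
  structure(cfg, class = "simulation_config")
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Deterministically (per seed) generates a genome, transcript models,
#' an FPKM expression matrix with planted differential expression and a
#' planted co-expression module, per-transcript coding evidence, a
#' coverage track with planted accessible regions, PWM motifs with
#' planted genomic instances, mature miRNAs with planted complementary
#' sites, and a truth manifest labelling every planted feature. If
#' `dir` is given, everything is also written in the package's standard
#' formats (FASTA, GTF, TSV, bedGraph, MEME).
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return List with components `genome`, `chrom_sizes`, `transcripts`,
#'   `small_rnas`, `expression`, `evidence`, `stats`, `coverage`,
#'   `motifs`, `mirnas`, `truth` and (if `dir` was given) `paths`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  ds <- with_seed(config$seed, simulate_dataset_impl(config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- list(
      genome = file.path(dir, "genome.fa"),
      chrom_sizes = file.path(dir, "genome.chrom.sizes"),
      annotation = file.path(dir, "transcripts.gtf"),
      small_rnas = file.path(dir, "small_rnas.tsv"),
      expression = file.path(dir, "expression.tsv"),
      evidence = file.path(dir, "coding_evidence.tsv"),
      stats = file.path(dir, "de_stats.tsv"),
      coverage = file.path(dir, "coverage.bedGraph"),
      motifs = file.path(dir, "motifs.meme"),
      mirnas = file.path(dir, "mirnas.fa"),
      truth = file.path(dir, "truth_transcripts.tsv"))
    write_fasta(ds$genome, p$genome)
    write_chrom_sizes(ds$chrom_sizes, p$chrom_sizes)
    write_gtf(ds$transcripts, p$annotation)
    write_tsv(data.frame(
      chrom = vapply(ds$small_rnas, function(x) x$chrom, character(1)),
      start = vapply(ds$small_rnas, function(x) x$start, numeric(1)),
      end = vapply(ds$small_rnas, function(x) x$end, numeric(1))),
      p$small_rnas)
    write_expression_tsv(ds$expression, p$expression)
    write_tsv(data.frame(
      transcript_id = vapply(ds$evidence, function(e) e$transcript_id,
                             character(1)),
      cpc_coding = vapply(ds$evidence, function(e) e$cpc_coding, logical(1)),
      pfam_hit = vapply(ds$evidence, function(e) e$pfam_hit, logical(1)),
      swissprot_hit = vapply(ds$evidence, function(e) e$swissprot_hit,
                             logical(1))), p$evidence)
    write_tsv(ds$stats, p$stats)
    write_bedgraph(ds$coverage, p$coverage)
    write_meme(ds$motifs, p$motifs)
    write_fasta(ds$mirnas, p$mirnas)
    write_tsv(ds$truth$transcripts, p$truth)
    ds$paths <- p
  }
  ds
}

simulate_dataset_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  sizes <- setNames(rep(cfg$chromosome_length, cfg$n_chromosomes), chroms)
  genome <- setNames(vapply(chroms, function(ch)
    random_dna(cfg$chromosome_length), character(1)), chroms)

  ## ---- transcript layout ------------------------------------------------
  roles <- c(rep("lncrna", cfg$n_lncrna),
             rep("coding_background", cfg$n_coding_background),
             rep("short", cfg$n_short),
             rep("small_rna_overlap", cfg$n_small_rna_overlap),
             rep("coding_potential", cfg$n_coding_potential),
             rep("low_expression", cfg$n_low_expression))
  n_tx <- length(roles)
  lnc_codes <- rep(c("u", "i", "x", "o"), length.out = cfg$n_lncrna)
  cursor <- setNames(rep(100, cfg$n_chromosomes), chroms)
  gap <- 60
  transcripts <- vector("list", n_tx)
  small_rnas <- list()
  truth_rows <- vector("list", n_tx)
  code_of <- function(i, role) {
    switch(role,
           lncrna = lnc_codes[i],
           coding_background = "=",
           short = "u", small_rna_overlap = "u",
           coding_potential = "u", low_expression = "u")
  }
  lnc_seen <- 0L
  for (i in seq_len(n_tx)) {
    role <- roles[i]
    if (role == "lncrna") lnc_seen <- lnc_seen + 1L
    spliced <- switch(role,
                      lncrna = 300 + (i %% 6) * 100,
                      coding_background = 400,
                      short = 150,
                      small_rna_overlap = 400,
                      coding_potential = 450,
                      low_expression = 400)
    two_exon <- role == "lncrna" && lnc_seen %% 2 == 0L
    intron <- if (two_exon) 100 else 0
    span <- spliced + intron
    ch <- chroms[1 + (i %% cfg$n_chromosomes)]
    start <- cursor[[ch]]
    if (start + span + gap > sizes[[ch]]) {
      ch <- chroms[which.max(sizes - cursor)]
      start <- cursor[[ch]]
      if (start + span + gap > sizes[[ch]])
        stop("chromosome_length too small for the configured transcripts")
    }
    cursor[[ch]] <- start + span + gap
    strand <- if (i %% 2 == 0) "+" else "-"
    iv <- genomic_interval(ch, start, start + span, strand)
    exons <- if (two_exon) {
      e1 <- floor(spliced / 2)
      list(genomic_interval(ch, start, start + e1, strand),
           genomic_interval(ch, start + e1 + intron, start + span, strand))
    } else list(iv)
    id <- sprintf("TX%04d", i)
    transcripts[[i]] <- transcript_model(
      transcript_id = id, gene_id = sprintf("G%04d", i),
      interval = iv, exons = exons,
      class_code = code_of(lnc_seen, role), source = "sim")
    if (role == "small_rna_overlap")
      small_rnas[[length(small_rnas) + 1L]] <-
        genomic_interval(ch, start + 50, start + 120)
    if (role == "coding_potential") {
      # plant an unbroken ATG + 100 codons + stop so the ORF heuristic
      # agrees with the evidence table
      orf <- paste0("ATG", strrep("GCT", 100), "TAA")
      substr(genome[[ch]], start + 1, start + nchar(orf)) <- orf
    }
    truth_rows[[i]] <- data.frame(
      transcript_id = id, role = role,
      is_lncrna = role == "lncrna",
      category = if (role == "lncrna")
        c(u = "lincRNA", i = "intronic", x = "antisense",
          o = "sense")[[code_of(lnc_seen, role)]] else NA_character_,
      chrom = ch, start = start, end = start + span,
      stringsAsFactors = FALSE)
  }
  truth_tx <- do.call(rbind, truth_rows)

  ## ---- expression matrix ------------------------------------------------
  genotypes <- c("tolerant", "sensitive")
  samples <- do.call(rbind, lapply(genotypes, function(g)
    do.call(rbind, lapply(c("control", "salt"), function(cd)
      data.frame(sample = sprintf("%s_%s_%d", g, cd,
                                  seq_len(cfg$replicates)),
                 genotype = g, condition = cd,
                 replicate = seq_len(cfg$replicates),
                 stringsAsFactors = FALSE)))))
  n_s <- nrow(samples)
  ids <- vapply(transcripts, function(tx) tx$transcript_id, character(1))
  base <- setNames(exp(rnorm(n_tx, mean = log(10), sd = 0.5)), ids)
  base[roles == "low_expression"] <- 0.8        # single-exon threshold is 2
  single_exon <- vapply(transcripts, function(tx) length(tx$exons) == 1L,
                        logical(1))
  # low-expression spoilers are single-exon by construction
  vals <- matrix(rep(base, n_s), nrow = n_tx, dimnames = list(ids, samples$sample))

  # planted DE in the configured genotype's salt samples
  n_de <- min(length(cfg$de_log2fc), cfg$n_lncrna)
  de_ids <- ids[which(roles == "lncrna")[seq_len(n_de)]]
  de_lfc <- cfg$de_log2fc[seq_len(n_de)]
  salt_cols <- samples$genotype == cfg$de_genotype &
    samples$condition == "salt"
  for (k in seq_len(n_de))
    vals[de_ids[k], salt_cols] <- vals[de_ids[k], salt_cols] * 2^de_lfc[k]

  # planted module: latent factor model on the log scale; the loading
  # sqrt(r) makes member pairs correlate at exactly r on the log scale,
  # so members (and the driver) receive no further independent noise
  module_ids <- ids[which(roles == "coding_background")[seq_len(cfg$module_size)]]
  driver_id <- if (cfg$n_lncrna > n_de) ids[which(roles == "lncrna")[n_de + 1L]]
               else NA_character_
  latent <- rnorm(n_s)
  lambda <- sqrt(max(0, cfg$module_r))
  for (id in module_ids) {
    eps <- rnorm(n_s)
    sig <- lambda * latent + sqrt(max(0, 1 - lambda^2)) * eps
    vals[id, ] <- vals[id, ] * exp(cfg$module_sd * sig)
  }
  if (!is.na(driver_id))
    vals[driver_id, ] <- vals[driver_id, ] * exp(cfg$module_sd * latent)

  # multiplicative log-normal noise on everything outside the module
  if (cfg$noise_sd > 0) {
    noisy <- !(ids %in% c(module_ids, driver_id))
    vals[noisy, ] <- vals[noisy, ] *
      exp(matrix(rnorm(sum(noisy) * n_s, sd = cfg$noise_sd),
                 sum(noisy), n_s))
  }
  expression <- expression_matrix(vals, samples)

  ## ---- coding evidence & DE stats ---------------------------------------
  evidence <- lapply(seq_len(n_tx), function(i)
    coding_evidence(ids[i],
                    cpc_coding = roles[i] %in% c("coding_background",
                                                 "coding_potential"),
                    pfam_hit = roles[i] == "coding_background",
                    swissprot_hit = roles[i] == "coding_background"))
  stats <- data.frame(transcript_id = ids,
                      qvalue = ifelse(ids %in% de_ids, 0.001, 0.9),
                      stringsAsFactors = FALSE)

  ## ---- coverage track with planted accessible regions --------------------
  covs <- lapply(setNames(chroms, chroms), function(ch)
    round(stats::rgamma(sizes[[ch]], shape = 4,
                        rate = 4 / cfg$coverage_background), 4))
  acc_idx <- which(roles == "lncrna")[seq_len(cfg$n_accessible)]
  accessible <- lapply(acc_idx, function(i) transcripts[[i]]$interval)
  for (iv in accessible)
    covs[[iv$chrom]][(iv$start + 1):iv$end] <-
      covs[[iv$chrom]][(iv$start + 1):iv$end] + cfg$accessibility_amplitude
  coverage <- coverage_track(covs, sizes)

  ## ---- motifs planted into the genome ------------------------------------
  motifs <- lapply(seq_len(cfg$n_motifs), function(k) {
    consensus <- chars(random_dna(cfg$motif_length))
    mat <- t(vapply(consensus, function(b) {
      p <- rep(0.01, 4); p[match(b, BASES)] <- 0.97; p
    }, numeric(4)))
    pwm_motif(sprintf("MOTIF%02d", k), mat)
  })
  instance_rows <- list()
  free_start <- max(cursor) + 500
  for (k in seq_along(motifs)) {
    consensus <- paste(BASES[apply(motifs[[k]]$matrix, 1, which.max)],
                       collapse = "")
    for (j in seq_len(cfg$motif_instances)) {
      ch <- chroms[1 + ((k + j) %% cfg$n_chromosomes)]
      slot <- (k - 1) * cfg$motif_instances + (j - 1)
      pos <- free_start + slot * cfg$motif_spacing
      if (pos + cfg$motif_length >= sizes[[ch]])
        stop("no room to plant motif instances; enlarge chromosomes")
      substr(genome[[ch]], pos + 1, pos + cfg$motif_length) <- consensus
      instance_rows[[length(instance_rows) + 1L]] <- data.frame(
        motif_id = motifs[[k]]$motif_id, chrom = ch, start = pos,
        end = pos + cfg$motif_length, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  motif_instances <- if (length(instance_rows) > 0)
    do.call(rbind, instance_rows)
  else data.frame(motif_id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0),
                  strand = character(0))

  ## ---- miRNAs with planted complementary sites ----------------------------
  mirnas <- setNames(vapply(seq_len(cfg$n_mirnas), function(k)
    random_dna(cfg$mirna_length), character(1)),
    sprintf("miR%02d", seq_len(cfg$n_mirnas)))
  site_rows <- list()
  lnc_idx <- which(roles == "lncrna")
  for (k in seq_len(cfg$n_mirnas)) {
    if (length(lnc_idx) == 0L) break
    tx <- transcripts[[lnc_idx[1 + (k - 1) %% length(lnc_idx)]]]
    site <- revcomp(mirnas[[k]])
    ex <- tx$exons[[1]]
    off <- 20
    if (interval_length(ex) < off + nchar(site) + 1)
      stop("lncRNA exon too short to host a miRNA site")
    pos <- ex$start + off
    substr(genome[[ex$chrom]], pos + 1, pos + nchar(site)) <- site
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      mirna_id = names(mirnas)[k], lncrna_id = tx$transcript_id,
      chrom = ex$chrom, start = pos, end = pos + nchar(site),
      stringsAsFactors = FALSE)
  }
  mirna_sites <- if (length(site_rows) > 0) do.call(rbind, site_rows)
  else data.frame(mirna_id = character(0), lncrna_id = character(0),
                  chrom = character(0), start = numeric(0),
                  end = numeric(0))

  ## ---- truth manifest ------------------------------------------------------
  truth_tx$is_de <- truth_tx$transcript_id %in% de_ids
  truth_tx$log2fc <- NA_real_
  truth_tx$log2fc[match(de_ids, truth_tx$transcript_id)] <- de_lfc
  truth_tx$direction <- ifelse(!truth_tx$is_de, "none",
                               ifelse(truth_tx$log2fc >= 1, "up",
                                      ifelse(truth_tx$log2fc <= -1, "down",
                                             "none")))
  truth_tx$in_module <- truth_tx$transcript_id %in% module_ids
  truth_tx$module_driver <- truth_tx$transcript_id %in% driver_id

  list(genome = genome, chrom_sizes = sizes, transcripts = transcripts,
       small_rnas = small_rnas, expression = expression,
       evidence = evidence, stats = stats, coverage = coverage,
       motifs = motifs, mirnas = mirnas,
       truth = list(transcripts = truth_tx,
                    accessible_regions = accessible,
                    motif_instances = motif_instances,
                    mirna_sites = mirna_sites,
                    module_members = module_ids,
                    module_driver = driver_id,
                    de_genotype = cfg$de_genotype))
}

#' Toy motif-based accessibility predictor
#'
#' A deterministic stand-in satisfying the [predictor()] contract: the
#' score of a window is the sum of forward-strand log-odds of all motif
#' matches (log-odds above `match_threshold`) within `receptive_field`
#' bases of the window center, squashed through a logistic to (0, 1).
#' With no matches the score is the baseline `plogis(0) = 0.5`.
#' Destroying a planted motif instance therefore strictly lowers the
#' score.
#'
#' @param motifs Non-empty list of [pwm_motif()].
#' @param window_length Input window length `L_in`.
#' @param receptive_field Width of the centered region the predictor
#'   actually reads, `<= window_length` (default `min(window_length,
#'   2001)`).
#' @param match_threshold Log-odds above which a position counts as a
#'   match (default 0).
#' @param scale Logistic temperature (default 4).
#' @return A [predictor()].
#' @export
toy_predictor <- function(motifs, window_length,
                          receptive_field = min(window_length, 2001),
                          match_threshold = 0, scale = 4) {
  if (length(motifs) == 0L) stop("toy predictor needs at least one motif")
  if (receptive_field > window_length)
    stop("window_length shorter than receptive_field")
  score_mats <- lapply(motifs, pwm_score_matrix)
  center <- floor(window_length / 2)
  r_start <- max(0, center - floor(receptive_field / 2))
  r_end <- min(window_length, r_start + receptive_field)
  predict <- function(sequence) {
    if (nchar(sequence) != window_length)
      stop("toy predictor expects windows of length ", window_length,
           ", got ", nchar(sequence))
    region <- substr(sequence, r_start + 1, r_end)
    base_idx <- match(chars(region), BASES)
    total <- 0
    for (sm in score_mats) {
      m <- nrow(sm)
      npos <- length(base_idx) - m + 1L
      if (npos < 1L) next
      scores <- numeric(npos)
      for (j in seq_len(m)) {
        contrib <- sm[j, base_idx[j:(j + npos - 1L)]]
        contrib[is.na(contrib)] <- 0
        scores <- scores + contrib
      }
      total <- total + sum(scores[scores > match_threshold])
    }
    stats::plogis(total / scale)
  }
  predictor(predict, window_length)
}
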