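#' Pipeline configuration
#'
#' Declarative configuration for an end-to-end run: input paths plus
#' every stage parameter, pre-filled with the analysis defaults
#' (expression filter FPKM 0.5 multi-exon / 2 single-exon in >= 2
#' samples, length > 200 bp, q <= 0.05 and |log2FC| >= 1, 100 kb cis
#' window, 50 null regions, 1000-nt mutagenesis window, peak z >= 3,
#' motif p <= 1e-10, mimicry expectation <= 5 with <= 3 mismatches).
#' Referenced files are checked at validation time, before any stage
#' runs.
#'
#' @param genome,annotation,expression,evidence,chrom_sizes Required
#'   input paths (FASTA, GTF, expression TSV, coding-evidence TSV,
#'   chrom.sizes).
#' @param small_rnas,stats,coverage,motifs,mirnas Optional input paths
#'   (small-RNA TSV, DE-stats TSV with q-values, bedGraph, MEME,
#'   miRNA FASTA). Stages missing their inputs are skipped.
#' @param out_dir Report directory (created if needed).
#' @param genotype Genotype contrasted for DE (default `"tolerant"`).
#' @param seed Integer seed for all stochastic stages.
#' @param q_threshold,lfc_threshold,cis_window,min_abs_r,n_null,
#'   ism_window,ism_window_length,ism_stride,z_threshold,p_threshold,
#'   max_expectation,max_mismatches Stage parameters.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, expression, evidence,
                            chrom_sizes, small_rnas = NULL, stats = NULL,
                            coverage = NULL, motifs = NULL, mirnas = NULL,
                            out_dir = "lncregnet_run", genotype = "tolerant",
                            seed = 1, q_threshold = 0.05, lfc_threshold = 1,
                            cis_window = 100000, min_abs_r = 0.8,
                            n_null = 50, ism_window = 1000,
                            ism_window_length = 20001, ism_stride = 50,
                            z_threshold = 3, p_threshold = 1e-10,
                            max_expectation = 5, max_mismatches = 3) {
  cfg <- as.list(environment())
  required <- c("genome", "annotation", "expression", "evidence",
                "chrom_sizes")
  for (f in required)
    if (!file.exists(cfg[[f]]))
      stop("missing required input file (", f, "): ", cfg[[f]])
  for (f in c("small_rnas", "stats", "coverage", "motifs", "mirnas"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured input file does not exist (", f, "): ", cfg[[f]])
  if (seed != round(seed)) stop("seed must be an integer")
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

transcript_sequence <- function(tx, genome) {
  seqs <- vapply(tx$exons, function(ex)
    substr(genome[[ex$chrom]], ex$start + 1, ex$end), character(1))
  s <- paste(seqs, collapse = "")
  if (tx$interval$strand == "-") s <- revcomp(s)
  s
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — lncRNA discovery,
#' differential expression, cis targets, trans modules, chromatin
#' accessibility, in-silico mutagenesis (with the built-in motif
#' predictor), motif scanning and miRNA mimicry — writing one TSV per
#' stage plus a run manifest (parameters, seed, per-stage row counts)
#' into the report directory. Re-running with the same config and seed
#' reproduces the report byte for byte. Stages whose optional inputs
#' are absent are skipped and recorded as such.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the report
#'   directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(name) file.path(config$out_dir, name)
  manifest <- list(seed = config$seed, genotype = config$genotype)

  genome <- run_stage("load", read_fasta(config$genome))
  sizes <- read_chrom_sizes(config$chrom_sizes)
  transcripts <- run_stage("load", read_gtf(config$annotation))
  expr <- run_stage("load", read_expression_tsv(config$expression))
  ev_df <- read_tsv_table(config$evidence)
  evidence <- lapply(seq_len(nrow(ev_df)), function(i)
    coding_evidence(ev_df$transcript_id[i], ev_df$cpc_coding[i],
                    ev_df$pfam_hit[i], ev_df$swissprot_hit[i]))
  small_rnas <- if (!is.null(config$small_rnas)) {
    sr <- read_tsv_table(config$small_rnas)
    lapply(seq_len(nrow(sr)), function(i)
      genomic_interval(sr$chrom[i], sr$start[i], sr$end[i]))
  } else list()

  ## discovery -------------------------------------------------------------
  disc <- run_stage("discovery",
    run_discovery_cascade(transcripts, expr, small_rnas, evidence))
  lnc_tx <- lapply(disc$annotations, function(a) a$transcript)
  write_gtf(lnc_tx, outp("lncrnas.gtf"))
  write_tsv(data.frame(stage = names(disc$counts),
                       n = as.integer(disc$counts)), outp("stage_counts.tsv"))
  manifest$n_lncrna <- length(lnc_tx)

  ## differential expression ----------------------------------------------
  lnc_ids <- vapply(lnc_tx, function(tx) tx$transcript_id, character(1))
  stats <- if (!is.null(config$stats)) read_tsv_table(config$stats) else NULL
  sub_expr <- expression_matrix(
    expr$values[rownames(expr$values) %in% lnc_ids, , drop = FALSE],
    expr$samples)
  de <- run_stage("differential_expression",
    de_table(sub_expr, config$genotype,
             stats = if (is.null(stats)) NULL
                     else stats[stats$transcript_id %in% lnc_ids, ],
             lfc_threshold = config$lfc_threshold,
             q_threshold = config$q_threshold))
  write_tsv(de, outp("de_lncrnas.tsv"))
  de_ids <- de$transcript_id[de$direction != "none"]
  manifest$n_de <- length(de_ids)
  de_tx <- lnc_tx[match(de_ids, lnc_ids)]

  ## cis targets ------------------------------------------------------------
  coding_tx <- transcripts[vapply(transcripts, function(tx)
    tx$class_code == "=", logical(1))]
  genes <- setNames(lapply(coding_tx, function(tx) tx$interval),
                    vapply(coding_tx, function(tx) tx$transcript_id,
                           character(1)))
  cis <- run_stage("cis_targets", do.call(rbind, lapply(de_tx, function(tx) {
    nb <- find_cis_neighbors(tx$interval, genes, window = config$cis_window)
    if (nrow(nb) == 0) return(NULL)
    nb$correlation <- vapply(nb$gene_id, function(g)
      tryCatch(pearson(fpkm_row(expr, tx$transcript_id), fpkm_row(expr, g)),
               error = function(e) NA_real_), numeric(1))
    nb <- nb[!is.na(nb$correlation), , drop = FALSE]
    nb <- call_cis_targets(nb, min_abs_r = config$min_abs_r)
    if (nrow(nb) == 0) return(NULL)
    cbind(lncrna_id = tx$transcript_id, nb)
  })))
  if (is.null(cis))
    cis <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = numeric(0), orientation = character(0),
                      correlation = numeric(0))
  write_tsv(cis, outp("cis_targets.tsv"))
  manifest$n_cis_pairs <- nrow(cis)

  ## trans modules ----------------------------------------------------------
  coding_ids <- names(genes)
  trans <- run_stage("trans_modules", {
    mod_expr <- expression_matrix(
      expr$values[rownames(expr$values) %in% coding_ids, , drop = FALSE],
      expr$samples)
    modules <- detect_modules(mod_expr)
    rows <- lapply(de_ids, function(id) {
      if (length(modules) == 0) return(NULL)
      assoc <- lapply(modules, function(mod)
        lncrna_module_association(fpkm_row(expr, id), mod, n_perm = 2000,
                                  seed = derive_seed(config$seed, 7)))
      best <- which.max(vapply(assoc, function(a) a$r_squared, numeric(1)))
      data.frame(lncrna_id = id, module_id = modules[[best]]$module_id,
                 module_size = length(modules[[best]]$members),
                 r_squared = assoc[[best]]$r_squared, p = assoc[[best]]$p,
                 stringsAsFactors = FALSE)
    })
    list(modules = modules, table = do.call(rbind, rows))
  })
  if (!is.null(trans$table)) write_tsv(trans$table, outp("trans_modules.tsv"))
  manifest$n_modules <- length(trans$modules)

  ## accessibility ----------------------------------------------------------
  acc <- NULL
  if (!is.null(config$coverage)) {
    track <- read_bedgraph(config$coverage, sizes)
    acc <- run_stage("accessibility", do.call(rbind, lapply(de_tx,
      function(tx) {
        t <- accessibility_significance(track, tx$interval,
                                        n_null = config$n_null,
                                        seed = derive_seed(config$seed, 11))
        data.frame(lncrna_id = tx$transcript_id,
                   observed_mean = t$observed_mean, z = t$z,
                   empirical_p = t$empirical_p, t_p = t$t_p,
                   stars = t$stars, stringsAsFactors = FALSE)
      })))
    if (!is.null(acc)) write_tsv(acc, outp("accessibility.tsv"))
  }

  ## mutagenesis + motif scan ------------------------------------------------
  ism_out <- NULL; motif_hits <- NULL
  if (!is.null(config$motifs) && length(de_tx) > 0) {
    motifs <- read_meme(config$motifs)
    pred <- toy_predictor(motifs, window_length = config$ism_window_length)
    tx <- de_tx[[1]]
    tss <- if (tx$interval$strand == "-") tx$interval$end - 1
           else tx$interval$start
    win <- extract_tss_window(genome, tx$interval$chrom, tss,
                              tx$interval$strand,
                              length = config$ism_window_length)
    ism_out <- run_stage("ism", {
      prof <- isms_scan(win, pred, window = config$ism_window,
                        stride = config$ism_stride,
                        seed = derive_seed(config$seed, 13))
      peaks <- call_isms_peaks(prof, z_threshold = config$z_threshold)
      write_tsv(data.frame(offset = prof$positions, isms = prof$scores,
                           z = prof$z), outp("ism_profile.tsv"))
      write_tsv(peaks, outp("ism_peaks.tsv"))
      list(profile = prof, peaks = peaks)
    })
    motif_hits <- run_stage("motif_scan", do.call(rbind, lapply(de_tx,
      function(tx) {
        seqd <- substr(genome[[tx$interval$chrom]], tx$interval$start + 1,
                       tx$interval$end)
        hits <- do.call(rbind, lapply(motifs, function(pw)
          scan_sequence(seqd, pw, p_threshold = config$p_threshold,
                        chrom = tx$interval$chrom,
                        origin = tx$interval$start)))
        if (nrow(hits) == 0) NULL else cbind(lncrna_id = tx$transcript_id,
                                             hits)
      })))
    if (!is.null(motif_hits)) write_tsv(motif_hits, outp("motif_hits.tsv"))
  }

  ## miRNA mimicry -----------------------------------------------------------
  mimicry <- NULL
  if (!is.null(config$mirnas) && length(de_tx) > 0) {
    mirnas <- read_fasta(config$mirnas)
    lseqs <- setNames(vapply(de_tx, transcript_sequence, character(1),
                             genome = genome),
                      vapply(de_tx, function(tx) tx$transcript_id,
                             character(1)))
    mimicry <- run_stage("mimicry",
      screen_mimics(mirnas, lseqs, max_expectation = config$max_expectation,
                    max_mismatches = config$max_mismatches))
    write_tsv(mimicry, outp("mimicry.tsv"))
  }

  params <- config[!vapply(config, is.null, logical(1))]
  write_tsv(data.frame(key = names(params),
                       value = vapply(params, function(v)
                         paste(as.character(v), collapse = ","),
                         character(1))),
            outp("run_manifest.tsv"))
  invisible(list(out_dir = config$out_dir, discovery = disc, de = de,
                 cis = cis, trans = trans, accessibility = acc,
                 ism = ism_out, motif_hits = motif_hits, mimicry = mimicry))
}
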