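test_that("class-code filter keeps exactly i, x, u, o", {
  codes <- c("u", "o", "i", "x", "=", "j", "c")
  txs <- lapply(seq_along(codes), function(i)
    mk_tx(paste0("t", i), start = i * 1000, class_code = codes[i]))
  kept <- filter_class_codes(txs)
  expect_equal(vapply(kept, function(t) t$class_code, character(1)),
               c("u", "o", "i", "x"))
  expect_identical(filter_class_codes(lapply(1:3, function(i)
    mk_tx(paste0("e", i), start = i * 1000, class_code = "="))), list())
  # the rice DE-lncRNA table carries only o and u codes: all retained
  tab <- rice_de_lncrnas()
  txs13 <- lapply(seq_len(nrow(tab)), function(i)
    mk_tx(tab$transcript_id[i], chrom = tab$chrom[i], start = tab$start[i],
          spliced = tab$length[i], class_code = tab$class_code[i]))
  expect_length(filter_class_codes(txs13), 13)
})

test_that("expression filter applies exon-dependent FPKM thresholds in >= 2 samples", {
  multi <- mk_tx("multi", start = 0, n_exons = 2)
  single <- mk_tx("single", start = 2000)
  spike <- mk_tx("spike", start = 4000, n_exons = 2)
  vals <- rbind(multi = c(0.5, 0.5, rep(0, 10)),
                single = rep(1.9, 12),
                spike = c(100, rep(0, 11)))
  em <- mk_expr(vals)
  kept <- filter_expression(list(multi, single, spike), em)
  expect_equal(vapply(kept, function(t) t$transcript_id, character(1)),
               "multi")
  expect_error(filter_expression(list(mk_tx("ghost")), em),
               "ghost")
})

test_that("small-RNA overlap removal uses any-bp half-open overlap", {
  tx <- mk_tx("t1", start = 100, spliced = 100)        # [100, 200)
  expect_length(remove_small_rna_overlaps(list(tx),
                                          list(mk_iv("chr1", 199, 250))), 0)
  expect_length(remove_small_rna_overlaps(list(tx),
                                          list(mk_iv("chr1", 200, 250))), 1)
  expect_identical(remove_small_rna_overlaps(list(tx), list()), list(tx))
  # intronic small RNA does not hit a two-exon transcript's exons
  tx2 <- mk_tx("t2", start = 1000, spliced = 400, n_exons = 2)
  intron_mid <- 1000 + 200 + 50
  expect_length(remove_small_rna_overlaps(
    list(tx2), list(mk_iv("chr1", intron_mid, intron_mid + 10))), 1)
})

test_that("length filter is strict at 200 bp of spliced length", {
  t200 <- mk_tx("t200", spliced = 200)
  t201 <- mk_tx("t201", start = 1000, spliced = 201)
  kept <- filter_length(list(t200, t201))
  expect_equal(vapply(kept, function(t) t$transcript_id, character(1)),
               "t201")
  # spliced, not genomic, length decides for multi-exon models
  tx <- mk_tx("spliced190", start = 3000, spliced = 190, n_exons = 2,
              intron = 500)
  expect_length(filter_length(list(tx)), 0)
  # the reported lncRNA.2-FL locus: single exon, length 828, retained
  fl2 <- mk_tx("lncRNA.2-FL", chrom = "chr6", start = 21764438,
               spliced = 828, class_code = "o")
  expect_equal(spliced_length(fl2), 828)
  expect_length(filter_length(list(fl2)), 1)
})

test_that("coding-potential filter is the three-way non-coding intersection", {
  tx <- mk_tx("a")
  expect_length(filter_coding_potential(
    list(tx), list(coding_evidence("a", FALSE, FALSE, FALSE))), 1)
  expect_length(filter_coding_potential(
    list(tx), list(coding_evidence("a", FALSE, TRUE, FALSE))), 0)
  expect_error(filter_coding_potential(list(tx), list()), "a")

  # brute-force set-intersection oracle on random verdicts
  withr::local_seed(21)
  txs <- lapply(1:10, function(i) mk_tx(paste0("t", i), start = i * 1000))
  ev <- lapply(txs, function(t)
    coding_evidence(t$transcript_id, sample(c(TRUE, FALSE), 1),
                    sample(c(TRUE, FALSE), 1), sample(c(TRUE, FALSE), 1)))
  pass_cpc <- vapply(ev, function(e) !e$cpc_coding, logical(1))
  pass_pfam <- vapply(ev, function(e) !e$pfam_hit, logical(1))
  pass_sp <- vapply(ev, function(e) !e$swissprot_hit, logical(1))
  expected <- vapply(txs, function(t) t$transcript_id,
                     character(1))[pass_cpc & pass_pfam & pass_sp]
  got <- vapply(filter_coding_potential(txs, ev),
                function(t) t$transcript_id, character(1))
  expect_identical(got, expected)
})

test_that("ORF heuristic matches a brute-force ORF scan", {
  withr::local_seed(31)
  no_atg <- paste(rep(c("C", "G"), 200), collapse = "")
  genome <- c(chr1 = no_atg)
  tx <- mk_tx("t", spliced = 400)
  ev <- orf_heuristic_evidence(list(tx), genome)
  expect_false(ev[[1]]$cpc_coding)
  expect_true(ev[[1]]$heuristic)

  # 303-bp ATG..stop ORF (100 codons + stop) is called coding
  orf <- paste0("ATG", strrep("GCA", 100), "TAA")
  genome2 <- c(chr1 = paste0(rand_dna(50), orf, rand_dna(50)))
  tx2 <- mk_tx("t2", spliced = nchar(genome2[[1]]))
  expect_true(orf_heuristic_evidence(list(tx2), genome2)[[1]]$cpc_coding)

  # random sequences agree with the independent oracle
  for (k in 1:20) {
    s <- rand_dna(300)
    tx3 <- mk_tx("t3", spliced = 300)
    got <- orf_heuristic_evidence(list(tx3), c(chr1 = s))[[1]]$cpc_coding
    expect_identical(got, oracle_longest_orf(s) >= 100)
  }
  expect_identical(orf_heuristic_evidence(list(), genome), list())
})

test_that("class codes map to lncRNA categories", {
  expect_equal(classify_lncrna(mk_tx("a", class_code = "u"))$category,
               "lincRNA")
  expect_equal(classify_lncrna(mk_tx("b", class_code = "x"))$category,
               "antisense")
  expect_equal(classify_lncrna(mk_tx("c", class_code = "i"))$category,
               "intronic")
  expect_equal(classify_lncrna(mk_tx("d", class_code = "o"))$category,
               "sense")
  expect_error(classify_lncrna(mk_tx("e", class_code = "=")),
               "cannot classify")
})

test_that("discovery cascade recovers the planted lncRNA set exactly", {
  cfg <- simulation_config(seed = 101, noise_sd = 0,
                           chromosome_length = 60000, n_lncrna = 12,
                           n_coding_background = 50, n_short = 6,
                           n_small_rna_overlap = 4, n_coding_potential = 6,
                           n_low_expression = 4, module_size = 20)
  ds <- simulate_dataset(cfg)
  res <- run_discovery_cascade(ds$transcripts, ds$expression, ds$small_rnas,
                               ds$evidence)
  got <- sort(vapply(res$annotations, function(a)
    a$transcript$transcript_id, character(1)))
  truth <- ds$truth$transcripts
  expect_identical(got, sort(truth$transcript_id[truth$is_lncrna]))
  # categories match the manifest too
  cats <- setNames(vapply(res$annotations, function(a) a$category,
                          character(1)),
                   vapply(res$annotations, function(a)
                     a$transcript$transcript_id, character(1)))
  expect_identical(unname(cats[truth$transcript_id[truth$is_lncrna]]),
                   truth$category[truth$is_lncrna])
  expect_true(all(diff(res$counts) <= 0))
  empty <- run_discovery_cascade(list(), ds$expression, list(), list())
  expect_identical(empty$annotations, list())
  expect_true(all(empty$counts == 0))
})

test_that("independent per-transcript filters commute and are idempotent", {
  cfg <- simulation_config(seed = 55, noise_sd = 0,
                           chromosome_length = 60000, n_lncrna = 10,
                           n_coding_background = 40, n_short = 5,
                           n_small_rna_overlap = 3, n_coding_potential = 5,
                           n_low_expression = 3, module_size = 15)
  ds <- simulate_dataset(cfg)
  ids <- function(x) sort(vapply(x, function(t) t$transcript_id,
                                 character(1)))
  f_class <- function(x) filter_class_codes(x)
  f_len <- function(x) filter_length(x)
  f_cod <- function(x) filter_coding_potential(x, ds$evidence)
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  filters <- list(f_class, f_len, f_cod)
  results <- lapply(perms, function(p) {
    out <- ds$transcripts
    for (k in p) out <- filters[[k]](out)
    ids(out)
  })
  for (r in results[-1]) expect_identical(r, results[[1]])
  # idempotence
  once <- f_class(ds$transcripts)
  expect_identical(ids(f_class(once)), ids(once))
  lened <- f_len(ds$transcripts)
  expect_identical(ids(f_len(lened)), ids(lened))
})
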