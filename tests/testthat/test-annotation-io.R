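test_that("GTF import converts 1-based inclusive to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsim\ttranscript\t11\t20\t.\t+\t.\t",
           "gene_id \"g1\"; transcript_id \"t1\"; class_code \"o\";"),
    paste0("chr1\tsim\texon\t11\t20\t.\t+\t.\t",
           "gene_id \"g1\"; transcript_id \"t1\"; class_code \"o\";")), path)
  tx <- read_gtf(path)
  expect_length(tx, 1)
  expect_equal(tx[[1]]$interval$start, 10)
  expect_equal(tx[[1]]$interval$end, 20)
  expect_equal(interval_length(tx[[1]]$interval), 10)
  expect_equal(tx[[1]]$class_code, "o")
})

test_that("GTF reader handles empty files, missing class codes and errors", {
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_identical(read_gtf(empty), list())

  nocode <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tsim\ttranscript\t1\t300\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "chr1\tsim\texon\t1\t300\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"),
    nocode)
  expect_equal(read_gtf(nocode)[[1]]$class_code, "=")

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tsim\ttranscript\t1\t300\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "chr1\tonly three fields"), bad)
  expect_error(read_gtf(bad), "line 2")

  orphan <- withr::local_tempfile(fileext = ".gtf")
  writeLines(
    "chr1\tsim\texon\t1\t300\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    orphan)
  expect_error(read_gtf(orphan), "parent transcript")
})

test_that("GTF round-trips random transcript models", {
  withr::local_seed(11)
  txs <- lapply(1:15, function(i) {
    start <- sample(0:5000, 1)
    mk_tx(sprintf("t%02d", i), chrom = sample(c("chr1", "chr2"), 1),
          start = start, spliced = sample(200:800, 1),
          class_code = sample(c("u", "i", "x", "o", "="), 1),
          strand = sample(c("+", "-"), 1),
          n_exons = sample(1:2, 1))
  })
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(txs, path)
  back <- read_gtf(path)
  expect_equal(length(back), length(txs))
  for (i in seq_along(txs)) {
    expect_equal(back[[i]]$transcript_id, txs[[i]]$transcript_id)
    expect_equal(back[[i]]$interval$start, txs[[i]]$interval$start)
    expect_equal(back[[i]]$interval$end, txs[[i]]$interval$end)
    expect_equal(back[[i]]$class_code, txs[[i]]$class_code)
    expect_equal(length(back[[i]]$exons), length(txs[[i]]$exons))
    expect_equal(vapply(back[[i]]$exons, interval_length, numeric(1)),
                 vapply(txs[[i]]$exons, interval_length, numeric(1)))
  }
})

test_that("coordinate conversion is a bijection over 1-based pairs", {
  withr::local_seed(3)
  for (k in 1:50) {
    s1 <- sample(1:100000, 1)
    e1 <- s1 + sample(0:5000, 1)
    # to internal and back
    s0 <- s1 - 1; e0 <- e1
    expect_equal(c(s0 + 1, e0), c(s1, e1))
    expect_gte(e0, s0)
  }
})

test_that("FASTA reader/writer round-trip and name truncation", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 description text", "ACGT"), path)
  expect_identical(read_fasta(path), c(c1 = "ACGT"))

  withr::local_seed(5)
  seqs <- setNames(vapply(1:5, function(i) rand_dna(sample(50:200, 1)),
                          character(1)), paste0("chr", 1:5))
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, p2)
  expect_identical(read_fasta(p2), seqs)
})

test_that("bedGraph reading fills dense tracks and checks bounds", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t5\t2.0", path)
  tr <- read_bedgraph(path, c(chr1 = 10))
  expect_equal(tr$values$chr1, c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0))

  bad <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t5\t15\t1.0", bad)
  expect_error(read_bedgraph(bad, c(chr1 = 10)), "exceeds chromosome size")
})

test_that("bedGraph writer round-trips random step tracks", {
  withr::local_seed(7)
  sizes <- c(chrA = 300, chrB = 150)
  values <- lapply(sizes, function(n) {
    v <- numeric(n)
    for (k in 1:5) {
      s <- sample(0:(n - 10), 1)
      v[(s + 1):(s + 10)] <- sample(1:50, 1) / 4
    }
    v
  })
  tr <- coverage_track(values, sizes)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, sizes)
  expect_equal(back$values, tr$values)
})

test_that("MEME minimal format round-trips and encodes determinism", {
  m1 <- pwm_motif("force_A", matrix(c(1, 0, 0, 0), 1, 4))
  expect_equal(unname(m1$matrix[1, "A"]), 1)
  withr::local_seed(9)
  m2 <- pwm_motif("mix", t(vapply(1:6, function(i) {
    p <- runif(4); round(p / sum(p), 6) -> p
    p[1] <- p[1] + (1 - sum(p)); p
  }, numeric(4))))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(m1, m2), path)
  back <- read_meme(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$motif_id, "force_A")
  expect_equal(back[[1]]$matrix[1, ], c(A = 1, C = 0, G = 0, T = 0),
               tolerance = 1e-5)
  expect_equal(unname(back[[2]]$matrix), unname(m2$matrix), tolerance = 1e-5)
})

test_that("TSV and chrom.sizes round-trip", {
  df <- data.frame(id = c("a", "b"), x = c(1.5, 2.25),
                   stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(df, p)
  expect_equal(read_tsv_table(p), df)
  sizes <- c(chr1 = 1000, chr2 = 500)
  p2 <- withr::local_tempfile()
  write_chrom_sizes(sizes, p2)
  expect_equal(read_chrom_sizes(p2), sizes)
})

test_that("interval and transcript invariants are enforced", {
  expect_error(genomic_interval("c", -1, 5), "invalid interval")
  expect_error(genomic_interval("c", 10, 5), "invalid interval")
  expect_error(genomic_interval("c", 0, 5, "?"), "strand")
  iv <- mk_iv("chr1", 0, 500, "+")
  expect_error(transcript_model("t", "g", iv,
                                list(mk_iv("chr1", 0, 300, "+"),
                                     mk_iv("chr1", 200, 500, "+"))),
               "overlap")
  expect_error(transcript_model("t", "g", iv,
                                list(mk_iv("chr2", 0, 300, "+"))),
               "chrom/strand")
  # half-open adjacency is not overlap
  expect_false(intervals_overlap(mk_iv("c", 0, 10), mk_iv("c", 10, 20)))
  expect_true(intervals_overlap(mk_iv("c", 0, 10), mk_iv("c", 9, 20)))
})
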