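test_that("cis windowing is edge-to-edge and inclusive at the window size", {
  lnc <- mk_iv("chr1", 500000, 501000)
  genes <- list(at_limit = mk_iv("chr1", 601000, 602000),       # 100000 away
                beyond = mk_iv("chr1", 601001, 602000),         # 100001 away
                overlapping = mk_iv("chr1", 500500, 500600),
                upstream93k = mk_iv("chr1", 405837, 406837),
                other_chrom = mk_iv("chr2", 500000, 501000))
  nb <- find_cis_neighbors(lnc, genes, window = 100000)
  expect_setequal(nb$gene_id, c("at_limit", "overlapping", "upstream93k"))
  expect_equal(nb$distance[nb$gene_id == "at_limit"], 100000)
  expect_equal(nb$distance[nb$gene_id == "overlapping"], 0)
  expect_equal(nb$orientation[nb$gene_id == "overlapping"], "overlapping")
  # the reported zinc-binding cis pair sat 93163 bp downstream
  gene <- mk_iv("chr4", 24983890 + 93163, 24983890 + 94163)
  nb2 <- find_cis_neighbors(mk_iv("chr4", 24983145, 24983890),
                            list(znf = gene))
  expect_equal(nb2$distance, 93163)
  expect_equal(nb2$orientation, "downstream")
})

test_that("cis windowing is symmetric between lncRNA and gene", {
  withr::local_seed(41)
  for (k in 1:30) {
    a <- mk_iv("chr1", s <- sample(0:1e6, 1), s + sample(100:2000, 1))
    b <- mk_iv("chr1", s2 <- sample(0:1e6, 1), s2 + sample(100:2000, 1))
    in_a <- nrow(find_cis_neighbors(a, list(x = b), window = 50000)) == 1
    in_b <- nrow(find_cis_neighbors(b, list(x = a), window = 50000)) == 1
    expect_identical(in_a, in_b)
  }
})

test_that("pearson matches the covariance formula and checks preconditions", {
  x <- c(1, 2, 3, 5, 8, 13)
  y <- c(2.2, 1.9, 3.5, 4.1, 9.0, 12.5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), oracle)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, rep(1, 6)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "length")
})

test_that("cis-target calling respects the |r| threshold", {
  pairs <- data.frame(gene_id = c("ppr", "chor"), distance = c(14000, 81000),
                      orientation = "upstream",
                      correlation = c(-0.97, 0.56))
  expect_equal(call_cis_targets(pairs)$gene_id, "ppr")
  expect_setequal(call_cis_targets(pairs, min_abs_r = 0.5)$gene_id,
                  c("ppr", "chor"))
  empty <- pairs[0, ]
  expect_equal(nrow(call_cis_targets(empty)), 0)
})

test_that("module detection separates perfectly correlated blocks", {
  withr::local_seed(61)
  t_idx <- seq_len(12)
  block1 <- outer(runif(12, 0.5, 2), sin(t_idx) + 2)
  block2 <- outer(runif(12, 0.5, 2), cos(1.7 * t_idx) + 2)
  vals <- rbind(block1, block2)
  rownames(vals) <- paste0("t", 1:24)
  em <- mk_expr(vals)
  mods <- detect_modules(em, min_module_size = 5)
  expect_length(mods, 2)
  members <- lapply(mods, function(m) m$members)
  expect_true(setequal(members[[1]], paste0("t", 1:12)) ||
                setequal(members[[2]], paste0("t", 1:12)))
  expect_setequal(c(members[[1]], members[[2]]), paste0("t", 1:24))
  # single transcript below min size is unassigned
  one <- mk_expr(rbind(a = rnorm(12, 10), b = rnorm(12, 10)))
  m1 <- detect_modules(one, min_module_size = 10)
  expect_length(m1, 0)
  expect_setequal(attr(m1, "unassigned"), c("a", "b"))
})

test_that("module detection is invariant to row permutation", {
  cfg <- simulation_config(seed = 71, chromosome_length = 40000,
                           n_lncrna = 8, n_coding_background = 30,
                           n_short = 2, n_small_rna_overlap = 2,
                           n_coding_potential = 2, n_low_expression = 2,
                           module_size = 15)
  ds <- simulate_dataset(cfg)
  coding <- ds$truth$transcripts$transcript_id[
    ds$truth$transcripts$role == "coding_background"]
  em <- expression_matrix(ds$expression$values[coding, ],
                          ds$expression$samples)
  withr::local_seed(1)
  perm <- sample(nrow(em$values))
  em_p <- expression_matrix(em$values[perm, ], em$samples)
  mods_a <- detect_modules(em)
  mods_b <- detect_modules(em_p)
  sets_a <- lapply(mods_a, function(m) sort(m$members))
  sets_b <- lapply(mods_b, function(m) sort(m$members))
  expect_setequal(vapply(sets_a, paste, character(1), collapse = ","),
                  vapply(sets_b, paste, character(1), collapse = ","))
})

test_that("planted modules are co-assigned across seeds", {
  co_assigned <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 1000 + s, chromosome_length = 40000,
                             n_lncrna = 6, n_coding_background = 30,
                             n_short = 2, n_small_rna_overlap = 2,
                             n_coding_potential = 2, n_low_expression = 2,
                             module_size = 20, module_r = 0.9)
    ds <- simulate_dataset(cfg)
    truth <- ds$truth$transcripts
    coding <- truth$transcript_id[truth$role == "coding_background"]
    em <- expression_matrix(ds$expression$values[coding, ],
                            ds$expression$samples)
    mods <- detect_modules(em, min_module_size = 10)
    if (length(mods) == 0) return(0)
    hits <- vapply(mods, function(m)
      length(intersect(m$members, ds$truth$module_members)), numeric(1))
    max(hits) / length(ds$truth$module_members)
  }, numeric(1))
  expect_gte(mean(co_assigned), 0.9)
})

test_that("lncRNA-module association: identity, planted driver, null p", {
  cfg <- simulation_config(seed = 91, noise_sd = 0,
                           chromosome_length = 40000, n_lncrna = 6,
                           n_coding_background = 30, n_short = 2,
                           n_small_rna_overlap = 2, n_coding_potential = 2,
                           n_low_expression = 2, module_size = 20,
                           module_r = 1)
  ds <- simulate_dataset(cfg)
  truth <- ds$truth$transcripts
  coding <- truth$transcript_id[truth$role == "coding_background"]
  em <- expression_matrix(ds$expression$values[coding, ],
                          ds$expression$samples)
  # non-member rows are exactly constant at zero noise and get dropped
  expect_warning(mods <- detect_modules(em, min_module_size = 10),
                 "constant transcript")
  expect_length(mods, 1)
  # summary profile correlates perfectly with itself
  self <- lncrna_module_association(mods[[1]]$summary_profile, mods[[1]],
                                    n_perm = 200, seed = 5)
  expect_equal(self$r_squared, 1)
  # the planted driver lncRNA reaches r^2 ~ 1 at p <= 1e-4
  drv <- ds$expression$values[ds$truth$module_driver, ]
  assoc <- lncrna_module_association(drv, mods[[1]], n_perm = 10000,
                                     seed = 6)
  expect_gte(assoc$r_squared, 0.99)
  expect_lte(assoc$p, 1e-4)
})

test_that("permutation p-values are uniform for independent vectors", {
  withr::local_seed(17)
  module <- list(module_id = "M", members = paste0("g", 1:10),
                 summary_profile = rnorm(12))
  ps <- vapply(1:200, function(k)
    lncrna_module_association(rnorm(12), module, n_perm = 199)$p,
    numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  universe <- paste0("g", 1:100)
  term <- list(T1 = paste0("g", 1:10))
  module <- c(paste0("g", 1:5), paste0("g", 50:54))
  res <- fisher_enrichment(module, term, universe)
  expect_equal(res$p, oracle_hyper_tail(5, 10, 100, 10))
  # member set identical to the term, universe twice the size
  res2 <- fisher_enrichment(paste0("g", 1:10),
                            list(T = paste0("g", 1:10)), paste0("g", 1:20))
  expect_equal(res2$p, oracle_hyper_tail(10, 10, 20, 10))
  expect_equal(res2$p, min(res2$p))          # smallest achievable for table
  # disjoint term: upper tail from k=0 is 1
  res3 <- fisher_enrichment(paste0("g", 1:5),
                            list(T = paste0("g", 90:95)), universe)
  expect_equal(res3$p, 1)
  expect_error(fisher_enrichment("g1", list(), character(0)), "universe")

  withr::local_seed(19)
  for (k in 1:25) {
    n_u <- sample(20:200, 1)
    uni <- paste0("u", seq_len(n_u))
    n_m <- sample(3:min(30, n_u), 1)
    mem <- sample(uni, n_m)
    terms <- list(A = sample(uni, sample(2:min(40, n_u), 1)),
                  B = sample(uni, sample(2:min(40, n_u), 1)))
    got <- fisher_enrichment(mem, terms, uni)
    for (tn in c("A", "B")) {
      kk <- length(intersect(mem, terms[[tn]]))
      expect_equal(got$p[got$term == tn],
                   oracle_hyper_tail(kk, length(unique(terms[[tn]])),
                                     n_u, n_m))
    }
    expect_equal(got$q, p.adjust(got$p, "BH"))
  }
})
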