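toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("gene features capture GC, intron class and expression medians", {
  # exon 1-4 "ATGC", intron 5-10 "GTATAG" (canonical), exon 11-14 "ATGC"
  genome <- toy_genome(c(c1 = "ATGCGTATAGATGCAAAAAAAAAA"))
  ann <- toy_ann(exons_gr("c1", "+", c("t", "t"), "g", c(1, 11), c(4, 14)))
  f <- extract_features(ann, genome)
  expect_equal(f$exon_gc, 0.5)
  expect_equal(f$exon_length, 4)
  expect_equal(f$intron_length, 6)
  expect_equal(f$n_gtag_introns, 1L)
  expect_equal(f$n_other_introns, 0L)
  # same intron on the minus strand is read reverse-complemented: not GT-AG
  ann_m <- toy_ann(exons_gr("c1", "-", c("t", "t"), "g", c(1, 11), c(4, 14)))
  fm <- extract_features(ann_m, genome)
  expect_equal(fm$n_gtag_introns, 0L)
  expect_equal(fm$n_other_introns, 1L)
  # mono-exonic gene zeroes all intron fields
  mono <- toy_ann(exons_gr("c1", "+", "t", "g", 1, 4))
  f0 <- extract_features(mono, genome)
  expect_equal(f0$intron_length, 0)
  expect_equal(f0$intron_gc, 0)
  expect_equal(f0$n_gtag_introns + f0$n_other_introns, 0L)
  expect_equal(f0$isoform_number, 1L)
  expect_error(extract_features(ann, toy_genome(c(other = "AAAA"))), "missing")
})

test_that("expression features default to zero for genes absent from the matrix", {
  sim <- shared_sim()
  cfg <- sim$config
  expr <- simulate_expression_matrix(gene_ids(sim$annotation)[-1], cfg)
  expect_warning(
    f <- extract_features(sim$annotation, sim$genome, expr,
                          genes = gene_ids(sim$annotation)[1:3]),
    "absent")
  expect_true(all(f[1, grepl("^expr_", colnames(f))] == 0))
  expect_false(all(f[2, grepl("^expr_", colnames(f))] == 0))
  expect_equal(sum(grepl("^expr_", colnames(f))), 14L)
})

test_that("training labels use a strict Jaccard cutoff", {
  ref <- toy_ann(exons_gr("c", "+", "r.t", "r", 1, 100))
  # identical -> positive
  same <- toy_ann(exons_gr("c", "+", "p.t", "p", 1, 100))
  expect_true(label_training_set(same, ref)$label)
  # jaccard exactly 0.6 (60/100) -> negative under strict >
  edge <- toy_ann(exons_gr("c", "+", "p.t", "p", 1, 60))
  lab <- label_training_set(edge, ref)
  expect_equal(lab$jaccard, 0.6)
  expect_false(lab$label)
  # non-overlapping -> negative
  far <- toy_ann(exons_gr("c", "+", "p.t", "p", 5000, 5100))
  expect_false(label_training_set(far, ref)$label)
})

test_that("the SVM filter separates a planted rule and collapses under permutation", {
  set.seed(10)
  n <- 120
  feats <- data.frame(
    isoform_number = c(rpois(n, 2) + 1L, rep(1L, n)),
    exon_length = c(rnorm(n, 400, 60), rnorm(n, 90, 20)),
    exon_gc = runif(2 * n, 0.3, 0.6),
    intron_length = c(rnorm(n, 80, 10), rep(0, n)),
    intron_gc = runif(2 * n, 0.3, 0.6),
    n_gtag_introns = c(rpois(n, 3), rep(0L, n)),
    n_other_introns = rpois(2 * n, 0.2),
    expr_f_gonad = c(rlnorm(n, 5, 1), rlnorm(n, 1, 1)))
  labels <- rep(c(TRUE, FALSE), each = n)
  m <- train_filter(feats, labels, kernels = "radial", cost = c(1, 10),
                    gamma = c(0.01, 0.1), seed = 1)
  expect_gte(m$cv_auc, 0.95)
  # paper incumbents present in the default grid
  m_def_grid <- do.call(rbind, lapply(c("radial", "sigmoid"), function(k)
    expand.grid(kernel = k, cost = 10^(-3:3), gamma = 10^(-3:3))))
  expect_true(any(m_def_grid$kernel == "radial" & m_def_grid$cost == 10 &
                    m_def_grid$gamma == 0.1))
  # permuted labels -> chance-level AUC
  aucs <- vapply(1:3, function(s) {
    set.seed(s)
    train_filter(feats, sample(labels), kernels = "radial", cost = 10,
                 gamma = 0.1, seed = s)$cv_auc
  }, numeric(1))
  expect_lt(mean(aucs), 0.65)
  expect_error(train_filter(feats, rep(TRUE, 2 * n)), "both positive and negative")
})

test_that("applying the filter removes planted noise and keeps true genes", {
  cfg <- simulation_config(seed = 31, n_genes = 40, noise_gene_rate = 0.5,
                           utr_truncation = 0.2)
  sim <- simulate_genome_and_annotation(cfg)
  pred <- perturb_annotation(sim$annotation, cfg)$annotation
  expr <- simulate_expression_matrix(gene_ids(pred), cfg)
  feats <- extract_features(pred, sim$genome, expr)
  lab <- label_training_set(pred, sim$annotation)
  m <- train_filter(feats[lab$gene_id, ], lab$label, kernels = "radial",
                    cost = c(1, 10), gamma = c(0.01, 0.1), seed = 1)
  kept <- apply_filter(m, pred, feats)
  noise <- grepl("^NOISE", gene_ids(pred))
  expect_gte(mean(!gene_ids(pred)[noise] %in% gene_ids(kept)), 0.8)
  expect_gte(mean(gene_ids(pred)[!noise] %in% gene_ids(kept)), 0.9)
  audit <- attr(kept, "audit")
  expect_setequal(audit$gene_id, setdiff(gene_ids(pred), gene_ids(kept)))
  expect_error(apply_filter(m, pred, feats[-1, , drop = FALSE]),
               "features missing")
})

test_that("reference merging extends matching transcripts by exon union", {
  ref <- toy_ann(exons_gr("c", "+", c("t1", "t1"), "g1", c(101, 301), c(200, 400)))
  # same intron chain, 100 bp longer 3' terminal exon
  pred <- toy_ann(exons_gr("c", "+", c("p1", "p1"), "gp", c(101, 301), c(200, 500)))
  merged <- merge_with_reference(pred, ref)
  expect_equal(n_transcripts(merged), 1L)
  ex <- ann_exons(merged)
  expect_equal(sort(end(ex)), c(200L, 500L))
  expect_equal(sort(start(ex)), c(101L, 301L))
  # every reference intron chain survives
  expect_true(all(setdiff(unique(intron_chains(ref)), "") %in%
                    intron_chains(merged)))
})

test_that("a junction-bridging transcript merges two reference genes", {
  ref <- toy_ann(exons_gr("c", "+", c("a.t", "a.t"), "gA", c(1, 201), c(100, 300)),
                 exons_gr("c", "+", "b.t", "gB", 1000, 1200))
  bridge <- toy_ann(exons_gr("c", "+", c("br", "br"), "gBr",
                             c(250, 1000), c(300, 1100)))
  merged <- merge_with_reference(bridge, ref)
  expect_equal(n_genes(merged), 1L)
  tt <- tx_table(merged)
  expect_equal(length(unique(tt$gene_id)), 1L)
  # all three transcripts retained (bridge is novel: chain differs)
  expect_equal(n_transcripts(merged), 3L)
})

test_that("reference merging is idempotent and bounded in gene count", {
  sim <- shared_sim()
  m <- merge_with_reference(sim$annotation, sim$annotation)
  expect_equal(exon_jaccard(m, sim$annotation), 1)
  expect_equal(n_transcripts(m), n_transcripts(sim$annotation))
  expect_equal(n_genes(m), n_genes(sim$annotation))
  for (seed in 1:5) {
    cfg <- simulation_config(seed = 400 + seed, utr_truncation = 0.5,
                             isoform_drop = 0.3, noise_gene_rate = 0.2)
    pred <- perturb_annotation(sim$annotation, cfg)$annotation
    merged <- merge_with_reference(pred, sim$annotation)
    expect_true(all(setdiff(unique(intron_chains(sim$annotation)), "") %in%
                      intron_chains(merged)))
    expect_lte(n_genes(merged), n_genes(sim$annotation) + n_genes(pred))
  }
})

test_that("mono-exonic models merge only when overlapping on the same strand", {
  ref <- toy_ann(exons_gr("c", "+", "r.t", "r", 1000, 1500))
  overlapping <- toy_ann(exons_gr("c", "+", "p.t", "p", 1200, 1700))
  apart <- toy_ann(exons_gr("c", "+", "p.t", "p", 5000, 5400))
  anti <- toy_ann(exons_gr("c", "-", "p.t", "p", 1200, 1700))
  expect_equal(n_transcripts(merge_with_reference(overlapping, ref)), 1L)
  expect_equal(n_transcripts(merge_with_reference(apart, ref)), 2L)
  m_anti <- merge_with_reference(anti, ref)
  expect_equal(n_transcripts(m_anti), 2L)
  expect_equal(n_genes(m_anti), 2L)
})
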