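test_that("simulated genomes hit the target GC and are seed-deterministic", {
  cfg <- simulation_config(seed = 91, n_contigs = 1, contig_length = 100000L,
                           gc_content = 0.5, n_genes = 10)
  sim <- simulate_genome_and_annotation(cfg)
  gc <- sum(Biostrings::letterFrequency(sim$genome, c("G", "C"))) /
    sum(Biostrings::width(sim$genome))
  expect_lt(abs(gc - 0.5), 0.02)
  sim2 <- simulate_genome_and_annotation(cfg)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(ann_exons(sim$annotation), ann_exons(sim2$annotation))
  # zero genes: sequence only
  none <- simulate_genome_and_annotation(
    simulation_config(seed = 91, n_genes = 0))
  expect_equal(n_genes(none$annotation), 0L)
  # overfull genomes refuse to pack
  expect_error(simulate_genome_and_annotation(
    simulation_config(seed = 91, n_contigs = 1, contig_length = 5000L,
                      n_genes = 200)), "packable")
})

test_that("canonical splice sites are written at the configured fraction", {
  cfg <- simulation_config(seed = 14, n_genes = 40, gtag_fraction = 1)
  sim <- simulate_genome_and_annotation(cfg)
  f <- extract_features(sim$annotation, sim$genome)
  expect_equal(sum(f$n_other_introns), 0L)
  expect_gt(sum(f$n_gtag_introns), 0L)
})

test_that("perturbation rates act as documented", {
  sim <- shared_sim()
  # all rates zero: identity
  same <- perturb_annotation(sim$annotation, simulation_config(seed = 1))
  expect_equal(exon_jaccard(same$annotation, sim$annotation), 1)
  expect_equal(nrow(same$changes), 0L)
  # gene_drop = 1: everything gone
  gone <- perturb_annotation(sim$annotation,
                             simulation_config(seed = 1, gene_drop = 1))
  expect_equal(n_genes(gone$annotation), 0L)
  # utr_truncation = 1 with 100 bp trim: terminal exons shrink by 100 (floor 1)
  cfg_t <- simulation_config(seed = 1, utr_truncation = 1, truncation_bp = 100L)
  trimmed <- perturb_annotation(sim$annotation, cfg_t)$annotation
  tt0 <- tx_table(sim$annotation)
  tt1 <- tx_table(trimmed)
  shared <- intersect(tt0$transcript_id, tt1$transcript_id)
  ex0 <- exons_by_tx(sim$annotation)
  for (t in shared[1:10]) {
    first_w <- width(BiocGenerics::sort(ex0[[t]]))[1]
    expect_equal(tt1$start[tt1$transcript_id == t],
                 tt0$start[tt0$transcript_id == t] + min(100L, first_w - 1L))
  }
})

test_that("simulated reads follow transcripts and plant exact noise rates", {
  cfg <- simulation_config(seed = 19, noise_read_rate = 0.2, read_depth = 8000)
  sim <- simulate_genome_and_annotation(cfg)
  reads <- simulate_reads(sim$annotation, cfg)
  frac <- unannotated_read_fraction(reads, sim$annotation)
  expect_lt(abs(frac - 0.2), 0.015)
  # no noise: zero unannotated reads
  cfg0 <- simulation_config(seed = 19, noise_read_rate = 0, read_depth = 1000)
  reads0 <- simulate_reads(sim$annotation, cfg0)
  expect_equal(unannotated_read_fraction(reads0, sim$annotation), 0)
  # spliced reads carry the exact intron of their source transcript
  meta <- attr(reads0, "meta")
  ints <- introns_by_tx(sim$annotation)
  spliced <- names(reads0)[S4Vectors::elementNROWS(reads0) > 1L]
  for (r in head(spliced, 20)) {
    src <- meta$tx[meta$read == r]
    gaps <- txharmonize:::exon_gaps(reads0[[r]])
    expect_true(all(txharmonize:::interval_keys(gaps) %in%
                      txharmonize:::interval_keys(ints[[src]])))
  }
  expect_equal(length(simulate_reads(sim$annotation, cfg, n_reads = 0)), 0L)
})

test_that("expression simulation plants biases and replicate structure", {
  genes <- sprintf("G%05d", 1:30)
  cfg0 <- simulation_config(seed = 23, replicate_noise_sd = 0, bias_fraction = 0)
  e0 <- simulate_expression_matrix(genes, cfg0)
  v <- e0$values
  st <- e0$samples$sex_tissue
  for (tissue in unique(st))
    expect_true(all(v[, st == tissue] == v[, which(st == tissue)[1]]))
  cfg1 <- simulation_config(seed = 23, bias_fraction = 0.5, bias_strength = 10)
  e1 <- simulate_expression_matrix(genes, cfg1)
  bias <- attr(e1, "bias")
  biased <- bias[!is.na(bias$biased_tissue), ]
  for (i in seq_len(nrow(biased))) {
    med <- median_tissue_expression(e1, biased$gene_id[i],
                                    tissues = sexed_tissues())
    expect_equal(names(which.max(med)), biased$biased_tissue[i])
  }
  # two copies of a biased (non-constant) profile correlate perfectly
  med <- median_tissue_expression(e1, biased$gene_id[1],
                                  tissues = sexed_tissues())
  expect_equal(spearman_cor(med, med * 2), 1)
})

test_that("the diverged species plants a bijective ortholog map", {
  cfg <- simulation_config(seed = 29, n_genes = 30, substitution_rate = 0,
                           rearrangement_rate = 0, rbh_dropout = 0)
  sim <- simulate_genome_and_annotation(cfg)
  q <- simulate_ortholog_pair_species(sim, cfg)
  expect_false(any(duplicated(q$pairs$ref_gene)))
  expect_false(any(duplicated(q$pairs$query_gene)))
  expect_equal(nrow(q$pairs), n_genes(sim$annotation))
  # zero divergence: perfect synteny and identity for every pair
  ro <- gene_order(sim$annotation); qo <- gene_order(q$annotation)
  rseq <- transcript_sequences(sim$annotation, sim$genome)
  qseq <- transcript_sequences(q$annotation, q$genome)
  rtt <- tx_table(sim$annotation); qtt <- tx_table(q$annotation)
  set.seed(1)
  for (i in sample(nrow(q$pairs), 8)) {
    p <- q$pairs[i, ]
    expect_equal(synteny_score(p$ref_gene, p$query_gene, q$homology, ro, qo), 1)
    rt <- rtt$transcript_id[rtt$gene_id == p$ref_gene][1]
    qt <- qtt$transcript_id[qtt$gene_id == p$query_gene][1]
    sim_pair <- sequence_similarity(rseq[[rt]], qseq[[qt]])
    expect_equal(unname(sim_pair), c(1, 1))
  }
})

test_that("substitution rate translates into matching sequence identity", {
  cfg <- simulation_config(seed = 37, n_genes = 25, substitution_rate = 0.1)
  sim <- simulate_genome_and_annotation(cfg)
  q <- simulate_ortholog_pair_species(sim, cfg)
  rseq <- transcript_sequences(sim$annotation, sim$genome)
  qseq <- transcript_sequences(q$annotation, q$genome)
  rtt <- tx_table(sim$annotation); qtt <- tx_table(q$annotation)
  ids <- vapply(seq_len(nrow(q$pairs)), function(i) {
    rt <- rtt$transcript_id[rtt$gene_id == q$pairs$ref_gene[i]][1]
    qt <- qtt$transcript_id[qtt$gene_id == q$pairs$query_gene[i]][1]
    sequence_similarity(rseq[[rt]], qseq[[qt]])[["identity_frac"]]
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.9), 0.02)
})

test_that("the synthetic assembler degrades monotonically away from its optimum", {
  sim <- shared_sim()
  opt <- list(c = 3, g = 50)
  asm <- make_synthetic_assembler(sim$annotation, opt,
                                  list(c = c(1, 9), g = c(10, 90)), sim$config)
  expect_equal(exon_jaccard(asm(NULL, opt), sim$annotation), 1)
  # strictly decreasing along single-parameter rays
  along_c <- vapply(c(3, 4, 5, 7, 9), function(v)
    exon_jaccard(asm(NULL, list(c = v, g = 50)), sim$annotation), numeric(1))
  expect_true(all(diff(along_c) < 0))
  along_g <- vapply(c(50, 60, 70, 90), function(v)
    exon_jaccard(asm(NULL, list(c = 3, g = v)), sim$annotation), numeric(1))
  expect_true(all(diff(along_g) < 0))
  expect_error(asm(NULL, list(zz = 1)), "unknown assembler parameter")
  # determinism per (params, seed)
  a1 <- asm(NULL, list(c = 5, g = 30))
  a2 <- asm(NULL, list(c = 5, g = 30))
  expect_identical(ann_exons(a1), ann_exons(a2))
})
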