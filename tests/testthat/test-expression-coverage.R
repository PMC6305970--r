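reads_grl <- function(...) GenomicRanges::GRangesList(...)

test_that("unannotated read fraction counts any-overlap reads as annotated", {
  ann <- toy_ann(exons_gr("c", "+", c("t", "t"), "g", c(1, 301), c(100, 500)))
  inside <- GenomicRanges::GRanges("c", IRanges::IRanges(10, 85), strand = "+")
  outside <- GenomicRanges::GRanges("c", IRanges::IRanges(2000, 2075), strand = "+")
  expect_equal(unannotated_read_fraction(reads_grl(r1 = inside, r2 = inside), ann), 0)
  expect_equal(unannotated_read_fraction(reads_grl(r1 = inside, r2 = outside), ann), 0.5)
  # spliced read with one block inside, one outside -> annotated
  spliced <- GenomicRanges::GRanges("c", IRanges::IRanges(c(480, 2000), c(500, 2050)),
                                    strand = "+")
  expect_equal(unannotated_read_fraction(reads_grl(r1 = spliced), ann), 0)
  # intronic read scores annotated under the span rule, unannotated exon-only
  intronic <- GenomicRanges::GRanges("c", IRanges::IRanges(150, 220), strand = "+")
  expect_equal(unannotated_read_fraction(reads_grl(r1 = intronic), ann), 0)
  expect_equal(unannotated_read_fraction(reads_grl(r1 = intronic), ann,
                                         region = "exon"), 1)
  expect_error(unannotated_read_fraction(reads_grl(), ann), "zero reads")
})

test_that("unannotated region fraction counts covered intergenic bases", {
  ann <- toy_ann(exons_gr("c", "+", "t", "g", 1, 500))
  cl <- c(c = 1000L)
  reads <- reads_grl(r1 = GenomicRanges::GRanges("c", IRanges::IRanges(601, 650),
                                                 strand = "+"))
  expect_equal(unannotated_region_fraction(reads, ann, cl), 50 / 500)
  expect_equal(unannotated_region_fraction(reads_grl(), ann, cl), 0)
  full <- reads_grl(r1 = GenomicRanges::GRanges("c", IRanges::IRanges(501, 1000),
                                                strand = "-"))
  expect_equal(unannotated_region_fraction(full, ann, cl), 1)
  whole <- toy_ann(exons_gr("c", "+", "t", "g", 1, 1000))
  expect_error(unannotated_region_fraction(reads, whole, cl), "entire genome")
})

test_that("region fraction agrees with a per-base mask oracle", {
  set.seed(33)
  sim <- shared_sim()
  cfg <- simulation_config(seed = 77, noise_read_rate = 0.3, read_depth = 800)
  reads <- simulate_reads(sim$annotation, cfg)
  cl <- contig_lengths(sim$genome)
  got <- unannotated_region_fraction(reads, sim$annotation, cl)
  # boolean masks per contig
  spans <- GenomicRanges::reduce(GenomicRanges::granges(tx_spans(sim$annotation)),
                                 ignore.strand = TRUE)
  blocks <- GenomicRanges::granges(BiocGenerics::unlist(reads, use.names = FALSE))
  num <- 0L; den <- 0L
  for (ct in names(cl)) {
    ann_mask <- rep(FALSE, cl[[ct]]); cov_mask <- rep(FALSE, cl[[ct]])
    sp <- spans[as.character(GenomicRanges::seqnames(spans)) == ct]
    for (i in seq_along(sp)) ann_mask[start(sp)[i]:end(sp)[i]] <- TRUE
    bl <- blocks[as.character(GenomicRanges::seqnames(blocks)) == ct]
    for (i in seq_along(bl)) cov_mask[start(bl)[i]:end(bl)[i]] <- TRUE
    num <- num + sum(!ann_mask & cov_mask)
    den <- den + sum(!ann_mask)
  }
  expect_equal(got, num / den)
})

test_that("per-sample evaluation returns NA cells for empty groups", {
  sim <- shared_sim()
  cfg <- simulation_config(seed = 12, noise_read_rate = 0.2, read_depth = 500)
  reads <- simulate_reads(sim$annotation, cfg)
  out <- evaluate_by_sample(list(a = reads, b = GenomicRanges::GRangesList()),
                            sim$annotation, contig_lengths(sim$genome),
                            metadata = data.frame(sample = c("a", "b"),
                                                  sex = c("f", "m"),
                                                  tissue = "head"))
  expect_equal(nrow(out), 2L)
  expect_false(is.na(out$unannotated_read_fraction[out$sample == "a"]))
  expect_true(is.na(out$unannotated_read_fraction[out$sample == "b"]))
  # a complete annotation drives the metric to zero
  done <- evaluate_by_sample(list(a = reads), sim$annotation,
                             contig_lengths(sim$genome))
  expect_gte(done$unannotated_read_fraction, 0)
})

test_that("median tissue expression reduces replicates per sexed tissue", {
  genes <- c("gA", "gB")
  samples <- expand.grid(replicate = 1:3, tissue = c("gonad", "head"),
                         sex = c("f", "m"), stringsAsFactors = FALSE)
  samples$sample_id <- with(samples, paste(sex, tissue, replicate, sep = "_"))
  values <- matrix(0, 2, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  values["gA", samples$sex == "f" & samples$tissue == "gonad"] <- c(2, 4, 6)
  expr <- expression_matrix(values, samples)
  med <- median_tissue_expression(expr, "gA",
                                  tissues = c("f_gonad", "m_head"))
  expect_equal(unname(med["f_gonad"]), 4)
  expect_equal(unname(med["m_head"]), 0)
  expect_equal(unname(median_tissue_expression(expr, "gB", "f_gonad")), 0)
  expect_error(median_tissue_expression(expr, "nope"), "unknown gene")
  expect_equal(length(expression_tissues()), 14L)
  expect_equal(length(sexed_tissues()), 16L)
})

test_that("expression matrices round-trip through TSV with their sidecar", {
  sim <- shared_sim()
  cfg <- simulation_config(seed = 21)
  expr <- simulate_expression_matrix(gene_ids(sim$annotation), cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(expr, f, m)
  back <- read_expression_matrix(f, m)
  expect_equal(back$values, expr$values, tolerance = 1e-8)
  expect_equal(back$samples$sex_tissue, expr$samples$sex_tissue)
})

test_that("BED12 blocks round-trip through write/read", {
  grl <- GenomicRanges::GRangesList(
    a = GenomicRanges::GRanges("c1", IRanges::IRanges(c(11, 101), c(50, 150)),
                               strand = "+"),
    b = GenomicRanges::GRanges("c2", IRanges::IRanges(7, 80), strand = "-"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(grl, f)
  back <- read_bed12(f)
  expect_equal(length(back), 2L)
  expect_equal(start(back[["a"]]), c(11L, 101L))
  expect_equal(end(back[["a"]]), c(50L, 150L))
  expect_equal(as.character(strand(back[["b"]])), "-")
})
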