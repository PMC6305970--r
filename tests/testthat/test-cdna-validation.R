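blocks <- function(contig, strand, starts, ends) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(starts, ends), strand = strand)
}

two_gene_ann <- function() {
  toy_ann(exons_gr("c", "+", c("t1", "t1", "t1"), "g1",
                   c(101, 301, 501), c(200, 400, 600)),
          exons_gr("c", "+", c("t2", "t2"), "g2",
                   c(2001, 2301), c(2100, 2400)),
          exons_gr("c", "-", "t3", "g3", 5000, 5400))
}

test_that("cDNA Jaccard takes the maximum over overlapping transcripts", {
  ann <- two_gene_ann()
  exact <- blocks("c", "+", c(101, 301, 501), c(200, 400, 600))
  expect_equal(cdna_jaccard(exact, ann), 1)
  nothing <- blocks("c", "+", 9000, 9100)
  expect_equal(cdna_jaccard(nothing, ann), 0)
  # two candidates: containment in t1 (100/300) vs near-match of t2
  both <- blocks("c", "+", c(2001, 2301), c(2100, 2390))
  expect_equal(cdna_jaccard(both, ann), 190 / 200)
})

test_that("end classification compares termini against the best-match span", {
  ann <- two_gene_ann()
  expect_equal(classify_ends(blocks("c", "+", c(120, 301), c(200, 380)), ann),
               "within")
  expect_equal(classify_ends(blocks("c", "+", c(51, 301), c(200, 400)), ann),
               "ext5_only")
  expect_equal(classify_ends(blocks("c", "+", c(101, 301), c(200, 650)), ann),
               "ext3_only")
  expect_equal(classify_ends(blocks("c", "+", c(51, 301), c(200, 650)), ann),
               "ext_both")
  expect_equal(classify_ends(blocks("c", "+", 9000, 9150), ann), "intergenic")
  # minus-strand cDNA: 5' is the right terminus
  expect_equal(classify_ends(blocks("c", "-", 4990, 5400), ann), "ext3_only")
  expect_equal(classify_ends(blocks("c", "-", 5000, 5450), ann), "ext5_only")
  # slack tolerates small overhangs
  expect_equal(classify_ends(blocks("c", "+", c(91, 301), c(200, 400)), ann,
                             slack = 20L), "within")
})

test_that("junction classification distinguishes the five categories", {
  ann <- two_gene_ann()
  idx <- cdna_index(ann)
  # exact chain of t1
  expect_equal(classify_junctions(blocks("c", "+", c(101, 301, 501),
                                         c(200, 400, 600)), idx), "all_present")
  # contiguous sub-chain (first intron only)
  expect_equal(classify_junctions(blocks("c", "+", c(150, 301),
                                         c(200, 350)), idx), "all_present")
  # introns from two different genes: all annotated, no single transcript
  expect_equal(classify_junctions(blocks("c", "+", c(101, 301, 2301),
                                         c(200, 2100, 2400)), idx),
               "called_annotated")
  # one annotated intron + one novel
  expect_equal(classify_junctions(blocks("c", "+", c(101, 301, 551),
                                         c(200, 520, 600)), idx),
               "partially_unannotated")
  # novel introns only
  expect_equal(classify_junctions(blocks("c", "+", c(101, 180), c(150, 220)),
                                  idx), "all_unannotated")
  # annotated introns but on the opposite strand
  expect_equal(classify_junctions(blocks("c", "-", c(101, 301, 501),
                                         c(200, 400, 600)), idx), "antisense")
  expect_error(classify_junctions(blocks("c", "+", 101, 200), idx),
               "mono-exonic")
})

test_that("a perfect cDNA is within, all_present and Jaccard 1", {
  sim <- shared_sim()
  idx <- cdna_index(sim$annotation)
  grl <- exons_by_tx(sim$annotation)
  multi <- which(S4Vectors::elementNROWS(grl) > 1L)[1:10]
  for (i in multi) {
    cdna <- grl[[i]]
    expect_equal(cdna_jaccard(cdna, idx), 1)
    expect_equal(classify_ends(cdna, idx), "within")
    expect_equal(classify_junctions(cdna, idx), "all_present")
  }
})

test_that("adding transcripts never demotes an all_present cDNA", {
  sim <- shared_sim()
  ann <- sim$annotation
  half_tx <- transcript_ids(ann)[seq_len(n_transcripts(ann) %/% 2)]
  half <- subset_annotation(ann, transcripts = half_tx)
  idx_half <- cdna_index(half)
  idx_full <- cdna_index(ann)
  grl <- exons_by_tx(half)
  for (t in names(grl)[S4Vectors::elementNROWS(grl) > 1L]) {
    if (classify_junctions(grl[[t]], idx_half) == "all_present")
      expect_equal(classify_junctions(grl[[t]], idx_full), "all_present")
  }
})

test_that("planted category mixes are recovered and partition the cohort", {
  sim <- shared_sim()
  emix <- c(within = 0.78, ext5_only = 0.05, ext3_only = 0.04,
            ext_both = 0.12, intergenic = 0.01)
  cd <- simulate_cdnas(sim, 1500, end_mix = emix)
  idx <- cdna_index(sim$annotation)
  got <- vapply(seq_along(cd), function(i) classify_ends(cd[[i]], idx),
                character(1))
  frac <- table(factor(got, levels = end_categories())) / length(cd)
  expect_equal(sum(frac), 1)
  expect_true(all(abs(frac[names(emix)] - emix) <= 0.01))
  jmix <- c(all_present = 0.78, called_annotated = 0.10,
            partially_unannotated = 0.10, all_unannotated = 0.01,
            antisense = 0.01)
  cj <- simulate_cdnas(sim, 1500, junction_mix = jmix)
  gotj <- vapply(seq_along(cj), function(i) classify_junctions(cj[[i]], idx),
                 character(1))
  fj <- table(factor(gotj, levels = junction_categories())) / length(cj)
  expect_equal(sum(fj), 1)
  expect_true(all(abs(fj[names(jmix)] - jmix) <= 0.01))
})

test_that("the validation report contrasts annotations and sums to one", {
  sim <- shared_sim()
  cfg <- simulation_config(seed = 42, utr_truncation = 0.6, gene_drop = 0.2)
  old <- perturb_annotation(sim$annotation, cfg)$annotation
  cd <- simulate_cdnas(sim, 300, end_mix = c(within = 1))
  rep <- validation_report(cd, old, sim$annotation)
  expect_equal(sum(rep$new$ends$fraction), 1)
  expect_equal(sum(rep$old$ends$fraction), 1)
  expect_equal(sum(rep$new$junctions$fraction), 1)
  # cDNAs drawn from the new annotation score 1 against it
  expect_true(all(rep$new$jaccard == 1))
  expect_equal(rep$new$ends$fraction[rep$new$ends$category == "within"], 1)
  # and strictly worse against the degraded legacy annotation
  expect_lt(mean(rep$old$jaccard), 1)
  expect_error(validation_report(GenomicRanges::GRangesList(), old,
                                 sim$annotation), "empty")
})
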