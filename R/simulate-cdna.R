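#' Simulate a full-length cDNA cohort with planted categories
#'
#' Generates spliced cDNA alignments from an annotation with a planted mix
#' of either end categories (see [classify_ends()]) or junction categories
#' (see [classify_junctions()]). Per-category templates are constructed
#' from the annotation's transcripts — exact copies for `within`/
#' `all_present`, terminal extensions (+30 bp) for the `ext*` classes,
#' intergenic placements, non-contiguous annotated-junction combinations,
#' novel introns carved into long exons, and strand flips for `antisense` —
#' then sampled with replacement to the requested counts
#' (`round(n * fraction)`, last category absorbing the remainder).
#'
#' @param truth Output of [simulate_genome_and_annotation()] (or any list
#'   with `annotation` and `config`).
#' @param n Cohort size.
#' @param end_mix Named fractions over [end_categories()] (exclusive with
#'   `junction_mix`).
#' @param junction_mix Named fractions over [junction_categories()].
#' @return A `GRangesList` of cDNA block sets; attribute `"truth"` holds
#'   the planted category per cDNA.
#' @export
simulate_cdnas <- function(truth, n, end_mix = NULL, junction_mix = NULL) {
  config <- truth$config
  ann <- truth$annotation
  set.seed(.sim_seed(config, 6L))
  if (is.null(end_mix) == is.null(junction_mix))
    stop("supply exactly one of end_mix or junction_mix")
  mix <- if (is.null(end_mix)) junction_mix else end_mix
  valid <- if (is.null(end_mix)) junction_categories() else end_categories()
  if (!all(names(mix) %in% valid) || abs(sum(mix) - 1) > 1e-8)
    stop("mix must be named fractions over the category vocabulary, summing to 1")
  templates <- if (is.null(end_mix))
    .junction_templates(ann) else .end_templates(ann, config)
  counts <- stats::setNames(round(n * mix), names(mix))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  rows <- list()
  truth_cat <- character(0)
  idx <- 0L
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k == 0L) next
    tpl <- templates[[cat]]
    if (length(tpl) == 0L) stop("no template available for category: ", cat)
    pick <- sample(length(tpl), k, replace = TRUE)
    picked <- tpl[pick]
    nb <- vapply(picked, function(t) length(t$start), integer(1))
    ids <- sprintf("cdna%06d", idx + seq_len(k))
    rows[[length(rows) + 1L]] <- data.frame(
      contig = rep(vapply(picked, `[[`, character(1), "contig"), nb),
      start = unlist(lapply(picked, `[[`, "start")),
      end = unlist(lapply(picked, `[[`, "end")),
      strand = rep(vapply(picked, `[[`, character(1), "strand"), nb),
      cdna = rep(ids, nb), stringsAsFactors = FALSE)
    truth_cat <- c(truth_cat, rep(cat, k))
    idx <- idx + k
  }
  df <- do.call(rbind, rows)
  gr <- makeGRangesFromDataFrame(df, keep.extra.columns = TRUE,
                                 seqnames.field = "contig")
  out <- GenomicRanges::split(granges(gr), mcols(gr)$cdna)
  out <- out[unique(df$cdna)]
  attr(out, "truth") <- data.frame(cdna_id = unique(df$cdna),
                                   category = truth_cat,
                                   stringsAsFactors = FALSE)
  out
}

# template = list(contig, start, end, strand) of block coordinates
.tpl <- function(contig, start, end, strand) {
  list(contig = contig, start = as.integer(start), end = as.integer(end),
       strand = strand)
}

.end_templates <- function(ann, config) {
  grl <- exons_by_tx(ann)
  delta <- 30L
  tpl <- list(within = list(), ext5_only = list(), ext3_only = list(),
              ext_both = list(), intergenic = list())
  # extensions must clear every isoform's span: use the span-defining
  # transcript of each gene as the template source
  tt <- tx_table(ann)
  g_start <- tapply(tt$start, tt$gene_id, min)[tt$gene_id]
  g_end <- tapply(tt$end, tt$gene_id, max)[tt$gene_id]
  primary <- tt$transcript_id[tt$start == g_start & tt$end == g_end]
  grl <- grl[names(grl) %in% primary]
  for (i in seq_along(grl)) {
    ex <- BiocGenerics::sort(grl[[i]])
    ct <- as.character(seqnames(ex))[1]
    st <- as.character(strand(ex))[1]
    s <- start(ex); e <- end(ex)
    if (s[1] - delta < 1L) next
    tpl$within[[length(tpl$within) + 1L]] <- .tpl(ct, s, e, st)
    s5 <- s; e5 <- e
    if (st == "+") s5[1] <- s5[1] - delta else e5[length(e5)] <- e5[length(e5)] + delta
    tpl$ext5_only[[length(tpl$ext5_only) + 1L]] <- .tpl(ct, s5, e5, st)
    s3 <- s; e3 <- e
    if (st == "+") e3[length(e3)] <- e3[length(e3)] + delta else s3[1] <- s3[1] - delta
    tpl$ext3_only[[length(tpl$ext3_only) + 1L]] <- .tpl(ct, s3, e3, st)
    sb <- s; eb <- e
    sb[1] <- sb[1] - delta
    eb[length(eb)] <- eb[length(eb)] + delta
    tpl$ext_both[[length(tpl$ext_both) + 1L]] <- .tpl(ct, sb, eb, st)
  }
  gaps <- .intergenic_regions(ann, config)
  gaps <- gaps[width(gaps) >= 200L]
  for (i in seq_along(gaps)) {
    tpl$intergenic[[i]] <- .tpl(as.character(seqnames(gaps))[i],
                                start(gaps)[i] + 20L,
                                start(gaps)[i] + 169L,
                                sample(c("+", "-"), 1))
  }
  tpl
}

.junction_templates <- function(ann) {
  grl <- exons_by_tx(ann)
  tpl <- list(all_present = list(), called_annotated = list(),
              partially_unannotated = list(), all_unannotated = list(),
              antisense = list())
  known <- unique(interval_keys(
    BiocGenerics::unlist(introns_by_tx(ann), use.names = FALSE)))
  novel_free <- function(ct, st, ns, ne) {
    # novel intron must collide with no annotated intron on either strand
    !any(paste0(ct, ":+:", ns, "-", ne) %in% known) &&
      !any(paste0(ct, ":-:", ns, "-", ne) %in% known)
  }
  for (i in seq_along(grl)) {
    ex <- BiocGenerics::sort(grl[[i]])
    if (length(ex) < 2L) next
    ct <- as.character(seqnames(ex))[1]
    st <- as.character(strand(ex))[1]
    s <- start(ex); e <- end(ex)
    tpl$all_present[[length(tpl$all_present) + 1L]] <- .tpl(ct, s, e, st)
    tpl$antisense[[length(tpl$antisense) + 1L]] <-
      .tpl(ct, s, e, if (st == "+") "-" else "+")
    ints <- exon_gaps(ex)
    if (length(ints) >= 3L) {
      # introns 1 and 3 of one chain: each annotated, chain in no transcript
      j1 <- c(start(ints)[1], end(ints)[1])
      j3 <- c(start(ints)[3], end(ints)[3])
      tpl$called_annotated[[length(tpl$called_annotated) + 1L]] <-
        .tpl(ct, c(s[1], j1[2] + 1L, j3[2] + 1L),
             c(j1[1] - 1L, j3[1] - 1L, e[length(e)]), st)
    }
    last_w <- e[length(e)] - s[length(s)] + 1L
    if (last_w >= 120L) {
      ns <- s[length(s)] + 40L; ne <- ns + 39L
      if (novel_free(ct, st, ns, ne)) {
        # annotated intron 1 + a novel intron carved into the last exon
        tpl$partially_unannotated[[length(tpl$partially_unannotated) + 1L]] <-
          .tpl(ct, c(s[1], end(ints)[1] + 1L, ne + 1L),
               c(start(ints)[1] - 1L, ns - 1L, e[length(e)]), st)
        # novel intron only, inside the last exon
        tpl$all_unannotated[[length(tpl$all_unannotated) + 1L]] <-
          .tpl(ct, c(s[length(s)], ne + 1L), c(ns - 1L, e[length(e)]), st)
      }
    }
  }
  tpl
}
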