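#' Jaccard index over genomic bases
#'
#' \eqn{|A \cap B| / |A \cup B|} computed over genomic base positions. The
#' canonical mode is stranded (the supported RNA-seq protocol is stranded);
#' `stranded = FALSE` reproduces the BEDTools default for cross-checks.
#'
#' @param a,b `GRanges` (arbitrary; reduced internally to disjoint base sets).
#' @param stranded Intersect per strand (default) or ignoring strand.
#' @return A number in `[0, 1]`.
#' @examples
#' a <- GenomicRanges::GRanges("c1:1-100:+")
#' b <- GenomicRanges::GRanges("c1:51-150:+")
#' jaccard_bases(a, b)  # 50 / 150
#' @export
jaccard_bases <- function(a, b, stranded = TRUE) {
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard undefined: both base sets are empty")
  ab <- .harmonize_pair(a, b, stranded)
  inter <- sum(width(GenomicRanges::intersect(ab$a, ab$b)))
  uni <- sum(width(GenomicRanges::union(ab$a, ab$b)))
  inter / uni
}

.harmonize_pair <- function(a, b, stranded) {
  a <- granges(a); b <- granges(b)
  if (!stranded) {
    strand(a) <- "*"
    strand(b) <- "*"
  }
  lev <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lev
  seqlevels(b) <- lev
  list(a = reduce(a), b = reduce(b))
}

#' Exon-level Jaccard between two annotations
#'
#' The similarity objective used throughout optimization: the base Jaccard
#' of the two unique-exon sets (duplicate exon coordinates across isoforms
#' collapse before the union, so duplicating a transcript changes nothing).
#'
#' @param ann_a,ann_b [AnnotationSet-class] objects on the same genome.
#' @inheritParams jaccard_bases
#' @return A number in `[0, 1]`.
#' @export
exon_jaccard <- function(ann_a, ann_b, stranded = TRUE) {
  jaccard_bases(ann_exons(ann_a), ann_exons(ann_b), stranded = stranded)
}

#' Transcript-level Jaccard
#'
#' Base Jaccard of two exonic block sets (a transcript model or a spliced
#' cDNA alignment). Different contigs, or different strands in stranded
#' mode, score 0 by definition.
#'
#' @param t,u `GRanges` of exonic blocks (single transcript each).
#' @inheritParams jaccard_bases
#' @return A number in `[0, 1]`.
#' @export
transcript_jaccard <- function(t, u, stranded = TRUE) {
  if (length(t) == 0L && length(u) == 0L)
    stop("Jaccard undefined: both block sets are empty")
  if (length(t) == 0L || length(u) == 0L) return(0)
  if (as.character(seqnames(t)[1]) != as.character(seqnames(u)[1])) return(0)
  if (stranded &&
      as.character(strand(t)[1]) != as.character(strand(u)[1])) return(0)
  jaccard_bases(t, u, stranded = stranded)
}

#' Shared splice junctions between two transcripts
#'
#' Counts introns with exactly matching coordinates (same contig and
#' strand); no positional slack is allowed.
#'
#' @param t,u `GRanges` of exonic blocks (single transcript each).
#' @return Integer, at most `min(#introns(t), #introns(u))`.
#' @export
shared_junctions <- function(t, u) {
  it <- unique(interval_keys(exon_gaps(granges(t))))
  iu <- unique(interval_keys(exon_gaps(granges(u))))
  length(intersect(it, iu))
}

#' Best-matching subject gene per query gene
#'
#' For every query gene, the subject gene maximizing the gene-level exonic
#' base Jaccard (union of the gene's unique exonic bases), together with the
#' maximum shared-junction count over transcript pairs of the best pair.
#' Ties break by higher shared junctions, then lexicographic subject id.
#' Queries overlapping no subject get Jaccard 0 and an empty subject id.
#'
#' @param query,subject [AnnotationSet-class] objects on the same genome.
#' @param stranded Stranded overlap and Jaccard (default).
#' @return `data.frame` with columns `query_gene_id`, `subject_gene_id`,
#'   `jaccard`, `shared_junctions`.
#' @export
best_match_table <- function(query, subject, stranded = TRUE) {
  qg <- exons_by_gene(query)
  sg <- exons_by_gene(subject)
  lev <- union(seqlevels(qg), seqlevels(sg))
  seqlevels(qg) <- lev
  seqlevels(sg) <- lev
  qtx <- exons_by_tx(query)
  stx <- exons_by_tx(subject)
  q_tt <- tx_table(query)
  s_tt <- tx_table(subject)
  hits <- findOverlaps(qg, sg, ignore.strand = !stranded)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  out <- data.frame(query_gene_id = names(qg),
                    subject_gene_id = "",
                    jaccard = 0,
                    shared_junctions = 0L,
                    stringsAsFactors = FALSE)
  pair_sj <- function(qgene, sgene) {
    qt <- q_tt$transcript_id[q_tt$gene_id == qgene]
    st <- s_tt$transcript_id[s_tt$gene_id == sgene]
    best <- 0L
    for (a in qt) for (b in st)
      best <- max(best, shared_junctions(qtx[[a]], stx[[b]]))
    best
  }
  for (i in seq_along(qg)) {
    cand <- sh[qh == i]
    if (length(cand) == 0L) next
    jac <- vapply(cand, function(j)
      jaccard_bases(qg[[i]], sg[[j]], stranded = stranded), numeric(1))
    top <- cand[jac == max(jac)]
    if (length(top) > 1L) {
      sj <- vapply(top, function(j) pair_sj(names(qg)[i], names(sg)[j]), integer(1))
      top <- top[sj == max(sj)]
      top <- top[order(names(sg)[top])][1]
    }
    out$subject_gene_id[i] <- names(sg)[top]
    out$jaccard[i] <- max(jac)
    out$shared_junctions[i] <- pair_sj(names(qg)[i], names(sg)[top])
  }
  out
}
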