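#' Merge filtered gene models with the reference annotation
#'
#' Builds the updated annotation while keeping every reference gene model:
#' \itemize{
#'   \item a filtered multi-exon transcript sharing the same structure for
#'     all introns (identical intron chain, same strand) with a reference
#'     transcript is replaced, together with that reference transcript, by
#'     one transcript whose exon set is the base union of both — extending
#'     terminal exons (typically UTRs) while preserving every junction;
#'   \item a filtered mono-exonic transcript merges with a reference
#'     mono-exonic transcript only when their exons overlap on the same
#'     strand (an empty intron chain alone is never a match);
#'   \item unmatched filtered transcripts are added as novel;
#'   \item gene membership is then recomputed as connected components of
#'     same-strand exonic overlap, so a novel transcript bridging two
#'     reference genes merges them into one gene model, and transcripts
#'     overlapping nothing found new genes.
#' }
#' Duplicate transcript structures are collapsed (reference ids win). The
#' operation is idempotent and never loses a reference intron chain.
#'
#' @param filtered The SVM-filtered predicted [AnnotationSet-class].
#' @param ref The reference [AnnotationSet-class].
#' @param species_code Optional two-letter code: when given, the result is
#'   re-identified with [assign_yo_ids()]; otherwise reference gene ids are
#'   kept where a component contains reference transcripts and novel genes
#'   get `NOVG` ids.
#' @return The merged [AnnotationSet-class].
#' @export
merge_with_reference <- function(filtered, ref, species_code = NULL) {
  f_grl <- exons_by_tx(filtered)
  r_grl <- exons_by_tx(ref)
  f_chain <- .chain_keys_grl(f_grl)
  r_chain <- .chain_keys_grl(r_grl)
  r_tt <- tx_table(ref)

  r_exons <- lapply(seq_along(r_grl), function(i) granges(r_grl[[i]]))
  names(r_exons) <- names(r_grl)
  consumed <- character(0)

  for (ftx in names(f_grl)) {
    fex <- f_grl[[ftx]]
    key <- f_chain[[ftx]]
    if (key != "") {
      cand <- names(r_chain)[r_chain == key]
    } else {
      hits <- findOverlaps(fex, r_grl, ignore.strand = FALSE)
      cand <- names(r_grl)[unique(subjectHits(hits))]
      cand <- cand[r_chain[cand] == ""]
    }
    if (length(cand) == 0L) next
    if (length(cand) > 1L) {
      jac <- vapply(cand, function(rtx)
        transcript_jaccard(fex, r_grl[[rtx]]), numeric(1))
      cand <- cand[order(-jac, cand)][1]
    }
    r_exons[[cand]] <- reduce(c(r_exons[[cand]], granges(fex)))
    consumed <- c(consumed, ftx)
  }

  novel <- setdiff(names(f_grl), consumed)
  all_tx <- c(r_exons, lapply(novel, function(t) granges(f_grl[[t]])))
  names(all_tx) <- c(names(r_exons), novel)

  # collapse duplicate structures, reference ids first
  struct <- vapply(all_tx, function(g)
    paste(interval_keys(BiocGenerics::sort(g)), collapse = "|"), character(1))
  ord <- order(!names(all_tx) %in% names(r_exons))
  keep <- names(all_tx)[ord][!duplicated(struct[ord])]
  all_tx <- all_tx[keep]

  n_ex <- vapply(all_tx, length, integer(1))
  flat <- BiocGenerics::unlist(GRangesList(unname(all_tx)), use.names = FALSE)
  mcols(flat)$transcript_id <- rep(names(all_tx), n_ex)
  mcols(flat)$gene_id <- "tmp"
  flat <- .regroup_genes(flat, prefix = "NOVG")

  # components containing reference transcripts keep a reference gene id
  comp <- mcols(flat)$gene_id
  is_ref <- mcols(flat)$transcript_id %in% r_tt$transcript_id
  remap <- character(0)
  for (cp in unique(comp)) {
    rtx <- unique(mcols(flat)$transcript_id[comp == cp & is_ref])
    if (length(rtx) > 0L)
      remap[cp] <- min(r_tt$gene_id[r_tt$transcript_id %in% rtx])
  }
  hit <- comp %in% names(remap)
  mcols(flat)$gene_id[hit] <- unname(remap[comp[hit]])

  out <- AnnotationSet(flat)
  if (!is.null(species_code)) out <- assign_yo_ids(out, species_code)
  out
}
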