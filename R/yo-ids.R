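#' Assign YO-style universal ids
#'
#' Re-identifies every gene and transcript with the harmonized id scheme
#' used across the re-annotated genomes: `YOgn<CODE><NNNNN>` for genes and
#' `YOtr<CODE><NNNNN>` for transcripts, where `<CODE>` is a two-letter
#' species code (e.g. `YA` for *D. yakuba*, giving `YOgnYA12345`) and
#' `<NNNNN>` a zero-padded 5-digit number. Numbering is deterministic:
#' genes are ordered by (contig, span start, span end, old id), transcripts
#' within that ordering by (start, end, old id).
#'
#' @param ann An [AnnotationSet-class].
#' @param species_code Two-letter code; the harmonized set is
#'   `ME, YA, AN, PS, PE, WI, MO, VI, GR`, but any two capital letters work.
#' @param start_index First number assigned (genes and transcripts each).
#' @return A re-identified [AnnotationSet-class]; old ids are kept in
#'   `old_gene_id`/`old_transcript_id` metadata columns.
#' @export
assign_yo_ids <- function(ann, species_code, start_index = 1L) {
  if (!grepl("^[A-Z]{2}$", species_code))
    stop("species_code must be two capital letters, e.g. 'ME' or 'GR'")
  ex <- ann@exons
  if (length(ex) == 0L) return(ann)
  tt <- tx_table(ann)
  gt <- data.frame(gene_id = unique(tt$gene_id), stringsAsFactors = FALSE)
  gt$contig <- tt$contig[match(gt$gene_id, tt$gene_id)]
  gt$start <- vapply(gt$gene_id, function(g) min(tt$start[tt$gene_id == g]), integer(1))
  gt$end <- vapply(gt$gene_id, function(g) max(tt$end[tt$gene_id == g]), integer(1))
  gt <- gt[order(gt$contig, gt$start, gt$end, gt$gene_id), , drop = FALSE]
  g_num <- start_index + seq_len(nrow(gt)) - 1L
  tt <- tt[order(match(tt$gene_id, gt$gene_id), tt$start, tt$end,
                 tt$transcript_id), , drop = FALSE]
  t_num <- start_index + seq_len(nrow(tt)) - 1L
  if (max(g_num, t_num) > 99999L)
    stop("id numbering exceeds 5 digits (", max(g_num, t_num), ")")
  new_gene <- stats::setNames(sprintf("YOgn%s%05d", species_code, g_num), gt$gene_id)
  new_tx <- stats::setNames(sprintf("YOtr%s%05d", species_code, t_num),
                            tt$transcript_id)
  mc <- mcols(ex)
  mc$old_gene_id <- mc$gene_id
  mc$old_transcript_id <- mc$transcript_id
  mc$gene_id <- unname(new_gene[mc$gene_id])
  mc$transcript_id <- unname(new_tx[mc$transcript_id])
  mcols(ex) <- mc
  AnnotationSet(ex)
}
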