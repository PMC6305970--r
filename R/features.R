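#' Extract sequences for ranges from an in-memory genome
#'
#' @param genome Named `DNAStringSet` (one entry per contig).
#' @param gr `GRanges`; minus-strand ranges are reverse-complemented.
#' @return `DNAStringSet`, one sequence per range.
#' @export
seq_for_granges <- function(genome, gr) {
  contigs <- as.character(seqnames(gr))
  missing <- setdiff(unique(contigs), names(genome))
  if (length(missing) > 0L)
    stop("contig(s) missing from genome: ", paste(missing, collapse = ", "))
  seqs <- DNAStringSet(vapply(seq_along(gr), function(i)
    as.character(subseq(genome[[contigs[i]]], start(gr)[i], end(gr)[i])),
    character(1)))
  neg <- as.character(strand(gr)) == "-"
  if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
  seqs
}

#' Spliced transcript sequences
#'
#' Concatenates exon sequences in transcript orientation (5' to 3').
#'
#' @param ann An [AnnotationSet-class].
#' @param genome Named `DNAStringSet`.
#' @param transcripts Transcript ids (default all).
#' @return Named `DNAStringSet`.
#' @export
transcript_sequences <- function(ann, genome, transcripts = transcript_ids(ann)) {
  grl <- exons_by_tx(ann)[transcripts]
  out <- DNAStringSet(vapply(seq_along(grl), function(i) {
    ex <- BiocGenerics::sort(grl[[i]])
    s <- seq_for_granges(genome, ex)
    if (as.character(strand(ex)[1]) == "-") s <- rev(s)
    paste(as.character(s), collapse = "")
  }, character(1)))
  names(out) <- names(grl)
  out
}

.gc_fraction <- function(seqs) {
  if (length(seqs) == 0L) return(0)
  counts <- colSums(letterFrequency(seqs, c("G", "C", "A", "T")))
  tot <- sum(counts)
  if (tot == 0) return(0)
  (counts[["G"]] + counts[["C"]]) / tot
}

#' Gene feature vectors for the model filter
#'
#' The 8-feature representation of a gene model used by the SVM filter:
#' isoform number; mean length and GC fraction of the gene's unique exons;
#' mean length and GC fraction of its unique introns (0 for mono-exonic
#' genes); counts of canonical GT-AG and non-GT-AG introns (donor/acceptor
#' dinucleotides read on the coding strand); and the median normalized
#' expression in the 14 sexed tissues. "Unique" deduplicates identical
#' coordinates across isoforms; per-gene scalars are means over the unique
#' set (`collapse = "median"` or `"total"` are available alternatives).
#'
#' @param ann An [AnnotationSet-class].
#' @param genome Named `DNAStringSet` covering the annotation contigs.
#' @param expr Optional [expression_matrix()]; genes absent from it get a
#'   zero expression vector with a warning.
#' @param genes Gene ids to featurize (default all).
#' @param tissues Sexed-tissue set for the expression block.
#' @param collapse How variable-length exon/intron lists collapse to a
#'   scalar: `"mean"` (default), `"median"` or `"total"`.
#' @return `data.frame`, one row per gene (rownames = gene ids), columns
#'   `isoform_number`, `exon_length`, `exon_gc`, `intron_length`,
#'   `intron_gc`, `n_gtag_introns`, `n_other_introns`, then one
#'   `expr_<sexed tissue>` column per tissue.
#' @export
extract_features <- function(ann, genome, expr = NULL, genes = gene_ids(ann),
                             tissues = expression_tissues(),
                             collapse = c("mean", "median", "total")) {
  collapse <- match.arg(collapse)
  agg <- switch(collapse, mean = mean, median = stats::median, total = sum)
  tt <- tx_table(ann)
  ex <- ann_exons(ann)
  ints <- introns_by_tx(ann)
  feat <- data.frame(row.names = genes)
  feat$isoform_number <- vapply(genes, function(g)
    sum(tt$gene_id == g), integer(1))
  if (any(feat$isoform_number == 0L))
    stop("unknown gene(s): ",
         paste(genes[feat$isoform_number == 0L], collapse = ", "))
  n <- length(genes)
  feat$exon_length <- numeric(n)
  feat$exon_gc <- numeric(n)
  feat$intron_length <- numeric(n)
  feat$intron_gc <- numeric(n)
  feat$n_gtag_introns <- integer(n)
  feat$n_other_introns <- integer(n)
  for (i in seq_len(n)) {
    g <- genes[i]
    gex <- ex[mcols(ex)$gene_id == g]
    uex <- gex[!duplicated(interval_keys(gex))]
    feat$exon_length[i] <- agg(width(uex))
    feat$exon_gc[i] <- .gc_fraction(seq_for_granges(genome, uex))
    tx <- tt$transcript_id[tt$gene_id == g]
    gint <- BiocGenerics::unlist(ints[tx], use.names = FALSE)
    if (length(gint) == 0L) next
    uint <- gint[!duplicated(interval_keys(gint))]
    feat$intron_length[i] <- agg(width(uint))
    iseq <- seq_for_granges(genome, uint)
    feat$intron_gc[i] <- .gc_fraction(iseq)
    chr <- as.character(iseq)
    gtag <- substr(chr, 1, 2) == "GT" &
      substr(chr, nchar(chr) - 1, nchar(chr)) == "AG"
    feat$n_gtag_introns[i] <- sum(gtag)
    feat$n_other_introns[i] <- sum(!gtag)
  }
  expr_block <- matrix(0, nrow = n, ncol = length(tissues),
                       dimnames = list(genes, paste0("expr_", tissues)))
  if (!is.null(expr)) {
    present <- genes %in% rownames(expr$values)
    if (any(!present))
      warning(sum(!present), " gene(s) absent from the expression matrix; ",
              "zero expression assumed")
    if (any(present)) {
      med <- median_tissue_matrix(expr, genes[present], tissues)
      med[is.na(med)] <- 0
      expr_block[present, ] <- med
    }
  }
  cbind(feat, as.data.frame(expr_block))
}
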