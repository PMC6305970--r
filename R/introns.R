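#' Derive introns from exon structure
#'
#' Introns are the gaps between consecutive exons of a transcript, on the
#' transcript's contig and strand. Mono-exonic transcripts have none.
#'
#' @param ann An [AnnotationSet-class].
#' @param transcript_id A transcript id present in `ann`.
#' @return A `GRanges` of introns, ordered by position (empty for
#'   mono-exonic transcripts).
#' @examples
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)),
#'   strand = "+", transcript_id = "t1", gene_id = "g1")
#' derive_introns(AnnotationSet(ex), "t1")  # one intron, 101..200
#' @export
derive_introns <- function(ann, transcript_id) {
  stopifnot(transcript_id %in% transcript_ids(ann))
  ex <- ann@exons[mcols(ann@exons)$transcript_id == transcript_id]
  exon_gaps(granges(ex))
}

# introns of a single transcript's exon GRanges (sorted by start)
exon_gaps <- function(ex) {
  if (length(ex) < 2L) return(GRanges())
  ex <- BiocGenerics::sort(ex)
  GRanges(seqnames(ex)[-1], IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1] - 1L),
          strand = strand(ex)[-1])
}

#' Introns for every transcript
#' @param ann An [AnnotationSet-class].
#' @return A `GRangesList` named by transcript id (empty elements for
#'   mono-exonic transcripts).
#' @export
introns_by_tx <- function(ann) {
  grl <- exons_by_tx(ann)
  spans <- BiocGenerics::unlist(range(grl))
  GenomicRanges::psetdiff(spans, grl)
}

# "contig:strand:start-end" keys for a GRanges
interval_keys <- function(gr) {
  if (length(gr) == 0L) return(character())
  paste0(as.character(seqnames(gr)), ":", as.character(strand(gr)), ":",
         start(gr), "-", end(gr))
}

#' Intron-chain keys
#'
#' The ordered list of intron coordinates is the identity key used for
#' transcript matching ("same structure for all introns"). Mono-exonic
#' transcripts get the empty string.
#'
#' @param ann An [AnnotationSet-class].
#' @return Named character vector, one key per transcript.
#' @export
intron_chains <- function(ann) {
  ints <- introns_by_tx(ann)
  n <- S4Vectors::elementNROWS(ints)
  flat <- BiocGenerics::unlist(ints, use.names = FALSE)
  keys <- character(length(ints))
  if (length(flat) > 0L) {
    per <- paste0(start(flat), "-", end(flat))
    keys[n > 0L] <- vapply(split(per, rep(seq_along(ints), n)),
                           paste, character(1), collapse = "|")
  }
  multi <- n > 0L
  contig <- vapply(seq_along(ints), function(i)
    if (multi[i]) as.character(seqnames(ints[[i]])[1]) else "", character(1))
  str <- vapply(seq_along(ints), function(i)
    if (multi[i]) as.character(strand(ints[[i]])[1]) else "", character(1))
  keys[multi] <- paste0(contig[multi], ":", str[multi], ":", keys[multi])
  stats::setNames(keys, names(ints))
}

#' Unique introns per gene
#' @param ann An [AnnotationSet-class].
#' @param genes Gene ids (default all).
#' @return Named integer vector: number of distinct intron coordinates
#'   across each gene's transcripts.
#' @export
unique_intron_count <- function(ann, genes = gene_ids(ann)) {
  ints <- introns_by_tx(ann)
  tt <- tx_table(ann)
  out <- stats::setNames(integer(length(genes)), genes)
  for (g in genes) {
    tx <- tt$transcript_id[tt$gene_id == g]
    if (length(tx) == 0L) stop("unknown gene: ", g)
    keys <- unique(interval_keys(BiocGenerics::unlist(ints[tx], use.names = FALSE)))
    out[g] <- length(keys)
  }
  out
}
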