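#' Annotation container
#'
#' An `AnnotationSet` holds a gene annotation as a single exon-level
#' [GenomicRanges::GRanges] whose metadata columns `transcript_id` and
#' `gene_id` group exons into transcripts and transcripts into genes.
#' Coordinates follow the Bioconductor convention (1-based, closed).
#'
#' Invariants enforced by the validity method: every exon carries a
#' transcript and gene id; all exons of a transcript lie on one contig and
#' one explicit strand (`+` or `-`); exons within a transcript are
#' non-overlapping; each transcript belongs to exactly one gene.
#'
#' @slot exons A `GRanges` with `transcript_id` and `gene_id` metadata
#'   columns (additional columns such as `fpkm`/`tpm` are preserved).
#' @export
setClass("AnnotationSet", representation(exons = "GRanges"))

setValidity("AnnotationSet", function(object) {
  ex <- object@exons
  mc <- mcols(ex)
  if (!all(c("transcript_id", "gene_id") %in% colnames(mc)))
    return("exons must carry 'transcript_id' and 'gene_id' metadata columns")
  if (length(ex) == 0L) return(TRUE)
  if (anyNA(mc$transcript_id) || anyNA(mc$gene_id))
    return("transcript_id/gene_id must not contain NA")
  if (any(as.character(strand(ex)) == "*")) {
    bad <- unique(mc$transcript_id[as.character(strand(ex)) == "*"])
    return(paste0("unstranded transcript(s): ", paste(head(bad, 3), collapse = ", "),
                  " (explicit '+' or '-' strand is required)"))
  }
  key <- paste(as.character(seqnames(ex)), as.character(strand(ex)))
  if (any(tapply(key, mc$transcript_id, function(k) length(unique(k))) > 1L))
    return("all exons of a transcript must share one contig and strand")
  g_per_tx <- tapply(mc$gene_id, mc$transcript_id, function(g) length(unique(g)))
  if (any(g_per_tx > 1L))
    return("a transcript_id maps to more than one gene_id")
  TRUE
})

#' Construct an AnnotationSet from exon ranges
#'
#' Exons are sorted by position within each transcript. Overlapping or
#' book-ended exons within one transcript are merged with a warning (some
#' GFF dialects emit overlapping exon/CDS records).
#'
#' @param exons `GRanges` with `transcript_id` and `gene_id` metadata columns.
#' @return An [AnnotationSet-class] object.
#' @export
AnnotationSet <- function(exons) {
  stopifnot(is(exons, "GRanges"))
  if (length(exons) > 0L) {
    exons <- exons[order(mcols(exons)$transcript_id, start(exons))]
    n <- length(exons)
    tx <- mcols(exons)$transcript_id
    touches <- n > 1L & tx[-1] == tx[-n] & start(exons)[-1] <= end(exons)[-n] + 1L
    if (any(touches)) {
      # merge overlapping (or book-ended) exons within a transcript
      bad_tx <- unique(tx[-1][touches])
      affected <- tx %in% bad_tx
      rd <- tapply(which(affected), tx[affected], function(i) {
        r <- reduce(exons[i], with.revmap = TRUE)
        mcols(r) <- mcols(exons)[i[vapply(mcols(r)$revmap, `[`, integer(1), 1L)],
                                 , drop = FALSE]
        r
      }, simplify = FALSE)
      merged <- do.call(c, unname(as.list(rd)))
      warning("overlapping exons within a transcript were merged (",
              sum(affected) - length(merged), " exon(s) collapsed)")
      exons <- c(exons[!affected], merged)
    }
    exons <- exons[order(mcols(exons)$gene_id, mcols(exons)$transcript_id,
                         start(exons))]
  }
  new("AnnotationSet", exons = exons)
}

setMethod("show", "AnnotationSet", function(object) {
  ex <- object@exons
  cat("AnnotationSet:", n_genes(object), "genes,", n_transcripts(object),
      "transcripts,", length(ex), "exons on",
      length(unique(as.character(seqnames(ex)))), "contig(s)\n")
})

#' Exon, transcript and gene accessors
#'
#' @param ann An [AnnotationSet-class].
#' @return `ann_exons()` the exon `GRanges`; `transcript_ids()`/`gene_ids()`
#'   character vectors; `n_transcripts()`/`n_genes()` integer counts.
#' @export
ann_exons <- function(ann) ann@exons

#' @rdname ann_exons
#' @export
transcript_ids <- function(ann) unique(mcols(ann@exons)$transcript_id)

#' @rdname ann_exons
#' @export
gene_ids <- function(ann) unique(mcols(ann@exons)$gene_id)

#' @rdname ann_exons
#' @export
n_transcripts <- function(ann) length(transcript_ids(ann))

#' @rdname ann_exons
#' @export
n_genes <- function(ann) length(gene_ids(ann))

#' Exons grouped by transcript
#' @param ann An [AnnotationSet-class].
#' @return A `GRangesList`, one element per transcript.
#' @export
exons_by_tx <- function(ann) {
  ex <- ann@exons
  GenomicRanges::split(granges(ex), mcols(ex)$transcript_id)
}

#' Exons grouped by gene
#' @param ann An [AnnotationSet-class].
#' @return A `GRangesList`, one element per gene.
#' @export
exons_by_gene <- function(ann) {
  ex <- ann@exons
  GenomicRanges::split(granges(ex), mcols(ex)$gene_id)
}

#' Transcript-level summary table
#'
#' One row per transcript: gene membership, span and exon count, plus any
#' transcript-level metadata (e.g. `fpkm`, `tpm`) carried on the exons.
#'
#' @param ann An [AnnotationSet-class].
#' @return A `data.frame`.
#' @export
tx_table <- function(ann) {
  ex <- ann@exons
  if (length(ex) == 0L)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_exons = integer(), stringsAsFactors = FALSE))
  f <- factor(mcols(ex)$transcript_id, levels = unique(mcols(ex)$transcript_id))
  first <- ex[!duplicated(f)]
  tab <- data.frame(
    transcript_id = levels(f),
    gene_id = mcols(first)$gene_id,
    contig = as.character(seqnames(first)),
    strand = as.character(strand(first)),
    start = as.integer(tapply(start(ex), f, min)),
    end = as.integer(tapply(end(ex), f, max)),
    n_exons = as.integer(tabulate(f)),
    stringsAsFactors = FALSE)
  for (extra in setdiff(colnames(mcols(ex)), c("transcript_id", "gene_id")))
    tab[[extra]] <- mcols(first)[[extra]]
  rownames(tab) <- NULL
  tab
}

#' Transcript spans
#' @param ann An [AnnotationSet-class].
#' @return `GRanges` named by transcript id, each the hull of its exons.
#' @export
tx_spans <- function(ann) {
  tt <- tx_table(ann)
  GRanges(tt$contig, IRanges(tt$start, tt$end), strand = tt$strand,
          transcript_id = tt$transcript_id, gene_id = tt$gene_id)
}

#' Gene spans
#' @param ann An [AnnotationSet-class].
#' @return `GRanges` named by gene id, each the hull of the gene's exons.
#' @export
gene_spans <- function(ann) {
  sp <- BiocGenerics::unlist(range(exons_by_gene(ann)))
  mcols(sp)$gene_id <- names(sp)
  sp
}

#' Subset an annotation
#' @param ann An [AnnotationSet-class].
#' @param genes,transcripts Character vectors of ids to keep (one of the two).
#' @return An [AnnotationSet-class].
#' @export
subset_annotation <- function(ann, genes = NULL, transcripts = NULL) {
  ex <- ann@exons
  keep <- rep(TRUE, length(ex))
  if (!is.null(genes)) keep <- keep & mcols(ex)$gene_id %in% genes
  if (!is.null(transcripts)) keep <- keep & mcols(ex)$transcript_id %in% transcripts
  new("AnnotationSet", exons = ex[keep])
}
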