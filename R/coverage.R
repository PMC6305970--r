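#' Sexed-tissue vocabulary
#'
#' The expression design profiles up to eight adult tissue types per sex
#' (whole organism, gonad, reproductive tract, terminalia, thorax, viscera,
#' head, abdomen), giving 16 sexed tissues. Expression features use the
#' 14-tissue subset that excludes terminalia in both sexes.
#'
#' @return Character vector of sexed-tissue labels (`sex_tissue`).
#' @export
sexed_tissues <- function() {
  tissues <- c("whole", "gonad", "reproductive_tract", "terminalia",
               "thorax", "viscera", "head", "abdomen")
  as.vector(outer(c("f", "m"), tissues, paste, sep = "_"))
}

#' @rdname sexed_tissues
#' @export
expression_tissues <- function() {
  setdiff(sexed_tissues(), c("f_terminalia", "m_terminalia"))
}

#' Read spliced read or cDNA alignments from BED12
#'
#' Each BED12 record becomes one element of a `GRangesList` holding its
#' exonic blocks in genomic coordinates.
#'
#' @param path Path to a BED12 file.
#' @return A `GRangesList` named by the BED name column.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  if (is.null(names(bl)) || anyNA(names(bl)))
    names(bl) <- paste0("read", seq_along(bl))
  bl
}

#' Write spliced blocks as BED12
#' @param reads A `GRangesList` of exonic blocks (one element per read/cDNA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(reads, path) {
  n <- length(reads)
  lines <- character(n)
  nm <- names(reads)
  if (is.null(nm)) nm <- paste0("read", seq_len(n))
  for (i in seq_len(n)) {
    b <- BiocGenerics::sort(reads[[i]])
    chromStart <- min(start(b)) - 1L
    chromEnd <- max(end(b))
    sizes <- paste(width(b), collapse = ",")
    starts <- paste(start(b) - 1L - chromStart, collapse = ",")
    lines[i] <- paste(as.character(seqnames(b))[1], chromStart, chromEnd,
                      nm[i], 0, as.character(strand(b))[1],
                      chromStart, chromEnd, "0,0,0", length(b),
                      paste0(sizes, ","), paste0(starts, ","), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# annotated gene regions: union of transcript spans (default) or exons only
.gene_regions <- function(ann, region = c("span", "exon")) {
  region <- match.arg(region)
  if (region == "span") reduce(granges(tx_spans(ann))) else
    reduce(granges(ann_exons(ann)))
}

#' Fraction of uniquely-mapped reads in unannotated regions
#'
#' The first annotation-completeness metric: the ratio of reads with no
#' overlap to any annotated gene region, over all (uniquely mapped) reads.
#' A spliced read counts as annotated if ANY of its blocks overlaps ANY
#' gene region by at least one base. "Gene region" defaults to the whole
#' transcript span (introns included), so pre-mRNA reads do not score as
#' unannotated; `region = "exon"` restricts to exonic bases.
#'
#' @param reads A `GRangesList` of read blocks (see [read_bed12()]).
#' @param ann An [AnnotationSet-class].
#' @param region `"span"` (default) or `"exon"`.
#' @param stranded Match read strand to annotation strand (default `TRUE`;
#'   use `FALSE` for unstranded libraries).
#' @return A number in `[0, 1]`.
#' @export
unannotated_read_fraction <- function(reads, ann, region = "span",
                                      stranded = TRUE) {
  if (length(reads) == 0L) stop("undefined ratio: zero reads")
  regions <- .gene_regions(ann, region)
  ov <- IRanges::overlapsAny(reads, regions, ignore.strand = !stranded)
  mean(!ov)
}

#' Fraction of unannotated bases covered by reads
#'
#' The companion metric, insensitive to read abundance from single highly
#' expressed loci: among genomic bases outside every annotated gene region,
#' the fraction covered by at least one read block. Computed unstranded
#' (genome bases have no strand).
#'
#' @inheritParams unannotated_read_fraction
#' @param contig_lengths Named integer vector of contig lengths covering
#'   all read and annotation contigs.
#' @return A number in `[0, 1]`.
#' @export
unannotated_region_fraction <- function(reads, ann, contig_lengths,
                                        region = "span") {
  genome <- GRanges(names(contig_lengths),
                    IRanges(1L, as.integer(contig_lengths)))
  regions <- .gene_regions(ann, region)
  strand(regions) <- "*"
  lev <- names(contig_lengths)
  missing <- setdiff(seqlevels(regions), lev)
  if (length(missing) > 0L)
    stop("contig_lengths missing contig(s): ", paste(missing, collapse = ", "))
  seqlevels(regions) <- lev
  unann <- GenomicRanges::setdiff(genome, regions)
  if (sum(width(unann)) == 0L)
    stop("undefined ratio: annotation covers the entire genome")
  if (length(reads) == 0L) return(0)
  cov <- reduce(granges(BiocGenerics::unlist(reads, use.names = FALSE)))
  strand(cov) <- "*"
  seqlevels(cov) <- union(lev, seqlevels(cov))
  covered <- GenomicRanges::intersect(unann, cov)
  sum(width(covered)) / sum(width(unann))
}

#' Evaluate an annotation across sample groups
#'
#' Computes both unannotated-fraction metrics for every read group
#' (species/sex/tissue), producing a heatmap-ready table. Groups with zero
#' reads yield `NA`.
#'
#' @param read_sets Named list of `GRangesList` read sets, one per group.
#' @param ann An [AnnotationSet-class].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param metadata Optional `data.frame` with a `sample` column matching
#'   `names(read_sets)` plus grouping columns (species, sex, tissue);
#'   carried through to the output.
#' @inheritParams unannotated_read_fraction
#' @return `data.frame` with one row per group and columns
#'   `unannotated_read_fraction`, `unannotated_region_fraction`.
#' @export
evaluate_by_sample <- function(read_sets, ann, contig_lengths,
                               metadata = NULL, region = "span",
                               stranded = TRUE) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  out <- data.frame(sample = names(read_sets), stringsAsFactors = FALSE)
  if (!is.null(metadata))
    out <- merge(out, metadata, by = "sample", all.x = TRUE, sort = FALSE)
  out$unannotated_read_fraction <- vapply(read_sets, function(r) {
    if (length(r) == 0L) return(NA_real_)
    unannotated_read_fraction(r, ann, region = region, stranded = stranded)
  }, numeric(1))
  out$unannotated_region_fraction <- vapply(read_sets, function(r) {
    if (length(r) == 0L) return(NA_real_)
    unannotated_region_fraction(r, ann, contig_lengths, region = region)
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Expression matrix with sample metadata
#'
#' A normalized gene-by-sample expression container. `samples` must have
#' columns `sample_id`, `sex`, `tissue` (and optionally `species`,
#' `replicate`); `sex_tissue` labels are derived as `sex_tissue`.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); no negative values.
#' @param samples `data.frame` of per-sample metadata.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)),
            all(c("sample_id", "sex", "tissue") %in% colnames(samples)))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (!setequal(colnames(values), samples$sample_id))
    stop("matrix columns and sample metadata do not match")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  samples$sex_tissue <- paste(samples$sex, samples$tissue, sep = "_")
  bad <- setdiff(unique(samples$sex_tissue), sexed_tissues())
  if (length(bad) > 0L)
    stop("unknown sexed tissue(s): ", paste(bad, collapse = ", "))
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples,", length(unique(x$samples$sex_tissue)), "sexed tissues\n")
  invisible(x)
}

#' Read/write an expression matrix (TSV + metadata sidecar)
#'
#' @param path TSV of the value matrix (first column = gene id).
#' @param metadata_path TSV sidecar with `sample_id`, `sex`, `tissue`
#'   (optionally `species`, `replicate`).
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, metadata_path) {
  df <- read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  expression_matrix(values, read.delim(metadata_path))
}

#' @rdname read_expression_matrix
#' @param expr An `expression_matrix`.
#' @export
write_expression_matrix <- function(expr, path, metadata_path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- expr$samples
  meta$sex_tissue <- NULL
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median expression per sexed tissue
#'
#' The per-tissue median of normalized counts across replicates, restricted
#' to a tissue set (default the 14 sexed tissues excluding terminalia).
#'
#' @param expr An [expression_matrix()].
#' @param gene_id A gene present in the matrix.
#' @param tissues Sexed-tissue labels to report.
#' @return Named numeric vector over `tissues` (`NA` for missing tissues).
#' @export
median_tissue_expression <- function(expr, gene_id,
                                     tissues = expression_tissues()) {
  if (!gene_id %in% rownames(expr$values)) stop("unknown gene: ", gene_id)
  v <- expr$values[gene_id, ]
  med <- tapply(v, expr$samples$sex_tissue, stats::median)
  out <- stats::setNames(rep(NA_real_, length(tissues)), tissues)
  shared <- intersect(tissues, names(med))
  out[shared] <- med[shared]
  out
}

#' Median-expression matrix over genes
#' @inheritParams median_tissue_expression
#' @param genes Gene ids (default all genes in the matrix).
#' @return Numeric matrix genes x tissues of medians across replicates.
#' @export
median_tissue_matrix <- function(expr, genes = rownames(expr$values),
                                 tissues = expression_tissues()) {
  t(vapply(genes, function(g) median_tissue_expression(expr, g, tissues),
           numeric(length(tissues))))
}
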