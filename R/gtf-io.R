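#' Read a GTF annotation
#'
#' Parses GTF2.2 `exon` records (other feature types are ignored) and groups
#' them into transcripts and genes by their `transcript_id` and `gene_id`
#' attributes. Numeric `FPKM`/`TPM` attributes, when present, are kept as
#' `fpkm`/`tpm` metadata columns.
#'
#' @param path Path to a GTF file.
#' @return An [AnnotationSet-class].
#' @seealso [write_gtf()], [read_gff3()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (.only_comments(path))
    return(AnnotationSet(GRanges(transcript_id = character(),
                                 gene_id = character())))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  .annotation_from_features(gr, path)
}

.only_comments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  all(grepl("^\\s*(#|$)", lines))
}

#' Read a GFF3 annotation
#'
#' Exon features are attached to transcripts through their `Parent`
#' attribute and transcripts to genes through theirs; exons whose `Parent`
#' is a gene directly are treated as single-transcript genes.
#'
#' @param path Path to a GFF3 file.
#' @return An [AnnotationSet-class].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (.only_comments(path))
    return(AnnotationSet(GRanges(transcript_id = character(),
                                 gene_id = character())))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  type <- as.character(gr$type)
  tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "tRNA", "rRNA",
                "snoRNA", "snRNA", "miRNA", "pseudogenic_transcript")
  txf <- gr[type %in% tx_types]
  tx2gene <- stats::setNames(
    vapply(txf$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    txf$ID)
  exf <- gr[type == "exon"]
  if (length(exf) == 0L)
    return(AnnotationSet(GRanges(transcript_id = character(), gene_id = character())))
  parents <- exf$Parent
  n_par <- lengths(parents)
  if (any(n_par == 0L)) stop("GFF3 exon without Parent attribute in ", path)
  exf <- exf[rep(seq_along(exf), n_par)]
  tx <- unlist(parents, use.names = FALSE)
  gene <- ifelse(is.na(tx2gene[tx]) | !tx %in% names(tx2gene), tx,
                 unname(tx2gene[tx]))
  out <- granges(exf)
  mcols(out)$transcript_id <- tx
  mcols(out)$gene_id <- gene
  .validate_parsed_exons(out, path)
  AnnotationSet(out)
}

.annotation_from_features <- function(gr, path) {
  gr <- gr[as.character(gr$type) == "exon"]
  mc <- mcols(gr)
  if (length(gr) > 0L &&
      (!all(c("transcript_id", "gene_id") %in% colnames(mc)) ||
       anyNA(mc$transcript_id) || anyNA(mc$gene_id)))
    stop("exon records in '", path, "' lack transcript_id/gene_id attributes")
  out <- granges(gr)
  mcols(out)$transcript_id <- mc$transcript_id
  mcols(out)$gene_id <- mc$gene_id
  for (ab in c("FPKM", "TPM")) {
    if (ab %in% colnames(mc))
      mcols(out)[[tolower(ab)]] <- suppressWarnings(as.numeric(mc[[ab]]))
  }
  .validate_parsed_exons(out, path)
  AnnotationSet(out)
}

.validate_parsed_exons <- function(ex, path) {
  if (length(ex) == 0L) return(invisible(TRUE))
  if (any(end(ex) < start(ex)))
    stop("exon with end < start in '", path, "'")
  if (any(as.character(strand(ex)) == "*")) {
    bad <- unique(mcols(ex)$transcript_id[as.character(strand(ex)) == "*"])
    stop("unstranded exon(s) in '", path, "' for transcript(s): ",
         paste(head(bad, 3), collapse = ", "),
         "; stranded annotations are required")
  }
  invisible(TRUE)
}

#' Write a GTF annotation
#'
#' Emits `transcript` and `exon` records (1-based, inclusive), sorted by
#' contig and start, with `gene_id` then `transcript_id` attributes.
#' `read_gtf(write_gtf(ann))` reproduces every exon interval exactly.
#'
#' @param ann An [AnnotationSet-class].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source = "txharmonize") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#gtf-version 2.2", con)
  ex <- ann@exons
  if (length(ex) == 0L) return(invisible(path))
  tt <- tx_table(ann)
  tt <- tt[order(tt$contig, tt$start, tt$end, tt$transcript_id), , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(tt))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tt$gene_id[i], tt$transcript_id[i])
    exi <- ex[mcols(ex)$transcript_id == tt$transcript_id[i]]
    exi <- BiocGenerics::sort(exi)
    lines <- c(lines,
               paste(tt$contig[i], source, "transcript", tt$start[i], tt$end[i],
                     ".", tt$strand[i], ".", attrs, sep = "\t"),
               paste(tt$contig[i], source, "exon", start(exi), end(exi),
                     ".", tt$strand[i], ".", attrs, sep = "\t"))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write a GFF3 annotation
#'
#' Emits a `gene` > `mRNA` > `exon` hierarchy with `ID`/`Parent` attributes.
#'
#' @inheritParams write_gtf
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, source = "txharmonize") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ex <- ann@exons
  if (length(ex) == 0L) return(invisible(path))
  tt <- tx_table(ann)
  gt <- data.frame(gene_id = unique(tt$gene_id), stringsAsFactors = FALSE)
  gt$contig <- tt$contig[match(gt$gene_id, tt$gene_id)]
  gt$strand <- tt$strand[match(gt$gene_id, tt$gene_id)]
  gt$start <- vapply(gt$gene_id, function(g) min(tt$start[tt$gene_id == g]), integer(1))
  gt$end <- vapply(gt$gene_id, function(g) max(tt$end[tt$gene_id == g]), integer(1))
  gt <- gt[order(gt$contig, gt$start, gt$end, gt$gene_id), , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(gt))) {
    g <- gt$gene_id[i]
    lines <- c(lines, paste(gt$contig[i], source, "gene", gt$start[i], gt$end[i],
                            ".", gt$strand[i], ".", sprintf("ID=%s", g), sep = "\t"))
    txi <- tt[tt$gene_id == g, , drop = FALSE]
    txi <- txi[order(txi$start, txi$end, txi$transcript_id), , drop = FALSE]
    for (j in seq_len(nrow(txi))) {
      tx <- txi$transcript_id[j]
      lines <- c(lines, paste(txi$contig[j], source, "mRNA", txi$start[j],
                              txi$end[j], ".", txi$strand[j], ".",
                              sprintf("ID=%s;Parent=%s", tx, g), sep = "\t"))
      exi <- BiocGenerics::sort(ex[mcols(ex)$transcript_id == tx])
      lines <- c(lines, paste(txi$contig[j], source, "exon", start(exi), end(exi),
                              ".", txi$strand[j], ".",
                              sprintf("ID=%s.e%d;Parent=%s", tx, seq_along(exi), tx),
                              sep = "\t"))
    }
  }
  writeLines(lines, con)
  invisible(path)
}
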