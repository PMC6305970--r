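#' Precomputed annotation index for cDNA classification
#'
#' Flattens an annotation into plain integer/character structures (per-
#' transcript block coordinates, spans, ordered intron-chain keys, and
#' per-strand intron sets) so that classifying large cDNA cohorts does not
#' re-derive them per cDNA. All `cdna_*` and `classify_*` functions accept
#' the index in place of recomputing it.
#'
#' @param ann An [AnnotationSet-class].
#' @return A `cdna_index` object.
#' @export
cdna_index <- function(ann) {
  grl <- exons_by_tx(ann)
  grl <- S4Vectors::endoapply(grl, BiocGenerics::sort)
  n <- length(grl)
  flat <- BiocGenerics::unlist(grl, use.names = FALSE)
  nb <- S4Vectors::elementNROWS(grl)
  grp <- rep(seq_len(n), nb)
  starts <- split(start(flat), grp)
  ends <- split(end(flat), grp)
  contig <- vapply(seq_len(n), function(i)
    as.character(seqnames(grl[[i]])[1]), character(1))
  str <- vapply(seq_len(n), function(i)
    as.character(strand(grl[[i]])[1]), character(1))
  chains <- lapply(seq_len(n), function(i) {
    s <- starts[[i]]; e <- ends[[i]]
    if (length(s) < 2L) return(character(0))
    paste0(e[-length(e)] + 1L, "-", s[-1] - 1L)
  })
  intron_sets <- list()
  for (i in seq_len(n)) {
    key <- paste0(contig[i], ":", str[i])
    intron_sets[[key]] <- c(intron_sets[[key]], chains[[i]])
  }
  intron_sets <- lapply(intron_sets, unique)
  structure(list(tx_ids = names(grl), contig = contig, strand = str,
                 starts = starts, ends = ends,
                 span_start = vapply(starts, min, integer(1)),
                 span_end = vapply(ends, max, integer(1)),
                 chains = chains, intron_sets = intron_sets),
            class = "cdna_index")
}

.as_index <- function(ann) {
  if (inherits(ann, "cdna_index")) ann else cdna_index(ann)
}

# intersection width of two disjoint sorted interval sets (1-based closed)
.blocks_inter <- function(s1, e1, s2, e2) {
  tot <- 0L
  for (i in seq_along(s1))
    tot <- tot + sum(pmax(0L, pmin(e1[i], e2) - pmax(s1[i], s2) + 1L))
  tot
}

# cDNA blocks as sorted integer vectors
.cdna_blocks <- function(cdna) {
  o <- order(start(cdna))
  list(contig = as.character(seqnames(cdna))[1],
       strand = as.character(strand(cdna))[1],
       start = start(cdna)[o], end = end(cdna)[o])
}

# indices of transcripts whose span overlaps the cDNA
.overlapping_tx <- function(b, idx, stranded) {
  hit <- idx$contig == b$contig &
    idx$span_start <= max(b$end) & idx$span_end >= min(b$start)
  if (stranded) hit <- hit & idx$strand == b$strand
  which(hit)
}

# per-candidate exonic Jaccard of a cDNA against indexed transcripts
.tx_jaccards <- function(b, idx, cand) {
  w_c <- sum(b$end - b$start + 1L)
  vapply(cand, function(i) {
    inter <- .blocks_inter(b$start, b$end, idx$starts[[i]], idx$ends[[i]])
    w_t <- sum(idx$ends[[i]] - idx$starts[[i]] + 1L)
    inter / (w_c + w_t - inter)
  }, numeric(1))
}

#' Best Jaccard of a cDNA against an annotation
#'
#' The maximum transcript-level Jaccard over all annotated transcripts
#' overlapping the cDNA alignment (0 when none overlaps on the same
#' strand).
#'
#' @param cdna `GRanges` of the cDNA's exonic blocks (one spliced
#'   alignment).
#' @param ann An [AnnotationSet-class] or a prebuilt [cdna_index()].
#' @param stranded Strand-matched Jaccard (default).
#' @return A number in `[0, 1]`.
#' @export
cdna_jaccard <- function(cdna, ann, stranded = TRUE) {
  idx <- .as_index(ann)
  b <- .cdna_blocks(cdna)
  cand <- .overlapping_tx(b, idx, stranded)
  if (length(cand) == 0L) return(0)
  jac <- .tx_jaccards(b, idx, cand)
  if (all(jac == 0)) 0 else max(jac)
}

#' Classify a cDNA's transcript ends against the annotation
#'
#' A cDNA with no exonic-base overlap to any gene is `intergenic`.
#' Otherwise its 5' and 3' termini are compared against the span of the
#' best-Jaccard transcript (unstranded best match, so antisense artifacts
#' still anchor to their locus): a terminus extending beyond that span by
#' more than `slack` bases is unannotated, giving `ext5_only`,
#' `ext3_only`, `ext_both` or `within`.
#'
#' @inheritParams cdna_jaccard
#' @param slack Tolerated terminal overhang in bases (default 0, strict).
#' @return One of `"within"`, `"ext5_only"`, `"ext3_only"`, `"ext_both"`,
#'   `"intergenic"`.
#' @export
classify_ends <- function(cdna, ann, slack = 0L) {
  idx <- .as_index(ann)
  b <- .cdna_blocks(cdna)
  cand <- .overlapping_tx(b, idx, stranded = FALSE)
  if (length(cand) == 0L) return("intergenic")
  jac <- .tx_jaccards(b, idx, cand)
  if (all(jac == 0)) return("intergenic")
  best <- cand[which.max(jac)]
  left_ext <- min(b$start) < idx$span_start[best] - slack
  right_ext <- max(b$end) > idx$span_end[best] + slack
  minus <- b$strand == "-"
  ext5 <- if (minus) right_ext else left_ext
  ext3 <- if (minus) left_ext else right_ext
  if (ext5 && ext3) "ext_both"
  else if (ext5) "ext5_only"
  else if (ext3) "ext3_only"
  else "within"
}

#' Classify a cDNA's splice junctions against the annotation
#'
#' For an intron-containing cDNA with intron set J, annotation intron set A
#' (same strand) and A' (opposite strand):
#' `antisense` when J is disjoint from A but fully contained in A';
#' `all_present` when J is a contiguous sub-chain of a single annotated
#' transcript's intron chain; `called_annotated` when every junction of J
#' is annotated but no single transcript carries the chain;
#' `all_unannotated` when J is disjoint from A (and not antisense);
#' otherwise `partially_unannotated`.
#'
#' @inheritParams cdna_jaccard
#' @return One of `"all_present"`, `"called_annotated"`,
#'   `"partially_unannotated"`, `"all_unannotated"`, `"antisense"`.
#' @export
classify_junctions <- function(cdna, ann) {
  idx <- .as_index(ann)
  b <- .cdna_blocks(cdna)
  if (length(b$start) < 2L) stop("not intron-containing: mono-exonic cDNA")
  J <- paste0(b$end[-length(b$end)] + 1L, "-", b$start[-1] - 1L)
  A <- idx$intron_sets[[paste0(b$contig, ":", b$strand)]]
  Ap <- idx$intron_sets[[paste0(b$contig, ":",
                                if (b$strand == "+") "-" else "+")]]
  n_in_A <- sum(J %in% A)
  if (n_in_A == 0L) {
    if (length(Ap) > 0L && all(J %in% Ap)) return("antisense")
    return("all_unannotated")
  }
  if (n_in_A == length(J)) {
    cand <- which(idx$contig == b$contig & idx$strand == b$strand &
                  vapply(idx$chains, length, integer(1)) >= length(J))
    for (i in cand) {
      pos <- match(J, idx$chains[[i]])
      if (anyNA(pos)) next
      if (identical(pos, seq(pos[1], by = 1L, length.out = length(pos))))
        return("all_present")
    }
    return("called_annotated")
  }
  "partially_unannotated"
}

#' Validate annotations against a full-length cDNA cohort
#'
#' For each annotation: the per-cDNA best-Jaccard distribution, the
#' fraction of annotation exonic bases covered by at least one cDNA block,
#' the end-category counts/fractions over all cDNAs and the
#' junction-category counts/fractions over the intron-containing cDNAs.
#'
#' @param cdnas `GRangesList` of cDNA alignments (see [read_bed12()]).
#' @param ann_old,ann_new The annotations to contrast (e.g. before and
#'   after re-annotation).
#' @param slack Terminal slack for [classify_ends()].
#' @return A `cdna_validation_report`: named list (per annotation) of
#'   `jaccard` (numeric vector), `base_coverage`, `ends` and `junctions`
#'   (count/fraction `data.frame`s).
#' @export
validation_report <- function(cdnas, ann_old, ann_new, slack = 0L) {
  if (length(cdnas) == 0L) stop("empty cDNA set")
  one <- function(ann) {
    idx <- cdna_index(ann)
    jac <- vapply(seq_along(cdnas), function(i) cdna_jaccard(cdnas[[i]], idx),
                  numeric(1))
    ends <- vapply(seq_along(cdnas), function(i)
      classify_ends(cdnas[[i]], idx, slack = slack), character(1))
    spliced <- which(S4Vectors::elementNROWS(cdnas) > 1L)
    juncs <- vapply(spliced, function(i) classify_junctions(cdnas[[i]], idx),
                    character(1))
    cov_blocks <- reduce(granges(BiocGenerics::unlist(cdnas, use.names = FALSE)),
                         ignore.strand = TRUE)
    ex <- reduce(granges(ann_exons(ann)), ignore.strand = TRUE)
    lev <- union(seqlevels(ex), seqlevels(cov_blocks))
    seqlevels(ex) <- lev; seqlevels(cov_blocks) <- lev
    strand(ex) <- "*"; strand(cov_blocks) <- "*"
    covered <- sum(width(GenomicRanges::intersect(ex, cov_blocks)))
    tab <- function(x, levels) {
      cnt <- table(factor(x, levels = levels))
      data.frame(category = levels, count = as.integer(cnt),
                 fraction = as.integer(cnt) / max(1L, length(x)),
                 stringsAsFactors = FALSE)
    }
    list(jaccard = jac,
         base_coverage = covered / sum(width(ex)),
         ends = tab(ends, end_categories()),
         junctions = tab(juncs, junction_categories()))
  }
  structure(list(old = one(ann_old), new = one(ann_new)),
            class = "cdna_validation_report")
}

#' Category vocabularies for cDNA validation
#' @return Character vectors of the end and junction category labels.
#' @export
end_categories <- function() {
  c("within", "ext5_only", "ext3_only", "ext_both", "intergenic")
}

#' @rdname end_categories
#' @export
junction_categories <- function() {
  c("all_present", "called_annotated", "partially_unannotated",
    "all_unannotated", "antisense")
}

#' @export
print.cdna_validation_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("== annotation:", nm, "==\n")
    cat("  cDNAs:", length(x[[nm]]$jaccard),
        "| median Jaccard:", round(stats::median(x[[nm]]$jaccard), 3),
        "| zero-overlap:", sum(x[[nm]]$jaccard == 0),
        "| base coverage:", round(x[[nm]]$base_coverage, 3), "\n")
    cat("  ends:", paste(sprintf("%s %.1f%%", x[[nm]]$ends$category,
                                 100 * x[[nm]]$ends$fraction), collapse = ", "), "\n")
    cat("  junctions:", paste(sprintf("%s %.1f%%", x[[nm]]$junctions$category,
                                      100 * x[[nm]]$junctions$fraction),
                              collapse = ", "), "\n")
  }
  invisible(x)
}
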