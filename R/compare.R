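#' Multi-level comparison of a predicted annotation against a reference
#'
#' Sensitivity `TP/(TP+FN)` and precision `TP/(TP+FP)` (in percent) at six
#' levels:
#' \describe{
#'   \item{base}{stranded exonic-base overlap; TP+FN = reference exonic
#'     bases, TP+FP = predicted exonic bases.}
#'   \item{exon}{exact unique-exon coordinate matches.}
#'   \item{intron}{exact unique-intron coordinate matches.}
#'   \item{intron_chain}{identical full ordered intron chains among unique
#'     multi-exon chains.}
#'   \item{transcript}{multi-exon transcripts match by identical intron
#'     chain; mono-exonic transcripts match a mono-exonic reference
#'     transcript with exonic Jaccard >= `mono_jaccard` (greedy one-to-one
#'     by descending Jaccard).}
#'   \item{gene}{genes with at least one matched transcript, paired
#'     one-to-one.}
#' }
#'
#' @param pred,ref [AnnotationSet-class] objects on the same genome.
#' @param mono_jaccard Exonic Jaccard threshold for mono-exonic transcript
#'   matches (default 0.6, the same cutoff used to label gene models).
#' @return A `comparison_report`: `data.frame` with columns `level`, `tp`,
#'   `fn`, `fp`, `sensitivity`, `precision` (percent; `NA` when a
#'   denominator is 0). The transcript-level matched pairs are attached as
#'   attribute `"matches"`.
#' @export
compare_annotations <- function(pred, ref, mono_jaccard = 0.6) {
  levels <- c("base", "exon", "intron", "intron_chain", "transcript", "gene")
  if (n_transcripts(pred) == 0L || n_transcripts(ref) == 0L) {
    warning("empty predicted or reference annotation: all-NA report")
    rep <- data.frame(level = levels, tp = NA_integer_, fn = NA_integer_,
                      fp = NA_integer_, sensitivity = NA_real_,
                      precision = NA_real_, stringsAsFactors = FALSE)
    class(rep) <- c("comparison_report", "data.frame")
    return(rep)
  }
  pex <- reduce(granges(ann_exons(pred)))
  rex <- reduce(granges(ann_exons(ref)))
  lev <- union(seqlevels(pex), seqlevels(rex))
  seqlevels(pex) <- lev; seqlevels(rex) <- lev
  base_tp <- sum(width(GenomicRanges::intersect(pex, rex)))
  base <- c(tp = base_tp, fn = sum(width(rex)) - base_tp,
            fp = sum(width(pex)) - base_tp)

  set_counts <- function(pk, sk) {
    tp <- length(intersect(pk, sk))
    c(tp = tp, fn = length(sk) - tp, fp = length(pk) - tp)
  }
  exon <- set_counts(unique(interval_keys(ann_exons(pred))),
                     unique(interval_keys(ann_exons(ref))))
  p_ints <- introns_by_tx(pred)
  r_ints <- introns_by_tx(ref)
  intron <- set_counts(
    unique(interval_keys(BiocGenerics::unlist(p_ints, use.names = FALSE))),
    unique(interval_keys(BiocGenerics::unlist(r_ints, use.names = FALSE))))

  p_chain <- intron_chains(pred)
  r_chain <- intron_chains(ref)
  chain <- set_counts(unique(p_chain[p_chain != ""]),
                      unique(r_chain[r_chain != ""]))

  matches <- .match_transcripts(pred, ref, p_chain, r_chain, mono_jaccard)
  tx <- c(tp = nrow(matches), fn = n_transcripts(ref) - nrow(matches),
          fp = n_transcripts(pred) - nrow(matches))

  gene <- .match_genes(matches, pred, ref)

  rep <- data.frame(level = levels, stringsAsFactors = FALSE)
  counts <- rbind(base, exon, intron, chain, tx, gene)
  rep$tp <- counts[, "tp"]; rep$fn <- counts[, "fn"]; rep$fp <- counts[, "fp"]
  rep$sensitivity <- ifelse(rep$tp + rep$fn > 0, 100 * rep$tp / (rep$tp + rep$fn), NA)
  rep$precision <- ifelse(rep$tp + rep$fp > 0, 100 * rep$tp / (rep$tp + rep$fp), NA)
  attr(rep, "matches") <- matches
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

# one-to-one transcript matching; returns data.frame(pred_tx, ref_tx)
.match_transcripts <- function(pred, ref, p_chain, r_chain, mono_jaccard) {
  out <- data.frame(pred_tx = character(), ref_tx = character(),
                    stringsAsFactors = FALSE)
  # multi-exon: pair within identical chain keys
  pm <- p_chain[p_chain != ""]
  rm_ <- r_chain[r_chain != ""]
  for (key in intersect(unique(pm), unique(rm_))) {
    a <- names(pm)[pm == key]
    b <- names(rm_)[rm_ == key]
    k <- min(length(a), length(b))
    out <- rbind(out, data.frame(pred_tx = a[seq_len(k)], ref_tx = b[seq_len(k)],
                                 stringsAsFactors = FALSE))
  }
  # mono-exonic: greedy by descending Jaccard among overlapping same-strand pairs
  p_mono <- names(p_chain)[p_chain == ""]
  r_mono <- names(r_chain)[r_chain == ""]
  if (length(p_mono) > 0L && length(r_mono) > 0L) {
    ptx <- exons_by_tx(pred)[p_mono]
    rtx <- exons_by_tx(ref)[r_mono]
    hits <- findOverlaps(ptx, rtx, ignore.strand = FALSE)
    if (length(hits) > 0L) {
      cand <- data.frame(pred_tx = p_mono[queryHits(hits)],
                         ref_tx = r_mono[subjectHits(hits)],
                         stringsAsFactors = FALSE)
      cand$jaccard <- mapply(function(a, b)
        transcript_jaccard(ptx[[a]], rtx[[b]]), cand$pred_tx, cand$ref_tx)
      cand <- cand[cand$jaccard >= mono_jaccard, , drop = FALSE]
      cand <- cand[order(-cand$jaccard, cand$pred_tx, cand$ref_tx), , drop = FALSE]
      used_p <- character(); used_r <- character()
      for (i in seq_len(nrow(cand))) {
        if (cand$pred_tx[i] %in% used_p || cand$ref_tx[i] %in% used_r) next
        used_p <- c(used_p, cand$pred_tx[i])
        used_r <- c(used_r, cand$ref_tx[i])
        out <- rbind(out, cand[i, c("pred_tx", "ref_tx"), drop = FALSE])
      }
    }
  }
  rownames(out) <- NULL
  out
}

# greedy one-to-one gene pairing from matched transcript pairs
.match_genes <- function(matches, pred, ref) {
  n_pg <- n_genes(pred); n_rg <- n_genes(ref)
  if (nrow(matches) == 0L) return(c(tp = 0L, fn = n_rg, fp = n_pg))
  p_tt <- tx_table(pred); r_tt <- tx_table(ref)
  links <- data.frame(
    pred_gene = p_tt$gene_id[match(matches$pred_tx, p_tt$transcript_id)],
    ref_gene = r_tt$gene_id[match(matches$ref_tx, r_tt$transcript_id)],
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = rep(1L, nrow(links))),
                          by = links[c("pred_gene", "ref_gene")], FUN = sum)
  agg <- agg[order(-agg$n, agg$pred_gene, agg$ref_gene), , drop = FALSE]
  used_p <- character(); used_r <- character(); tp <- 0L
  for (i in seq_len(nrow(agg))) {
    if (agg$pred_gene[i] %in% used_p || agg$ref_gene[i] %in% used_r) next
    used_p <- c(used_p, agg$pred_gene[i])
    used_r <- c(used_r, agg$ref_gene[i])
    tp <- tp + 1L
  }
  c(tp = tp, fn = n_rg - tp, fp = n_pg - tp)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Annotation comparison (sensitivity/precision, %):\n")
  df <- as.data.frame(x)
  df$sensitivity <- round(df$sensitivity, 1)
  df$precision <- round(df$precision, 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report as TSV
#' @param report A `comparison_report` from [compare_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
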