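#' Gene order along contigs
#'
#' @param ann An [AnnotationSet-class].
#' @return A `gene_order` object: `data.frame` with `gene_id`, `contig`,
#'   `rank` (1-based rank by gene-span start within each contig).
#' @export
gene_order <- function(ann) {
  sp <- gene_spans(ann)
  df <- data.frame(gene_id = mcols(sp)$gene_id,
                   contig = as.character(seqnames(sp)),
                   start = start(sp), stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$start, df$gene_id), , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$contig, FUN = seq_along)
  rownames(df) <- NULL
  structure(df[c("gene_id", "contig", "rank")], class = c("gene_order", "data.frame"))
}

#' Homology table helpers
#'
#' A homology table is a `data.frame` with columns `ref_gene`, `query_gene`,
#' `score`, `rbh` (logical reciprocal-best-hit flag); at most one RBH
#' partner per gene on each side.
#'
#' @param path TSV path.
#' @return `read_homology_table()`: the table; `write_homology_table()`:
#'   `path`, invisibly.
#' @export
read_homology_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("ref_gene", "query_gene", "score", "rbh") %in% colnames(df)))
  df$rbh <- as.logical(df$rbh)
  df
}

#' @rdname read_homology_table
#' @param homology The homology table.
#' @export
write_homology_table <- function(homology, path) {
  write.table(homology, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# query gene -> ref gene RBH lookup (and the reverse)
.rbh_map <- function(homology, from = c("query", "ref")) {
  from <- match.arg(from)
  h <- homology[homology$rbh, , drop = FALSE]
  if (from == "query") stats::setNames(h$ref_gene, h$query_gene)
  else stats::setNames(h$query_gene, h$ref_gene)
}

#' Flanking-gene synteny score
#'
#' For the up-to-10 genes on each side of `query_gene`, the fraction whose
#' reciprocal-best-hit partner lies within `window` ranks of `ref_gene` on
#' the reference contig. Flanking genes without an RBH partner stay in the
#' denominator; at contig edges the denominator shrinks to the flanks that
#' exist.
#'
#' @param ref_gene,query_gene Gene ids placed in their respective orders.
#' @param homology Homology table (see [read_homology_table()]).
#' @param ref_order,query_order [gene_order()] of the two species.
#' @param window Flank size in genes (default 10).
#' @return A number in `[0, 1]`.
#' @export
synteny_score <- function(ref_gene, query_gene, homology, ref_order,
                          query_order, window = 10L) {
  qrow <- match(query_gene, query_order$gene_id)
  rrow <- match(ref_gene, ref_order$gene_id)
  if (is.na(qrow) || is.na(rrow))
    stop("gene not placed in its gene order")
  qc <- query_order$contig[qrow]; qr <- query_order$rank[qrow]
  on_contig <- query_order[query_order$contig == qc, , drop = FALSE]
  flanks <- on_contig$gene_id[abs(on_contig$rank - qr) <= window &
                              on_contig$rank != qr]
  if (length(flanks) == 0L) return(0)
  rbh <- .rbh_map(homology, from = "query")
  partners <- rbh[flanks]
  rc <- ref_order$contig[rrow]; rr <- ref_order$rank[rrow]
  hit <- vapply(partners, function(p) {
    if (is.na(p)) return(FALSE)
    i <- match(p, ref_order$gene_id)
    !is.na(i) && ref_order$contig[i] == rc && abs(ref_order$rank[i] - rr) <= window
  }, logical(1))
  sum(hit) / length(flanks)
}

#' Tissue-expression correlation between candidate orthologs
#'
#' Spearman rank correlation of the two genes' median-expression vectors
#' over the 14 sexed tissues.
#'
#' @param ref_gene,query_gene Gene ids.
#' @param ref_expr,query_expr [expression_matrix()] objects.
#' @param tissues Sexed-tissue set (default the 14 excluding terminalia).
#' @return Spearman's r in `[-1, 1]`; `NA` with a warning when either
#'   vector is constant.
#' @export
expr_correlation <- function(ref_gene, query_gene, ref_expr, query_expr,
                             tissues = expression_tissues()) {
  x <- median_tissue_expression(ref_expr, ref_gene, tissues)
  y <- median_tissue_expression(query_expr, query_gene, tissues)
  spearman_cor(x, y)
}

#' @rdname expr_correlation
#' @param x,y Numeric vectors (used directly instead of gene lookups).
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant expression vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Intron-structure ratio
#'
#' `(unique introns of the query gene + 1) / (unique introns of the
#' reference gene + 1)`; the +1 avoids division by zero for intron-less
#' genes.
#'
#' @param n_ref,n_query Unique-intron counts (see [unique_intron_count()]);
#'   vectorized.
#' @return Positive numeric.
#' @export
intron_ratio <- function(n_ref, n_query) {
  (n_query + 1) / (n_ref + 1)
}

#' Sequence similarity of candidate ortholog transcripts
#'
#' Global (Needleman-Wunsch) alignment of the two longest transcripts
#' (match +1, mismatch -1, gap open -2, gap extend -0.5; an external
#' aligner can be substituted upstream by supplying its aligned strings).
#' Reports `alignable_frac` = columns with a residue in both sequences over
#' total alignment columns, and `identity_frac` = identical columns over
#' alignable columns.
#'
#' @param ref_seq,query_seq `DNAString`/character sequences (non-empty).
#' @return Named numeric vector `c(alignable_frac, identity_frac)`.
#' @export
sequence_similarity <- function(ref_seq, query_seq) {
  ref_seq <- as.character(ref_seq); query_seq <- as.character(query_seq)
  if (nchar(ref_seq) == 0L || nchar(query_seq) == 0L)
    stop("empty sequence")
  sub <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- pairwiseAlignment(DNAString(query_seq), DNAString(ref_seq),
                           type = "global", substitutionMatrix = sub,
                           gapOpening = 2, gapExtension = 0.5)
  p <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  alignable <- p != "-" & s != "-"
  ident <- alignable & p == s
  c(alignable_frac = sum(alignable) / length(p),
    identity_frac = if (sum(alignable) == 0L) 0 else sum(ident) / sum(alignable))
}

# shared SVM trainer for the two ortholog stages
.train_stage_svm <- function(features, labels, cost, gamma) {
  y <- factor(ifelse(as.logical(labels), "pos", "neg"), levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both positive and negative examples are required")
  scaler <- .fit_scaler(features)
  x <- .apply_scaler(features, scaler)
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(svm = fit, scaler = scaler, cost = cost, gamma = gamma),
            class = "ortholog_stage_model")
}

#' Train the stage-1 ortholog classifier
#'
#' An rbf-kernel SVM over the three structural/expression features
#' (`synteny`, `expr_spearman`, `intron_ratio`) separating known 1:1
#' orthologs from random gene pairs. Defaults to the tuned hyperparameters
#' C = 1000, gamma = 0.001.
#'
#' @param features `data.frame` with columns `synteny`, `expr_spearman`,
#'   `intron_ratio`.
#' @param labels Logical vector (TRUE = known ortholog pair).
#' @param cost,gamma SVM hyperparameters.
#' @return An `ortholog_stage_model`.
#' @export
train_stage1 <- function(features, labels, cost = 1000, gamma = 0.001) {
  .train_stage_svm(features[c("synteny", "expr_spearman", "intron_ratio")],
                   labels, cost, gamma)
}

#' Train the stage-2 ortholog classifier
#'
#' An rbf-kernel SVM over the two sequence-similarity features
#' (`alignable_frac`, `identity_frac`); defaults C = 1000, gamma = 0.01.
#'
#' @param features `data.frame` with columns `alignable_frac`,
#'   `identity_frac`.
#' @inheritParams train_stage1
#' @return An `ortholog_stage_model`.
#' @export
train_stage2 <- function(features, labels, cost = 1000, gamma = 0.01) {
  .train_stage_svm(features[c("alignable_frac", "identity_frac")],
                   labels, cost, gamma)
}

#' @export
print.ortholog_stage_model <- function(x, ...) {
  cat("ortholog_stage_model: rbf kernel, C =", x$cost, ", gamma =", x$gamma,
      ";", length(names(x$scaler$center)), "features\n")
  invisible(x)
}

#' Decision scores from a stage model
#' @param model An `ortholog_stage_model`.
#' @param features Feature rows to score.
#' @return Numeric decision values (positive = predicted ortholog).
#' @export
stage_decision <- function(model, features) {
  x <- .apply_scaler(features[names(model$scaler$center)], model$scaler)
  .svm_decision(model$svm, x)
}

#' Resolve stage-2 survivors into 1:1 orthologs
#'
#' Positives sharing a reference or query gene with another positive are
#' one-to-many and excluded; the final table is a partial bijection.
#'
#' @param candidates `data.frame` with `ref_gene`, `query_gene` and a
#'   logical `stage2_pass` column.
#' @return The `candidates` with a `status` column
#'   (`one_to_one` / `one_to_many` / `rejected`).
#' @export
classify_stage2 <- function(candidates) {
  status <- rep("rejected", nrow(candidates))
  pos <- which(candidates$stage2_pass)
  if (length(pos) > 0L) {
    rg <- candidates$ref_gene[pos]; qg <- candidates$query_gene[pos]
    multi <- rg %in% rg[duplicated(rg)] | qg %in% qg[duplicated(qg)]
    status[pos[multi]] <- "one_to_many"
    status[pos[!multi]] <- "one_to_one"
  }
  candidates$status <- status
  candidates
}

#' Two-stage discovery of novel 1:1 orthologs
#'
#' The full pipeline relative to a reference species: train a stage-1 SVM
#' on known 1:1 orthologs vs seeded random gene pairs using synteny,
#' tissue-expression Spearman correlation and the intron-structure ratio;
#' score candidate pairs outside the known set (restricted, for
#' tractability, to pairs linked by an RBH hit or lying within the synteny
#' window of a flank's RBH partner); align the longest transcripts of
#' stage-1 survivors and filter with a stage-2 SVM on the
#' alignable/identity fractions; finally resolve multi-candidates as
#' one-to-many and keep the 1:1 pairs.
#'
#' @param ref_ann,query_ann [AnnotationSet-class] objects of the two species.
#' @param ref_expr,query_expr [expression_matrix()] objects.
#' @param ref_seqs,query_seqs Named `DNAStringSet` of transcript sequences
#'   (per transcript; the longest per gene is used).
#' @param homology Homology/RBH table.
#' @param known `data.frame` with `ref_gene`, `query_gene`: the current 1:1
#'   ortholog set used for training.
#' @param window Synteny flank size (default 10).
#' @param stage1_cost,stage1_gamma,stage2_cost,stage2_gamma SVM
#'   hyperparameters for the two stages.
#' @param seed Seed for the random-pair null (size = number of known pairs).
#' @return `data.frame` of scored candidates with feature values, stage
#'   decisions and `status`; attribute `"models"` holds the two stage
#'   models.
#' @export
find_orthologs <- function(ref_ann, query_ann, ref_expr, query_expr,
                           ref_seqs, query_seqs, homology, known,
                           window = 10L, stage1_cost = 1000,
                           stage1_gamma = 0.001, stage2_cost = 1000,
                           stage2_gamma = 0.01, seed = 1) {
  ref_order <- gene_order(ref_ann)
  query_order <- gene_order(query_ann)
  ref_introns <- unique_intron_count(ref_ann)
  query_introns <- unique_intron_count(query_ann)
  ref_tt <- tx_table(ref_ann); query_tt <- tx_table(query_ann)

  pair_features <- function(pairs) {
    data.frame(
      ref_gene = pairs$ref_gene, query_gene = pairs$query_gene,
      synteny = mapply(synteny_score, pairs$ref_gene, pairs$query_gene,
                       MoreArgs = list(homology = homology,
                                       ref_order = ref_order,
                                       query_order = query_order,
                                       window = window)),
      expr_spearman = suppressWarnings(
        mapply(function(r, q) expr_correlation(r, q, ref_expr, query_expr),
               pairs$ref_gene, pairs$query_gene)),
      intron_ratio = intron_ratio(ref_introns[pairs$ref_gene],
                                  query_introns[pairs$query_gene]),
      stringsAsFactors = FALSE, row.names = NULL)
  }

  set.seed(seed)
  nulls <- data.frame(
    ref_gene = sample(ref_order$gene_id, nrow(known), replace = TRUE),
    query_gene = sample(query_order$gene_id, nrow(known), replace = TRUE),
    stringsAsFactors = FALSE)
  planted_key <- paste(known$ref_gene, known$query_gene)
  nulls <- nulls[!paste(nulls$ref_gene, nulls$query_gene) %in% planted_key, ,
                 drop = FALSE]
  train1 <- rbind(pair_features(known), pair_features(nulls))
  train1$expr_spearman[is.na(train1$expr_spearman)] <- 0
  labels1 <- rep(c(TRUE, FALSE), c(nrow(known), nrow(nulls)))
  m1 <- train_stage1(train1, labels1, cost = stage1_cost, gamma = stage1_gamma)

  cands <- .candidate_pairs(homology, known, ref_order, query_order, window)
  if (nrow(cands) == 0L) {
    out <- data.frame(ref_gene = character(), query_gene = character(),
                      status = character(), stringsAsFactors = FALSE)
    attr(out, "models") <- list(stage1 = m1, stage2 = NULL)
    return(out)
  }
  feats <- pair_features(cands)
  feats$expr_spearman[is.na(feats$expr_spearman)] <- 0
  feats$stage1_score <- stage_decision(m1, feats)
  surv <- feats[feats$stage1_score > 0, , drop = FALSE]

  longest_tx <- function(tt, seqs) {
    w <- stats::setNames(Biostrings::width(seqs), names(seqs))
    tt$len <- w[tt$transcript_id]
    picked <- tt[order(tt$gene_id, -tt$len), ]
    picked <- picked[!duplicated(picked$gene_id), ]
    stats::setNames(picked$transcript_id, picked$gene_id)
  }
  ref_long <- longest_tx(ref_tt, ref_seqs)
  query_long <- longest_tx(query_tt, query_seqs)
  seq_feats <- function(pairs) {
    sim <- t(mapply(function(r, q)
      sequence_similarity(ref_seqs[[ref_long[[r]]]],
                          query_seqs[[query_long[[q]]]]),
      pairs$ref_gene, pairs$query_gene))
    data.frame(alignable_frac = sim[, 1], identity_frac = sim[, 2],
               row.names = NULL)
  }
  train2 <- rbind(seq_feats(known), seq_feats(nulls))
  m2 <- train_stage2(train2, labels1, cost = stage2_cost, gamma = stage2_gamma)

  if (nrow(surv) > 0L) {
    sf <- seq_feats(surv)
    surv$alignable_frac <- sf$alignable_frac
    surv$identity_frac <- sf$identity_frac
    surv$stage2_score <- stage_decision(m2, surv)
    surv$stage2_pass <- surv$stage2_score > 0
    surv <- classify_stage2(surv)
  } else {
    surv$alignable_frac <- surv$identity_frac <- surv$stage2_score <- numeric(0)
    surv$stage2_pass <- logical(0)
    surv$status <- character(0)
  }
  out <- merge(feats, surv[setdiff(colnames(surv), colnames(feats)[-(1:2)])],
               by = c("ref_gene", "query_gene"), all.x = TRUE, sort = FALSE)
  out$status[is.na(out$status)] <- "rejected"
  out <- out[order(out$ref_gene, out$query_gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "models") <- list(stage1 = m1, stage2 = m2)
  out
}

# blocking step: pairs outside the known set reachable by an RBH link or by
# the synteny neighborhood of a flank's RBH partner
.candidate_pairs <- function(homology, known, ref_order, query_order, window) {
  known_ref <- unique(known$ref_gene)
  known_query <- unique(known$query_gene)
  rbh <- .rbh_map(homology, from = "query")
  pairs <- list()
  for (q in setdiff(query_order$gene_id, known_query)) {
    refs <- character(0)
    direct <- unname(rbh[q])
    if (!is.na(direct)) refs <- direct
    qi <- match(q, query_order$gene_id)
    qc <- query_order$contig[qi]; qr <- query_order$rank[qi]
    on_contig <- query_order[query_order$contig == qc, , drop = FALSE]
    flanks <- on_contig$gene_id[abs(on_contig$rank - qr) <= window &
                                on_contig$rank != qr]
    partners <- rbh[flanks]
    partners <- partners[!is.na(partners)]
    for (p in partners) {
      pi <- match(p, ref_order$gene_id)
      if (is.na(pi)) next
      pc <- ref_order$contig[pi]; pr <- ref_order$rank[pi]
      near <- ref_order$gene_id[ref_order$contig == pc &
                                abs(ref_order$rank - pr) <= window]
      refs <- c(refs, near)
    }
    refs <- setdiff(unique(refs), known_ref)
    if (length(refs) > 0L)
      pairs[[length(pairs) + 1L]] <- data.frame(ref_gene = refs, query_gene = q,
                                                stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L)
    return(data.frame(ref_gene = character(), query_gene = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}
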