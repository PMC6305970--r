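#' Simulation configuration
#'
#' Parameters of the seeded generators that produce every input the
#' toolkit consumes. Defaults describe a compact fly-like toy genome:
#' short introns (log-normal around 80 bp), ~300 bp exons, a 42% GC
#' background, mostly canonical GT-AG junctions, stranded 76 bp reads and
#' the 16 sexed-tissue expression design with quadruplicate replicates.
#'
#' @param seed Master seed; each generator derives its own fixed offset
#'   stream from it, so outputs are byte-identical per (config, seed).
#' @param n_contigs,contig_length,gc_content,n_genes Genome shape.
#' @param exon_mean Mean extra exons per transcript (exon count is
#'   `1 + Poisson(exon_mean)`).
#' @param exon_meanlog,exon_sdlog,intron_meanlog,intron_sdlog Log-normal
#'   exon/intron length parameters (bp).
#' @param isoform_mean Mean extra isoforms per gene (`1 + Poisson`).
#' @param intergenic_meanlog,intergenic_sdlog Log-normal intergenic gaps.
#' @param gtag_fraction Fraction of introns written with canonical GT-AG
#'   boundaries.
#' @param utr_truncation,gene_split,gene_drop,isoform_drop,noise_gene_rate
#'   Perturbation rates in `[0, 1]` emulating legacy-annotation deficits
#'   (truncated UTRs, split genes, missing genes/isoforms, spurious short
#'   mono-exonic calls).
#' @param truncation_bp Fixed trim applied by `utr_truncation`.
#' @param read_length,read_depth,noise_read_rate Read simulation: stranded
#'   spliced reads along transcripts plus intergenic noise reads.
#' @param expr_meanlog,expr_sdlog,bias_fraction,bias_strength,replicate_noise_sd
#'   Expression model: log-normal baselines, a tissue-biased gene fraction
#'   with a multiplicative bias, and log-normal replicate noise.
#' @param substitution_rate,rearrangement_rate,intron_change_rate,known_withheld,rbh_dropout,expr_noise_sd
#'   Ortholog divergence model for the second species.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_contigs = 2L,
                              contig_length = 100000L,
                              gc_content = 0.42,
                              n_genes = 50L,
                              exon_mean = 3,
                              exon_meanlog = log(300), exon_sdlog = 0.5,
                              intron_meanlog = log(80), intron_sdlog = 0.5,
                              isoform_mean = 1,
                              intergenic_meanlog = log(700),
                              intergenic_sdlog = 0.4,
                              gtag_fraction = 0.9,
                              utr_truncation = 0, gene_split = 0,
                              gene_drop = 0, isoform_drop = 0,
                              noise_gene_rate = 0, truncation_bp = 100L,
                              read_length = 76L, read_depth = 10000L,
                              noise_read_rate = 0,
                              expr_meanlog = log(100), expr_sdlog = 1,
                              bias_fraction = 0.3, bias_strength = 8,
                              replicate_noise_sd = 0.2,
                              substitution_rate = 0,
                              rearrangement_rate = 0,
                              intron_change_rate = 0,
                              known_withheld = 0.2,
                              rbh_dropout = 0.05,
                              expr_noise_sd = 0.1) {
  cfg <- as.list(environment())
  rates <- c("gc_content", "gtag_fraction", "utr_truncation", "gene_split",
             "gene_drop", "isoform_drop", "noise_gene_rate",
             "noise_read_rate", "bias_fraction", "substitution_rate",
             "rearrangement_rate", "intron_change_rate", "known_withheld",
             "rbh_dropout")
  for (r in rates)
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop("rate '", r, "' must be in [0, 1]")
  if (cfg$seed >= 2^31 - 10) stop("seed too large")
  structure(cfg, class = "simulation_config")
}

# fixed per-generator seed offsets keep generator streams independent
.sim_seed <- function(config, offset) as.integer(config$seed) + offset

#' Contig lengths of an in-memory genome
#' @param genome Named `DNAStringSet`.
#' @return Named integer vector.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Simulate a genome with a truth annotation
#'
#' Generates random contig sequences at the target GC, packs non-overlapping
#' genes on both strands with log-normal exon/intron/intergenic lengths and
#' Poisson exon/isoform counts, and writes canonical GT-AG dinucleotides at
#' a configured fraction of intron boundaries (on the coding strand).
#' Additional isoforms are built by exon skipping, intron retention or
#' 5'-truncation. Deterministic per (config, seed).
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named `DNAStringSet`), `annotation`
#'   ([AnnotationSet-class]) and `config`.
#' @export
simulate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.sim_seed(config, 0L))
  contigs <- paste0("ctg", seq_len(config$n_contigs))
  cursor <- stats::setNames(rep(1L, config$n_contigs), contigs)
  exon_rows <- list()
  placed <- 0L
  ci <- 1L
  gi <- 0L
  while (placed < config$n_genes) {
    gap <- max(50L, round(rlnorm(1, config$intergenic_meanlog,
                                 config$intergenic_sdlog)))
    n_ex <- 1L + rpois(1, config$exon_mean)
    ex_w <- pmax(30L, round(rlnorm(n_ex, config$exon_meanlog, config$exon_sdlog)))
    in_w <- if (n_ex > 1L)
      pmax(40L, round(rlnorm(n_ex - 1L, config$intron_meanlog,
                             config$intron_sdlog))) else integer(0)
    span <- sum(ex_w) + sum(in_w)
    tries <- 0L
    while (cursor[ci] + gap + span > config$contig_length - 100L) {
      ci <- ci + 1L
      tries <- tries + 1L
      if (ci > config$n_contigs) ci <- 1L
      if (tries > config$n_contigs)
        stop("genes requested exceed packable space (placed ", placed,
             " of ", config$n_genes, ")")
    }
    gi <- gi + 1L
    gene_id <- sprintf("G%05d", gi)
    strand <- sample(c("+", "-"), 1)
    g_start <- cursor[ci] + gap
    starts <- g_start + cumsum(c(0L, head(ex_w, -1) + in_w))
    ends <- starts + ex_w - 1L
    iso <- .make_isoforms(starts, ends, config)
    for (k in seq_along(iso)) {
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        contig = contigs[ci], start = iso[[k]]$start, end = iso[[k]]$end,
        strand = strand, transcript_id = sprintf("%s.t%d", gene_id, k),
        gene_id = gene_id, stringsAsFactors = FALSE)
    }
    cursor[ci] <- max(ends) + 1L
    placed <- placed + 1L
  }
  ann <- if (length(exon_rows) == 0L) {
    AnnotationSet(GRanges(transcript_id = character(), gene_id = character()))
  } else {
    exdf <- do.call(rbind, exon_rows)
    AnnotationSet(makeGRangesFromDataFrame(exdf, keep.extra.columns = TRUE,
                                           seqnames.field = "contig"))
  }
  genome <- .random_genome(contigs, config$contig_length, config$gc_content)
  genome <- .write_splice_sites(genome, ann, config$gtag_fraction)
  list(genome = genome, annotation = ann, config = config)
}

.make_isoforms <- function(starts, ends, config) {
  n_ex <- length(starts)
  iso <- list(list(start = starts, end = ends))
  extra <- rpois(1, config$isoform_mean)
  for (k in seq_len(extra)) {
    if (n_ex >= 3L) {             # skip one internal exon
      drop <- sample(2:(n_ex - 1L), 1)
      cand <- list(start = starts[-drop], end = ends[-drop])
    } else if (n_ex == 2L) {      # retain the intron
      cand <- list(start = starts[1], end = ends[2])
    } else {                      # alternative (truncated) 5' end
      delta <- min(ends[1] - starts[1] - 30L, 50L)
      if (delta <= 0L) next
      cand <- list(start = starts[1] + delta, end = ends[1])
    }
    if (!any(vapply(iso, function(x) identical(x, cand), logical(1))))
      iso[[length(iso) + 1L]] <- cand
  }
  iso
}

.random_genome <- function(contigs, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(contigs, function(ct)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
  DNAStringSet(stats::setNames(seqs, contigs))
}

.write_splice_sites <- function(genome, ann, gtag_fraction) {
  ints <- BiocGenerics::unlist(introns_by_tx(ann), use.names = FALSE)
  if (length(ints) == 0L) return(genome)
  ints <- ints[!duplicated(interval_keys(ints))]
  canonical <- runif(length(ints)) < gtag_fraction
  chars <- lapply(genome, function(s) strsplit(as.character(s), "")[[1]])
  for (i in which(canonical)) {
    ct <- as.character(seqnames(ints)[i])
    s <- start(ints)[i]; e <- end(ints)[i]
    if (as.character(strand(ints)[i]) == "+") {
      chars[[ct]][s:(s + 1L)] <- c("G", "T")
      chars[[ct]][(e - 1L):e] <- c("A", "G")
    } else {
      chars[[ct]][s:(s + 1L)] <- c("C", "T")
      chars[[ct]][(e - 1L):e] <- c("A", "C")
    }
  }
  DNAStringSet(stats::setNames(
    vapply(chars, paste, character(1), collapse = ""), names(genome)))
}

#' Perturb a truth annotation into a "legacy" annotation
#'
#' Applies, at the configured rates: gene drops, gene splits (a multi-exon
#' gene cut at one of its introns into two gene models), isoform drops
#' (keeping at least one isoform), terminal-exon truncation by
#' `truncation_bp` (floor 1 bp) emulating missing UTRs, and spurious short
#' mono-exonic noise genes added in intergenic space. Deterministic per
#' (config, seed).
#'
#' @param truth The truth [AnnotationSet-class].
#' @param config A [simulation_config()].
#' @return List with `annotation` (the perturbed [AnnotationSet-class]) and
#'   `changes` (`data.frame` of per-gene actions).
#' @export
perturb_annotation <- function(truth, config) {
  set.seed(.sim_seed(config, 1L))
  ex <- ann_exons(truth)
  changes <- data.frame(gene_id = character(), action = character(),
                        stringsAsFactors = FALSE)
  log_change <- function(g, a)
    changes <<- rbind(changes, data.frame(gene_id = g, action = a,
                                          stringsAsFactors = FALSE))
  genes <- unique(mcols(ex)$gene_id)
  # gene drops
  drop <- genes[runif(length(genes)) < config$gene_drop]
  for (g in drop) log_change(g, "gene_drop")
  ex <- ex[!mcols(ex)$gene_id %in% drop]
  # gene splits
  genes <- unique(mcols(ex)$gene_id)
  for (g in genes[runif(length(genes)) < config$gene_split]) {
    gex <- ex[mcols(ex)$gene_id == g]
    tx1 <- mcols(gex)$transcript_id[1]
    ints <- exon_gaps(granges(gex[mcols(gex)$transcript_id == tx1]))
    if (length(ints) == 0L) next
    cut <- ints[sample(length(ints), 1)]
    pos <- start(cut) + (width(cut) %/% 2L)
    left <- end(gex) < pos
    if (!any(left) || all(left)) next
    mc <- mcols(gex)
    mc$gene_id <- ifelse(left, paste0(g, "a"), paste0(g, "b"))
    mc$transcript_id <- paste0(mc$transcript_id, ifelse(left, "a", "b"))
    mcols(gex) <- mc
    ex <- c(ex[mcols(ex)$gene_id != g], gex)
    log_change(g, "gene_split")
  }
  # isoform drops (keep >=1 per gene)
  tt_tx <- unique(mcols(ex)$transcript_id)
  first_tx <- tapply(mcols(ex)$transcript_id, mcols(ex)$gene_id,
                     function(t) t[1])
  droppable <- setdiff(tt_tx, unname(first_tx))
  tdrop <- droppable[runif(length(droppable)) < config$isoform_drop]
  if (length(tdrop) > 0L) {
    for (t in tdrop)
      log_change(mcols(ex)$gene_id[mcols(ex)$transcript_id == t][1],
                 "isoform_drop")
    ex <- ex[!mcols(ex)$transcript_id %in% tdrop]
  }
  # terminal-exon truncation
  genes <- unique(mcols(ex)$gene_id)
  for (g in genes[runif(length(genes)) < config$utr_truncation]) {
    idx <- which(mcols(ex)$gene_id == g)
    for (t in unique(mcols(ex)$transcript_id[idx])) {
      ti <- which(mcols(ex)$transcript_id == t)
      ti <- ti[order(start(ex)[ti])]
      first <- ti[1]; last <- ti[length(ti)]
      trim <- min(config$truncation_bp, width(ex)[first] - 1L)
      start(ex)[first] <- start(ex)[first] + trim
      trim <- min(config$truncation_bp, width(ex)[last] - 1L)
      end(ex)[last] <- end(ex)[last] - trim
    }
    log_change(g, "utr_truncation")
  }
  # spurious mono-exonic noise genes
  n_noise <- round(config$noise_gene_rate * length(unique(mcols(ex)$gene_id)))
  if (n_noise > 0L) {
    gaps <- .intergenic_regions(truth, config)
    gaps <- gaps[width(gaps) >= 400L]
    noise <- GRanges()
    for (i in seq_len(n_noise)) {
      r <- gaps[sample(length(gaps), 1, prob = width(gaps))]
      w <- sample(60:200, 1)
      s <- start(r) + sample.int(width(r) - w, 1)
      g <- GRanges(seqnames(r), IRanges(s, s + w - 1L),
                   strand = sample(c("+", "-"), 1))
      mcols(g)$transcript_id <- sprintf("NOISE%04d.t1", i)
      mcols(g)$gene_id <- sprintf("NOISE%04d", i)
      noise <- c(noise, g)
      log_change(sprintf("NOISE%04d", i), "noise_gene")
    }
    ex <- c(ex, noise)
  }
  list(annotation = AnnotationSet(ex), changes = changes)
}

.intergenic_regions <- function(truth, config) {
  genome <- GRanges(paste0("ctg", seq_len(config$n_contigs)),
                    IRanges(1L, config$contig_length))
  sp <- reduce(granges(gene_spans(truth)), ignore.strand = TRUE)
  seqlevels(sp) <- seqlevels(genome)
  GenomicRanges::setdiff(genome, sp, ignore.strand = TRUE)
}

#' Simulate stranded spliced reads
#'
#' Samples reads along transcripts proportional to expression weights (by
#' default, uniform per transcript scaled by spliced length); reads follow
#' the transcript strand and carry the exact introns they cross. A
#' configured fraction of reads is intergenic noise, placed wholly outside
#' every gene span. Deterministic per (config, seed).
#'
#' @param truth The truth [AnnotationSet-class].
#' @param config A [simulation_config()].
#' @param expression Optional named per-transcript weights.
#' @param n_reads Number of reads (default `config$read_depth`).
#' @return A `GRangesList` of read blocks; attribute `"meta"` maps each
#'   read to its source transcript (or `"noise"`).
#' @export
simulate_reads <- function(truth, config, expression = NULL,
                           n_reads = config$read_depth) {
  set.seed(.sim_seed(config, 2L))
  if (n_reads == 0L) return(GRangesList())
  rl <- config$read_length
  grl <- exons_by_tx(truth)
  grl <- S4Vectors::endoapply(grl, BiocGenerics::sort)
  lens <- sum(width(grl))
  w <- if (is.null(expression)) rep(1, length(grl)) else
    expression[names(grl)]
  w[is.na(w)] <- 0
  w <- w * lens
  is_noise <- runif(n_reads) < config$noise_read_rate
  n_genic <- sum(!is_noise)
  rows <- list()
  if (n_genic > 0L) {
    tx_of <- sample(seq_along(grl), n_genic, replace = TRUE, prob = w)
    for (ti in unique(tx_of)) {
      idx <- which(tx_of == ti)
      ex <- grl[[ti]]
      L <- sum(width(ex))
      len <- min(rl, L)
      s <- if (L > len) sample.int(L - len + 1L, length(idx), replace = TRUE)
           else rep(1L, length(idx))
      e <- s + len - 1L
      cw <- cumsum(width(ex))
      cs <- c(0L, head(cw, -1)) + 1L
      for (j in seq_along(ex)) {
        lo <- pmax(s, cs[j]); hi <- pmin(e, cw[j])
        hit <- lo <= hi
        if (!any(hit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          contig = as.character(seqnames(ex))[1],
          start = start(ex)[j] + lo[hit] - cs[j],
          end = start(ex)[j] + hi[hit] - cs[j],
          strand = as.character(strand(ex))[1],
          read = paste0("r", idx[hit]),
          tx = names(grl)[ti], stringsAsFactors = FALSE)
      }
    }
  }
  if (any(is_noise)) {
    gaps <- .intergenic_regions(truth, config)
    gaps <- gaps[width(gaps) >= rl]
    n_ns <- sum(is_noise)
    pick <- sample(length(gaps), n_ns, replace = TRUE,
                   prob = width(gaps) - rl + 1L)
    s <- start(gaps)[pick] +
      floor(runif(n_ns) * (width(gaps)[pick] - rl + 1L))
    rows[[length(rows) + 1L]] <- data.frame(
      contig = as.character(seqnames(gaps))[pick],
      start = as.integer(s), end = as.integer(s + rl - 1L),
      strand = sample(c("+", "-"), n_ns, replace = TRUE),
      read = paste0("n", seq_len(n_ns)), tx = "noise",
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- makeGRangesFromDataFrame(df, keep.extra.columns = TRUE,
                                 seqnames.field = "contig")
  reads <- GenomicRanges::split(granges(gr), mcols(gr)$read)
  meta <- df[!duplicated(df$read), c("read", "tx")]
  meta <- meta[match(names(reads), meta$read), ]
  rownames(meta) <- NULL
  attr(reads, "meta") <- meta
  reads
}

#' Simulate a tissue-biased expression matrix
#'
#' Log-normal per-gene baselines; a configured fraction of genes gets a
#' multiplicative bias in one random sexed tissue; log-normal replicate
#' noise. Deterministic per (config, seed).
#'
#' @param genes Character vector of gene ids.
#' @param config A [simulation_config()].
#' @param tissues Sexed-tissue labels (default all 16).
#' @param replicates Replicates per tissue (default 4).
#' @return An [expression_matrix()]; attribute `"bias"` holds the planted
#'   per-gene bias labels.
#' @export
simulate_expression_matrix <- function(genes, config,
                                       tissues = sexed_tissues(),
                                       replicates = 4L) {
  set.seed(.sim_seed(config, 3L))
  n <- length(genes)
  baseline <- rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  biased <- rep(NA_character_, n)
  pick <- sample(n, floor(config$bias_fraction * n))
  biased[pick] <- sample(tissues, length(pick), replace = TRUE)
  samples <- expand.grid(replicate = seq_len(replicates), tissue = tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sex <- sub("_.*", "", samples$tissue)
  samples$tissue <- sub("^[fm]_", "", samples$tissue)
  samples$sample_id <- paste0(samples$sex, "_", samples$tissue, "_r",
                              samples$replicate)
  values <- matrix(0, n, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  st <- paste(samples$sex, samples$tissue, sep = "_")
  for (j in seq_len(nrow(samples))) {
    mult <- ifelse(!is.na(biased) & biased == st[j], config$bias_strength, 1)
    noise <- if (config$replicate_noise_sd > 0)
      exp(rnorm(n, 0, config$replicate_noise_sd)) else 1
    values[, j] <- baseline * mult * noise
  }
  out <- expression_matrix(values, samples)
  attr(out, "bias") <- data.frame(gene_id = genes, biased_tissue = biased,
                                  stringsAsFactors = FALSE)
  out
}

#' Simulate a diverged second species with planted orthologs
#'
#' Duplicates the reference gene complement onto fresh contigs with the
#' gene order rearranged at a configured rate, gene sequences mutated by
#' i.i.d. substitutions, and (optionally) intron structure changed for a
#' fraction of genes. Returns the planted 1:1 map (a bijection over
#' retained genes) with a configured fraction flagged as withheld from the
#' "known ortholog" training set, an RBH homology table with dropout, and
#' an expression matrix correlated with the reference one.
#'
#' @param truth Output of [simulate_genome_and_annotation()].
#' @param config A [simulation_config()].
#' @param ref_expr Optional reference [expression_matrix()]; when given, a
#'   correlated query matrix is returned.
#' @return List with `genome`, `annotation` (query species), `homology`,
#'   `pairs` (`ref_gene`, `query_gene`, `withheld`), and `expr` (or `NULL`).
#' @export
simulate_ortholog_pair_species <- function(truth, config, ref_expr = NULL) {
  set.seed(.sim_seed(config, 4L))
  ann <- truth$annotation
  genome <- truth$genome
  ord <- gene_order(ann)
  sp <- gene_spans(ann)
  span_of <- stats::setNames(seq_along(sp), mcols(sp)$gene_id)
  ex <- ann_exons(ann)
  exon_rows <- list()
  qseqs <- list()
  pairs <- list()
  qi <- 0L
  for (ct in unique(ord$contig)) {
    ids <- ord$gene_id[ord$contig == ct]
    # rearrangement: remove and reinsert selected genes at random positions
    movers <- ids[runif(length(ids)) < config$rearrangement_rate]
    for (m in movers) {
      ids <- ids[ids != m]
      at <- sample.int(length(ids) + 1L, 1)
      ids <- append(ids, m, after = at - 1L)
    }
    cursor <- 1L
    qct <- paste0("q_", ct)
    chunk <- character(0)
    for (g in ids) {
      gap <- max(50L, round(rlnorm(1, config$intergenic_meanlog,
                                   config$intergenic_sdlog)))
      chunk <- c(chunk, paste(sample(c("A", "C", "G", "T"), gap,
                                     replace = TRUE), collapse = ""))
      gsp <- sp[span_of[[g]]]
      seq0 <- as.character(subseq(genome[[as.character(seqnames(gsp))]],
                                  start(gsp), end(gsp)))
      seq1 <- .mutate_sequence(seq0, config$substitution_rate)
      chunk <- c(chunk, seq1)
      qi <- qi + 1L
      qg <- sprintf("QG%05d", qi)
      offset <- cursor + gap - start(gsp)
      gex <- ex[mcols(ex)$gene_id == g]
      qex <- data.frame(contig = qct, start = start(gex) + offset,
                        end = end(gex) + offset,
                        strand = as.character(strand(gex)),
                        transcript_id = sub(g, qg, mcols(gex)$transcript_id,
                                            fixed = TRUE),
                        gene_id = qg, stringsAsFactors = FALSE)
      if (runif(1) < config$intron_change_rate) {
        # drop the gene's last intron: fuse the two last exons of each tx
        qex <- do.call(rbind, lapply(split(qex, qex$transcript_id), function(d) {
          d <- d[order(d$start), , drop = FALSE]
          if (nrow(d) >= 2L) {
            d$end[nrow(d) - 1L] <- d$end[nrow(d)]
            d <- d[-nrow(d), , drop = FALSE]
          }
          d
        }))
      }
      exon_rows[[length(exon_rows) + 1L]] <- qex
      pairs[[length(pairs) + 1L]] <- data.frame(ref_gene = g, query_gene = qg,
                                                stringsAsFactors = FALSE)
      cursor <- cursor + gap + nchar(seq1)
    }
    qseqs[[qct]] <- paste(chunk, collapse = "")
  }
  qgenome <- DNAStringSet(unlist(qseqs))
  qann <- AnnotationSet(makeGRangesFromDataFrame(
    do.call(rbind, exon_rows), keep.extra.columns = TRUE,
    seqnames.field = "contig"))
  pairs <- do.call(rbind, pairs)
  pairs$withheld <- FALSE
  pairs$withheld[sample(nrow(pairs), floor(config$known_withheld * nrow(pairs)))] <- TRUE
  keep_rbh <- runif(nrow(pairs)) >= config$rbh_dropout
  homology <- data.frame(ref_gene = pairs$ref_gene[keep_rbh],
                         query_gene = pairs$query_gene[keep_rbh],
                         score = 1 - config$substitution_rate,
                         rbh = TRUE, stringsAsFactors = FALSE)
  expr <- NULL
  if (!is.null(ref_expr)) {
    ridx <- match(pairs$ref_gene, rownames(ref_expr$values))
    values <- ref_expr$values[ridx, , drop = FALSE] *
      exp(matrix(rnorm(length(ridx) * ncol(ref_expr$values), 0,
                       config$expr_noise_sd),
                 nrow = length(ridx)))
    rownames(values) <- pairs$query_gene
    meta <- ref_expr$samples
    meta$sex_tissue <- NULL
    expr <- expression_matrix(values, meta)
  }
  list(genome = qgenome, annotation = qann, homology = homology,
       pairs = pairs, expr = expr)
}

.mutate_sequence <- function(seq, rate) {
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(ch)) < rate)
  if (length(idx) > 0L) {
    bases <- c("A", "C", "G", "T")
    ch[idx] <- vapply(ch[idx], function(b)
      sample(setdiff(bases, b), 1), character(1))
  }
  paste(ch, collapse = "")
}

#' Build a synthetic assembler with a planted optimum
#'
#' Returns an assembler function honoring the [run_sweep()] contract whose
#' output quality degrades monotonically with the normalized distance
#' between the supplied parameters and a planted optimum: transcripts are
#' dropped (in a fixed seeded order, nested across distances), terminal
#' exons truncated proportionally to the distance, and spurious mono-exonic
#' fragments added — the error modes a mistuned assembler shows. At the
#' optimum the truth annotation is returned exactly (exon Jaccard 1); the
#' objective strictly decreases along any single-parameter ray away from
#' it. Deterministic per (params, seed). Transcripts carry seeded
#' `fpkm`/`tpm` abundances so merge thresholds are exercised.
#'
#' @param truth The truth [AnnotationSet-class] the assembler reconstructs.
#' @param planted_optimum Named list of optimal parameter values.
#' @param param_ranges Named list of `c(min, max)` per parameter, used to
#'   normalize distances.
#' @param config A [simulation_config()] (for intergenic noise placement).
#' @param trunc_scale Max terminal truncation in bp at distance 1.
#' @param drop_frac Max fraction of transcripts dropped at distance 1.
#' @param noise_max Max number of spurious fragments at distance 1.
#' @return A function `(reads, params)` returning an [AnnotationSet-class].
#' @export
make_synthetic_assembler <- function(truth, planted_optimum, param_ranges,
                                     config, trunc_scale = 500L,
                                     drop_frac = 0.5, noise_max = 20L) {
  stopifnot(setequal(names(planted_optimum), names(param_ranges)))
  set.seed(.sim_seed(config, 5L))
  tx_ids <- transcript_ids(truth)
  drop_order <- sample(tx_ids)
  gaps <- .intergenic_regions(truth, config)
  gaps <- gaps[width(gaps) >= 300L]
  noise <- GRanges()
  for (i in seq_len(noise_max)) {
    r <- gaps[sample(length(gaps), 1, prob = width(gaps))]
    w <- sample(60:150, 1)
    s <- start(r) + sample.int(width(r) - w, 1)
    g <- GRanges(seqnames(r), IRanges(s, s + w - 1L),
                 strand = sample(c("+", "-"), 1))
    mcols(g)$transcript_id <- sprintf("ASM.noise%03d.t1", i)
    mcols(g)$gene_id <- sprintf("ASM.noise%03d", i)
    noise <- c(noise, g)
  }
  abundance <- stats::setNames(round(rlnorm(length(tx_ids), log(20), 1), 3),
                               tx_ids)
  function(reads, params) {
    unknown <- setdiff(names(params), names(planted_optimum))
    if (length(unknown) > 0L)
      stop("unknown assembler parameter(s): ", paste(unknown, collapse = ", "))
    d_i <- vapply(names(planted_optimum), function(p) {
      if (is.null(params[[p]])) return(0)
      r <- param_ranges[[p]]
      min(1, abs(params[[p]] - planted_optimum[[p]]) / (r[2] - r[1]))
    }, numeric(1))
    d <- mean(d_i)
    ex <- ann_exons(truth)
    n_drop <- min(length(tx_ids) - 1L, floor(d * drop_frac * length(tx_ids)))
    keep <- !mcols(ex)$transcript_id %in% drop_order[seq_len(n_drop)]
    ex <- ex[keep]
    trim <- as.integer(ceiling(d * trunc_scale))
    if (trim > 0L && length(ex) > 0L) {
      o <- order(mcols(ex)$transcript_id, start(ex))
      ex <- ex[o]
      txv <- mcols(ex)$transcript_id
      s <- start(ex); e <- end(ex)
      first <- !duplicated(txv)
      last <- !duplicated(txv, fromLast = TRUE)
      s2 <- s; e2 <- e
      s2[first] <- pmin(s[first] + trim, e[first])
      e2[last] <- pmax(e[last] - trim, s2[last])
      gr <- GRanges(seqnames(ex), IRanges(pmin(s2, e2), pmax(s2, e2)),
                    strand = strand(ex))
      mcols(gr) <- mcols(ex)
      ex <- gr
    }
    n_noise <- min(length(noise), floor(d * noise_max))
    out <- c(granges(ex), granges(noise[seq_len(n_noise)]))
    mcols(out)$transcript_id <- c(mcols(ex)$transcript_id,
                                  if (n_noise > 0L)
                                    mcols(noise)$transcript_id[seq_len(n_noise)])
    mcols(out)$gene_id <- c(mcols(ex)$gene_id,
                            if (n_noise > 0L)
                              mcols(noise)$gene_id[seq_len(n_noise)])
    ab <- abundance[mcols(out)$transcript_id]
    ab[is.na(ab)] <- 1
    mcols(out)$fpkm <- unname(ab)
    mcols(out)$tpm <- unname(ab)
    AnnotationSet(out)
  }
}
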