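# in-code fixtures shared by the suite

exons_gr <- function(contig, strand, tx, gene, starts, ends) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(starts, ends),
                         strand = strand, transcript_id = tx, gene_id = gene)
}

toy_ann <- function(...) {
  AnnotationSet(suppressWarnings(do.call(c, list(...))))
}

# one shared small simulated genome, built once per session
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_genome_and_annotation(
        simulation_config(seed = 42, n_genes = 30))
    cache
  }
})

# per-base boolean-vector Jaccard oracle on a single contig
oracle_jaccard <- function(sa, ea, sb, eb, L) {
  A <- rep(FALSE, L); B <- rep(FALSE, L)
  for (i in seq_along(sa)) A[sa[i]:ea[i]] <- TRUE
  for (i in seq_along(sb)) B[sb[i]:eb[i]] <- TRUE
  sum(A & B) / sum(A | B)
}

# random disjoint interval set on one contig
random_intervals <- function(n, L) {
  s <- sort(sample.int(L - 10L, n))
  e <- pmin(s + sample.int(200L, n), L)
  red <- IRanges::reduce(IRanges::IRanges(s, e))
  list(start = IRanges::start(red), end = IRanges::end(red))
}

# classify a cohort by distinct block structure (template-sampled cohorts
# contain many exact duplicates; the classification is structure-determined)
classify_cohort <- function(cohort, fun) {
  flat <- BiocGenerics::unlist(cohort, use.names = FALSE)
  grp <- rep(seq_along(cohort), S4Vectors::elementNROWS(cohort))
  per <- paste0(GenomicRanges::start(flat), "-", GenomicRanges::end(flat))
  sig <- paste(as.character(GenomicRanges::seqnames(flat))[!duplicated(grp)],
               as.character(BiocGenerics::strand(flat))[!duplicated(grp)],
               vapply(split(per, grp), paste, character(1), collapse = ";"))
  u <- which(!duplicated(sig))
  lut <- stats::setNames(
    vapply(u, function(i) fun(cohort[[i]]), character(1)), sig[u])
  unname(lut[sig])
}

# brute-force maximum bipartite matching of transcripts (chain equality for
# multi-exon; exonic Jaccard >= cutoff for mono-exonic), via augmenting paths
oracle_tx_matches <- function(pred, ref, cutoff = 0.6) {
  pgrl <- exons_by_tx(pred); rgrl <- exons_by_tx(ref)
  pch <- intron_chains(pred)[names(pgrl)]
  rch <- intron_chains(ref)[names(rgrl)]
  ok <- matrix(FALSE, length(pgrl), length(rgrl))
  for (i in seq_along(pgrl)) for (j in seq_along(rgrl)) {
    if (pch[i] != "" || rch[j] != "") {
      ok[i, j] <- pch[i] != "" && identical(unname(pch[i]), unname(rch[j]))
    } else {
      ok[i, j] <- transcript_jaccard(pgrl[[i]], rgrl[[j]]) >= cutoff
    }
  }
  match_of <- rep(0L, length(rgrl))
  try_assign <- function(i, env) {
    for (j in which(ok[i, ])) {
      if (env$seen[j]) next
      env$seen[j] <- TRUE
      if (match_of[j] == 0L || try_assign(match_of[j], env)) {
        match_of[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_len(nrow(ok))) {
    env <- new.env()
    env$seen <- rep(FALSE, ncol(ok))
    if (try_assign(i, env)) n <- n + 1L
  }
  n
}
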