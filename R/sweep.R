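#' Assembler parameter grid
#'
#' An ordered map from parameter name to a strictly increasing list of
#' candidate values, e.g. the first-round assembler grid
#' `parameter_grid(c = c(1, 3, 5, 7, 9), g = c(10, 30, 50, 70, 90), ...)`.
#'
#' @param ... Named numeric vectors, one per parameter.
#' @return A `parameter_grid` object.
#' @export
parameter_grid <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1]]) && is.null(names(vals)[1]))
    vals <- vals[[1]]
  nm <- names(vals)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("parameters must have unique non-empty names")
  for (p in nm) {
    v <- vals[[p]]
    if (!is.numeric(v) || length(v) == 0L)
      stop("parameter '", p, "' must have a non-empty numeric value list")
    if (any(diff(v) <= 0))
      stop("values of parameter '", p, "' must be strictly increasing")
  }
  structure(vals, class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat("parameter_grid (", length(x), " parameters, ",
      prod(lengths(unclass(x))), " combinations):\n", sep = "")
  for (p in names(x)) cat("  ", p, ": ", paste(x[[p]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate all parameter combinations
#'
#' Full Cartesian product in deterministic row-major order: the
#' first-declared parameter varies slowest, the last fastest. The row count
#' is the product of the value-list lengths (the second- and third-round
#' assembler grids enumerate to 89,100 and 152,460 combinations).
#'
#' @param grid A [parameter_grid()].
#' @return `data.frame`, one row per combination, columns in declared order.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  vals <- unclass(grid)
  if (length(vals) == 0L) stop("empty parameter grid")
  combos <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  combos <- combos[, rev(seq_along(vals)), drop = FALSE]
  rownames(combos) <- NULL
  combos
}

#' Run a parameter sweep against a reference annotation
#'
#' Evaluates every combination of `grid` by calling the assembler and
#' scoring the exon-level Jaccard of its output against the gold-standard
#' reference. A failing combination is recorded as `NA` and the sweep
#' continues. Ties for the maximum break by enumeration order.
#'
#' @param assembler A function `(reads, params)` returning an
#'   [AnnotationSet-class]; `params` is a named list (one grid row). See
#'   [make_synthetic_assembler()] for the packaged test assembler and
#'   [stringtie_assembler()] for wrapping an external binary.
#' @param reads Read blocks passed through to the assembler.
#' @param grid A [parameter_grid()].
#' @param reference Gold-standard [AnnotationSet-class].
#' @param stranded Stranded Jaccard objective (default).
#' @param cache Optional environment; objectives are memoized by parameter
#'   combination so a refinement schedule never re-runs an evaluated point.
#' @param round Round index stored in the result.
#' @return A `sweep_result`: list with `results` (combinations + objective),
#'   `best` (named list), `best_objective`, `round`.
#' @export
run_sweep <- function(assembler, reads, grid, reference, stranded = TRUE,
                      cache = NULL, round = 1L) {
  stopifnot(is.function(assembler), n_transcripts(reference) > 0L)
  combos <- enumerate_grid(grid)
  obj <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    key <- paste(names(params), unlist(params), sep = "=", collapse = ";")
    if (!is.null(cache) && !is.null(cache[[key]])) {
      obj[i] <- cache[[key]]
      next
    }
    obj[i] <- tryCatch(
      exon_jaccard(assembler(reads, params), reference, stranded = stranded),
      error = function(e) {
        message("combination ", key, " failed: ", conditionMessage(e))
        NA_real_
      })
    if (!is.null(cache)) cache[[key]] <- obj[i]
  }
  if (all(is.na(obj))) stop("no successful evaluation in sweep")
  results <- combos
  results$objective <- obj
  best_i <- which(obj == max(obj, na.rm = TRUE))[1]
  structure(list(results = results,
                 best = as.list(combos[best_i, , drop = FALSE]),
                 best_objective = obj[best_i],
                 round = round),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result (round ", x$round, "): ", nrow(x$results),
      " combinations, best objective ", signif(x$best_objective, 4), " at\n  ",
      paste(names(x$best), unlist(x$best), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Refine a grid around the incumbent optimum
#'
#' Builds the next-round grid: per parameter, values bracketing the
#' previous optimum at finer spacing (`seq(best - radius, best + radius,
#' by = step)`), clipped to hard bounds; a boundary optimum yields a
#' one-sided refinement (reported via `message()`). The incumbent value is
#' always a grid point, so the best objective never regresses between
#' rounds.
#'
#' @param prev_grid The previous [parameter_grid()].
#' @param best_combo Named list, the incumbent optimum (values present in
#'   `prev_grid`).
#' @param spec Named list, one entry per parameter:
#'   `list(radius = , step = )`.
#' @param bounds Optional named list of `c(lower, upper)` hard bounds.
#' @return A [parameter_grid()].
#' @export
refine_grid <- function(prev_grid, best_combo, spec, bounds = NULL) {
  stopifnot(inherits(prev_grid, "parameter_grid"))
  out <- list()
  for (p in names(prev_grid)) {
    b <- best_combo[[p]]
    if (is.null(b) || !any(abs(prev_grid[[p]] - b) < 1e-9))
      stop("best_combo value for '", p, "' is not in the previous grid")
    s <- spec[[p]]
    if (is.null(s)) {
      out[[p]] <- prev_grid[[p]]
      next
    }
    v <- seq(b - s$radius, b + s$radius, by = s$step)
    if (!is.null(bounds[[p]])) {
      keep <- v >= bounds[[p]][1] & v <= bounds[[p]][2]
      if (any(!keep))
        message("parameter '", p, "': refinement clipped to [",
                bounds[[p]][1], ", ", bounds[[p]][2], "] (one-sided)")
      v <- v[keep]
    }
    v <- sort(unique(round(c(v, b), 9)))
    if (length(v) == 0L) stop("refinement spec empties parameter '", p, "'")
    out[[p]] <- v
  }
  do.call(parameter_grid, out)
}

#' Multi-round sweep with grid refinement
#'
#' Runs `run_sweep` on the initial grid, then for each entry of `schedule`
#' refines around the incumbent (injecting it into the refined grid) and
#' sweeps again. Objectives are memoized across rounds, so the best
#' objective is non-decreasing.
#'
#' @inheritParams run_sweep
#' @param schedule List of refinement specs (see [refine_grid()]), one per
#'   additional round.
#' @param bounds Optional hard bounds passed to [refine_grid()].
#' @return List of `sweep_result`, one per round.
#' @export
run_refinement_schedule <- function(assembler, reads, grid, reference,
                                    schedule, bounds = NULL, stranded = TRUE) {
  cache <- new.env(parent = emptyenv())
  rounds <- list(run_sweep(assembler, reads, grid, reference,
                           stranded = stranded, cache = cache, round = 1L))
  for (k in seq_along(schedule)) {
    prev <- rounds[[k]]
    grid <- refine_grid(grid, prev$best, schedule[[k]], bounds = bounds)
    rounds[[k + 1L]] <- run_sweep(assembler, reads, grid, reference,
                                  stranded = stranded, cache = cache,
                                  round = k + 1L)
  }
  rounds
}

#' Merge sample-level annotations
#'
#' The merge contract behind species-level annotation building: transcripts
#' passing the abundance thresholds (`min_fpkm` = "F", `min_tpm` = "T") are
#' pooled across samples; multi-exon transcripts sharing an identical
#' intron chain collapse to one transcript whose exon set is the base
#' union; mono-exonic transcripts on the same strand within `gap` ("g")
#' bases of each other (or overlapping) are merged into one. Genes are
#' re-derived as connected components of same-strand exonic overlap.
#'
#' @param ann_list List of [AnnotationSet-class] objects whose exons may
#'   carry `fpkm`/`tpm` metadata columns (absent columns pass all
#'   thresholds).
#' @param min_fpkm,min_tpm,gap Merge parameters F, T, g.
#' @return An [AnnotationSet-class] with `MRG`-prefixed ids.
#' @export
merge_annotations <- function(ann_list, min_fpkm = 0, min_tpm = 0, gap = 0) {
  stopifnot(length(ann_list) >= 1L)
  pooled <- list()
  for (k in seq_along(ann_list)) {
    ex <- ann_exons(ann_list[[k]])
    if (length(ex) == 0L) next
    keep_tx <- transcript_ids(ann_list[[k]])
    mc <- mcols(ex)
    if ("fpkm" %in% colnames(mc)) {
      lvl <- tapply(mc$fpkm, mc$transcript_id, function(v) v[1])
      keep_tx <- intersect(keep_tx, names(lvl)[!is.na(lvl) & lvl >= min_fpkm])
    }
    if ("tpm" %in% colnames(mc)) {
      lvl <- tapply(mc$tpm, mc$transcript_id, function(v) v[1])
      keep_tx <- intersect(keep_tx, names(lvl)[!is.na(lvl) & lvl >= min_tpm])
    }
    ex <- ex[mc$transcript_id %in% keep_tx]
    if (length(ex) == 0L) next
    out <- granges(ex)
    mcols(out)$transcript_id <- paste0("s", k, ".", mcols(ex)$transcript_id)
    pooled[[length(pooled) + 1L]] <- out
  }
  if (length(pooled) == 0L)
    stop("no transcript passes the abundance thresholds")
  ex <- BiocGenerics::unlist(GRangesList(pooled))
  grl <- GenomicRanges::split(granges(ex), mcols(ex)$transcript_id)

  spans <- BiocGenerics::unlist(range(grl))
  chains <- .chain_keys_grl(grl)
  merged <- list()
  # multi-exon: one transcript per distinct chain (exon base union)
  multi <- names(chains)[chains != ""]
  for (key in unique(chains[multi])) {
    members <- names(chains)[chains == key]
    merged[[length(merged) + 1L]] <-
      reduce(BiocGenerics::unlist(grl[members], use.names = FALSE))
  }
  # mono-exonic: single-linkage clustering with gap tolerance
  mono <- names(chains)[chains == ""]
  if (length(mono) > 0L) {
    iv <- BiocGenerics::unlist(grl[mono], use.names = FALSE)
    cl <- reduce(iv, min.gapwidth = gap + 1L)
    for (i in seq_along(cl)) merged[[length(merged) + 1L]] <- cl[i]
  }
  exl <- GRangesList(merged)
  n_ex <- S4Vectors::elementNROWS(exl)
  flat <- BiocGenerics::unlist(exl, use.names = FALSE)
  mcols(flat)$transcript_id <- paste0("MRG.t", rep(seq_along(exl), n_ex))
  mcols(flat)$gene_id <- "tmp"
  flat <- .regroup_genes(flat, prefix = "MRG.g")
  AnnotationSet(flat)
}

# chain keys for a GRangesList of per-transcript exons
.chain_keys_grl <- function(grl) {
  vapply(seq_along(grl), function(i) {
    ints <- exon_gaps(grl[[i]])
    if (length(ints) == 0L) return("")
    paste0(as.character(seqnames(ints)[1]), ":", as.character(strand(ints)[1]),
           ":", paste0(start(ints), "-", end(ints), collapse = "|"))
  }, character(1)) -> keys
  stats::setNames(keys, names(grl))
}

# reassign gene_id by connected components of same-strand exonic overlap
.regroup_genes <- function(ex, prefix = "G") {
  tx <- factor(mcols(ex)$transcript_id, levels = unique(mcols(ex)$transcript_id))
  hits <- findOverlaps(ex, ex, ignore.strand = FALSE)
  a <- as.integer(tx[queryHits(hits)])
  b <- as.integer(tx[subjectHits(hits)])
  parent <- seq_len(nlevels(tx))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(nlevels(tx)), find, integer(1))
  comp <- match(roots, unique(roots))
  mcols(ex)$gene_id <- sprintf("%s%05d", prefix, comp[as.integer(tx)])
  ex
}

#' Optimize annotation-merge parameters
#'
#' Grid search over the merge parameters F (minimum FPKM), T (minimum TPM)
#' and g (merge gap): each combination merges the sample-level annotations
#' and scores the exon-level Jaccard against the reference. Combinations
#' producing an empty merge are recorded as `NA`.
#'
#' @param ann_list List of sample-level [AnnotationSet-class] objects (>= 2).
#' @param grid [parameter_grid()] over parameters named `F`, `T`, `g`.
#' @param reference Gold-standard [AnnotationSet-class].
#' @param stranded Stranded objective (default).
#' @return A `sweep_result`.
#' @export
optimize_merge_params <- function(ann_list, grid, reference, stranded = TRUE) {
  stopifnot(length(ann_list) >= 2L)
  merger <- function(reads, params) {
    merge_annotations(ann_list,
                      min_fpkm = if (is.null(params$F)) 0 else params$F,
                      min_tpm = if (is.null(params$T)) 0 else params$T,
                      gap = if (is.null(params$g)) 0 else params$g)
  }
  run_sweep(merger, reads = NULL, grid = grid, reference = reference,
            stranded = stranded)
}

#' Write sweep results as TSV
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_result <- function(sweep, path) {
  write.table(sweep$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Wrap an external assembler binary
#'
#' Builds an assembler function that shells out to a StringTie-compatible
#' binary through a command template. Placeholders `{bam}`, `{out}` and
#' `{params}` are substituted; parameters render as `-name value`. The
#' fixed settings of the optimized protocol (minimum transcript length 30,
#' the shortest annotated gene, and stranded mode `--rf`) are appended by
#' default. Requires the binary at run time; all package tests use
#' [make_synthetic_assembler()] instead.
#'
#' @param template Command template, e.g.
#'   `"stringtie {bam} {params} -m 30 --rf -o {out}"`.
#' @return A function `(reads, params)` where `reads` is a path to a BAM
#'   file; returns the assembled [AnnotationSet-class].
#' @export
stringtie_assembler <- function(template = "stringtie {bam} {params} -m 30 --rf -o {out}") {
  function(reads, params) {
    out <- tempfile(fileext = ".gtf")
    pstr <- paste(sprintf("-%s %s", names(params), unlist(params)),
                  collapse = " ")
    cmd <- gsub("{bam}", reads, template, fixed = TRUE)
    cmd <- gsub("{out}", out, cmd, fixed = TRUE)
    cmd <- gsub("{params}", pstr, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop("assembler command failed (exit ", status, "): ", cmd)
    read_gtf(out)
  }
}
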