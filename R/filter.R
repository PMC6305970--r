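#' Label predicted genes against the gold standard
#'
#' A predicted gene is a positive training example iff its best-matching
#' reference gene has exonic Jaccard strictly greater than `cutoff`
#' (default 0.6, the cutoff separating consistently predicted gene models
#' from assembler-only calls).
#'
#' @param pred,ref [AnnotationSet-class] objects on the same genome.
#' @param cutoff Jaccard cutoff in (0, 1).
#' @return `data.frame` with columns `gene_id`, `best_match`, `jaccard`,
#'   `shared_junctions`, `label` (logical).
#' @export
label_training_set <- function(pred, ref, cutoff = 0.6) {
  stopifnot(cutoff > 0, cutoff < 1)
  bm <- best_match_table(pred, ref)
  data.frame(gene_id = bm$query_gene_id,
             best_match = bm$subject_gene_id,
             jaccard = bm$jaccard,
             shared_junctions = bm$shared_junctions,
             label = bm$jaccard > cutoff,
             stringsAsFactors = FALSE)
}

# standardization used by every SVM in the package: natural-log(x+1) on
# expression columns, then z-scores from training statistics
.fit_scaler <- function(x) {
  x <- as.matrix(x)
  expr_cols <- grepl("^expr_", colnames(x))
  x[, expr_cols] <- log1p(x[, expr_cols])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale, expr_cols = expr_cols)
}

.apply_scaler <- function(x, scaler) {
  x <- as.matrix(x)
  x <- x[, names(scaler$center), drop = FALSE]
  x[, scaler$expr_cols] <- log1p(x[, scaler$expr_cols])
  scale(x, center = scaler$center, scale = scaler$scale)
}

# decision values oriented so that larger = more positive-class
.svm_decision <- function(fit, x) {
  p <- predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  if (strsplit(colnames(dv)[1], "/")[[1]][1] != "pos") dv <- -dv
  as.numeric(dv)
}

.binary_auc <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c("neg", "pos"), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# stratified k-fold assignment
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Train the SVM gene-model filter
#'
#' Grid search over kernel, penalty C and kernel coefficient gamma,
#' selecting by stratified cross-validated ROC AUC. The default grid is
#' kernels rbf and sigmoid with C and gamma each in
#' `10^(-3..3)`, plus the linear kernel over the same C list (gamma does
#' not apply); the incumbent optimum (rbf, C = 10, gamma = 0.1) is always a
#' grid point. Features are log1p-transformed (expression columns) and
#' z-standardized with training statistics before fitting.
#'
#' @param features Feature `data.frame` from [extract_features()] (rows
#'   named by gene).
#' @param labels Logical (or two-level) vector, one per row of `features`.
#' @param kernels Kernels to try (`"radial"` is the rbf kernel).
#' @param cost,gamma Numeric grids for C and gamma.
#' @param folds Cross-validation folds (stratified; default 5).
#' @param seed Seed for the fold assignment.
#' @return A `filter_model`: the refit [e1071::svm] model, the
#'   standardization statistics, the per-combination CV AUC table
#'   (`grid_results`), the selected hyperparameters (`best`) and their CV
#'   AUC (`cv_auc`).
#' @export
train_filter <- function(features, labels,
                         kernels = c("radial", "sigmoid", "linear"),
                         cost = 10^(-3:3), gamma = 10^(-3:3),
                         folds = 5, seed = 1) {
  y <- factor(ifelse(as.logical(labels), "pos", "neg"), levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both positive and negative examples are required")
  scaler <- .fit_scaler(features)
  x <- .apply_scaler(features, scaler)
  set.seed(seed)
  fold <- .stratified_folds(y, folds)
  grid <- do.call(rbind, lapply(kernels, function(k) {
    if (k == "linear") data.frame(kernel = k, cost = cost, gamma = NA_real_)
    else expand.grid(kernel = k, cost = cost, gamma = gamma,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  grid$cv_auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    aucs <- numeric(folds)
    ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2L || nlevels(droplevels(y[!tr])) < 2L) {
        ok <- FALSE
        break
      }
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                        kernel = grid$kernel[i], cost = grid$cost[i],
                        gamma = if (is.na(grid$gamma[i])) 1 / ncol(x)
                                else grid$gamma[i],
                        scale = FALSE)
      aucs[f] <- .binary_auc(y[!tr], .svm_decision(fit, x[!tr, , drop = FALSE]))
    }
    if (ok) grid$cv_auc[i] <- mean(aucs)
  }
  if (all(is.na(grid$cv_auc))) stop("cross-validation failed for every combination")
  best_i <- which(grid$cv_auc == max(grid$cv_auc, na.rm = TRUE))[1]
  best <- list(kernel = grid$kernel[best_i], cost = grid$cost[best_i],
               gamma = grid$gamma[best_i])
  fit <- e1071::svm(x, y, kernel = best$kernel, cost = best$cost,
                    gamma = if (is.na(best$gamma)) 1 / ncol(x) else best$gamma,
                    scale = FALSE)
  structure(list(svm = fit, scaler = scaler, grid_results = grid,
                 best = best, cv_auc = grid$cv_auc[best_i],
                 feature_names = colnames(.apply_scaler(features, scaler))),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  g <- if (is.na(x$best$gamma)) "-" else x$best$gamma
  cat("filter_model: kernel =", x$best$kernel, ", C =", x$best$cost,
      ", gamma =", g, "; CV AUC =", round(x$cv_auc, 3), "\n")
  invisible(x)
}

#' Apply the gene-model filter
#'
#' Classifies each predicted gene with a trained [train_filter()] model and
#' keeps the positives. The rejected genes, with their decision scores, are
#' attached as the `"audit"` attribute (and written to `audit_path` as TSV
#' when given).
#'
#' @param model A `filter_model`.
#' @param ann The predicted [AnnotationSet-class].
#' @param features Feature rows for (at least) every gene of `ann`.
#' @param audit_path Optional TSV path for the rejection audit.
#' @return The filtered [AnnotationSet-class] (attribute `"audit"`:
#'   `data.frame` of rejected genes with `decision` scores).
#' @export
apply_filter <- function(model, ann, features, audit_path = NULL) {
  genes <- gene_ids(ann)
  missing <- setdiff(genes, rownames(features))
  if (length(missing) > 0L)
    stop("features missing for gene(s): ", paste(head(missing, 3), collapse = ", "))
  x <- .apply_scaler(features[genes, , drop = FALSE], model$scaler)
  dv <- .svm_decision(model$svm, x)
  keep <- dv > 0
  audit <- data.frame(gene_id = genes[!keep], decision = dv[!keep],
                      stringsAsFactors = FALSE)
  if (!is.null(audit_path))
    write.table(audit, audit_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- subset_annotation(ann, genes = genes[keep])
  attr(out, "audit") <- audit
  out
}
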