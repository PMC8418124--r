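#' Rank genes by SVM recursive feature elimination
#'
#' Trains a linear soft-margin SVM (C = 1) on the current gene set, scores
#' genes by squared weight, and eliminates the lowest-scoring
#' ceiling(step_fraction * remaining) genes per round (one at a time once
#' fewer than 20 remain). The output is the elimination order reversed: the
#' last surviving gene gets rank 1.
#'
#' @param expr genes x samples matrix over the candidate genes (z-scored
#'   internally per gene).
#' @param labels binary class labels over the samples.
#' @param step_fraction fraction of remaining genes dropped per round.
#' @param seed seed (recorded; the linear SVM fit is deterministic).
#' @return character vector of gene ids, best (rank 1) first.
#' @export
svm_rfe_rank <- function(expr, labels, step_fraction = 0.1, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (length(labels) != ncol(expr)) stop("labels must match sample count")
  x <- t(zscore_rows(expr))
  genes <- colnames(x)
  if (length(genes) == 1L) return(genes)
  set.seed(seed)
  eliminated <- character(0)
  remaining <- genes
  while (length(remaining) > 1L) {
    fit <- e1071::svm(x = x[, remaining, drop = FALSE], y = labels,
                      type = "C-classification", kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    crit <- w^2
    n_drop <- if (length(remaining) < 20L) 1L
              else min(ceiling(step_fraction * length(remaining)),
                       length(remaining) - 1L)
    drop <- remaining[order(crit)][seq_len(n_drop)]
    eliminated <- c(eliminated, drop)
    remaining <- setdiff(remaining, drop)
  }
  rev(c(eliminated, remaining))
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sd[sd == 0] <- 1
  (m - mu) / sd
}

#' Choose a signature size by cross-validated SVM accuracy
#'
#' For each candidate size m, estimates the stratified cross-validated
#' accuracy of a linear SVM trained on the top-m ranked genes and returns
#' the genes of the size with the highest accuracy, ties toward smaller m.
#'
#' @param ranked gene ids ordered best-first (from \code{\link{svm_rfe_rank}}).
#' @param expr genes x samples matrix containing the ranked genes.
#' @param labels binary class labels.
#' @param candidate_sizes sizes to evaluate; defaults to a grid from 10 to
#'   min(300, length(ranked)).
#' @param cv_folds number of stratified folds.
#' @param seed seed for fold assignment.
#' @return list with \code{genes} (the selected top-m set), \code{size},
#'   and \code{accuracy} (data.frame of size vs CV accuracy).
#' @export
select_signature <- function(ranked, expr, labels, candidate_sizes = NULL,
                             cv_folds = 5L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (is.null(candidate_sizes)) {
    hi <- min(300L, length(ranked))
    candidate_sizes <- unique(c(seq(10L, hi, by = 10L), hi))
    candidate_sizes <- candidate_sizes[candidate_sizes >= 1L]
  }
  if (any(candidate_sizes < 1L | candidate_sizes > length(ranked)))
    stop("candidate sizes must lie in [1, length(ranked)]")
  x <- t(zscore_rows(expr[ranked, , drop = FALSE]))
  set.seed(seed)
  folds <- stratified_folds(labels, cv_folds)
  acc <- vapply(candidate_sizes, function(m) {
    cols <- ranked[seq_len(m)]
    correct <- 0L
    for (f in seq_len(max(folds))) {
      test <- folds == f
      if (length(unique(labels[!test])) < 2L) next
      fit <- e1071::svm(x = x[!test, cols, drop = FALSE], y = labels[!test],
                        type = "C-classification", kernel = "linear",
                        cost = 1, scale = FALSE)
      pred <- stats::predict(fit, x[test, cols, drop = FALSE])
      correct <- correct + sum(pred == labels[test])
    }
    correct / length(labels)
  }, numeric(1L))
  ord <- order(-acc, candidate_sizes)
  best <- as.integer(candidate_sizes[ord[1L]])
  list(genes = ranked[seq_len(best)], size = best,
       accuracy = data.frame(size = candidate_sizes, accuracy = acc))
}

# stratified fold ids: samples of each class spread evenly across folds
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  # guard: a fold must not hold all samples of a class
  folds
}

#' Consensus-cluster signature genes
#'
#' Groups the signature genes by consensus clustering with a
#' 1 - Pearson-correlation distance and a hierarchical base clusterer, so
#' co-regulated genes land in the same cluster.
#'
#' @param expr genes x samples matrix over the signature genes.
#' @param k_values cluster numbers to scan (default 2).
#' @param n_resamples consensus resamples.
#' @param seed integer seed.
#' @return list with \code{labels} (named per-gene cluster ids) and
#'   \code{selected_k}, plus the full \code{consensus_result}.
#' @export
cluster_signature_genes <- function(expr, k_values = 2L, n_resamples = 50L,
                                    seed = 1L) {
  if (nrow(expr) < 2L) {
    lab <- stats::setNames(rep(1L, nrow(expr)), rownames(expr))
    return(list(labels = lab, selected_k = 1L, consensus = NULL))
  }
  if (identical(as.integer(k_values), 1L)) {
    lab <- stats::setNames(rep(1L, nrow(expr)), rownames(expr))
    return(list(labels = lab, selected_k = 1L, consensus = NULL))
  }
  cr <- consensus_cluster(expr, k_values = k_values, n_resamples = n_resamples,
                          base = "hierarchical", distance = "one_minus_pearson",
                          seed = seed)
  lab <- stats::setNames(cr$labels[[as.character(cr$selected_k)]], rownames(expr))
  list(labels = lab, selected_k = cr$selected_k, consensus = cr)
}

#' First-principal-component summary of a gene cluster
#'
#' Genes are z-scored over the training samples, the first principal axis of
#' the samples x genes matrix is extracted, and its sign is oriented so the
#' PC1 sample score correlates positively with the cluster's mean z-scored
#' expression (PCA is sign-ambiguous without such a convention). Zero-variance
#' genes are dropped with a warning; a single-gene cluster reduces to the
#' z-scored gene itself.
#'
#' @param expr genes x samples matrix over one cluster's genes.
#' @return list with \code{loadings} (named unit vector), \code{center} and
#'   \code{sd} (per-gene standardisation), and \code{scores} (training PC1
#'   sample scores).
#' @export
fit_pc1 <- function(expr) {
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from PC1 fit")
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!nrow(expr)) stop("all genes have zero variance")
  center <- rowMeans(expr)
  z <- (expr - center) / sds
  if (nrow(z) == 1L) {
    loadings <- stats::setNames(1, rownames(z))
    scores <- as.numeric(z[1L, ])
  } else {
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    loadings <- pc$rotation[, 1L]
    scores <- as.numeric(t(z) %*% loadings)
    if (stats::cor(scores, colMeans(z)) < 0) {
      loadings <- -loadings
      scores <- -scores
    }
  }
  list(loadings = loadings, center = center, sd = sds,
       scores = stats::setNames(scores, colnames(expr)))
}

#' Assign hazard-direction sets to gene clusters
#'
#' Each cluster's oriented PC1 sample score is fitted in a single-covariate
#' Cox model; clusters with hazard ratio > 1 form the risk-increasing "i"
#' set and the rest (HR <= 1) the protective "j" set.
#'
#' @param cluster_labels named per-gene cluster ids.
#' @param expr genes x samples matrix over the signature genes.
#' @param surv a \code{\link{surv_data}} object over the same samples.
#' @return list with \code{direction} (named per-cluster "i"/"j"),
#'   \code{pc1} (per-cluster \code{\link{fit_pc1}} results), and
#'   \code{hr} (per-cluster hazard ratios).
#' @export
assign_direction_sets <- function(cluster_labels, expr, surv) {
  clusters <- sort(unique(cluster_labels))
  direction <- stats::setNames(character(length(clusters)), clusters)
  hr <- stats::setNames(numeric(length(clusters)), clusters)
  pc1 <- stats::setNames(vector("list", length(clusters)), clusters)
  for (cl in as.character(clusters)) {
    genes <- names(cluster_labels)[cluster_labels == cl]
    fit <- fit_pc1(expr[genes, , drop = FALSE])
    cf <- cox_fit(surv, fit$scores)
    hr[cl] <- cf$coefficients$hr[1L]
    direction[cl] <- if (hr[cl] > 1) "i" else "j"
    pc1[[cl]] <- fit
  }
  if (all(direction == "i") || all(direction == "j"))
    warning("all gene clusters fall in one hazard direction; the other set is empty")
  list(direction = direction, pc1 = pc1, hr = hr)
}

#' Compute TME-scores from a fitted model
#'
#' score = sum of PC1 sample scores over clusters in the risk-increasing
#' "i" set minus the sum over the protective "j" set. By default genes are
#' re-standardised within the scored cohort before projection (cross-platform
#' application); set \code{use_training_standardization = TRUE} to reuse the
#' training means/SDs. Requires >= 80% of the signature genes; missing genes'
#' loadings are dropped and each affected loading vector renormalised to unit
#' norm with a warning.
#'
#' @param expr genes x samples matrix (log2 scale recommended, matching
#'   training).
#' @param model a \code{tmescore_model} (see \code{\link{tmescore}}).
#' @param use_training_standardization reuse training per-gene center/sd.
#' @return data.frame with sample_id, per-cluster PC1 columns, tme_score,
#'   and group ("high"/"low" by the model cutoff).
#' @export
tme_score <- function(expr, model, use_training_standardization = FALSE) {
  sig <- model$signature_genes
  present <- intersect(sig, rownames(expr))
  cov <- length(present) / length(sig)
  if (cov < 0.8)
    stop(sprintf("signature coverage %.0f%% < 80%%; missing: %s", 100 * cov,
                 paste(setdiff(sig, present), collapse = ", ")))
  if (cov < 1)
    warning(length(sig) - length(present),
            " signature gene(s) missing; loadings renormalised")
  n <- ncol(expr)
  clusters <- names(model$direction)
  comp <- matrix(0, n, length(clusters),
                 dimnames = list(colnames(expr), paste0("PC1_cluster", clusters)))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    fit <- model$pc1[[cl]]
    genes <- intersect(names(fit$loadings), present)
    if (!length(genes)) stop("cluster ", cl, " has no genes present")
    load <- fit$loadings[genes]
    if (length(genes) < length(fit$loadings))
      load <- load / sqrt(sum(load^2))
    x <- expr[genes, , drop = FALSE]
    if (use_training_standardization) {
      z <- (x - fit$center[genes]) / fit$sd[genes]
    } else {
      sds <- apply(x, 1L, stats::sd)
      sds[sds == 0] <- 1
      z <- (x - rowMeans(x)) / sds
    }
    comp[, ci] <- as.numeric(t(z) %*% load)
  }
  sign_vec <- ifelse(model$direction == "i", 1, -1)
  score <- as.numeric(comp %*% sign_vec)
  group <- ifelse(score > model$cutoff, "high", "low")
  out <- data.frame(sample_id = colnames(expr), comp, tme_score = score,
                    group = group, row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Cytolytic activity score
#'
#' Geometric mean of the two cytolytic effector markers GZMA and PRF1 on
#' linear (TPM) scale, with a 0.01 pseudocount.
#'
#' @param expr linear-scale genes x samples matrix.
#' @param markers the two marker gene ids.
#' @return named numeric vector of per-sample CYT scores.
#' @export
cyt_score <- function(expr, markers = c("GZMA", "PRF1")) {
  miss <- setdiff(markers, rownames(expr))
  if (length(miss)) stop("cytolytic marker(s) absent: ", paste(miss, collapse = ", "))
  x <- expr[markers, , drop = FALSE] + 0.01
  stats::setNames(exp(colMeans(log(x))), colnames(expr))
}

#' T-cell-inflamed gene-expression-profile score
#'
#' Unweighted mean of log2 expression over an 18-gene inflammation panel.
#'
#' @param expr log2-scale genes x samples matrix.
#' @param gep_genes the 18 panel gene ids (supplied by the user; the panel
#'   is an input, not a bundled asset).
#' @param tolerance maximum number of panel genes allowed to be absent.
#' @return named numeric vector of per-sample GEP scores.
#' @export
gep_score <- function(expr, gep_genes, tolerance = 0L) {
  if (length(gep_genes) != 18L)
    stop("GEP panel must contain 18 genes, got ", length(gep_genes))
  miss <- setdiff(gep_genes, rownames(expr))
  if (length(miss) > tolerance)
    stop(length(miss), " GEP gene(s) missing: ", paste(miss, collapse = ", "))
  present <- intersect(gep_genes, rownames(expr))
  stats::setNames(colMeans(expr[present, , drop = FALSE]), colnames(expr))
}
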