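#' Fit a tumor-microenvironment scoring model
#'
#' Runs the full discovery pipeline on a training cohort: log2
#' transformation (and batch correction when batch labels are present),
#' nu-SVR deconvolution of immune-cell fractions against the reference
#' signature, consensus PAM clustering of the fractions into TME phenotypes,
#' empirical-Bayes moderated differential expression between the two
#' phenotypes, univariate Cox screening of the DEGs, consensus gene-cluster
#' discovery among patients, SVM-RFE ranking of the top DEG pool with
#' cross-validation-selected signature size, gene-side consensus clustering
#' of the signature, hazard-direction assignment of each gene cluster by a
#' Cox fit on its oriented PC1 score, and finally the per-sample
#' TME-score = sum(PC1, HR > 1 clusters) - sum(PC1, HR <= 1 clusters),
#' dichotomised at the maximally selected survival cutpoint.
#'
#' @param expr linear-scale genes x samples expression matrix (TPM-like).
#' @param clinical data.frame with sample_id, os_time, os_event and
#'   optionally batch; rows are matched to the expression columns by id.
#' @param reference linear-scale genes x cell-types signature matrix.
#' @param k_values phenotype cluster numbers scanned by consensus clustering.
#' @param n_resamples consensus resamples (1000 for production runs; small
#'   values keep exploratory runs fast).
#' @param deconv_permutations permutations for deconvolution p-values
#'   (0 skips them; they are not needed downstream).
#' @param fdr_threshold DEG threshold on the BH-adjusted p (default 0.01).
#' @param screen_threshold univariate Cox screening p threshold (default 0.05).
#' @param top_pool maximum DEG pool size handed to SVM-RFE (default 300).
#' @param candidate_sizes signature sizes scanned by cross-validation;
#'   defaults to a 10..300 grid clipped to the pool size.
#' @param cv_folds folds for the signature-size selection.
#' @param minprop minimum group fraction for the survival cutpoint.
#' @param seed integer seed controlling every stochastic stage.
#' @return object of class \code{tmescore}; see
#'   \code{\link{predict.tmescore}} for applying it to new cohorts.
#' @export
tmescore <- function(expr, clinical, reference, k_values = 2:6,
                     n_resamples = 50L, deconv_permutations = 0L,
                     fdr_threshold = 0.01, screen_threshold = 0.05,
                     top_pool = 300L, candidate_sizes = NULL, cv_folds = 5L,
                     minprop = 0.1, seed = 1L) {
  cl <- match.call()
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (length(shared) < 10L) stop("fewer than 10 samples shared between expression and clinical tables")
  expr <- expr[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  validate_clinical(clinical)
  surv <- surv_data(clinical$os_time, clinical$os_event, clinical$sample_id)

  # --- preprocessing -------------------------------------------------------
  log_expr <- log2_transform(expr)
  batch <- clinical$batch
  if (!is.null(batch) && length(unique(batch)) > 1L) {
    log_expr <- batch_correct(log_expr, batch)
  }
  lin_expr <- pmax(unlog2_transform(log_expr), 0)

  # --- deconvolution and phenotype discovery -------------------------------
  fractions <- nusvr_deconvolve(lin_expr, reference,
                                n_permutations = deconv_permutations,
                                seed = seed)
  frac_z <- scale(fractions$fractions)
  frac_z[, attr(frac_z, "scaled:scale") == 0] <- 0
  phen_cc <- consensus_cluster(frac_z, k_values = k_values,
                               n_resamples = n_resamples, base = "pam",
                               distance = "euclidean", seed = seed + 11L)
  if (phen_cc$selected_k == 2L) {
    phenotype <- phen_cc$labels[["2"]]
  } else {
    warning("consensus selected k = ", phen_cc$selected_k,
            "; using the k = 2 partition for the two-phenotype contrast")
    phenotype <- phen_cc$labels[["2"]]
  }
  phenotype <- stats::setNames(phenotype, shared)

  # --- differential expression and Cox screening ---------------------------
  de <- moderated_t_test(log_expr, phenotype)
  degs <- select_degs(de, fdr_threshold)
  if (length(degs) < 10L) stop("fewer than 10 DEGs at the FDR threshold; cannot build a signature")
  screen <- univariate_screen(log_expr[degs, , drop = FALSE], surv,
                              threshold = screen_threshold)
  representative <- screen$feature[screen$representative & !screen$skipped]
  if (length(representative) < 10L)
    stop("fewer than 10 prognostic DEGs after Cox screening")
  pool <- representative[seq_len(min(top_pool, length(representative)))]

  # --- patient gene-clusters and SVM-RFE signature -------------------------
  gene_cc <- consensus_cluster(t(zscore_rows(log_expr[pool, , drop = FALSE])),
                               k_values = 2L, n_resamples = n_resamples,
                               base = "pam", distance = "euclidean",
                               seed = seed + 23L)
  patient_gene_cluster <- stats::setNames(gene_cc$labels[["2"]], shared)
  ranked <- svm_rfe_rank(log_expr[pool, , drop = FALSE], patient_gene_cluster,
                         seed = seed + 31L)
  sel <- select_signature(ranked, log_expr, patient_gene_cluster,
                          candidate_sizes = candidate_sizes,
                          cv_folds = cv_folds, seed = seed + 41L)
  signature_genes <- sel$genes

  # --- gene clusters, directions, PC1 fits ---------------------------------
  sig_clust <- cluster_signature_genes(log_expr[signature_genes, , drop = FALSE],
                                       k_values = 2L, n_resamples = n_resamples,
                                       seed = seed + 53L)
  dir_fit <- assign_direction_sets(sig_clust$labels,
                                   log_expr[signature_genes, , drop = FALSE],
                                   surv)

  model <- list(signature_genes = signature_genes,
                gene_cluster_labels = sig_clust$labels,
                direction = dir_fit$direction,
                cluster_hr = dir_fit$hr,
                pc1 = dir_fit$pc1,
                cutoff = 0,
                provenance = list(seed = as.integer(seed),
                                  fdr_threshold = fdr_threshold,
                                  screen_threshold = screen_threshold,
                                  top_pool = as.integer(top_pool),
                                  n_resamples = as.integer(n_resamples),
                                  minprop = minprop,
                                  package_version = as.character(utils::packageVersion("tmescorer"))))
  class(model) <- "tmescore"

  # --- score the training cohort and learn the cutoff ----------------------
  scores <- tme_score(log_expr, model)
  cut <- optimal_cutpoint(scores$tme_score, surv, minprop = minprop)
  model$cutoff <- cut$cutoff
  scores$group <- ifelse(scores$tme_score > model$cutoff, "high", "low")

  lr <- logrank_test(surv, scores$group)
  cox_score <- cox_fit(surv, scale(scores$tme_score)[, 1L])

  model$training <- list(sample_ids = shared, phenotype = phenotype,
                         fractions = fractions, consensus = phen_cc,
                         de = de, degs = degs, screen = screen,
                         pool = pool,
                         patient_gene_cluster = patient_gene_cluster,
                         size_selection = sel$accuracy,
                         scores = scores, cutpoint = cut, logrank = lr,
                         cox_score = cox_score, surv = surv,
                         log_expr_signature = log_expr[signature_genes, , drop = FALSE])
  model$call <- cl
  model
}

#' Apply a fitted TME-score model to a cohort
#'
#' Scores a (possibly external) cohort with the trained signature. Requires
#' at least 80% of the signature genes. With survival data and
#' \code{refit_cutoff = TRUE} a cohort-specific dichotomisation cutoff is
#' determined by the maximally selected log-rank statistic; otherwise the
#' training cutoff is reused.
#'
#' @param object a fitted \code{tmescore} model.
#' @param expr linear-scale genes x samples matrix for the new cohort
#'   (log2-transformed internally), or a log2 matrix with
#'   \code{expr_scale = "log2"}.
#' @param surv optional \code{\link{surv_data}} for the cohort.
#' @param batch optional per-sample batch labels; when given, the log2
#'   matrix is batch-corrected before scoring (as in training).
#' @param refit_cutoff refit the dichotomisation cutoff in this cohort.
#' @param use_training_standardization standardise genes with the training
#'   means/SDs instead of within-cohort (default FALSE: cross-platform
#'   cohorts are re-standardised after preprocessing).
#' @param expr_scale declared scale of \code{expr}.
#' @param ... unused.
#' @return data.frame of per-sample scores and groups; when \code{surv} is
#'   given, attributes \code{logrank} and \code{cutoff} carry the survival
#'   contrast of the high/low groups.
#' @export
predict.tmescore <- function(object, expr, surv = NULL, batch = NULL,
                             refit_cutoff = FALSE,
                             use_training_standardization = FALSE,
                             expr_scale = c("linear", "log2"), ...) {
  expr_scale <- match.arg(expr_scale)
  log_expr <- if (expr_scale == "linear") log2_transform(expr) else expr
  if (!is.null(batch) && length(unique(batch)) > 1L)
    log_expr <- batch_correct(log_expr, batch)
  res <- tme_score(log_expr, object,
                   use_training_standardization = use_training_standardization)
  cutoff <- object$cutoff
  lr <- NULL
  if (!is.null(surv)) {
    if (refit_cutoff) {
      cut <- optimal_cutpoint(res$tme_score, surv,
                              minprop = object$provenance$minprop)
      cutoff <- cut$cutoff
      res$group <- ifelse(res$tme_score > cutoff, "high", "low")
    }
    lr <- logrank_test(surv, res$group)
  }
  attr(res, "cutoff") <- cutoff
  attr(res, "logrank") <- lr
  res
}

#' @export
print.tmescore <- function(x, ...) {
  n_i <- sum(x$direction == "i"); n_j <- sum(x$direction == "j")
  cat("TME-score model\n")
  cat(sprintf("  signature genes: %d in %d cluster(s) (%d HR>1 'i', %d HR<=1 'j')\n",
              length(x$signature_genes), length(x$direction), n_i, n_j))
  cat(sprintf("  dichotomisation cutoff: %.4f\n", x$cutoff))
  if (!is.null(x$training))
    cat(sprintf("  trained on %d samples; high-vs-low log-rank p = %.3g\n",
                length(x$training$sample_ids), x$training$logrank$p))
  invisible(x)
}

#' @export
summary.tmescore <- function(object, ...) {
  x <- object
  cat("TME-score model summary\n\n")
  cat("Gene clusters and hazard directions:\n")
  for (cl in names(x$direction)) {
    cat(sprintf("  cluster %s: %d genes, HR = %.3f, direction '%s'\n", cl,
                sum(x$gene_cluster_labels == as.integer(cl)),
                x$cluster_hr[cl], x$direction[cl]))
  }
  if (!is.null(x$training)) {
    tr <- x$training
    cat(sprintf("\nTraining cohort: %d samples, %d DEGs at FDR < %g, pool %d\n",
                length(tr$sample_ids), length(tr$degs),
                x$provenance$fdr_threshold, length(tr$pool)))
    cat(sprintf("Selected phenotype k: %d\n", tr$consensus$selected_k))
    cat(sprintf("Cutpoint %.4f (log-rank chi2 %.2f); Cox per-SD HR %.3f (p %.3g)\n",
                x$cutoff, tr$cutpoint$chi2,
                tr$cox_score$coefficients$hr[1L], tr$cox_score$coefficients$p[1L]))
  }
  invisible(x)
}

#' @export
coef.tmescore <- function(object, ...) {
  data.frame(cluster = names(object$direction),
             n_genes = as.integer(table(object$gene_cluster_labels)[names(object$direction)]),
             hr = unname(object$cluster_hr),
             direction = unname(object$direction),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves of the high/low TME-score groups
#'
#' @param x a fitted \code{tmescore} model with training data.
#' @param ... passed to \code{plot}.
#' @method plot tmescore
#' @export
plot.tmescore <- function(x, ...) {
  if (is.null(x$training)) stop("model carries no training data to plot")
  surv <- x$training$surv
  grp <- x$training$scores$group
  fit <- survival::survfit(as_Surv(surv) ~ grp)
  graphics::plot(fit, col = c("firebrick", "steelblue"), lwd = 2,
                 xlab = "Time (days)", ylab = "Survival probability", ...)
  graphics::legend("topright", legend = c("high TME-score", "low TME-score"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  graphics::title(sprintf("log-rank p = %.3g", x$training$logrank$p))
  invisible(x)
}

#' Serialise a TME-score model to JSON
#'
#' Writes the fields needed to score new cohorts (signature genes, gene
#' clusters, directions, PC1 loadings and standardisation, cutoff,
#' provenance) at full double precision, so a round trip reproduces scores
#' bitwise.
#'
#' @param model a \code{tmescore} model.
#' @param path output path.
#' @export
write_tmescore_model <- function(model, path) {
  obj <- list(signature_genes = model$signature_genes,
              gene_cluster_labels = as.list(model$gene_cluster_labels),
              direction = as.list(model$direction),
              cluster_hr = as.list(model$cluster_hr),
              pc1 = lapply(model$pc1, function(f)
                list(loadings = as.list(f$loadings),
                     center = as.list(f$center),
                     sd = as.list(f$sd))),
              cutoff = model$cutoff,
              provenance = model$provenance)
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a TME-score model from JSON
#' @param path path written by \code{\link{write_tmescore_model}}.
#' @return a \code{tmescore} model (without training data).
#' @export
read_tmescore_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- list(signature_genes = unlist(obj$signature_genes),
                gene_cluster_labels = unlist(obj$gene_cluster_labels),
                direction = unlist(obj$direction),
                cluster_hr = unlist(obj$cluster_hr),
                pc1 = lapply(obj$pc1, function(f)
                  list(loadings = unlist(f$loadings),
                       center = unlist(f$center),
                       sd = unlist(f$sd))),
                cutoff = obj$cutoff,
                provenance = obj$provenance)
  class(model) <- "tmescore"
  model
}
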