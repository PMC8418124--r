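#' Convert FPKM to TPM
#'
#' Column-wise renormalisation: TPM[g,j] = FPKM[g,j] / sum_g FPKM[g,j] * 1e6,
#' so every sample sums to one million.
#'
#' @param m linear-scale genes x samples matrix of FPKM values.
#' @return matrix of TPM values.
#' @export
fpkm_to_tpm <- function(m) {
  if (any(m < 0)) stop("FPKM values must be nonnegative")
  cs <- colSums(m)
  if (any(cs == 0)) stop("all-zero column(s): ",
                         paste(colnames(m)[cs == 0], collapse = ", "))
  sweep(m, 2L, cs, "/") * 1e6
}

#' Log2 transform with pseudocount
#'
#' @param m linear-scale matrix.
#' @param pseudocount added before taking log2; default 1.
#' @return log2-scale matrix.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (pseudocount <= 0 && any(m == 0))
    stop("pseudocount must be positive when the matrix contains zeros")
  log2(m + pseudocount)
}

#' Inverse of \code{log2_transform}
#' @param m log2-scale matrix.
#' @param pseudocount the pseudocount used in the forward transform.
#' @export
unlog2_transform <- function(m, pseudocount = 1) {
  2^m - pseudocount
}

#' Quantile normalisation
#'
#' Forces all samples onto a common distribution: each column's sorted values
#' are replaced by the across-column mean of the order statistics; tied
#' values receive the mean of their positions' reference values so ties stay
#' tied.
#'
#' @param m genes x samples matrix, at least two samples.
#' @return normalised matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L) {
    warning("quantile normalisation needs >= 2 samples; returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Empirical-Bayes batch correction
#'
#' Parametric location/scale adjustment: per-gene batch means and variances
#' are shrunk toward pooled priors, subtracted and rescaled (ComBat). Input
#' should be on log scale. Biological group labels can be protected so their
#' signal is not absorbed into the batch term. A single batch is a no-op.
#'
#' @param m genes x samples matrix (log2 scale recommended).
#' @param batch per-sample batch labels.
#' @param protect optional per-sample group labels to preserve.
#' @return adjusted matrix.
#' @export
batch_correct <- function(m, batch, protect = NULL) {
  batch <- as.factor(batch)
  if (length(batch) != ncol(m)) stop("batch labels must match sample count")
  if (nlevels(droplevels(batch)) < 2L) return(m)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  mod <- NULL
  if (!is.null(protect)) mod <- stats::model.matrix(~ as.factor(protect))
  # drop genes that are constant within some batch (zero within-batch variance
  # breaks the scale model); reinstate them unchanged afterwards
  ok <- rep(TRUE, nrow(m))
  for (b in levels(batch)) {
    v <- matrixStats_rowVars(m[, batch == b, drop = FALSE])
    ok <- ok & v > 1e-12
  }
  out <- m
  if (any(ok)) {
    adj <- suppressMessages(
      sva::ComBat(dat = m[ok, , drop = FALSE], batch = batch, mod = mod,
                  par.prior = TRUE, prior.plots = FALSE))
    out[ok, ] <- adj
  }
  if (any(!ok))
    warning(sum(!ok), " gene(s) constant within a batch left unadjusted")
  out
}

# row variances without extra dependencies
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

#' Merge expression cohorts on their shared genes
#'
#' Restricts every cohort to the intersection of gene identifiers and
#' concatenates samples, tagging each with its cohort label. Duplicate
#' sample ids across cohorts are suffixed with the cohort label. Callers
#' building a meta-cohort are expected to follow with
#' \code{\link{batch_correct}} using the returned cohort labels.
#'
#' @param cohorts named list; each element a list with \code{expr}
#'   (genes x samples matrix) and optionally \code{clinical} (data.frame).
#' @return list with \code{expr}, \code{clinical} (row-bound, possibly NULL),
#'   and \code{cohort} (per-sample label vector).
#' @export
merge_cohorts <- function(cohorts) {
  if (length(cohorts) < 2L) stop("need at least two cohorts")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  genes <- Reduce(intersect, lapply(cohorts, function(x) rownames(x$expr)))
  if (!length(genes)) stop("no genes shared across cohorts")
  seen <- character(0)
  mats <- vector("list", length(cohorts))
  clin <- vector("list", length(cohorts))
  labels <- character(0)
  for (i in seq_along(cohorts)) {
    m <- cohorts[[i]]$expr[genes, , drop = FALSE]
    dup <- colnames(m) %in% seen
    if (any(dup)) {
      warning("duplicate sample ids across cohorts suffixed with cohort label")
      colnames(m)[dup] <- paste(colnames(m)[dup], names(cohorts)[i], sep = "_")
    }
    seen <- c(seen, colnames(m))
    mats[[i]] <- m
    labels <- c(labels, rep(names(cohorts)[i], ncol(m)))
    ci <- cohorts[[i]]$clinical
    if (!is.null(ci)) {
      ci$cohort <- names(cohorts)[i]
      clin[[i]] <- ci
    }
  }
  clin <- clin[!vapply(clin, is.null, logical(1L))]
  clinical <- if (length(clin)) do.call(rbind, clin) else NULL
  if (!is.null(clinical)) rownames(clinical) <- NULL
  list(expr = do.call(cbind, mats), clinical = clinical, cohort = labels)
}
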