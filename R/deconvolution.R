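#' Estimate immune-cell fractions by nu-SVR deconvolution
#'
#' Regresses each bulk mixture on a reference signature matrix with linear
#' nu-support-vector regression, the estimator popularised for leukocyte
#' deconvolution with the LM22 reference. For every sample the mixture and
#' the signature columns are z-standardised over the genes shared with the
#' reference, a linear nu-SVR is fitted for each value on the nu grid,
#' negative coefficients are clipped to zero and the remainder renormalised
#' to a fraction vector summing to one. The nu minimising the RMSE between
#' the reconstructed and observed standardised mixture is kept (ties toward
#' smaller nu). Significance is assessed by permuting the mixture values
#' across genes: the p-value is the fraction of permutations whose best-fit
#' Pearson r reaches the observed one.
#'
#' @param mixture linear-scale genes x samples bulk matrix.
#' @param sig linear-scale genes x cell-types reference signature matrix.
#' @param nu_grid values of nu to try; default c(0.25, 0.5, 0.75).
#' @param n_permutations permutations for the p-value; 0 skips it (p = NA).
#' @param seed integer seed for the permutation stream.
#' @return object of class \code{cell_fractions}: list with \code{fractions}
#'   (samples x cell types, rows on the probability simplex), \code{rmse},
#'   \code{pearson_r}, \code{p_value} (per sample) and \code{n_permutations}.
#' @export
nusvr_deconvolve <- function(mixture, sig, nu_grid = c(0.25, 0.5, 0.75),
                             n_permutations = 100L, seed = 1L) {
  if (ncol(sig) < 2L) stop("reference needs at least 2 cell types")
  shared <- intersect(rownames(mixture), rownames(sig))
  cov <- length(shared) / nrow(sig)
  if (cov < 0.5)
    stop(sprintf("only %.0f%% of signature genes present in mixture (need >= 50%%)",
                 100 * cov))
  if (cov < 0.8)
    warning(sprintf("signature gene coverage is %.0f%%", 100 * cov))
  S <- sig[shared, , drop = FALSE]
  Sz <- scale(S)
  M <- mixture[shared, , drop = FALSE]
  n_s <- ncol(M)
  k <- ncol(S)
  fractions <- matrix(0, n_s, k, dimnames = list(colnames(M), colnames(S)))
  rmse <- pearson_r <- rep(NA_real_, n_s)
  p_value <- rep(NA_real_, n_s)

  fit_one <- function(y) {
    yz <- as.numeric(scale(y))
    best <- NULL
    for (nu in nu_grid) {
      fit <- e1071::svm(x = Sz, y = yz, type = "nu-regression",
                        kernel = "linear", cost = 1, nu = nu, scale = FALSE)
      w <- as.numeric(t(fit$coefs) %*% fit$SV)
      u <- pmax(w, 0)
      recon <- as.numeric(Sz %*% u)
      r <- sum((recon - yz)^2)
      if (is.null(best) || r < best$sse - 1e-12) {
        best <- list(w = u, sse = r,
                     rmse = sqrt(mean((recon - yz)^2)),
                     r = suppressWarnings(stats::cor(recon, yz)))
      }
    }
    best
  }

  for (j in seq_len(n_s)) {
    b <- fit_one(M[, j])
    if (sum(b$w) > 0) fractions[j, ] <- b$w / sum(b$w)
    rmse[j] <- b$rmse
    pearson_r[j] <- if (is.na(b$r)) 0 else b$r
  }

  if (n_permutations > 0L) {
    set.seed(seed)
    null_r <- vapply(seq_len(n_permutations), function(i) {
      y <- sample(as.numeric(M))[seq_along(shared)]
      b <- fit_one(y)
      if (is.na(b$r)) 0 else b$r
    }, numeric(1L))
    for (j in seq_len(n_s)) {
      if (sum(fractions[j, ]) == 0) p_value[j] <- 1
      else p_value[j] <- mean(null_r >= pearson_r[j])
    }
  }

  structure(list(fractions = fractions, rmse = rmse, pearson_r = pearson_r,
                 p_value = p_value, n_permutations = as.integer(n_permutations),
                 nu_grid = nu_grid, seed = as.integer(seed)),
            class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat(sprintf("Cell fractions: %d samples x %d cell types (nu grid %s, %d permutations)\n",
              nrow(x$fractions), ncol(x$fractions),
              paste(x$nu_grid, collapse = "/"), x$n_permutations))
  cat("Mean fractions:\n")
  print(round(colMeans(x$fractions), 3))
  invisible(x)
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ranks for ties)
#' and each gene set is scored by the integrated difference between the
#' rank-weighted empirical CDF of set members and the uniform ECDF of
#' non-members, walking gene positions in decreasing rank order:
#' ES = sum_i (cum. weighted hit mass - cum. miss mass) with hit weights
#' rank^alpha.
#'
#' @param expr genes x samples matrix (any monotone scale; scores are
#'   rank-based within sample).
#' @param sets named list of gene-id vectors.
#' @param alpha rank-weighting exponent; default 0.25.
#' @param rescale if TRUE, additionally min-max rescale each set's scores
#'   across samples to [0, 1].
#' @return samples x sets numeric matrix.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, rescale = FALSE) {
  sets <- lapply(sets, intersect, y = rownames(expr))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("gene set(s) with no members in the matrix: ",
         paste(empty, collapse = ", "))
  n_g <- nrow(expr)
  out <- matrix(NA_real_, ncol(expr), length(sets),
                dimnames = list(colnames(expr), names(sets)))
  memb <- lapply(sets, function(s) rownames(expr) %in% s)
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    ra <- r[ord]^alpha
    for (s in seq_along(sets)) {
      hit <- memb[[s]][ord]
      n_in <- sum(hit)
      hit_mass <- cumsum(ra * hit) / sum(ra[hit])
      miss_mass <- cumsum(!hit) / max(n_g - n_in, 1L)
      out[j, s] <- sum(hit_mass - miss_mass)
    }
  }
  if (rescale) {
    rng <- apply(out, 2L, function(v) diff(range(v)))
    mins <- apply(out, 2L, min)
    out <- sweep(sweep(out, 2L, mins, "-"), 2L,
                 ifelse(rng > 0, rng, 1), "/")
  }
  out
}

#' Immune, stromal and combined microenvironment scores
#'
#' ssGSEA enrichment of an immune and a stromal gene set per sample, plus
#' their sum, mirroring the ESTIMATE convention for quantifying non-tumor
#' content from expression.
#'
#' @param expr genes x samples matrix.
#' @param immune_set,stromal_set character vectors of gene ids.
#' @param alpha rank-weighting exponent passed to \code{\link{ssgsea_scores}}.
#' @return samples x 3 matrix with columns ImmuneScore, StromalScore,
#'   ESTIMATEScore.
#' @export
estimate_scores <- function(expr, immune_set, stromal_set, alpha = 0.25) {
  if (length(intersect(immune_set, stromal_set)))
    warning("immune and stromal sets overlap")
  if (!length(intersect(immune_set, rownames(expr))))
    stop("immune set absent from expression matrix")
  if (!length(intersect(stromal_set, rownames(expr))))
    stop("stromal set absent from expression matrix")
  s <- ssgsea_scores(expr, list(ImmuneScore = immune_set,
                                StromalScore = stromal_set), alpha = alpha)
  cbind(s, ESTIMATEScore = s[, "ImmuneScore"] + s[, "StromalScore"])
}
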