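#' Empirical-Bayes moderated two-sample t-test
#'
#' Per gene: the group mean difference on the log2 scale, the pooled
#' residual variance s2 with d = n - 2 degrees of freedom, and a moderated
#' t-statistic in which s2 is shrunk toward a prior variance s0^2 with d0
#' prior degrees of freedom. The hyperparameters (d0, s0^2) are estimated by
#' matching the moments of log s2 to a scaled-F model across genes
#' (trigamma inversion of the excess variance of log s2); the posterior
#' variance is (d0 s0^2 + d s2) / (d0 + d) and p-values use d0 + d degrees
#' of freedom. When the gene-wise variances carry no excess spread, d0 is
#' infinite and every gene gets the common variance.
#'
#' @param expr log2-scale genes x samples matrix.
#' @param groups two-level factor (or coercible) over the samples; the
#'   reported log fold change is level 2 minus level 1.
#' @return data.frame (one row per gene) with columns gene_id, log_fc, t_mod,
#'   df_total, p, fdr, plus attributes \code{d0} and \code{s0_sq}.
#' @export
moderated_t_test <- function(expr, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (length(groups) != ncol(expr)) stop("groups must match sample count")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 samples")
  x1 <- expr[, groups == levels(groups)[1L], drop = FALSE]
  x2 <- expr[, groups == levels(groups)[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  beta <- m2 - m1
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- ss / df

  hp <- fit_f_dist(s2[s2 > 0], df)
  d0 <- hp$d0; s0_sq <- hp$s0_sq

  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, beta / se, 0)
  # a gene flat in both groups carries no evidence either way
  t_mod[s2 == 0 & beta == 0] <- 0
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[s2 == 0 & beta == 0] <- 1
  out <- data.frame(gene_id = rownames(expr), log_fc = beta, t_mod = t_mod,
                    df_total = rep(df_total, length(beta)), p = p,
                    fdr = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Moment-matching fit of a scaled F / log-chi-square model to gene variances:
# log s2 has mean log s0^2 + digamma(d/2) - log(d/2) - (digamma(d0/2) -
# log(d0/2)) and excess variance trigamma(d0/2) beyond trigamma(d/2).
fit_f_dist <- function(s2, df) {
  if (!length(s2)) stop("no positive gene variances to fit")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- sum((e - e_mean)^2) / (length(e) - 1L)
  excess <- e_var - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in log s2: all genes share one variance, estimated
    # by the plain mean (the limiting form of the posterior as d0 -> Inf)
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x on y > 0 (trigamma is strictly decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment q_(i) = min_{j >= i} m p_(j) / j, capped at 1 and
#' mapped back to the input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return vector of FDR values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes at an FDR threshold
#'
#' @param t data.frame from \code{\link{moderated_t_test}}.
#' @param fdr_threshold FDR cutoff; genes with fdr < threshold are returned.
#' @return character vector of gene ids sorted by decreasing |t_mod|.
#' @export
select_degs <- function(t, fdr_threshold = 0.01) {
  keep <- t[t$fdr < fdr_threshold, , drop = FALSE]
  keep$gene_id[order(-abs(keep$t_mod))]
}
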