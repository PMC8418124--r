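#' Partitioning Around Medoids on a dissimilarity matrix
#'
#' k-medoids clustering: a greedy BUILD phase seeds the medoids, then SWAP
#' passes exchange a medoid and a non-medoid whenever that strictly lowers
#' the total dissimilarity of items to their medoids, until a local optimum.
#' Deterministic given the input order.
#'
#' @param dissimilarity square symmetric nonnegative matrix with zero diagonal.
#' @param k number of clusters, 1 <= k <= n.
#' @param seed unused by the deterministic algorithm; kept for interface
#'   stability and recorded in the result.
#' @return object of class \code{pam_result}: list with \code{medoid_indices},
#'   \code{labels} (medoid index of each item recoded 1..k) and
#'   \code{total_cost}.
#' @export
pam_cluster <- function(dissimilarity, k, seed = 1L) {
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  if (ncol(d) != n) stop("dissimilarity must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity must be symmetric")
  if (any(d < 0)) stop("dissimilarity must be nonnegative")
  if (k < 1L || k > n) stop("k must be in [1, n]")
  if (k == n) {
    return(structure(list(medoid_indices = seq_len(n), labels = seq_len(n),
                          total_cost = 0), class = "pam_result"))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE, do.swap = TRUE,
                      keep.diss = FALSE, keep.data = FALSE)
  med <- as.integer(fit$id.med)
  labels <- as.integer(fit$clustering)
  total_cost <- sum(d[cbind(seq_len(n), med[labels])])
  structure(list(medoid_indices = med, labels = labels,
                 total_cost = total_cost, seed = as.integer(seed)),
            class = "pam_result")
}

#' @export
print.pam_result <- function(x, ...) {
  cat(sprintf("PAM: %d clusters over %d items, total cost %.4f\n",
              length(x$medoid_indices), length(x$labels), x$total_cost))
  invisible(x)
}

cluster_items <- function(d, k, base) {
  if (base == "pam") {
    pam_cluster(d, k)$labels
  } else {
    as.integer(stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k = k))
  }
}

dissimilarity_matrix <- function(features, distance) {
  d <- switch(distance,
    euclidean = as.matrix(stats::dist(features)),
    one_minus_pearson = 1 - stats::cor(t(features)))
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Consensus clustering over item resampling
#'
#' Repeatedly subsamples items, clusters the subsample with the base method,
#' and records how often each item pair lands in the same cluster relative
#' to how often it was co-sampled. The resulting consensus matrix (per k)
#' yields stable final labels (base clustering of 1 - consensus) and the
#' CDF / delta-area diagnostics used to choose the number of clusters: the
#' selected k maximises the relative increment in area under the consensus
#' CDF, ties toward smaller k.
#'
#' @param features items x features numeric matrix.
#' @param k_values integer vector of cluster numbers to scan (default 2:6).
#' @param n_resamples number of subsamples per k (default 1000; tests use 50).
#' @param item_fraction fraction of items drawn per subsample (default 0.8).
#' @param base base clustering method, \code{"pam"} or \code{"hierarchical"}.
#' @param distance \code{"euclidean"} or \code{"one_minus_pearson"}.
#' @param seed integer seed for the resampling stream.
#' @return object of class \code{consensus_result}: per-k \code{consensus}
#'   matrices, \code{labels}, \code{cdf} (sorted upper-triangle entries),
#'   \code{area}, \code{delta_area}, and \code{selected_k}.
#' @export
consensus_cluster <- function(features, k_values = 2:6, n_resamples = 1000L,
                              item_fraction = 0.8,
                              base = c("pam", "hierarchical"),
                              distance = c("euclidean", "one_minus_pearson"),
                              seed = 1L) {
  base <- match.arg(base)
  distance <- match.arg(distance)
  if (n_resamples < 2L) stop("need at least 2 resamples")
  if (item_fraction <= 0 || item_fraction > 1) stop("item_fraction must be in (0, 1]")
  n <- nrow(features)
  if (max(k_values) > n) stop("k exceeds item count")
  d_full <- dissimilarity_matrix(features, distance)
  m_sub <- ceiling(item_fraction * n)

  set.seed(seed)
  draws <- lapply(seq_len(n_resamples), function(i) sort(sample.int(n, m_sub)))

  consensus <- labels <- cdf <- list()
  area <- delta_area <- stats::setNames(numeric(length(k_values)),
                                        as.character(k_values))
  for (ki in seq_along(k_values)) {
    k <- k_values[ki]
    co_clust <- matrix(0, n, n)
    co_samp <- matrix(0, n, n)
    for (idx in draws) {
      lab <- cluster_items(d_full[idx, idx, drop = FALSE], k, base)
      ind <- matrix(0, n, 1L); ind[idx, 1L] <- 1
      co_samp <- co_samp + tcrossprod(ind)
      for (cl in unique(lab)) {
        v <- matrix(0, n, 1L); v[idx[lab == cl], 1L] <- 1
        co_clust <- co_clust + tcrossprod(v)
      }
    }
    cons <- matrix(0, n, n)
    seen <- co_samp > 0
    cons[seen] <- co_clust[seen] / co_samp[seen]
    if (any(!seen[upper.tri(seen)]))
      warning("item pair(s) never co-sampled; consensus set to 0 for those pairs")
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(features), rownames(features))
    lab_final <- cluster_items(1 - cons, k, base)
    ut <- sort(cons[upper.tri(cons)])
    # area under the empirical CDF of consensus entries on [0, 1]
    a <- sum(diff(c(0, ut, 1)) * c(0, seq_along(ut) / length(ut)))
    consensus[[as.character(k)]] <- cons
    labels[[as.character(k)]] <- lab_final
    cdf[[as.character(k)]] <- ut
    area[ki] <- a
    delta_area[ki] <- if (ki == 1L) a else max(0, (a - area[ki - 1L]) / area[ki - 1L])
  }
  selected_k <- k_values[which.max(delta_area)]
  structure(list(k_values = k_values, consensus = consensus, labels = labels,
                 cdf = cdf, area = area, delta_area = delta_area,
                 selected_k = selected_k, base = base, distance = distance,
                 n_resamples = as.integer(n_resamples),
                 item_fraction = item_fraction, seed = as.integer(seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering (%s base, %s distance, %d resamples)\n",
              x$base, x$distance, x$n_resamples))
  cat("  delta area:", paste(sprintf("k=%s: %.3f", names(x$delta_area),
                                     x$delta_area), collapse = ", "), "\n")
  cat("  selected k:", x$selected_k, "\n")
  invisible(x)
}

#' Chi-square association between two labelings
#'
#' Pearson chi-square test on the contingency table of two categorical
#' labelings of the same samples. Categories with a zero margin are dropped
#' with a warning.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return list with \code{chi2}, \code{df}, \code{p} and \code{table}.
#' @export
crosstab_association <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  tab <- table(droplevels(as.factor(labels_a)), droplevels(as.factor(labels_b)))
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("zero-margin categories dropped")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("each labeling needs at least two observed categories")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
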