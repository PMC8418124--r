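sep_gene_data <- function(seed, n = 60, n_noise = 50, delta = 4) {
  set.seed(seed)
  labels <- rep(c(1, 2), each = n / 2)
  x <- matrix(rnorm((n_noise + 1) * n), n_noise + 1, n)
  x[1, labels == 2] <- x[1, labels == 2] + delta
  rownames(x) <- c("driver", paste0("noise", seq_len(n_noise)))
  list(x = x, labels = labels)
}

test_that("SVM-RFE ranks a perfectly separating gene first", {
  top_hits <- vapply(1:10, function(s) {
    d <- sep_gene_data(700 + s)
    ranked <- svm_rfe_rank(d$x, d$labels, seed = s)
    ranked[1] == "driver"
  }, logical(1))
  expect_gte(sum(top_hits), 9)
})

test_that("SVM-RFE concentrates planted informative genes near the top", {
  frac_top <- vapply(1:5, function(s) {
    set.seed(800 + s)
    n <- 150; n_genes <- 500; n_true <- 20
    labels <- rep(c(1, 2), each = n / 2)
    x <- matrix(rnorm(n_genes * n), n_genes, n)
    x[1:n_true, labels == 2] <- x[1:n_true, labels == 2] + 1.5
    rownames(x) <- paste0("g", seq_len(n_genes))
    ranked <- svm_rfe_rank(x, labels, seed = s)
    mean(paste0("g", 1:n_true) %in% ranked[1:50])
  }, numeric(1))
  expect_gte(median(frac_top), 0.9)
})

test_that("SVM-RFE degenerate inputs", {
  d <- sep_gene_data(41)
  expect_identical(svm_rfe_rank(d$x[1, , drop = FALSE], d$labels), "driver")
  expect_error(svm_rfe_rank(d$x, rep(1, ncol(d$x))), "two classes")
})

test_that("signature size selection maximises CV accuracy with ties to smaller", {
  d <- sep_gene_data(42, n = 80)
  ranked <- svm_rfe_rank(d$x, d$labels, seed = 1)
  # the driver separates perfectly, so several sizes tie at accuracy 1 and
  # the smallest candidate must win
  sel <- select_signature(ranked, d$x, d$labels,
                          candidate_sizes = c(5L, 20L, 40L), seed = 2)
  expect_identical(sel$size, 5L)
  expect_gte(max(sel$accuracy$accuracy), 0.9)

  full <- select_signature(ranked, d$x, d$labels,
                           candidate_sizes = length(ranked), seed = 2)
  expect_identical(full$genes, ranked)
  expect_error(select_signature(ranked, d$x, d$labels,
                                candidate_sizes = c(2, 9999)), "candidate sizes")
})

test_that("gene clusters split correlated blocks and anti-correlated pairs", {
  set.seed(43)
  n <- 60
  shared1 <- rnorm(n); shared2 <- rnorm(n)
  block1 <- t(sapply(1:8, function(i) shared1 + rnorm(n, sd = 0.3)))
  block2 <- t(sapply(1:8, function(i) shared2 + rnorm(n, sd = 0.3)))
  x <- rbind(block1, block2)
  rownames(x) <- paste0("g", 1:16)
  res <- cluster_signature_genes(x, k_values = 2, n_resamples = 25, seed = 3)
  expect_equal(mclust::adjustedRandIndex(res$labels, rep(1:2, each = 8)), 1)

  forced <- cluster_signature_genes(x, k_values = 1, seed = 3)
  expect_true(all(forced$labels == 1L))

  anti <- rbind(a = shared1, b = -shared1 + rnorm(n, sd = 1e-3))
  res2 <- cluster_signature_genes(anti, k_values = 2, n_resamples = 25, seed = 4)
  expect_false(res2$labels["a"] == res2$labels["b"])
})

test_that("PC1 fit matches an independent eigendecomposition and orients itself", {
  set.seed(44)
  n <- 50
  pattern <- rnorm(n)
  x <- t(sapply(1:6, function(i) 2 * pattern + rnorm(n, sd = 0.02)))
  rownames(x) <- paste0("g", 1:6)
  fit <- fit_pc1(x)
  expect_equal(sum(fit$loadings^2), 1, tolerance = 1e-10)

  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  ev <- eigen(cov(t(z)))
  v1 <- ev$vectors[, 1]
  expect_equal(abs(as.numeric(fit$loadings)), abs(v1), tolerance = 1e-8)
  # rank-1 structure: PC1 dominates
  expect_gte(ev$values[1] / sum(ev$values), 0.999)
  # orientation convention: positive correlation with the cluster mean
  expect_gt(cor(fit$scores, colMeans(z)), 0)
  expect_gt(cor(fit$scores, pattern), 0.99)

  single <- fit_pc1(x[1, , drop = FALSE])
  expect_equal(unname(single$loadings), 1)
  expect_equal(unname(single$scores), as.numeric(scale(x[1, ])),
               tolerance = 1e-12)

  xz <- rbind(x, flat = rep(5, n))
  expect_warning(fit2 <- fit_pc1(xz), "zero-variance")
  expect_false("flat" %in% names(fit2$loadings))
})

test_that("direction sets follow the hazard ratio of the cluster score", {
  hits <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 200
    risk <- rnorm(n)
    x <- t(sapply(1:5, function(i) risk + rnorm(n, sd = 0.4)))
    rownames(x) <- paste0("g", 1:5)
    colnames(x) <- paste0("s", 1:n)
    t <- rexp(n, 0.01 * exp(log(2) * scale(colMeans(x))[, 1]))
    srv <- surv_data(t, rep(1L, n))
    res <- suppressWarnings(
      assign_direction_sets(setNames(rep(1L, 5), rownames(x)), x, srv))
    res$direction[["1"]] == "i"
  }, logical(1))
  expect_gte(sum(hits), 9)

  # protective cluster lands in j, and a one-direction model warns
  set.seed(45)
  n <- 200
  prot <- rnorm(n)
  x <- t(sapply(1:4, function(i) prot + rnorm(n, sd = 0.4)))
  rownames(x) <- paste0("g", 1:4); colnames(x) <- paste0("s", 1:n)
  t <- rexp(n, 0.01 * exp(-log(2) * scale(colMeans(x))[, 1]))
  srv <- surv_data(t, rep(1L, n))
  expect_warning(
    res <- assign_direction_sets(setNames(rep(1L, 4), rownames(x)), x, srv),
    "one hazard direction")
  expect_identical(unname(res$direction), "j")
})

test_that("TME-score formula, invariances, and coverage rules hold", {
  cohort <- small_cohort(seed = 6, n = 60)
  lexpr <- log2_transform(cohort$expr)
  genes <- rownames(lexpr)[1:12]
  labels <- setNames(rep(1:2, each = 6), genes)
  srv <- surv_data(cohort$clinical$os_time, cohort$clinical$os_event)
  dirs <- suppressWarnings(assign_direction_sets(labels, lexpr[genes, ], srv))
  model <- structure(list(signature_genes = genes,
                          gene_cluster_labels = labels,
                          direction = dirs$direction, cluster_hr = dirs$hr,
                          pc1 = dirs$pc1, cutoff = 0,
                          provenance = list(minprop = 0.1)),
                     class = "tmescore")
  sc <- tme_score(lexpr, model)
  # non-signature genes are irrelevant
  sc_sub <- tme_score(lexpr[c(genes, rownames(lexpr)[100:200]), ], model)
  expect_equal(sc$tme_score, sc_sub$tme_score)
  # permuting samples permutes scores identically
  perm <- sample(ncol(lexpr))
  sc_perm <- tme_score(lexpr[, perm], model)
  expect_identical(sc_perm$tme_score, sc$tme_score[perm])
  # score equals the signed sum of the per-cluster PC1 columns
  sgn <- ifelse(dirs$direction == "i", 1, -1)
  manual <- as.matrix(sc[, paste0("PC1_cluster", names(dirs$direction))]) %*% sgn
  expect_equal(sc$tme_score, as.numeric(manual))
  # with every cluster in i, the score is the plain sum
  model_i <- model
  model_i$direction[] <- "i"
  sc_i <- tme_score(lexpr, model_i)
  expect_equal(sc_i$tme_score,
               rowSums(sc_i[, paste0("PC1_cluster", names(dirs$direction))]))
  # missing genes: tolerated to 80%, fatal below
  drop2 <- setdiff(rownames(lexpr), genes[1:2])
  expect_warning(sc_m <- tme_score(lexpr[drop2, ], model), "renormalised")
  expect_true(all(is.finite(sc_m$tme_score)))
  drop4 <- setdiff(rownames(lexpr), genes[1:4])
  expect_error(tme_score(lexpr[drop4, ], model), "coverage")
})

test_that("cytolytic score is the geometric mean of the two markers", {
  expr <- rbind(GZMA = c(4, 0, 7), PRF1 = c(9, 0, 7))
  colnames(expr) <- paste0("s", 1:3)
  cyt <- cyt_score(expr)
  expect_equal(unname(cyt[1]), 6, tolerance = 0.02)
  expect_equal(unname(cyt[2]), 0.01)
  expect_equal(unname(cyt[3]), 7.01)
  expect_error(cyt_score(expr[1, , drop = FALSE]), "PRF1")
})

test_that("GEP score is the plain mean over the 18-gene panel", {
  panel <- paste0("gep", 1:18)
  expr <- matrix(5, 18, 2, dimnames = list(panel, c("a", "b")))
  expr[, 2] <- expr[, 2] + 1
  sc <- gep_score(expr, panel)
  expect_equal(unname(sc), c(5, 6))
  expect_equal(unname(gep_score(expr + 1, panel)), c(6, 7))
  expect_error(gep_score(expr, panel[1:17]), "18 genes")
  expect_error(gep_score(expr[1:17, ], panel), "missing")
})
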