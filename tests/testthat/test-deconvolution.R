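test_that("pure reference columns deconvolve to their own cell type", {
  ref <- tiny_reference()
  mix <- ref
  colnames(mix) <- paste0("pure_", colnames(ref))
  cf <- nusvr_deconvolve(mix, ref, n_permutations = 0)
  expect_true(all(diag(cf$fractions) >= 0.95))
  expect_equal(unname(rowSums(cf$fractions)), rep(1, ncol(ref)),
               tolerance = 1e-8)
})

test_that("noiseless known mixtures are recovered with small error", {
  ref <- tiny_reference(n_types = 8L, markers = 40L)
  f_true <- rbind(c(0.5, 0.3, 0.2, 0, 0, 0, 0, 0),
                  rep(0.125, 8),
                  c(0.7, 0.1, 0.1, 0.1, 0, 0, 0, 0))
  mix <- ref %*% t(f_true)
  colnames(mix) <- paste0("m", 1:3)
  cf <- nusvr_deconvolve(mix, ref, n_permutations = 0, seed = 2)
  expect_lt(mean(abs(cf$fractions - f_true)), 0.02)
})

test_that("deconvolution is invariant to positive rescaling of the mixture", {
  ref <- tiny_reference()
  set.seed(4)
  f <- rdir <- rgamma(4, 1); f <- f / sum(f)
  mix <- cbind(s = as.numeric(ref %*% f))
  rownames(mix) <- rownames(ref)
  a <- nusvr_deconvolve(mix, ref, n_permutations = 0)
  b <- nusvr_deconvolve(mix * 37.5, ref, n_permutations = 0)
  expect_equal(a$fractions, b$fractions, tolerance = 1e-6)
})

test_that("permutation p-values are calibrated for gene-shuffled mixtures", {
  # a shuffled reference column is exchangeable with its own permutation
  # null, so the p-values across replicates should look uniform
  ref <- tiny_reference()
  ps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- cbind(x = sample(as.numeric(ref[, 1])))
    rownames(y) <- rownames(ref)
    nusvr_deconvolve(y, ref, n_permutations = 50, seed = s)$p_value[1]
  }, numeric(1))
  expect_gt(median(ps), 0.2)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.05)
  expect_lte(mean(ps <= 0.05), 0.2)
})

test_that("insufficient gene overlap is a hard error", {
  ref <- tiny_reference()
  mix <- ref[1:10, , drop = FALSE]  # 25% coverage
  expect_error(nusvr_deconvolve(mix, ref, n_permutations = 0), "50%")
})

test_that("ssGSEA matches the brute-force running-sum definition", {
  # 5-gene, 1-sample worked case: set = top-2 genes, alpha = 0.25
  vals <- c(10, 8, 6, 4, 2)
  expr <- cbind(s1 = vals)
  rownames(expr) <- paste0("g", 1:5)
  got <- ssgsea_scores(expr, list(top = c("g1", "g2")), alpha = 0.25)
  expect_equal(got["s1", "top"], ssgsea_bruteforce(vals, 1:2, 0.25),
               tolerance = 1e-9)

  set.seed(6)
  expr2 <- matrix(rnorm(40 * 3), 40,
                  dimnames = list(paste0("g", 1:40), paste0("s", 1:3)))
  idx <- c(3, 7, 19, 25, 31)
  got2 <- ssgsea_scores(expr2, list(s = paste0("g", idx)), alpha = 0.25)
  for (j in 1:3)
    expect_equal(unname(got2[j, "s"]),
                 ssgsea_bruteforce(expr2[, j], idx, 0.25), tolerance = 1e-9)
})

test_that("ssGSEA is rank-based: whole-genome sets and monotone transforms", {
  set.seed(7)
  expr <- matrix(rexp(30 * 4), 30,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  all_set <- list(all = rownames(expr))
  sc <- ssgsea_scores(expr, all_set)
  expect_lt(diff(range(sc[, "all"])), 1e-9)

  some <- list(s = paste0("g", c(2, 9, 17)))
  base <- ssgsea_scores(expr, some)
  warped <- expr
  warped[, 2] <- exp(expr[, 2] * 3)  # strictly increasing transform
  expect_equal(ssgsea_scores(warped, some)[2, ], base[2, ], tolerance = 1e-12)

  expect_error(ssgsea_scores(expr, list(bad = c("nope"))), "bad")
})

test_that("immune/stromal scores sum to the combined score and track signal", {
  set.seed(8)
  expr <- matrix(rnorm(50 * 2, mean = 5), 50,
                 dimnames = list(paste0("g", 1:50), c("base", "hot")))
  immune <- paste0("g", 1:10)
  stromal <- paste0("g", 41:50)
  expr[immune, "hot"] <- expr[immune, "hot"] + 3
  sc <- estimate_scores(expr, immune, stromal)
  expect_equal(sc[, "ESTIMATEScore"],
               sc[, "ImmuneScore"] + sc[, "StromalScore"])
  expect_gt(sc["hot", "ImmuneScore"], sc["base", "ImmuneScore"])
  expect_error(estimate_scores(expr, c("absent1", "absent2"), stromal),
               "immune")
  expect_warning(estimate_scores(expr, immune, c(immune[1], stromal)),
                 "overlap")
})
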