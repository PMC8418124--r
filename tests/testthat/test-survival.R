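test_that("Kaplan-Meier estimator matches the hand product-limit", {
  s <- surv_data(c(1, 2, 3), c(1, 1, 1))
  km <- km_curve(s)
  expect_equal(km$survival, c(2/3, 1/3, 0))

  cens <- surv_data(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_curve(cens)$survival == 1))

  # no censoring: KM equals the empirical survival function
  set.seed(31)
  t <- rexp(40)
  km2 <- km_curve(surv_data(t, rep(1, 40)))
  emp <- vapply(km2$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$survival, emp)

  # time rescaling only stretches the x-axis
  km3 <- km_curve(surv_data(2 * t, rep(1, 40)))
  expect_equal(km3$survival, km2$survival)
  expect_equal(km3$time, 2 * km2$time)
})

test_that("log-rank test matches the longhand O/E oracle", {
  # 10-subject two-group example with staggered events and censoring
  times <- c(2, 4, 5, 7, 8, 3, 6, 6, 9, 11)
  events <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 5)
  res <- logrank_test(surv_data(times, events), grp)
  expect_equal(res$chi2, logrank_oracle_chi2(times, events, grp == "a"),
               tolerance = 1e-9)
  expect_identical(res$df, 1L)

  # two identical copies of one group: no difference
  dup <- logrank_test(surv_data(rep(times, 2), rep(events, 2)),
                      rep(c("x", "y"), each = 10))
  expect_lt(dup$chi2, 1e-10)
  expect_equal(dup$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(surv_data(times, events), rep("one", 10)),
               "two groups")
})

test_that("fast binary log-rank equals survdiff across random datasets", {
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 60
    t <- round(rexp(n, 0.1), 1)  # force ties
    e <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5) == 1
    if (length(unique(g)) < 2 || sum(e) == 0) next
    sd_ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(tmescorer:::binary_logrank_chi2(t, e, g),
                 unname(sd_ref$chisq), tolerance = 1e-9)
  }
})

test_that("Cox regression recovers a known log hazard ratio", {
  est <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    t_event <- rexp(n, rate = 0.01 * exp(log(2) * x))
    t_cens <- runif(n, 0, quantile(t_event, 0.9) * 2.3)
    time <- pmin(t_event, t_cens)
    fit <- cox_fit(surv_data(time, as.integer(t_event <= t_cens)), x)
    fit$coefficients$beta[1]
  }, numeric(1))
  expect_lt(abs(mean(est) - log(2)), 0.1)
})

test_that("Cox tie corrections coincide without ties and inputs validate", {
  set.seed(32)
  n <- 80
  x <- rnorm(n)
  t <- rexp(n, exp(0.5 * x) / 50)   # continuous: no ties
  s <- surv_data(t, rbinom(n, 1, 0.8))
  fe <- cox_fit(s, x, ties = "efron")
  fb <- cox_fit(s, x, ties = "breslow")
  expect_equal(fe$coefficients$beta, fb$coefficients$beta, tolerance = 1e-10)
  expect_true(fe$coefficients$ci95_low < fe$coefficients$hr &&
                fe$coefficients$hr < fe$coefficients$ci95_high)
  expect_error(cox_fit(s, rep(2, n)), "constant")
})

test_that("Cox score matches the log-rank association for a binary split", {
  set.seed(33)
  n <- 120
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.02 * exp(0.7 * g)) + runif(n, 0, 1e-4)  # break ties
  s <- surv_data(t, rep(1L, n))
  lr <- logrank_test(s, g)
  cf <- cox_fit(s, g)
  # Wald and log-rank p agree closely in a well-behaved binary design
  expect_lt(abs(log10(cf$coefficients$p[1]) - log10(lr$p)), 0.5)
})

test_that("univariate screening flags prognostic features and skips flat ones", {
  set.seed(34)
  n <- 200
  prog <- rnorm(n)
  noise <- matrix(rnorm(5 * n), 5)
  t <- rexp(n, 0.01 * exp(log(2) * prog))
  feats <- rbind(prog = prog, noise, flat = rep(1, n))
  rownames(feats) <- c("prog", paste0("n", 1:5), "flat")
  res <- univariate_screen(feats, surv_data(t, rep(1L, n)))
  expect_true(res$representative[res$feature == "prog"])
  expect_gt(res$hr[res$feature == "prog"], 1)
  expect_true(res$skipped[res$feature == "flat"])
  expect_true(is.na(res$p[res$feature == "flat"]))
})

test_that("pure-noise features are flagged at roughly the nominal rate", {
  set.seed(35)
  n <- 100
  t <- rexp(n, 0.01)
  feats <- matrix(rnorm(200 * n), 200)
  rownames(feats) <- paste0("g", 1:200)
  res <- univariate_screen(feats, surv_data(t, rep(1L, n)))
  expect_lt(abs(mean(res$representative) - 0.05), 0.05)
})

test_that("maximally selected cutpoint recovers a planted change-point", {
  errs <- vapply(1:20, function(s) {
    set.seed(600 + s)
    n <- 300
    score <- runif(n)
    thr <- quantile(score, 0.6)
    t <- rexp(n, 0.01 * ifelse(score > thr, 3, 1))
    oc <- optimal_cutpoint(score, surv_data(t, rep(1L, n)))
    mean(score <= oc$cutoff) - 0.6
  }, numeric(1))
  expect_lt(abs(median(errs)), 0.10)
})

test_that("cutpoint respects minprop and beats the median split", {
  set.seed(36)
  n <- 120
  score <- rnorm(n)
  t <- rexp(n, 0.02 * exp(0.4 * score))
  s <- surv_data(t, rep(1L, n))
  oc <- optimal_cutpoint(score, s, minprop = 0.2)
  frac <- mean(score <= oc$cutoff)
  expect_gte(frac, 0.2); expect_lte(frac, 0.8)
  med_chi2 <- tmescorer:::binary_logrank_chi2(t, rep(1L, n),
                                              score > median(score))
  expect_gte(oc$chi2, med_chi2 - 1e-9)
  expect_error(optimal_cutpoint(rep(1, n), s), "constant")
})

test_that("null cutpoint statistic is calibrated against its permutation reference", {
  set.seed(37)
  n <- 80
  score <- rnorm(n)
  t <- rexp(n, 0.02)  # survival independent of the score
  s <- surv_data(t, rep(1L, n))
  oc <- optimal_cutpoint(score, s, n_permutations = 100, seed = 9)
  # naive p is optimistic; the permutation p must not be significant here
  expect_gt(oc$p_perm, 0.05)
  expect_lte(oc$p, oc$p_perm + 1e-9)
})

test_that("AUC equals the concordant-pair count and cross-checks pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(38)
  score <- rnorm(200)
  lab <- rbinom(200, 1, 0.4)
  got <- roc_auc(score, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)

  set.seed(39)
  null_auc <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(null_auc - 0.5), 0.03)
})
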