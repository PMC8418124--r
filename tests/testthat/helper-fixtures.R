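# Shared fixtures: all synthetic, generated in code at test time.

# small marker-structured reference for deconvolution tests
tiny_reference <- function(n_types = 4L, markers = 10L, seed = 11L) {
  cfg <- sim_config(n_cell_types = n_types, markers_per_type = markers,
                    n_background_genes = 0L, n_planted_degs = 0L, seed = seed)
  generate_reference(cfg)
}

# down-scaled cohort that still carries the full pipeline structure
small_cohort <- function(seed = 5L, n = 150L, biology_seed = NULL) {
  cfg <- sim_config(n_samples = n, markers_per_type = 30L,
                    n_background_genes = 400L, n_planted_degs = 60L,
                    seed = seed, biology_seed = biology_seed)
  generate_cohort(cfg)
}

fit_small_model <- function(cohort, seed = 5L) {
  suppressWarnings(tmescore(cohort$expr, cohort$clinical, cohort$reference,
                            n_resamples = 25L, cv_folds = 3L, seed = seed))
}

# brute-force step-up FDR, deliberately naive: the oracle for bh_adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# exhaustive k-medoid search: optimal cost over all medoid subsets
brute_force_pam_cost <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  min(apply(combs, 2L, function(m) sum(apply(d[, m, drop = FALSE], 1L, min))))
}

# TRUE if no single medoid/non-medoid swap lowers the total cost
is_swap_local_optimum <- function(d, medoids) {
  cost <- function(m) sum(apply(d[, m, drop = FALSE], 1L, min))
  c0 <- cost(medoids)
  for (i in seq_along(medoids)) {
    for (j in setdiff(seq_len(nrow(d)), medoids)) {
      m2 <- medoids; m2[i] <- j
      if (cost(m2) < c0 - 1e-12) return(FALSE)
    }
  }
  TRUE
}

# literal running-sum transcription of the ssGSEA definition for one sample
ssgsea_bruteforce <- function(values, set_idx, alpha) {
  n <- length(values)
  r <- rank(values, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  hit <- seq_len(n) %in% set_idx
  hit <- hit[ord]
  ra <- r[ord]^alpha
  es <- 0; cum_hit <- 0; cum_miss <- 0
  denom_hit <- sum(ra[hit]); denom_miss <- max(n - sum(hit), 1)
  for (i in seq_len(n)) {
    if (hit[i]) cum_hit <- cum_hit + ra[i] / denom_hit
    else cum_miss <- cum_miss + 1 / denom_miss
    es <- es + (cum_hit - cum_miss)
  }
  unname(es)
}

# per-event-time O/E log-rank table, written out longhand as the oracle
logrank_oracle_chi2 <- function(times, events, group1) {
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group1)
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & group1)
    O <- O + d1_t
    E <- E + d_t * n1_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  (O - E)^2 / V
}
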