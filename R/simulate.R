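#' Simulation configuration for synthetic bulk cohorts
#'
#' Bundles the generator parameters with their defaults: a cohort of 400
#' samples over ~2000 genes built from 8 cell types, two latent infiltration
#' phenotypes given by Dirichlet concentration vectors (phenotype 1 tilted
#' toward the first two, "suppressive-like", cell types), 100 planted
#' differentially expressed background genes shifted by 2 log2 units in
#' phenotype 1, multiplicative log-normal noise (SD 0.5 on the log2 scale),
#' two batches with a +1 log2 additive shift on the second, and exponential
#' survival whose hazard doubles in phenotype 1 with 30% uniform censoring.
#'
#' @param n_samples number of samples.
#' @param n_cell_types number of reference cell types (<= 22).
#' @param markers_per_type marker genes per cell type.
#' @param n_background_genes genes with no cell-type specificity.
#' @param alpha_phenotype1,alpha_phenotype2 Dirichlet concentrations
#'   (length n_cell_types) for the two phenotypes.
#' @param n_planted_degs number of background genes shifted in phenotype 1.
#' @param deg_effect log2 shift of planted DEGs.
#' @param noise_sd SD of the log2-scale multiplicative noise.
#' @param batch_count number of batches.
#' @param batch_shift additive log2 shift per batch step.
#' @param baseline_hazard exponential event rate (per day) in phenotype 2.
#' @param true_beta log hazard ratio of phenotype 1 vs 2.
#' @param censoring_fraction target fraction of censored samples.
#' @param seed integer seed; the generators are pure functions of the config.
#' @param biology_seed seed for the cohort-invariant biology (reference
#'   profiles and which background genes are planted as DEGs). Defaults to
#'   \code{seed}; give several configs the same \code{biology_seed} to draw
#'   independent cohorts from one underlying disease process, as when
#'   simulating training and external-validation datasets.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 400L, n_cell_types = 8L,
                       markers_per_type = 40L, n_background_genes = 1680L,
                       alpha_phenotype1 = NULL, alpha_phenotype2 = NULL,
                       n_planted_degs = 100L, deg_effect = 2,
                       noise_sd = 0.5, batch_count = 2L, batch_shift = 1,
                       baseline_hazard = 1 / 500, true_beta = log(2),
                       censoring_fraction = 0.3, seed = 1L,
                       biology_seed = NULL) {
  if (is.null(biology_seed)) biology_seed <- seed
  if (n_cell_types < 2L || n_cell_types > 22L)
    stop("n_cell_types must be in [2, 22]")
  if (is.null(alpha_phenotype1)) {
    alpha_phenotype1 <- rep(1, n_cell_types)
    alpha_phenotype1[1:2] <- 4
  }
  if (is.null(alpha_phenotype2)) {
    alpha_phenotype2 <- rep(1, n_cell_types)
    alpha_phenotype2[3:4] <- 4
  }
  if (length(alpha_phenotype1) != n_cell_types ||
      length(alpha_phenotype2) != n_cell_types)
    stop("concentration vectors must have length n_cell_types")
  if (any(alpha_phenotype1 <= 0) || any(alpha_phenotype2 <= 0))
    stop("concentrations must be positive")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0, 1)")
  if (n_planted_degs > n_background_genes)
    stop("planted DEGs exceed background genes")
  cfg <- list(n_samples = as.integer(n_samples),
              n_cell_types = as.integer(n_cell_types),
              markers_per_type = as.integer(markers_per_type),
              n_background_genes = as.integer(n_background_genes),
              alpha_phenotype1 = alpha_phenotype1,
              alpha_phenotype2 = alpha_phenotype2,
              n_planted_degs = as.integer(n_planted_degs),
              deg_effect = deg_effect, noise_sd = noise_sd,
              batch_count = as.integer(batch_count),
              batch_shift = batch_shift,
              baseline_hazard = baseline_hazard, true_beta = true_beta,
              censoring_fraction = censoring_fraction, seed = as.integer(seed),
              biology_seed = as.integer(biology_seed))
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cell-type reference signature matrix
#'
#' A stand-in for an LM22-like reference: each cell type receives
#' \code{markers_per_type} marker genes with high expression in that type
#' (log-normal around 6 log2 units, SD 0.5) and low elsewhere (around 1,
#' SD 0.5); background genes are flat across types. Linear scale.
#'
#' @param config a \code{\link{sim_config}}.
#' @return genes x cell-types nonnegative matrix.
#' @export
generate_reference <- function(config) {
  set.seed(config$biology_seed %||% config$seed)
  k <- config$n_cell_types
  mpt <- config$markers_per_type
  n_marker <- k * mpt
  types <- paste0("CT", seq_len(k))
  marker_ids <- paste0("MK", seq_len(n_marker))
  bg_ids <- if (config$n_background_genes > 0)
    paste0("BG", seq_len(config$n_background_genes)) else character(0)
  log2_m <- matrix(stats::rnorm(n_marker * k, mean = 1, sd = 0.5), n_marker, k)
  for (t in seq_len(k)) {
    rows <- ((t - 1L) * mpt + 1L):(t * mpt)
    log2_m[rows, t] <- stats::rnorm(mpt, mean = 6, sd = 0.5)
  }
  bg_level <- stats::rnorm(config$n_background_genes, mean = 3, sd = 0.5)
  log2_bg <- matrix(rep(bg_level, k), ncol = k)
  out <- 2^rbind(log2_m, log2_bg)
  dimnames(out) <- list(c(marker_ids, bg_ids), types)
  out
}

#' Generate a synthetic bulk cohort with known ground truth
#'
#' Samples a latent phenotype per patient, draws cell-type fractions from
#' the phenotype's Dirichlet, mixes the linear-scale reference profiles
#' accordingly, multiplies log-normal noise, shifts the planted DEGs in
#' phenotype 1, applies an additive log2 batch shift, and draws exponential
#' survival times whose hazard depends on phenotype, with independent
#' uniform censoring calibrated to the requested fraction.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{expr} (linear-scale genes x samples matrix),
#'   \code{clinical} (sample_id, os_time, os_event, batch), \code{reference}
#'   (the marker-gene signature submatrix for deconvolution), and
#'   \code{truth} (true_fractions, phenotype, planted_deg_ids, batch,
#'   true_beta).
#' @export
generate_cohort <- function(config) {
  ref_full <- generate_reference(config)
  marker_ids <- grep("^MK", rownames(ref_full), value = TRUE)
  # which background genes carry the planted effect is part of the biology
  # and shared by every cohort drawn with the same biology_seed
  bg_ids <- grep("^BG", rownames(ref_full), value = TRUE)
  set.seed((config$biology_seed %||% config$seed) + 1L)
  planted <- sort(sample(bg_ids, config$n_planted_degs))
  up1 <- planted[seq_len(ceiling(length(planted) / 2))]
  up2 <- setdiff(planted, up1)
  set.seed(config$seed + 2L)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  phenotype <- stats::rbinom(n, 1L, 0.5) + 1L
  alpha <- rbind(config$alpha_phenotype1, config$alpha_phenotype2)
  fractions <- matrix(NA_real_, n, config$n_cell_types,
                      dimnames = list(ids, colnames(ref_full)))
  for (ph in 1:2) {
    idx <- phenotype == ph
    if (any(idx)) fractions[idx, ] <- rdirichlet(sum(idx), alpha[ph, ])
  }
  expr <- ref_full %*% t(fractions)
  # multiplicative log-normal noise on linear scale
  expr <- expr * 2^matrix(stats::rnorm(length(expr), sd = config$noise_sd),
                          nrow(expr), ncol(expr))
  # planted DEGs: half shifted up in phenotype 1, half up in phenotype 2,
  # emulating both risk and protective programmes
  expr[up1, phenotype == 1L] <- expr[up1, phenotype == 1L] * 2^config$deg_effect
  if (length(up2))
    expr[up2, phenotype == 2L] <- expr[up2, phenotype == 2L] * 2^config$deg_effect
  # batch assignment and additive log2 shift
  batch <- sample(rep_len(seq_len(config$batch_count), n))
  if (config$batch_count > 1L && config$batch_shift != 0)
    expr <- expr * 2^(config$batch_shift *
                        matrix(batch - 1L, nrow(expr), n, byrow = TRUE))
  # exponential survival, hazard raised by exp(true_beta) in phenotype 1
  rate <- config$baseline_hazard * exp(config$true_beta * (phenotype == 1L))
  t_event <- stats::rexp(n, rate = rate)
  if (config$censoring_fraction > 0) {
    u_max <- calibrate_censoring(rate, config$censoring_fraction)
    t_cens <- stats::runif(n, 0, u_max)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
  } else {
    os_time <- t_event
    os_event <- rep(1L, n)
  }
  os_time <- pmax(os_time, 1e-6)
  clinical <- data.frame(sample_id = ids, os_time = os_time,
                         os_event = os_event, batch = batch,
                         stringsAsFactors = FALSE)
  dimnames(expr) <- list(rownames(ref_full), ids)
  truth <- list(true_fractions = fractions, phenotype = stats::setNames(phenotype, ids),
                planted_deg_ids = planted,
                planted_deg_direction = stats::setNames(
                  ifelse(planted %in% up1, 1L, 2L), planted),
                batch = stats::setNames(batch, ids),
                true_beta = config$true_beta)
  list(expr = expr, clinical = clinical,
       reference = ref_full[marker_ids, , drop = FALSE], truth = truth,
       config = config)
}

# upper bound of the uniform censoring window giving the target expected
# censoring fraction under the cohort's mix of exponential rates
calibrate_censoring <- function(rates, target) {
  p_cens <- function(u) mean((1 - exp(-rates * u)) / (rates * u))
  # p_cens decreases from 1 (u -> 0) toward 0 (u -> Inf)
  lo <- 1e-6; hi <- 1
  while (p_cens(hi) > target && hi < 1e12) hi <- hi * 2
  stats::uniroot(function(u) p_cens(u) - target, c(lo, hi))$root
}

#' Compare pipeline outputs with simulation ground truth
#'
#' Computes whichever recovery metrics the supplied outputs allow: adjusted
#' Rand index of discovered phenotypes, mean absolute error of cell
#' fractions, planted-DEG recall/precision, signature recall of planted
#' genes, Cox log-hazard error, and score-vs-phenotype AUC.
#'
#' @param truth the \code{truth} element of \code{\link{generate_cohort}}.
#' @param phenotype_labels named per-sample discovered labels (optional).
#' @param fractions named samples x cell-types estimate (optional).
#' @param deg_ids discovered DEG identifiers (optional).
#' @param signature_genes selected signature gene identifiers (optional).
#' @param cox_beta estimated phenotype log hazard (optional).
#' @param scores named per-sample risk scores (optional).
#' @return list of the computed metrics.
#' @export
truth_metrics <- function(truth, phenotype_labels = NULL, fractions = NULL,
                          deg_ids = NULL, signature_genes = NULL,
                          cox_beta = NULL, scores = NULL) {
  out <- list()
  ids <- names(truth$phenotype)
  if (!is.null(phenotype_labels)) {
    if (!is.null(names(phenotype_labels)) &&
        !identical(names(phenotype_labels), ids))
      stop("phenotype labels misaligned with truth sample ids")
    out$phenotype_ari <- mclust::adjustedRandIndex(phenotype_labels,
                                                   truth$phenotype)
  }
  if (!is.null(fractions)) {
    if (!identical(rownames(fractions), rownames(truth$true_fractions)))
      stop("fraction rows misaligned with truth sample ids")
    cols <- colnames(truth$true_fractions)
    out$fraction_mae <- mean(abs(fractions[, cols] - truth$true_fractions))
  }
  if (!is.null(deg_ids)) {
    out$deg_recall <- mean(truth$planted_deg_ids %in% deg_ids)
    out$deg_precision <- if (length(deg_ids))
      mean(deg_ids %in% truth$planted_deg_ids) else NA_real_
  }
  if (!is.null(signature_genes)) {
    out$signature_planted_recall <-
      mean(signature_genes %in% truth$planted_deg_ids)
  }
  if (!is.null(cox_beta)) {
    out$cox_beta_error <- abs(cox_beta) - abs(truth$true_beta)
  }
  if (!is.null(scores)) {
    if (!is.null(names(scores)) && !identical(names(scores), ids))
      stop("scores misaligned with truth sample ids")
    out$score_phenotype_auc <- roc_auc(scores,
                                       as.integer(truth$phenotype == 1L))
  }
  out
}
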