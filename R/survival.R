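#' Construct survival data
#'
#' @param times positive follow-up times (days).
#' @param events 0/1 event indicators (1 = death observed).
#' @param sample_ids optional ids aligned with times.
#' @return object of class \code{surv_data}.
#' @export
surv_data <- function(times, events, sample_ids = NULL) {
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(times))
  structure(list(times = as.numeric(times), events = as.integer(events),
                 sample_ids = as.character(sample_ids)),
            class = "surv_data")
}

as_Surv <- function(surv) survival::Surv(surv$times, surv$events)

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; censored observations leave the risk set without
#' producing a step.
#'
#' @param surv a \code{\link{surv_data}} object.
#' @return data.frame with time, n_risk, n_event, survival.
#' @export
km_curve <- function(surv) {
  if (!length(surv$times)) stop("empty survival data")
  fit <- survival::survfit(as_Surv(surv) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Log-rank test between groups
#'
#' @param surv a \code{\link{surv_data}} object.
#' @param groups per-sample group labels (>= 2 groups).
#' @return list with chi2, df, p.
#' @export
logrank_test <- function(surv, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (length(groups) != length(surv$times)) stop("groups must match sample count")
  sd <- survival::survdiff(as_Surv(surv) ~ groups)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximisation of the partial likelihood with Efron (default)
#' or Breslow handling of tied event times.
#'
#' @param surv a \code{\link{surv_data}} object.
#' @param covariates numeric vector or samples x covariates matrix.
#' @param ties \code{"efron"} or \code{"breslow"}.
#' @return object of class \code{cox_fit}: per-covariate data.frame
#'   \code{coefficients} (beta, se, hr, ci95_low, ci95_high, z, p) plus
#'   \code{loglik}, \code{n}, \code{n_events}, \code{ties}.
#' @export
cox_fit <- function(surv, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (nrow(x) != length(surv$times)) stop("covariates must match sample count")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant covariate(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  if (sum(surv$events) < ncol(x) + 1L)
    stop("too few events for the number of covariates")
  fit <- survival::coxph(as_Surv(surv) ~ x, ties = ties,
                         control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  if (any(abs(beta) > 15))
    warning("very large coefficient(s); possible monotone likelihood / separation")
  z <- beta / se
  coefs <- data.frame(term = colnames(x), beta = beta, se = unname(se),
                      hr = exp(beta), ci95_low = exp(beta - 1.96 * se),
                      ci95_high = exp(beta + 1.96 * se), z = z,
                      p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, loglik = fit$loglik[2L],
                 n = length(surv$times), n_events = sum(surv$events),
                 ties = ties), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Univariate Cox screening of features
#'
#' One single-covariate Cox fit per feature; features are z-scored first so
#' hazard ratios are per standard deviation and comparable across features.
#' Features with a Wald p below the screening threshold are flagged as
#' representative; zero-variance features are skipped with a flag.
#'
#' @param features features x samples numeric matrix.
#' @param surv a \code{\link{surv_data}} object aligned with the columns.
#' @param threshold screening p-value threshold (default 0.05).
#' @return data.frame with feature, beta, se, hr, z, p, representative,
#'   skipped.
#' @export
univariate_screen <- function(features, surv, threshold = 0.05) {
  if (ncol(features) != length(surv$times)) stop("features must match sample count")
  out <- data.frame(feature = rownames(features), beta = NA_real_,
                    se = NA_real_, hr = NA_real_, z = NA_real_, p = NA_real_,
                    representative = FALSE, skipped = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(features))) {
    v <- features[i, ]
    if (stats::sd(v) == 0) { out$skipped[i] <- TRUE; next }
    f <- cox_fit(surv, (v - mean(v)) / stats::sd(v))
    co <- f$coefficients
    out$beta[i] <- co$beta; out$se[i] <- co$se; out$hr[i] <- co$hr
    out$z[i] <- co$z; out$p[i] <- co$p
    out$representative[i] <- co$p < threshold
  }
  out
}

# closed-form two-group log-rank chi-square (observed minus expected over
# shared event times, hypergeometric variance); equals survdiff's statistic
binary_logrank_chi2 <- function(times, events, g) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord] == 1; g_s <- g[ord]
  n <- length(t_s)
  ut <- unique(t_s)
  first <- match(ut, t_s)
  n_risk <- n - first + 1
  cg <- cumsum(g_s)
  n1_risk <- sum(g_s) - c(0, cg)[first]
  f <- factor(t_s, levels = ut)
  d_all <- as.numeric(rowsum(as.numeric(e_s), f))
  d1 <- as.numeric(rowsum(as.numeric(e_s & g_s), f))
  keep <- d_all > 0
  d_all <- d_all[keep]; d1 <- d1[keep]
  n_risk <- n_risk[keep]; n1_risk <- n1_risk[keep]
  pr <- n1_risk / n_risk
  o_minus_e <- sum(d1) - sum(d_all * pr)
  v <- sum(d_all * pr * (1 - pr) * (n_risk - d_all) / pmax(n_risk - 1, 1))
  if (v <= 0) return(0)
  o_minus_e^2 / v
}

logrank_chi2_split <- function(times, events, score, cutoffs) {
  vapply(cutoffs, function(cc)
    binary_logrank_chi2(times, events, score > cc), numeric(1L))
}

#' Maximally selected survival cutpoint
#'
#' Scans every candidate split of a continuous score that leaves at least
#' \code{minprop} of the samples on each side and returns the cutoff
#' maximising the two-group log-rank statistic. The reported p-value comes
#' from the naive chi-square(1) reference and is optimistic because the
#' maximum is taken over many correlated statistics; when
#' \code{n_permutations > 0} a permutation p-value for the maximal statistic
#' is computed as well.
#'
#' @param score per-sample numeric score.
#' @param surv a \code{\link{surv_data}} object.
#' @param minprop minimum fraction of samples on each side of the split.
#' @param n_permutations permutations for the corrected p-value (0 = skip).
#' @param seed seed for the permutation stream.
#' @return list with cutoff, chi2, p (naive), p_perm (or NA).
#' @export
optimal_cutpoint <- function(score, surv, minprop = 0.1, n_permutations = 0L,
                             seed = 1L) {
  if (length(score) != length(surv$times)) stop("score must match sample count")
  if (stats::sd(score) == 0) stop("score is constant")
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must be in (0, 0.5)")
  n <- length(score)
  s <- sort(unique(score))
  cand <- (s[-length(s)] + s[-1L]) / 2
  lo <- vapply(cand, function(cc) sum(score <= cc), numeric(1L))
  ok <- lo >= minprop * n & (n - lo) >= minprop * n
  if (!any(ok)) stop("no split satisfies the minprop constraint")
  cand <- cand[ok]
  chi2 <- logrank_chi2_split(surv$times, surv$events, score, cand)
  best <- which.max(chi2)
  p_naive <- stats::pchisq(chi2[best], df = 1L, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_permutations > 0L) {
    set.seed(seed)
    null_max <- vapply(seq_len(n_permutations), function(i) {
      sp <- sample(score)
      max(logrank_chi2_split(surv$times, surv$events, sp, cand))
    }, numeric(1L))
    p_perm <- mean(null_max >= chi2[best])
  }
  list(cutoff = cand[best], chi2 = chi2[best], p = p_naive, p_perm = p_perm)
}

#' Area under the ROC curve
#'
#' Mann-Whitney probability that a random positive scores above a random
#' negative, ties counted one half.
#'
#' @param score per-sample numeric score.
#' @param label binary labels (0/1 or two-level factor; second level = positive).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(score, label) {
  label <- as.integer(as.factor(label)) - 1L
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
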