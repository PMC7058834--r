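#' Cochran's Q heterogeneity statistic for per-SNP ratio estimates
#'
#' Q = sum over SNPs of `w_j (b_j - b_ivw)^2`, where `b_j` are the per-SNP
#' Wald ratios and `b_ivw` is their w-weighted mean.  `first_order` weights
#' are `beta_exp^2 / se_out^2` (the inverse first-order ratio variance);
#' `modified_second_order` weights also propagate the exposure SE,
#' `w_j = 1 / (se_out^2/beta_exp^2 + b_j^2 se_exp^2/beta_exp^2)`.  Excess Q
#' relative to a chi-square with `nsnp - 1` df signals heterogeneity
#' (potential horizontal pleiotropy).
#'
#' @param h a [harmonized_set()] with at least 2 SNPs.
#' @param weighting `"first_order"` or `"modified_second_order"`.
#' @return list with `q_stat`, `q_df`, `q_pvalue`, `weighting`.
#' @export
cochran_q <- function(h, weighting = c("first_order",
                                       "modified_second_order")) {
  weighting <- match.arg(weighting)
  L <- nsnp(h)
  if (L < 2) stop("Cochran's Q needs at least 2 SNPs")
  b <- h$beta_outcome / h$beta_exposure
  w <- if (weighting == "first_order") {
    h$beta_exposure^2 / h$se_outcome^2
  } else {
    1 / (h$se_outcome^2 / h$beta_exposure^2 +
           b^2 * h$se_exposure^2 / h$beta_exposure^2)
  }
  bhat <- sum(w * b) / sum(w)
  q <- sum(w * (b - bhat)^2)
  list(q_stat = q, q_df = L - 1L,
       q_pvalue = stats::pchisq(q, L - 1, lower.tail = FALSE),
       weighting = weighting)
}

presso_loo_rss <- function(bx, by, w) {
  num <- sum(w * bx * by)
  den <- sum(w * bx^2)
  loo <- (num - w * bx * by) / (den - w * bx^2)
  list(loo = loo, rss = sum(w * (by - loo * bx)^2))
}

#' MR-PRESSO global test for horizontal pleiotropy
#'
#' The observed residual sum of squares uses leave-one-out IVW slopes:
#' `rss_obs = sum_j w_j (beta_out_j - b^(-j) beta_exp_j)^2` with
#' `w_j = 1/se_out_j^2`.  Its null distribution is built by parametric
#' resampling: outcome effects are drawn from
#' `N(b^(-j) beta_exp_j, se_out_j)` and exposure effects from their own
#' normals, and the RSS recomputed (with that replicate's leave-one-out
#' slopes).  The empirical p-value uses the +1 correction, so its floor is
#' `1/(n_sim + 1)`.
#'
#' @param h a [harmonized_set()] with at least 4 SNPs.
#' @param n_sim number of parametric resamples.
#' @param seed RNG seed (caller's stream untouched).
#' @return list with `rss_obs`, `global_pvalue`, `n_sim`.
#' @export
mr_presso_global <- function(h, n_sim = 1000, seed = NULL) {
  L <- nsnp(h)
  if (L < 4) stop("MR-PRESSO global test needs at least 4 SNPs")
  w <- 1 / h$se_outcome^2
  obs <- presso_loo_rss(h$beta_exposure, h$beta_outcome, w)
  mu_out <- obs$loo * h$beta_exposure
  rss_sim <- with_seed(seed, {
    BX <- matrix(stats::rnorm(n_sim * L, rep(h$beta_exposure, each = n_sim),
                              rep(h$se_exposure, each = n_sim)), nrow = n_sim)
    BY <- matrix(stats::rnorm(n_sim * L, rep(mu_out, each = n_sim),
                              rep(h$se_outcome, each = n_sim)), nrow = n_sim)
    W <- matrix(w, n_sim, L, byrow = TRUE)
    P <- W * BX * BY
    num <- rowSums(P)
    den <- rowSums(W * BX^2)
    LOO <- (num - P) / (den - W * BX^2)
    rowSums(W * (BY - LOO * BX)^2)
  })
  list(rss_obs = obs$rss,
       global_pvalue = (1 + sum(rss_sim >= obs$rss)) / (n_sim + 1),
       n_sim = n_sim)
}

#' MR Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome.  Per instrument, `r2 = z^2/(z^2 + n - 2)`; r2 values are summed
#' over (conditionally independent) instruments per trait.  The test statistic
#' compares Fisher-transformed multiple correlations,
#' `Z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp-3) + 1/(n_out-3))`.
#' Direction is `exposure_to_outcome` when the instruments explain more
#' variance in the exposure.
#'
#' @param z_exp,z_out per-instrument z-statistics (beta/se) in the exposure
#'   and outcome studies.
#' @param n_exp,n_out study sample sizes (scalars, >= 4).
#' @return object of class `steiger_test` with `r2_exposure`, `r2_outcome`,
#'   `direction`, `z_stat`, `pvalue`.
#' @export
steiger_test <- function(z_exp, n_exp, z_out, n_out) {
  if (n_exp < 4 || n_out < 4) stop("Steiger test needs n >= 4 in both studies")
  r2e <- sum(z_exp^2 / (z_exp^2 + n_exp - 2))
  r2o <- sum(z_out^2 / (z_out^2 + n_out - 2))
  if (r2e >= 1 || r2o >= 1)
    stop("invalid instrument set: summed r2 reaches 1")
  z <- (atanh(sqrt(r2e)) - atanh(sqrt(r2o))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  direction <- if (r2e > r2o) "exposure_to_outcome"
  else if (r2e < r2o) "outcome_to_exposure"
  else "undetermined"
  structure(list(r2_exposure = r2e, r2_outcome = r2o, direction = direction,
                 z_stat = z, pvalue = two_sided_p(z)),
            class = "steiger_test")
}

#' @export
print.steiger_test <- function(x, ...) {
  cat("MR Steiger directionality test\n")
  cat(sprintf("  r2(exposure) = %s, r2(outcome) = %s\n",
              format(x$r2_exposure, digits = 4),
              format(x$r2_outcome, digits = 4)))
  cat(sprintf("  direction: %s (Z = %s, p = %s)\n", x$direction,
              format(x$z_stat, digits = 4), format(x$pvalue, digits = 3)))
  invisible(x)
}

#' Combined pleiotropy diagnostics for an exposure-outcome pair
#'
#' Bundles the modified-weights Cochran Q, the MR-PRESSO global test and the
#' MR-Egger intercept into one report.
#'
#' @param h a [harmonized_set()] with at least 4 SNPs.
#' @param n_sim,seed passed to [mr_presso_global()].
#' @return object of class `pleiotropy_report`.
#' @export
pleiotropy_report <- function(h, n_sim = 1000, seed = NULL) {
  q <- cochran_q(h, "modified_second_order")
  pr <- mr_presso_global(h, n_sim = n_sim, seed = seed)
  eg <- mr_egger(h)
  structure(list(q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
                 presso_rss_obs = pr$rss_obs,
                 presso_global_pvalue = pr$global_pvalue,
                 egger_intercept = eg$intercept,
                 egger_intercept_pvalue = eg$intercept_pvalue),
            class = "pleiotropy_report")
}

#' @export
print.pleiotropy_report <- function(x, ...) {
  cat("Pleiotropy diagnostics\n")
  cat(sprintf("  Q = %s on %d df (p = %s, modified weights)\n",
              format(x$q_stat, digits = 4), x$q_df,
              format(x$q_pvalue, digits = 3)))
  cat(sprintf("  MR-PRESSO global: RSS = %s, p = %s\n",
              format(x$presso_rss_obs, digits = 4),
              format(x$presso_global_pvalue, digits = 3)))
  cat(sprintf("  Egger intercept = %s (p = %s)\n",
              format(x$egger_intercept, digits = 4),
              format(x$egger_intercept_pvalue, digits = 3)))
  invisible(x)
}
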