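new_mediation_result <- function(method, indirect, se_indirect, total = NULL,
                                 se_total = NULL, direct = NULL, ...) {
  prop <- NULL
  prop_valid <- FALSE
  if (!is.null(total)) {
    prop_valid <- total != 0 && sign(indirect) == sign(total)
    prop <- if (total != 0) indirect / total else NA_real_
  }
  structure(c(list(method = method, indirect = indirect,
                   se_indirect = se_indirect,
                   pvalue = two_sided_p(indirect / se_indirect),
                   total = total, se_total = se_total, direct = direct,
                   proportion_mediated = prop,
                   proportion_valid = prop_valid),
              list(...)),
            class = "mediation_result")
}

#' Two-step MR indirect effect (product of coefficients)
#'
#' With theta1 the exposure-to-mediator effect and theta2 the conditional
#' mediator-to-outcome effect, the indirect effect is `theta1 * theta2` with
#' delta-method SE `sqrt(theta2^2 se1^2 + theta1^2 se2^2)` (the covariance of
#' the two estimates is taken as zero: in a two-step two-sample design they
#' come from non-overlapping samples).  If a total effect is supplied, the
#' proportion mediated `indirect/total` is reported with a validity flag
#' (flagged invalid when the total is zero or of opposite sign).
#'
#' @param theta1,se1 step-1 estimate and SE.
#' @param theta2,se2 step-2 estimate and SE.
#' @param total,se_total optional total causal effect (numeric or `mr_fit`).
#' @return object of class `mediation_result`.
#' @export
two_step_indirect <- function(theta1, se1, theta2, se2, total = NULL,
                              se_total = NULL) {
  if (inherits(total, "mr_fit")) {
    se_total <- total$se
    total <- total$estimate
  }
  stopifnot(se1 > 0, se2 > 0)
  indirect <- theta1 * theta2
  se_ind <- sqrt(theta2^2 * se1^2 + theta1^2 * se2^2)
  direct <- if (!is.null(total)) total - indirect else NULL
  new_mediation_result("product", indirect, se_ind, total, se_total, direct,
                       theta1 = theta1, se_theta1 = se1,
                       theta2 = theta2, se_theta2 = se2)
}

#' Difference-of-coefficients indirect effect
#'
#' `indirect = total - direct`, with SE `sqrt(se_total^2 + se_direct^2)`
#' (independence of the two estimates is assumed; they share the outcome
#' sample, so this SE is approximate and is flagged as such).
#'
#' @param total,se_total total causal effect (numeric or `mr_fit`).
#' @param direct,se_direct direct effect, typically from [mvmr_fit()].
#' @return object of class `mediation_result`.
#' @export
difference_indirect <- function(total, se_total = NULL, direct,
                                se_direct) {
  if (inherits(total, "mr_fit")) {
    se_total <- total$se
    total <- total$estimate
  }
  stopifnot(se_total > 0, se_direct > 0)
  indirect <- total - direct
  se_ind <- sqrt(se_total^2 + se_direct^2)
  new_mediation_result("difference", indirect, se_ind, total, se_total,
                       direct, se_direct = se_direct,
                       se_independence_assumed = TRUE)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation (", x$method, " of coefficients)\n", sep = "")
  cat(sprintf("  indirect = %s (se %s, p = %s)\n",
              format(x$indirect, digits = 4),
              format(x$se_indirect, digits = 4),
              format(x$pvalue, digits = 3)))
  if (!is.null(x$total)) {
    cat(sprintf("  total = %s, direct = %s\n",
                format(x$total, digits = 4), format(x$direct, digits = 4)))
    cat(sprintf("  proportion mediated = %s%%%s\n",
                format(100 * x$proportion_mediated, digits = 3),
                if (x$proportion_valid) "" else " (flagged: sign conflict or zero total)"))
  }
  invisible(x)
}

#' Multivariable MR with two exposures
#'
#' Weighted least squares of the SNP-outcome effects on the two columns of
#' SNP-exposure effects, no intercept, weights `1/se_out^2`.  The fitted
#' coefficients are the direct effects of each exposure conditional on the
#' other; subtracting a direct effect from the corresponding total effect
#' gives the difference-of-coefficients indirect effect.  Conditional
#' instrument strength is reported per exposure as the Q-form statistic from
#' a weighted no-intercept regression of that exposure's SNP effects on the
#' other's (weights `1/se_exp^2`); it is reported, not thresholded.
#'
#' @param beta_exposure L x 2 matrix of SNP-exposure effects.
#' @param se_exposure L x 2 matrix of their SEs.
#' @param beta_outcome,se_outcome SNP-outcome effects and SEs (length L).
#' @return object of class `mvmr_fit` with `direct_effects`, `ses`,
#'   `pvalues`, `conditional_strength_q`, `heterogeneity_q`,
#'   `heterogeneity_df`, `heterogeneity_pvalue`.
#' @export
mvmr_fit <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  X <- as.matrix(beta_exposure)
  L <- nrow(X)
  if (ncol(X) != 2) stop("exactly two exposures are supported")
  if (L < 3) stop("multivariable MR needs at least 3 SNPs")
  if (qr(X)$rank < 2) stop("collinear exposures: design is rank deficient")
  w <- 1 / se_outcome^2
  XtW <- t(X * w)
  A <- XtW %*% X
  Ai <- solve(A)
  est <- drop(Ai %*% XtW %*% beta_outcome)
  ses <- sqrt(diag(Ai))
  resid <- beta_outcome - drop(X %*% est)
  q <- sum(w * resid^2)
  sx <- as.matrix(se_exposure)
  cond_q <- vapply(1:2, function(k) {
    wk <- 1 / sx[, k]^2
    xo <- X[, -k]
    delta <- sum(wk * X[, k] * xo) / sum(wk * xo^2)
    sum(wk * (X[, k] - delta * xo)^2)
  }, 0)
  names(est) <- names(ses) <- colnames(X) %||% c("exposure1", "exposure2")
  structure(list(direct_effects = est, ses = ses,
                 pvalues = two_sided_p(est / ses),
                 conditional_strength_q = cond_q,
                 heterogeneity_q = q, heterogeneity_df = L - 2L,
                 heterogeneity_pvalue = stats::pchisq(q, L - 2,
                                                      lower.tail = FALSE),
                 nsnp = L),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat("Multivariable MR (", x$nsnp, " SNPs)\n", sep = "")
  df <- data.frame(direct = x$direct_effects, se = x$ses, p = x$pvalues,
                   cond_Q = x$conditional_strength_q)
  print(df, digits = 4)
  cat(sprintf("  Heterogeneity: Q = %s on %d df (p = %s)\n",
              format(x$heterogeneity_q, digits = 4), x$heterogeneity_df,
              format(x$heterogeneity_pvalue, digits = 3)))
  invisible(x)
}

#' @export
coef.mvmr_fit <- function(object, ...) object$direct_effects

#' Mediation results as a TSV table
#' @param results list of `mediation_result` objects.
#' @param exposure,mediator,outcome trait labels (recycled).
#' @param path optional output path.
#' @return data.frame with the mediation-table layout.
#' @export
mediation_table <- function(results, exposure = NA, mediator = NA,
                            outcome = NA, path = NULL) {
  if (inherits(results, "mediation_result")) results <- list(results)
  num <- function(v) vapply(results, function(r) r[[v]] %||% NA_real_, 0)
  df <- data.frame(exposure = exposure, mediator = mediator,
                   outcome = outcome,
                   total = num("total"), direct = num("direct"),
                   indirect = num("indirect"),
                   se_indirect = num("se_indirect"), p = num("pvalue"),
                   proportion_mediated = num("proportion_mediated"),
                   method = vapply(results, `[[`, "", "method"),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
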