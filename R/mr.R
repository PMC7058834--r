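#' Fit a two-sample Mendelian randomization model
#'
#' Central fitting front-end.  Given a [harmonized_set()] of SNP-exposure and
#' SNP-outcome effects, estimates the causal effect of the exposure on the
#' outcome (in outcome units per SD of exposure) by the requested method and
#' returns a classed `mr_fit` object with `print`, `summary`, `coef`,
#' `confint`, `plot` and `residuals` methods.
#'
#' Methods: `"ivw"` (fixed-effects inverse-variance weighted meta-analysis of
#' per-SNP Wald ratios; reduces to the single Wald ratio for one SNP),
#' `"wald"` (single-SNP ratio), `"egger"` (weighted regression with an
#' unconstrained intercept; the intercept tests directional pleiotropy),
#' `"weighted_median"` (consistent when at least half the instrument weight is
#' valid), and `"ivw_correlated"` (generalized weighted regression through the
#' origin using an LD correlation matrix, for instruments in linkage
#' disequilibrium).
#'
#' @param h a [harmonized_set()].
#' @param method one of `"ivw"`, `"wald"`, `"egger"`, `"weighted_median"`,
#'   `"ivw_correlated"`.
#' @param se_order Wald-ratio SE order, `"first"` (default; delta-method SE
#'   using the outcome SE only) or `"second"` (adds the exposure-SE term).
#' @param ld an [ld_matrix()], required for `method = "ivw_correlated"`.
#' @param n_boot,seed parametric-bootstrap settings for the weighted median.
#' @return an object of classes `c("mr_<method>", "mr_fit")`.
#' @export
mr <- function(h, method = c("ivw", "wald", "egger", "weighted_median",
                             "ivw_correlated"),
               se_order = c("first", "second"), ld = NULL, n_boot = 1000,
               seed = NULL) {
  method <- match.arg(method)
  se_order <- match.arg(se_order)
  stopifnot(inherits(h, "harmonized_set"))
  switch(method,
    ivw = ivw_fixed(ratio_estimates(h, se_order)),
    wald = {
      if (nsnp(h) != 1) stop("method 'wald' needs exactly one SNP")
      ivw_fixed(ratio_estimates(h, se_order))
    },
    egger = mr_egger(h),
    weighted_median = weighted_median(ratio_estimates(h, se_order),
                                      n_boot = n_boot, seed = seed),
    ivw_correlated = ivw_correlated(h, ld))
}

#' Wald ratio estimates
#'
#' The per-SNP causal estimate beta_out/beta_exp with a delta-method SE:
#' first order `se_out/|beta_exp|`, second order
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2/beta_exp^4)`.
#'
#' @param beta_exp,se_exp SNP-exposure effect and SE (vectors).
#' @param beta_out,se_out SNP-outcome effect and SE.
#' @param se_order `"first"` or `"second"`.
#' @param variant_id optional IDs.
#' @return data.frame of class `ratio_estimate` with columns `variant_id`,
#'   `estimate`, `se`, `se_order`.
#' @export
wald_ratio <- function(beta_exp, se_exp = NULL, beta_out, se_out,
                       se_order = c("first", "second"), variant_id = NULL) {
  se_order <- match.arg(se_order)
  if (any(beta_exp == 0))
    stop("weak instrument: beta_exp is zero for ",
         paste(which(beta_exp == 0), collapse = ", "))
  est <- beta_out / beta_exp
  se <- if (se_order == "first") {
    se_out / abs(beta_exp)
  } else {
    if (is.null(se_exp)) stop("second-order SE requires se_exp")
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  }
  out <- data.frame(
    variant_id = variant_id %||% as.character(seq_along(est)),
    estimate = est, se = se, se_order = se_order,
    stringsAsFactors = FALSE)
  class(out) <- c("ratio_estimate", "data.frame")
  out
}

#' @rdname wald_ratio
#' @param h a [harmonized_set()].
#' @export
ratio_estimates <- function(h, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  wald_ratio(h$beta_exposure, h$se_exposure, h$beta_outcome, h$se_outcome,
             se_order = se_order, variant_id = h$snp)
}

new_mr_fit <- function(method, estimate, se, nsnp, ..., data = NULL) {
  extras <- list(...)
  obj <- c(list(method = method, estimate = estimate, se = se,
                pvalue = two_sided_p(estimate / se), nsnp = nsnp),
           extras)
  obj$data <- data
  structure(obj, class = c(paste0("mr_", method), "mr_fit"))
}

#' Fixed-effects inverse-variance weighted meta-analysis of ratio estimates
#'
#' With weights `w_j = 1/se_j^2`, the pooled estimate is
#' `sum(w b)/sum(w)` with SE `1/sqrt(sum(w))`.  A single ratio is returned
#' unchanged with method `"wald"`.  Cochran's Q across the ratios is attached.
#'
#' @param ratios a `ratio_estimate` data.frame (see [wald_ratio()]).
#' @return an `mr_fit`.
#' @export
ivw_fixed <- function(ratios) {
  if (nrow(ratios) == 0) stop("no ratio estimates supplied")
  if (nrow(ratios) == 1)
    return(new_mr_fit("wald", ratios$estimate, ratios$se, 1L))
  w <- 1 / ratios$se^2
  est <- sum(w * ratios$estimate) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (ratios$estimate - est)^2)
  df <- nrow(ratios) - 1L
  new_mr_fit("ivw", est, se, nrow(ratios),
             q_stat = q, q_df = df,
             q_pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with an unconstrained intercept and weights `1/se_out^2`, after
#' re-orienting SNPs so all exposure effects are non-negative.  The slope is
#' the pleiotropy-adjusted causal estimate; a non-zero intercept indicates
#' directional pleiotropy.  SEs use multiplicative random-effects scaling with
#' the residual SD floored at 1.
#'
#' @param h a [harmonized_set()] with at least 3 SNPs.
#' @return an `mr_fit` with `intercept`, `intercept_se`, `intercept_pvalue`
#'   and heterogeneity fields.
#' @export
mr_egger <- function(h) {
  L <- nsnp(h)
  if (L < 3) stop("MR-Egger needs at least 3 SNPs (got ", L, ")")
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  bx <- s * h$beta_exposure
  by <- s * h$beta_outcome
  if (stats::var(bx) == 0)
    stop("degenerate design: no variance in exposure effects")
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # coefficient SEs under multiplicative random effects, residual SD >= 1
  scale <- max(1, sm$sigma) / sm$sigma
  co <- sm$coefficients
  est <- co["bx", "Estimate"]
  se <- co["bx", "Std. Error"] * scale
  q <- sum(w * stats::residuals(fit)^2)
  new_mr_fit("egger", est, se, L,
             intercept = co["(Intercept)", "Estimate"],
             intercept_se = co["(Intercept)", "Std. Error"] * scale,
             intercept_pvalue = two_sided_p(
               co["(Intercept)", "Estimate"] /
                 (co["(Intercept)", "Std. Error"] * scale)),
             q_stat = q, q_df = L - 2L,
             q_pvalue = stats::pchisq(q, L - 2, lower.tail = FALSE),
             data = h)
}

wm_point <- function(est, w) {
  o <- order(est)
  e <- est[o]
  wn <- w[o] / sum(w)
  S <- cumsum(wn) - wn / 2
  L <- length(e)
  if (S[1] >= 0.5) return(e[1])
  if (S[L] <= 0.5) return(e[L])
  j <- max(which(S < 0.5))
  e[j] + (e[j + 1] - e[j]) * (0.5 - S[j]) / (S[j + 1] - S[j])
}

#' Weighted median estimator
#'
#' The causal estimate is the linear interpolation of the sorted per-SNP
#' ratios at cumulative weight one half, using midpoint cumulative sums of the
#' normalized inverse-variance weights.  The SE comes from a parametric
#' bootstrap: each ratio is resampled from its normal distribution and the
#' weighted median recomputed.
#'
#' @param ratios a `ratio_estimate` data.frame with at least 3 rows.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap (the caller's RNG stream is left
#'   untouched).
#' @return an `mr_fit`.
#' @export
weighted_median <- function(ratios, n_boot = 1000, seed = NULL) {
  L <- nrow(ratios)
  if (L < 3) stop("weighted median needs at least 3 ratios (got ", L, ")")
  w <- 1 / ratios$se^2
  est <- wm_point(ratios$estimate, w)
  boots <- with_seed(seed, {
    B <- matrix(stats::rnorm(n_boot * L, mean = rep(ratios$estimate, each = n_boot),
                             sd = rep(ratios$se, each = n_boot)),
                nrow = n_boot)
    apply(B, 1, wm_point, w = w)
  })
  new_mr_fit("weighted_median", est, stats::sd(boots), L, n_boot = n_boot)
}

#' Correlated-instrument IVW (generalized weighted regression)
#'
#' For instruments in linkage disequilibrium, the causal effect is estimated
#' by generalized least squares through the origin with covariance
#' `Omega_ij = se_out_i se_out_j rho_ij`.  SNP pairs with `rho^2 >= 0.8` are
#' pruned first, dropping the member with the larger exposure p-value
#' (mirroring an `r^2 < 0.8` instrument-inclusion rule).
#'
#' @param h a [harmonized_set()].
#' @param ld an [ld_matrix()] covering exactly the SNPs of `h`.
#' @return an `mr_fit` recording the pruned SNPs in `$pruned`.
#' @export
ivw_correlated <- function(h, ld) {
  if (is.null(ld)) stop("ivw_correlated requires an LD matrix")
  if (!setequal(ld$snp, h$snp))
    stop("LD matrix must cover exactly the SNPs of the harmonized set")
  ord <- match(h$snp, ld$snp)
  rho <- ld$rho[ord, ord, drop = FALSE]
  keep <- seq_along(h$snp)
  p_exp <- h$pvalue_exposure
  repeat {
    r2 <- rho[keep, keep, drop = FALSE]^2
    diag(r2) <- 0
    if (length(keep) < 2 || max(r2) < 0.8) break
    idx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    drop <- pair[which.max(p_exp[pair])]
    keep <- setdiff(keep, drop)
  }
  x <- h$beta_exposure[keep]
  y <- h$beta_outcome[keep]
  so <- h$se_outcome[keep]
  omega <- (so %o% so) * rho[keep, keep, drop = FALSE]
  oi <- tryCatch(solve(omega), error = function(e)
    stop("singular instrument covariance after pruning (snps: ",
         paste(h$snp[keep], collapse = ", "), ")"))
  xox <- drop(t(x) %*% oi %*% x)
  est <- drop(t(x) %*% oi %*% y) / xox
  se <- sqrt(1 / xox)
  r <- y - est * x
  q <- drop(t(r) %*% oi %*% r)
  new_mr_fit("ivw_correlated", est, se, length(keep),
             q_stat = q, q_df = length(keep) - 1L,
             q_pvalue = stats::pchisq(q, length(keep) - 1,
                                      lower.tail = FALSE),
             pruned = h$snp[setdiff(seq_along(h$snp), keep)], data = h)
}
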