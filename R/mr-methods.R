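method_label <- c(wald = "Wald ratio",
                  ivw = "Inverse-variance weighted (fixed effects)",
                  egger = "MR-Egger",
                  weighted_median = "Weighted median",
                  ivw_correlated = "IVW, correlated instruments (GLS)")

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(method_label[[x$method]], "\n")
  cat(sprintf("  nsnp = %d, b = %s, se = %s, p = %s\n", x$nsnp,
              format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              format(x$pvalue, digits = 3)))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %s (se %s, p = %s)\n",
                format(x$intercept, digits = digits),
                format(x$intercept_se, digits = digits),
                format(x$intercept_pvalue, digits = 3)))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  ci <- confint(f)
  cat(sprintf("  95%% CI [%s, %s]\n", format(ci[1], digits = 4),
              format(ci[2], digits = 4)))
  if (!is.null(f$q_stat))
    cat(sprintf("  Heterogeneity: Q = %s on %d df (p = %s)\n",
                format(f$q_stat, digits = 4), f$q_df,
                format(f$q_pvalue, digits = 3)))
  if (!is.null(f$pruned) && length(f$pruned) > 0)
    cat("  Pruned (rho^2 >= 0.8):", paste(f$pruned, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (!is.null(object$intercept))
    c(intercept = object$intercept, slope = object$estimate)
  else c(estimate = object$estimate)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(object$estimate - z * object$se, object$estimate + z * object$se)
}

#' @export
residuals.mr_fit <- function(object, ...) {
  h <- object$data
  if (is.null(h)) stop("fit does not carry its harmonized data")
  int <- object$intercept %||% 0
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  s * h$beta_outcome - (int + object$estimate * s * h$beta_exposure)
}

#' Scatter plot of SNP effects with the fitted causal slope
#' @param x an `mr_fit` carrying its harmonized data, or pass `h`.
#' @param h optional [harmonized_set()] when the fit does not store one.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, h = NULL, ...) {
  h <- h %||% x$data
  if (is.null(h)) stop("supply the harmonized set used for the fit")
  bx <- h$beta_exposure; by <- h$beta_outcome
  graphics::plot(bx, by, pch = 19,
                 xlab = "SNP effect on exposure (SD/allele)",
                 ylab = "SNP effect on outcome (SD/allele)", ...)
  graphics::segments(bx, by - 1.96 * h$se_outcome,
                     bx, by + 1.96 * h$se_outcome, col = "grey60")
  graphics::segments(bx - 1.96 * h$se_exposure, by,
                     bx + 1.96 * h$se_exposure, by, col = "grey60")
  graphics::abline(a = x$intercept %||% 0, b = x$estimate, col = "firebrick")
  invisible(x)
}

#' Serialize MR results as a TSV row set
#'
#' One row per fit with columns `method`, `exposure`, `outcome`, `nsnp`, `b`,
#' `se`, `pval` (the layout of a per-CpG results table).
#'
#' @param fits a list of `mr_fit` objects (or a single fit).
#' @param exposure,outcome trait labels (recycled).
#' @param path optional output path; when given the table is written as TSV.
#' @return the results data.frame, invisibly when `path` is given.
#' @export
mr_results_table <- function(fits, exposure = NA, outcome = NA, path = NULL) {
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  df <- data.frame(
    method = vapply(fits, `[[`, "", "method"),
    exposure = exposure, outcome = outcome,
    nsnp = vapply(fits, `[[`, 0L, "nsnp"),
    b = vapply(fits, `[[`, 0, "estimate"),
    se = vapply(fits, `[[`, 0, "se"),
    pval = vapply(fits, `[[`, 0, "pvalue"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
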