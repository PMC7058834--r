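#' Ground-truth evaluation studies
#'
#' These functions rerun the estimators over many seeded synthetic datasets
#' and measure frequentist operating characteristics against the recorded
#' ground truth: confidence-interval coverage and Steiger direction accuracy
#' under a direct-effect diagram, mediation-proportion recovery under a
#' mediation diagram, type-I error of the heterogeneity tests under the null,
#' and colocalization PPA behaviour on shared-variant and null regions.
#'
#' @name evaluation
NULL

#' @describeIn evaluation IVW coverage of the true effect and Steiger
#'   direction accuracy over `n_rep` replicates of the `M_to_Y` diagram.
#'   Returns `coverage` (proportion of nominal-level CIs covering the true
#'   total effect), `steiger_correct` (proportion of replicates with
#'   direction `exposure_to_outcome`), and the per-replicate estimates.
#' @param n_rep number of replicates.
#' @param config a [sim_config()]; per-replicate seeds are derived from
#'   `seed`.
#' @param seed base seed.
#' @param level nominal confidence level.
#' @param se_order Wald-ratio SE order.  The default is `"second"`: with an
#'   exposure sample two orders of magnitude smaller than the outcome sample,
#'   the exposure-SE term dominates the ratio variance and first-order
#'   intervals undercover badly.
#' @export
evaluate_ivw_coverage <- function(n_rep = 200, config = sim_config(),
                                  seed = 1, level = 0.95,
                                  se_order = "second") {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- se <- numeric(n_rep)
  direction <- character(n_rep)
  truth_total <- NA_real_
  for (i in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- seed * 1000 + i
    d <- simulate_dataset(cfg)
    truth_total <- d$truth$total
    ins <- select_instruments(d$sample1$methylation)
    h <- harmonize(ins, d$sample2$lung_function)
    fit <- mr(h, if (nsnp(h) == 1) "wald" else "ivw", se_order = se_order)
    est[i] <- fit$estimate
    se[i] <- fit$se
    st <- steiger_test(h$beta_exposure / h$se_exposure, h$n_exposure,
                       h$beta_outcome / h$se_outcome, h$n_outcome)
    direction[i] <- st$direction
  }
  list(coverage = mean(abs(est - truth_total) <= z * se),
       steiger_correct = mean(direction == "exposure_to_outcome"),
       estimates = est, ses = se, truth = truth_total)
}

#' @describeIn evaluation Two-step product-of-coefficients recovery of the
#'   proportion mediated under the `M_to_S_to_Y` diagram.  Each replicate
#'   estimates theta1 (M on S: M's instruments from the small sample, smoking
#'   associations from the large one), theta2 (S on Y: smoking instruments
#'   selected and estimated in the large sample, mirroring their real-world
#'   origin in a large GWAS) and the total (M on Y), and forms
#'   `theta1*theta2 / total`.  Returns the mean recovered proportion, its
#'   Monte-Carlo SE, and the true value.
#' @export
evaluate_mediation_recovery <- function(n_rep = 200,
                                        config = sim_config(dag = "M_to_S_to_Y"),
                                        seed = 1, se_order = "second") {
  prop <- numeric(n_rep)
  truth_prop <- NA_real_
  fit_pair <- function(ins, outcome) {
    h <- harmonize(ins, outcome)
    mr(h, if (nsnp(h) == 1) "wald" else "ivw", se_order = se_order)
  }
  for (i in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- seed * 1000 + i
    d <- simulate_dataset(cfg)
    truth_prop <- d$truth$proportion_mediated
    ins_m <- select_instruments(d$sample1$methylation)
    ins_s <- select_instruments(d$sample2$smoking, 5e-8)
    step1 <- fit_pair(ins_m, d$sample2$smoking)
    step2 <- fit_pair(ins_s, d$sample2$lung_function)
    total <- fit_pair(ins_m, d$sample2$lung_function)
    med <- two_step_indirect(step1$estimate, step1$se,
                             step2$estimate, step2$se, total = total)
    prop[i] <- med$proportion_mediated
  }
  list(mean_proportion = mean(prop), mc_se = stats::sd(prop) / sqrt(n_rep),
       proportions = prop, truth = truth_prop)
}

# Summary-level null draws: true per-SNP exposure effects with a homogeneous
# causal effect, estimates drawn from their sampling normals.  Exposure
# effects are measured nearly without error: the MR-PRESSO resampling scheme
# conditions on the observed exposure effects as truth, so its size is exact
# only in that regime (the conservative drift as exposure noise grows is
# described in the methods vignette).
null_summary_draw <- function(L, theta = 0.3) {
  bx0 <- stats::runif(L, 0.2, 0.5)
  sx <- rep(0.002, L)
  sy <- stats::runif(L, 0.01, 0.03)
  harmonized_set(snp = paste0("rs", seq_len(L)),
                 beta_exposure = stats::rnorm(L, bx0, sx),
                 se_exposure = sx,
                 beta_outcome = stats::rnorm(L, theta * bx0, sy),
                 se_outcome = sy)
}

#' @describeIn evaluation Type-I error of Cochran's Q at `alpha` under
#'   homogeneous-effect null simulations (summary-level draws with valid
#'   instruments).  Returns the rejection rate and the binomial 95% band
#'   around `alpha`.
#' @param n_snps instruments per replicate.
#' @param alpha test level.
#' @param weighting passed to [cochran_q()].
#' @export
evaluate_q_calibration <- function(n_rep = 2000, n_snps = 10, alpha = 0.05,
                                   weighting = "first_order", seed = 1) {
  rej <- with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      cochran_q(null_summary_draw(n_snps), weighting)$q_pvalue < alpha
    }, TRUE)
  })
  band <- alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / n_rep)
  list(rate = mean(rej), band = band, n_rep = n_rep)
}

#' @describeIn evaluation Type-I error of the MR-PRESSO global test at
#'   `alpha` under the same null.
#' @param n_sim resamples per replicate (see [mr_presso_global()]).
#' @export
evaluate_presso_calibration <- function(n_rep = 100, n_snps = 10,
                                        n_sim = 1000, alpha = 0.05,
                                        seed = 1) {
  pvals <- with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      h <- null_summary_draw(n_snps)
      mr_presso_global(h, n_sim = n_sim)$global_pvalue
    }, 0)
  })
  band <- alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / n_rep)
  list(rate = mean(pvals < alpha), band = band, pvalues = pvals,
       n_rep = n_rep)
}

#' @describeIn evaluation Colocalization PPA behaviour over `n_rep` seeded
#'   regions simulated under `scenario`.  Returns the per-region three-way
#'   PPAs and the proportion reaching `threshold` (the 80% decision rule).
#' @param scenario a configuration label (see [simulate_region()]).
#' @param threshold PPA decision threshold.
#' @param ... passed to [moloc_posteriors()].
#' @export
evaluate_coloc <- function(n_rep = 200, config = sim_config(),
                           scenario = "null", threshold = 0.8, seed = 1,
                           ...) {
  ppa <- vapply(seq_len(n_rep), function(i) {
    r <- simulate_region(config, scenario, seed = seed * 1000 + i)
    moloc_posteriors(r$region, ...)$ppa_three_way
  }, 0)
  list(rate = mean(ppa >= threshold), ppa = ppa, n_rep = n_rep)
}
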