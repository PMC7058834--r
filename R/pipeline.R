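#' Bonferroni family-wise threshold
#'
#' `alpha / n_tests`, where `n_tests` is the realized number of tests in the
#' family (e.g. 0.05/415 = 1.2e-4 for a 415-CpG discovery family, 0.05/18 =
#' 0.0028 for an 18-CpG replication family).  Summaries report it at two
#' significant figures; full precision is used internally.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a single value >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / n_tests
}

#' Direction concordance between discovery and replication estimates
#'
#' Share of effect estimates whose replication sign matches discovery,
#' rounded to a whole percent (15 of 18 concordant gives 83).
#'
#' @param b_discovery,b_replication paired effect estimates.
#' @export
direction_concordance <- function(b_discovery, b_replication) {
  stopifnot(length(b_discovery) == length(b_replication),
            length(b_discovery) >= 1)
  round(100 * mean(sign(b_discovery) == sign(b_replication)))
}

#' Share of exposures proxied by a single instrument
#'
#' Given per-exposure instrument counts, the percentage proxied by exactly
#' one SNP, rounded to a whole percent (406 single-SNP CpGs out of 474 gives
#' 86).
#'
#' @param n_instruments integer vector of per-exposure instrument counts.
#' @export
single_snp_share <- function(n_instruments) {
  stopifnot(length(n_instruments) >= 1)
  round(100 * mean(n_instruments == 1))
}

new_stage_report <- function(stage, results, threshold, passing, ...) {
  structure(c(list(stage = stage, results = results,
                   tested = nrow(results), threshold = threshold,
                   passing = passing), list(...)),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("Stage '%s': %d tested, threshold %s, %d passing\n",
              x$stage, x$tested, format(signif(x$threshold, 2)),
              length(x$passing)))
  if (!is.null(x$concordance))
    cat(sprintf("  direction concordance: %d%%\n", x$concordance))
  if (length(x$passing) > 0)
    cat("  passing:", paste(x$passing, collapse = ", "), "\n")
  invisible(x)
}

estimate_one <- function(ins, outcome, palindrome_eaf_limit) {
  h <- harmonize(ins, outcome, palindrome_eaf_limit)
  fit <- if (nsnp(h) == 1) mr(h, "wald") else mr(h, "ivw")
  list(h = h, fit = fit)
}

#' Discovery-stage MR across an exposure manifest
#'
#' For every exposure (CpG site), selects instruments at `p_instrument`,
#' harmonizes them against the outcome table, and estimates the causal effect
#' by Wald ratio (one instrument) or fixed-effects IVW (several).  The
#' Bonferroni threshold uses the number of exposures actually tested, and
#' exposures passing it flow to later stages.
#'
#' @param exposures named list of `sumstats` (one per exposure).
#' @param outcome outcome `sumstats` table.
#' @param alpha family-wise error rate.
#' @param p_instrument instrument-selection p-value threshold.
#' @param palindrome_eaf_limit passed to [harmonize()].
#' @param stage stage name recorded in the report.
#' @return a `stage_report` with `results` (exposure, method, nsnp, b, se,
#'   pval), `threshold`, `passing`, and `skipped` (exposures with no usable
#'   instruments, with reasons).
#' @export
mr_discovery <- function(exposures, outcome, alpha = 0.05,
                         p_instrument = 1e-7, palindrome_eaf_limit = 0.42,
                         stage = "discovery") {
  stopifnot(length(exposures) >= 1, !is.null(names(exposures)))
  rows <- list()
  skipped <- list()
  for (cpg in names(exposures)) {
    ins <- select_instruments(exposures[[cpg]], p_instrument)
    if (nrow(ins) == 0) {
      skipped[[cpg]] <- "no instruments at threshold"
      next
    }
    est <- tryCatch(estimate_one(ins, outcome, palindrome_eaf_limit),
                    error = function(e) conditionMessage(e))
    if (is.character(est)) {
      skipped[[cpg]] <- est
      next
    }
    rows[[cpg]] <- data.frame(exposure = cpg, method = est$fit$method,
                              nsnp = est$fit$nsnp, b = est$fit$estimate,
                              se = est$fit$se, pval = est$fit$pvalue,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("empty stage: no testable exposure")
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  threshold <- bonferroni_threshold(alpha, nrow(results))
  new_stage_report(stage, results, threshold,
                   results$exposure[results$pval < threshold],
                   alpha = alpha, skipped = skipped)
}

#' Replication-stage MR restricted to the discovery passing set
#'
#' Re-estimates the exposures that passed discovery against a replication
#' outcome table, applies Bonferroni over the passing count, and reports the
#' direction concordance with the discovery estimates as a whole percent.
#' Refuses to run when discovery produced no passing exposures (stage
#' ordering is enforced).
#'
#' @param discovery the discovery `stage_report`.
#' @param exposures the exposure manifest (named list of `sumstats`).
#' @param outcome replication outcome `sumstats`.
#' @inheritParams mr_discovery
#' @return a `stage_report` with `concordance` and `replicated`.
#' @export
mr_replication <- function(discovery, exposures, outcome, alpha = 0.05,
                           p_instrument = 1e-7,
                           palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(discovery, "stage_report"))
  if (length(discovery$passing) == 0)
    stop("replication requires a completed discovery stage with >= 1 passing exposure")
  missing <- setdiff(discovery$passing, names(exposures))
  if (length(missing) > 0)
    stop("exposures absent from manifest: ", paste(missing, collapse = ", "))
  rep_report <- mr_discovery(exposures[discovery$passing], outcome,
                             alpha = alpha, p_instrument = p_instrument,
                             palindrome_eaf_limit = palindrome_eaf_limit,
                             stage = "replication")
  shared <- intersect(rep_report$results$exposure,
                      discovery$results$exposure)
  conc <- direction_concordance(
    discovery$results$b[match(shared, discovery$results$exposure)],
    rep_report$results$b[match(shared, rep_report$results$exposure)])
  rep_report$concordance <- conc
  rep_report$replicated <- rep_report$passing
  rep_report
}

#' Bidirectional MR with a Steiger directionality verdict
#'
#' Runs the forward MR (exposure instruments against the outcome table), the
#' reciprocal MR (outcome instruments against the exposure table), and the
#' Steiger test on the forward instruments, and records a per-pair verdict:
#' `"exposure_to_outcome"` when the forward fit is significant at
#' `alpha`, the reverse is not, and Steiger agrees; the mirror image for
#' `"outcome_to_exposure"`; otherwise `"undetermined"`.
#'
#' @param exposure_assoc exposure-study `sumstats` (instrument source).
#' @param outcome_assoc outcome-study `sumstats` covering those SNPs.
#' @param reverse_instruments outcome-study `sumstats` used as reverse
#'   instruments (e.g. FEV1 GWAS hits at p < 5e-8).
#' @param reverse_outcome_assoc exposure-study `sumstats` covering the
#'   reverse instruments.
#' @param p_instrument forward instrument threshold.
#' @param p_instrument_reverse reverse instrument threshold.
#' @param alpha significance level for the verdict.
#' @param palindrome_eaf_limit passed to [harmonize()].
#' @return object of class `bidirectional_mr`: `forward`, `reverse`
#'   (`mr_fit`s), `steiger`, `verdict`.
#' @export
bidirectional_mr <- function(exposure_assoc, outcome_assoc,
                             reverse_instruments, reverse_outcome_assoc,
                             p_instrument = 1e-7,
                             p_instrument_reverse = 5e-8, alpha = 0.05,
                             palindrome_eaf_limit = 0.42) {
  ins_f <- select_instruments(exposure_assoc, p_instrument)
  fwd <- estimate_one(ins_f, outcome_assoc, palindrome_eaf_limit)
  ins_r <- select_instruments(reverse_instruments, p_instrument_reverse)
  rev <- estimate_one(ins_r, reverse_outcome_assoc, palindrome_eaf_limit)
  h <- fwd$h
  n_exp <- h$n_exposure
  n_out <- h$n_outcome
  st <- steiger_test(h$beta_exposure / h$se_exposure, n_exp,
                     h$beta_outcome / h$se_outcome, n_out)
  fwd_sig <- fwd$fit$pvalue < alpha
  rev_sig <- rev$fit$pvalue < alpha
  verdict <- if (fwd_sig && !rev_sig && st$direction == "exposure_to_outcome")
    "exposure_to_outcome"
  else if (rev_sig && !fwd_sig && st$direction == "outcome_to_exposure")
    "outcome_to_exposure"
  else "undetermined"
  structure(list(forward = fwd$fit, reverse = rev$fit, steiger = st,
                 verdict = verdict), class = "bidirectional_mr")
}

#' @export
print.bidirectional_mr <- function(x, ...) {
  cat("Bidirectional MR\n")
  cat("Forward:  "); print(x$forward)
  cat("Reverse:  "); print(x$reverse)
  print(x$steiger)
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

#' Consolidated pipeline report
#'
#' Writes a consolidated TSV of every stage's per-exposure results plus a
#' human-readable summary (tested counts, thresholds at two significant
#' figures, passing exposures, concordance).  Output is deterministic given
#' the inputs: re-running with the same stage reports, seed and
#' configuration yields byte-identical files.
#'
#' @param reports list of `stage_report` objects.
#' @param dir output directory (created if needed).
#' @param seed,config optional provenance recorded in the summary.
#' @return invisible character vector of the files written.
#' @export
mr_report <- function(reports, dir, seed = NULL, config = NULL) {
  stopifnot(length(reports) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all <- do.call(rbind, lapply(reports, function(r)
    cbind(stage = r$stage, r$results)))
  results_path <- file.path(dir, "results.tsv")
  utils::write.table(all, results_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- c("methylmr pipeline report", "")
  if (!is.null(seed)) lines <- c(lines, paste("seed:", seed))
  if (!is.null(config)) {
    cfg <- paste(deparse(unclass(config)), collapse = " ")
    hash <- sum(utf8ToInt(cfg) * (seq_len(nchar(cfg)) %% 997)) %% 2^31
    lines <- c(lines, paste("config hash:", format(hash)))
  }
  for (r in reports) {
    lines <- c(lines, "",
               sprintf("stage %s: tested %d, threshold %s, passing %d",
                       r$stage, r$tested, format(signif(r$threshold, 2)),
                       length(r$passing)))
    if (!is.null(r$concordance))
      lines <- c(lines, sprintf("  direction concordance: %d%%",
                                r$concordance))
    if (length(r$passing) > 0)
      lines <- c(lines, paste("  passing:", paste(r$passing, collapse = ", ")))
  }
  summary_path <- file.path(dir, "summary.txt")
  writeLines(lines, summary_path)
  invisible(c(results_path, summary_path))
}
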