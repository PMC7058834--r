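#' Construct a harmonized exposure/outcome set directly
#'
#' Users with summary statistics already aligned to a common effect allele can
#' build a `harmonized_set` without going through [harmonize()].
#'
#' @param snp variant IDs.
#' @param beta_exposure,se_exposure SNP-exposure effects and SEs.
#' @param beta_outcome,se_outcome SNP-outcome effects and SEs.
#' @param n_exposure,n_outcome per-study sample sizes.
#' @param effect_allele,other_allele optional allele labels (exposure
#'   orientation).
#' @param eaf_exposure,eaf_outcome optional effect-allele frequencies.
#' @param pvalue_exposure,pvalue_outcome optional p-values; recomputed from
#'   beta/se when absent.
#' @param exclusions data.frame `(variant_id, reason)` of dropped SNPs.
#' @return an object of class `harmonized_set`.
#' @export
harmonized_set <- function(snp, beta_exposure, se_exposure, beta_outcome,
                           se_outcome, n_exposure = NA_real_,
                           n_outcome = NA_real_, effect_allele = NULL,
                           other_allele = NULL, eaf_exposure = NULL,
                           eaf_outcome = NULL, pvalue_exposure = NULL,
                           pvalue_outcome = NULL,
                           exclusions = data.frame(variant_id = character(),
                                                   reason = character())) {
  L <- length(snp)
  stopifnot(L >= 1)
  recycle <- function(x) if (length(x) == 1) rep(x, L) else x
  beta_exposure <- recycle(beta_exposure)
  se_exposure <- recycle(se_exposure)
  beta_outcome <- recycle(beta_outcome)
  se_outcome <- recycle(se_outcome)
  stopifnot(length(beta_exposure) == L, length(se_exposure) == L,
            length(beta_outcome) == L, length(se_outcome) == L)
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("standard errors must be positive")
  structure(list(
    snp = as.character(snp),
    effect_allele = effect_allele %||% rep(NA_character_, L),
    other_allele = other_allele %||% rep(NA_character_, L),
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    eaf_exposure = eaf_exposure %||% rep(NA_real_, L),
    pvalue_exposure = pvalue_exposure %||%
      two_sided_p(beta_exposure / se_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    eaf_outcome = eaf_outcome %||% rep(NA_real_, L),
    pvalue_outcome = pvalue_outcome %||%
      two_sided_p(beta_outcome / se_outcome),
    n_exposure = n_exposure,
    n_outcome = n_outcome,
    exclusions = exclusions
  ), class = "harmonized_set")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns SNP-outcome records to the exposure's effect allele for every SNP
#' present in both tables.  Swapped outcome alleles flip the outcome beta sign
#' and replace eaf by 1-eaf; strand-complement alleles are reconciled the same
#' way.  Strand-ambiguous (A/T, C/G) SNPs are retained only when both
#' effect-allele frequencies are informative: present, outside
#' `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`, and on the same side of
#' 0.5 after textual orientation.  Every exclusion carries a machine-readable
#' reason.
#'
#' @param exposure,outcome `sumstats` data.frames keyed by `variant_id`.
#' @param palindrome_eaf_limit ambiguity band half-width (default 0.42, the
#'   common two-sample MR convention).
#' @return a [harmonized_set()].
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  if (nrow(exposure) == 0 || nrow(outcome) == 0)
    stop("exposure and outcome records must be nonempty")
  exposure <- exposure[!duplicated(exposure$variant_id), , drop = FALSE]
  outcome <- outcome[!duplicated(outcome$variant_id), , drop = FALSE]
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0)
    stop("no overlapping variants between exposure and outcome")
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  lim <- palindrome_eaf_limit
  keep <- logical(length(shared))
  flip <- logical(length(shared))
  reason <- character(length(shared))
  for (i in seq_along(shared)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    EA <- ou$effect_allele[i]; OA <- ou$other_allele[i]
    palindromic <- ea == COMPLEMENT[[oa]]
    if (!palindromic) {
      if (EA == ea && OA == oa) { keep[i] <- TRUE
      } else if (EA == oa && OA == ea) { keep[i] <- TRUE; flip[i] <- TRUE
      } else if (EA == COMPLEMENT[[ea]] && OA == COMPLEMENT[[oa]]) {
        keep[i] <- TRUE
      } else if (EA == COMPLEMENT[[oa]] && OA == COMPLEMENT[[ea]]) {
        keep[i] <- TRUE; flip[i] <- TRUE
      } else reason[i] <- "allele mismatch"
    } else {
      if (!setequal(c(EA, OA), c(ea, oa))) {
        reason[i] <- "allele mismatch"
      } else {
        flip_i <- EA != ea
        f_exp <- ex$eaf[i]
        f_out <- if (flip_i) 1 - ou$eaf[i] else ou$eaf[i]
        ambiguous <- is.na(f_exp) || is.na(f_out) ||
          (f_exp >= lim && f_exp <= 1 - lim) ||
          (f_out >= lim && f_out <= 1 - lim) ||
          ((f_exp > 0.5) != (f_out > 0.5))
        if (ambiguous) reason[i] <- "palindromic, ambiguous eaf"
        else { keep[i] <- TRUE; flip[i] <- flip_i }
      }
    }
  }
  excl <- data.frame(variant_id = shared[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  if (!any(keep))
    stop("no SNPs survive harmonization (", nrow(excl), " excluded)")
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  sgn <- ifelse(flip[keep], -1, 1)
  harmonized_set(
    snp = ex$variant_id,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se,
    eaf_exposure = ex$eaf, pvalue_exposure = ex$pvalue,
    beta_outcome = sgn * ou$beta, se_outcome = ou$se,
    eaf_outcome = ifelse(flip[keep], 1 - ou$eaf, ou$eaf),
    pvalue_outcome = ou$pvalue,
    n_exposure = stats::median(ex$n, na.rm = TRUE),
    n_outcome = stats::median(ou$n, na.rm = TRUE),
    exclusions = excl)
}

#' Number of SNPs in a harmonized set
#' @param h a `harmonized_set`.
#' @export
nsnp <- function(h) length(h$snp)

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized exposure/outcome set:", nsnp(x), "SNP(s)\n")
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    cat("Excluded:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  df <- data.frame(snp = x$snp,
                   beta_exposure = x$beta_exposure,
                   se_exposure = x$se_exposure,
                   beta_outcome = x$beta_outcome,
                   se_outcome = x$se_outcome)
  print(utils::head(df, 10), row.names = FALSE)
  if (nsnp(x) > 10) cat("...", nsnp(x) - 10, "more\n")
  invisible(x)
}

#' @export
as.data.frame.harmonized_set <- function(x, ...) {
  data.frame(variant_id = x$snp,
             effect_allele = x$effect_allele,
             other_allele = x$other_allele,
             beta_exposure = x$beta_exposure,
             se_exposure = x$se_exposure,
             eaf_exposure = x$eaf_exposure,
             pvalue_exposure = x$pvalue_exposure,
             beta_outcome = x$beta_outcome,
             se_outcome = x$se_outcome,
             eaf_outcome = x$eaf_outcome,
             pvalue_outcome = x$pvalue_outcome,
             stringsAsFactors = FALSE)
}

#' Write a harmonized set (and its exclusion report) as TSV
#' @param h a `harmonized_set`.
#' @param path output path for the harmonized table.
#' @param exclusions_path optional path for the exclusion report.
#' @export
write_harmonized <- function(h, path, exclusions_path = NULL) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(exclusions_path))
    utils::write.table(h$exclusions, exclusions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
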