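#' Summary-statistic tables
#'
#' An object of class `sumstats` is a `data.frame` with one row per SNP-trait
#' association and the canonical columns `variant_id`, `chromosome`,
#' `position`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#' `n`, `trait_id`, `trait_type`.  `beta` is the effect in trait units per copy
#' of the effect allele (for methylation, the SD change in methylation; for
#' lung function, the SD change in FEV1).
#'
#' @param x a data.frame with at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`.  Missing optional columns are filled with
#'   `NA`; a missing `pvalue` is recomputed from `beta/se` under the two-sided
#'   normal approximation.
#' @return a validated `sumstats` data.frame.
#' @export
as_sumstats <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(mandatory, names(x))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  optional <- c(chromosome = NA_character_, position = NA_integer_,
                eaf = NA_real_, pvalue = NA_real_, n = NA_real_,
                trait_id = NA_character_, trait_type = NA_character_)
  for (col in names(optional)) if (is.null(x[[col]])) x[[col]] <- optional[[col]]
  x$beta <- as.numeric(x$beta)
  x$se <- as.numeric(x$se)
  x$eaf <- as.numeric(x$eaf)
  x$n <- as.numeric(x$n)
  x$position <- as.integer(x$position)
  x$pvalue <- as.numeric(x$pvalue)
  fill <- is.na(x$pvalue)
  x$pvalue[fill] <- two_sided_p(x$beta[fill] / x$se[fill])
  x <- x[, c("variant_id", "chromosome", "position", "effect_allele",
             "other_allele", "eaf", "beta", "se", "pvalue", "n",
             "trait_id", "trait_type")]
  validate_sumstats(x)
  class(x) <- c("sumstats", "data.frame")
  x
}

validate_sumstats <- function(x) {
  if (any(!x$effect_allele %in% ALLELES) || any(!x$other_allele %in% ALLELES))
    stop("alleles must be single bases A/C/G/T")
  if (any(x$effect_allele == x$other_allele))
    stop("effect_allele must differ from other_allele")
  if (any(x$se <= 0))
    stop("standard errors must be positive")
  if (any(x$pvalue <= 0 | x$pvalue > 1))
    stop("p-values must lie in (0, 1]")
  if (any(!is.na(x$n) & x$n < 2))
    stop("sample sizes must be >= 2")
  ok <- !is.na(x$eaf)
  if (any(ok & (x$eaf <= 0 | x$eaf >= 1)))
    stop("effect-allele frequencies must lie in (0, 1)")
  # p-values supplied alongside beta/se should agree with the normal
  # approximation to one significant figure (rounding in published tables);
  # deep tails are skipped, where t- and normal-based p legitimately diverge
  chk <- is.finite(x$pvalue) & x$pvalue > 1e-10
  expect <- pmax(two_sided_p(x$beta[chk] / x$se[chk]), 1e-300)
  bad <- abs(log10(x$pvalue[chk]) - log10(expect)) > 1
  if (any(bad))
    warning(sum(bad), " record(s) have p-values inconsistent with beta/se")
  invisible(x)
}

#' Read a tab-separated summary-statistics file
#'
#' Reads a header-labelled TSV of per-SNP association statistics.  Alternative
#' header names are resolved through `dialect`, a named character vector
#' mapping canonical names (`variant_id`, `effect_allele`, `other_allele`,
#' `beta`, `se`, and optionally `chromosome`, `position`, `eaf`, `pvalue`,
#' `n`) to the column names used in the file.  Rows whose `beta` or `se` do
#' not parse as numbers (or with non-positive `se`) are collected in the
#' `rejects` attribute rather than silently dropped.
#'
#' @param path file path.
#' @param dialect named character vector, canonical name -> file column name.
#' @param trait_id,trait_type labels attached to every record.
#' @return a `sumstats` data.frame with attribute `rejects`, a data.frame of
#'   `(variant_id, reason)`.
#' @export
read_sumstats <- function(path, dialect = NULL, trait_id = NA_character_,
                          trait_type = NA_character_) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0) stop("empty summary-statistics file: ", path)
  canon <- c("variant_id", "chromosome", "position", "effect_allele",
             "other_allele", "eaf", "beta", "se", "pvalue", "n")
  map <- stats::setNames(canon, canon)
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  for (col in mandatory)
    if (!map[[col]] %in% names(raw))
      stop("missing mandatory column '", map[[col]], "' (for ", col, ")")
  get_col <- function(col) if (map[[col]] %in% names(raw)) raw[[map[[col]]]] else NA
  df <- data.frame(variant_id = get_col("variant_id"),
                   chromosome = as.character(get_col("chromosome")),
                   position = suppressWarnings(as.integer(get_col("position"))),
                   effect_allele = toupper(get_col("effect_allele")),
                   other_allele = toupper(get_col("other_allele")),
                   eaf = suppressWarnings(as.numeric(get_col("eaf"))),
                   beta = suppressWarnings(as.numeric(get_col("beta"))),
                   se = suppressWarnings(as.numeric(get_col("se"))),
                   pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
                   n = suppressWarnings(as.numeric(get_col("n"))),
                   trait_id = trait_id, trait_type = trait_type,
                   stringsAsFactors = FALSE)
  bad_beta <- is.na(df$beta)
  bad_se <- !bad_beta & (is.na(df$se) | df$se <= 0)
  rejects <- data.frame(
    variant_id = df$variant_id[bad_beta | bad_se],
    reason = c(rep("unparseable beta", sum(bad_beta)),
               rep("unparseable se", sum(bad_se))),
    stringsAsFactors = FALSE)
  out <- as_sumstats(df[!(bad_beta | bad_se), , drop = FALSE])
  attr(out, "rejects") <- rejects
  out
}

#' Write summary statistics as TSV
#' @param x a `sumstats` data.frame.
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select genome-wide-significant instruments
#'
#' Retains mQTL (or GWAS) records with `pvalue < p_threshold`.  The default
#' threshold of 1e-7 is the catalog inclusion rule for conditionally
#' independent mQTLs.
#'
#' @param x a `sumstats` data.frame.
#' @param p_threshold p-value cutoff (exclusive).
#' @return the retained records (possibly zero rows).
#' @export
select_instruments <- function(x, p_threshold = 1e-7) {
  if (nrow(x) == 0) stop("no records supplied")
  x[x$pvalue < p_threshold, , drop = FALSE]
}

#' Instrument strength from summary statistics
#'
#' For a single SNP with z = beta/se and sample size n, the variance explained
#' is r2 = z^2 / (z^2 + n - 2) and the single-SNP F statistic is z^2; the two
#' are linked by F = r2 (n - 2) / (1 - r2).
#'
#' @param x a `sumstats` data.frame (requires `beta`, `se`, `n`).
#' @return data.frame with `variant_id`, `r_squared`, `f_stat`.
#' @export
instrument_strength <- function(x) {
  if (any(is.na(x$n) | x$n < 3))
    stop("degenerate sample size: instrument strength needs n >= 3")
  z2 <- (x$beta / x$se)^2
  data.frame(variant_id = x$variant_id,
             r_squared = z2 / (z2 + x$n - 2),
             f_stat = z2,
             stringsAsFactors = FALSE)
}

#' LD correlation matrices
#'
#' Construct or read a matrix of pairwise genotype correlations used to weight
#' correlated instruments.
#'
#' @param snp character vector of variant IDs.
#' @param rho square numeric matrix of correlations in `[-1, 1]` with unit
#'   diagonal, rows/columns ordered as `snp`.
#' @return an object of class `ld_matrix` with fields `snp` and `rho`.
#' @export
ld_matrix <- function(snp, rho) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho) || nrow(rho) != length(snp))
    stop("LD matrix dimensions must match the variant list")
  if (max(abs(rho - t(rho))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (max(abs(rho)) > 1 + 1e-8) stop("correlations must lie in [-1, 1]")
  dimnames(rho) <- list(snp, snp)
  structure(list(snp = as.character(snp), rho = rho), class = "ld_matrix")
}

#' @rdname ld_matrix
#' @param path whitespace-delimited square matrix with a header row of
#'   variant IDs.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE))
  ld_matrix(colnames(m), unname(m))
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD matrix for", length(x$snp), "variants\n")
  invisible(x)
}
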