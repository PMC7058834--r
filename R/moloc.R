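#' Wakefield approximate Bayes factor
#'
#' For an estimated effect `beta` with variance `V = se^2` and a normal
#' effect prior with variance `W = prior_sd^2`, the Bayes factor in favour of
#' association is `sqrt(V/(V+W)) * exp(z^2 W / (2 (V+W)))` with `z = beta/se`.
#' Computed in log space.
#'
#' @param beta,se effect estimate and SE (vectors).
#' @param prior_sd prior SD of the true effect (default 0.15, a standard
#'   choice for quantitative traits in SD units).
#' @param log return the log Bayes factor.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15, log = FALSE) {
  stopifnot(all(se > 0), prior_sd > 0)
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  labf <- 0.5 * (base::log(V) - base::log(V + W)) + z2 * W / (2 * (V + W))
  if (log) labf else exp(labf)
}

#' Enumerate colocalization sharing configurations
#'
#' A configuration assigns a subset of the traits to disjoint sharing blocks,
#' each block harbouring one causal variant (distinct across blocks);
#' unassigned traits are unassociated.  For k traits this yields the sum over
#' subsets of the number of set partitions: 2, 5 and 15 configurations for 1,
#' 2 and 3 traits.  Labels use letters per trait, blocks separated by commas
#' (e.g. `"abc"`, `"ab,c"`, `"a"`, `"null"`).
#'
#' @param n_traits 1, 2 or 3.
#' @return list of configurations, each `list(label, blocks)` with `blocks` a
#'   list of integer vectors of trait indices.
#' @export
enumerate_configurations <- function(n_traits) {
  if (!n_traits %in% 1:3)
    stop("unsupported number of traits: ", n_traits)
  subsets <- function(x) {
    if (length(x) == 0) return(list(integer()))
    rest <- subsets(x[-1])
    c(rest, lapply(rest, function(s) c(x[1], s)))
  }
  partitions <- function(x) {
    if (length(x) == 0) return(list(list()))
    rest <- partitions(x[-1])
    out <- list()
    for (p in rest) {
      for (i in seq_along(p)) {
        q <- p
        q[[i]] <- c(x[1], q[[i]])
        out <- c(out, list(q))
      }
      out <- c(out, list(c(p, list(x[1]))))
    }
    out
  }
  lab <- function(blocks) {
    if (length(blocks) == 0) return("null")
    parts <- sort(vapply(blocks, function(b)
      paste(letters[sort(b)], collapse = ""), ""))
    paste(parts, collapse = ",")
  }
  out <- list()
  for (s in subsets(seq_len(n_traits)))
    for (p in partitions(s)) {
      p <- lapply(p, sort)
      out <- c(out, list(list(label = lab(p), blocks = p)))
    }
  out[order(vapply(out, `[[`, "", "label"))]
}

#' Per-variant multi-trait region data
#'
#' Holds, for every variant in a genomic window (at most 2 Mb), the per-trait
#' effect estimate and SE, the minor-allele frequency, and per-trait sample
#' sizes, for the ordered traits methylation, expression, lung function.
#'
#' @param window list with `chromosome`, `start`, `end` (1-based).
#' @param variants data.frame with `variant_id`, `position`, `maf`.
#' @param betas,ses numeric matrices, variants x traits.
#' @param n per-trait sample sizes (length = number of traits).
#' @param traits ordered trait labels.
#' @return object of class `region_dataset`.
#' @export
region_dataset <- function(window, variants, betas, ses, n,
                           traits = c("methylation", "expression",
                                      "lung_function")) {
  betas <- as.matrix(betas)
  ses <- as.matrix(ses)
  k <- length(traits)
  stopifnot(nrow(betas) == nrow(variants), ncol(betas) == k,
            all(dim(ses) == dim(betas)), length(n) == k)
  if (!is.null(window$start) && !is.null(window$end) &&
      window$end - window$start > 2e6)
    stop("region window exceeds 2 Mb")
  structure(list(window = window, variants = variants, betas = betas,
                 ses = ses, n = n, traits = traits),
            class = "region_dataset")
}

#' @export
print.region_dataset <- function(x, ...) {
  cat(sprintf("Region %s:%s-%s, %d variants, traits: %s\n",
              x$window$chromosome %||% "?",
              format(x$window$start %||% NA), format(x$window$end %||% NA),
              nrow(x$variants), paste(x$traits, collapse = ", ")))
  invisible(x)
}

# Exact log-scale sum over assignments of distinct causal variants to blocks.
# lfs: list of per-variant log score vectors, one per block.
log_distinct_sum <- function(lfs) {
  nb <- length(lfs)
  if (nb == 0) return(0)
  S <- function(...) logsumexp(Reduce(`+`, list(...)))
  if (nb == 1) return(S(lfs[[1]]))
  if (nb == 2) {
    return(signed_logsumexp(
      c(S(lfs[[1]]) + S(lfs[[2]]), S(lfs[[1]], lfs[[2]])), c(1, -1)))
  }
  f <- lfs[[1]]; g <- lfs[[2]]; h <- lfs[[3]]
  signed_logsumexp(
    c(S(f) + S(g) + S(h),
      S(f, g) + S(h), S(f, h) + S(g), S(g, h) + S(f),
      base::log(2) + S(f, g, h)),
    c(1, -1, -1, -1, 1))
}

#' Multi-trait colocalization posteriors
#'
#' For each of the 15 three-trait sharing configurations, the marginal
#' likelihood sums, over assignments of one causal variant per block (distinct
#' variants across blocks), the product of per-variant Wakefield Bayes factors
#' for the traits in each block, weighted by the per-variant prior for a block
#' of that size (`p1` one trait, `p2` two traits sharing, `p3` all three
#' sharing).  Posteriors are normalized over all configurations.  Variants are
#' first filtered to MAF >= 0.05 and complete statistics; fewer than 50
#' qualifying variants is an error (regions that sparse are not analyzed).
#'
#' @param region a [region_dataset()] with three traits.
#' @param priors per-variant configuration priors `c(p1, p2, p3)`.
#' @param prior_sd per-trait effect prior SDs (recycled to 3).
#' @return object of class `moloc_fit`: `posteriors` (named vector over the
#'   15 configuration labels), `ppa_three_way` (posterior of `"abc"`),
#'   `ppa_meth_fev1` (mass of configurations where methylation and lung
#'   function share a block), `n_variants`, `best_gene`.
#' @export
moloc_posteriors <- function(region, priors = c(1e-4, 1e-6, 1e-7),
                             prior_sd = c(0.15, 0.15, 0.15)) {
  stopifnot(inherits(region, "region_dataset"), length(region$traits) == 3)
  prior_sd <- rep(prior_sd, length.out = 3)
  keep <- region$variants$maf >= 0.05 &
    stats::complete.cases(region$betas) & stats::complete.cases(region$ses)
  if (sum(keep) < 50)
    stop("only ", sum(keep), " qualifying variants (need >= 50 with MAF >= 0.05)")
  betas <- region$betas[keep, , drop = FALSE]
  ses <- region$ses[keep, , drop = FALSE]
  lbf <- vapply(1:3, function(t)
    wakefield_abf(betas[, t], ses[, t], prior_sd[t], log = TRUE),
    numeric(sum(keep)))
  configs <- enumerate_configurations(3)
  scores <- vapply(configs, function(cfg) {
    if (length(cfg$blocks) == 0) return(0)
    lfs <- lapply(cfg$blocks, function(b) rowSums(lbf[, b, drop = FALSE]))
    sum(base::log(priors[lengths(cfg$blocks)])) + log_distinct_sum(lfs)
  }, 0)
  labels <- vapply(configs, `[[`, "", "label")
  post <- exp(scores - logsumexp(scores))
  names(post) <- labels
  shares_13 <- vapply(configs, function(cfg)
    any(vapply(cfg$blocks, function(b) all(c(1L, 3L) %in% b), TRUE)), TRUE)
  structure(list(posteriors = post,
                 ppa_three_way = unname(post[labels == "abc"]),
                 ppa_meth_fev1 = sum(post[shares_13]),
                 n_variants = sum(keep),
                 best_gene = NA_character_,
                 priors = priors, prior_sd = prior_sd,
                 traits = region$traits),
            class = "moloc_fit")
}

#' @export
print.moloc_fit <- function(x, ...) {
  cat("Multi-trait colocalization (", x$n_variants, " variants)\n", sep = "")
  if (!is.na(x$best_gene)) cat("  best gene:", x$best_gene, "\n")
  cat(sprintf("  PPA(all three share) = %s%%\n",
              format(100 * x$ppa_three_way, digits = 3)))
  cat(sprintf("  PPA(methylation & lung function share) = %s%%\n",
              format(100 * x$ppa_meth_fev1, digits = 3)))
  top <- sort(x$posteriors, decreasing = TRUE)[1:3]
  cat("  top configurations:",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Scan candidate genes and report the strongest colocalization
#'
#' Runs [moloc_posteriors()] once per candidate gene (each region carries the
#' methylation and lung-function statistics alongside that gene's expression;
#' in practice, all genes with transcription start within 1 Mb of the CpG) and
#' returns the result with the highest three-way PPA, annotated with the gene
#' label.  Regions failing the 50-variant filter are skipped; it is an error
#' if all are.
#'
#' @param gene_regions named list of [region_dataset()] objects, one per gene.
#' @param ... passed to [moloc_posteriors()].
#' @return the winning `moloc_fit`, with `best_gene` set and attribute
#'   `all_ppas` giving every tested gene's three-way PPA.
#' @export
best_gene_scan <- function(gene_regions, ...) {
  stopifnot(length(gene_regions) >= 1)
  nm <- names(gene_regions) %||% as.character(seq_along(gene_regions))
  fits <- lapply(gene_regions, function(r)
    tryCatch(moloc_posteriors(r, ...), error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    stop("no testable gene: all regions fail the variant filters")
  ppas <- vapply(fits[ok], `[[`, 0, "ppa_three_way")
  best <- which(ok)[which.max(ppas)]
  out <- fits[[best]]
  out$best_gene <- nm[best]
  attr(out, "all_ppas") <- stats::setNames(ppas, nm[ok])
  out
}

#' Write colocalization posteriors as TSV
#' @param fit a `moloc_fit`.
#' @param path output path.
#' @export
write_moloc <- function(fit, path) {
  df <- data.frame(configuration = names(fit$posteriors),
                   posterior = unname(fit$posteriors))
  df <- rbind(df,
              data.frame(configuration = c("PPA_three_way", "PPA_meth_fev1"),
                         posterior = c(fit$ppa_three_way, fit$ppa_meth_fev1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
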