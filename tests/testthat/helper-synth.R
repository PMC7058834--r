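# Shared fixtures built in code.

make_records <- function(ids, ea, oa, beta, se, eaf = NA_real_, n = NA_real_,
                         pvalue = NA_real_) {
  as_sumstats(data.frame(variant_id = ids, effect_allele = ea,
                         other_allele = oa, beta = beta, se = se,
                         eaf = eaf, n = n, pvalue = pvalue,
                         stringsAsFactors = FALSE))
}

toy_harmonized <- function(bx, sx, by, sy, ...) {
  harmonized_set(paste0("rs", seq_along(bx)), bx, sx, by, sy, ...)
}

# Independent configuration counter: sum over trait subsets of the Bell
# number of the subset (Bell via the standard recurrence), written without
# reference to the package's recursive enumerator.
count_configurations_oracle <- function(k) {
  bell <- c(1)  # Bell(0)
  for (m in seq_len(k)) {
    bell <- c(bell, sum(choose(m - 1, 0:(m - 1)) * bell))
  }
  sum(choose(k, 0:k) * bell[1:(k + 1)])
}

# Summary-level manifest: K CpG exposures, each with `n_ins` strong
# instruments, true causal effects `theta` (length K), shared outcome table.
make_manifest <- function(K, theta, n_ins = 1, seed = 1,
                          n1 = 846, n2 = 50000) {
  withr::local_seed(seed)
  exposures <- list()
  out_rows <- list()
  for (k in seq_len(K)) {
    ids <- sprintf("rs%d_%d", k, seq_len(n_ins))
    bx0 <- 0.4
    sx <- 0.03
    sy <- 0.0045
    bx <- stats::rnorm(n_ins, bx0, sx)
    by <- stats::rnorm(n_ins, theta[k] * bx0, sy)
    exposures[[sprintf("cpg%02d", k)]] <-
      make_records(ids, "A", "G", bx, sx, eaf = 0.3, n = n1)
    out_rows[[k]] <- data.frame(variant_id = ids, effect_allele = "A",
                                other_allele = "G", beta = by, se = sy,
                                eaf = 0.3, n = n2, stringsAsFactors = FALSE)
  }
  list(exposures = exposures,
       outcome = as_sumstats(do.call(rbind, out_rows)))
}
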