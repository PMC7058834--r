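#' Configuration for the synthetic two-sample study generator
#'
#' Defines the conditions the generator emulates: a small methylation sample
#' (ARIES-like, default 846 individuals) and a large, non-overlapping outcome
#' sample (biobank-like, default 50,000); one or two cis-mQTL instruments per
#' CpG with large per-SNP variance explained (default 10%-25%, the strong end
#' of the reported 2.9%-31.3% range, keeping weak-instrument bias an order
#' below the sampling error) against many polygenic smoking instruments with
#' small per-SNP variance explained (default 0.1%, chosen so their z-scores
#' at the simulated GWAS size match the genome-wide-significant range of real
#' smoking hits); and a configurable causal diagram among methylation (M),
#' smoking (S) and lung function (Y) with effects in SD units.
#'
#' @param seed base RNG seed; all emitted datasets are deterministic given
#'   the configuration.
#' @param n_sample1,n_sample2 individuals in the exposure and outcome samples
#'   (non-overlapping by construction).
#' @param n_instruments named vector: instruments per trait
#'   (`methylation`, `smoking`, optionally `lung_function` for a polygenic
#'   lung-function background usable as reverse-direction instruments).
#' @param n_null_snps extra SNPs with no effect on any trait.
#' @param maf_range sampling range for minor-allele frequencies (within
#'   `[0.01, 0.5]`); the default stops short of 0.5 so that strand-ambiguous
#'   (A/T, C/G) variants always remain resolvable by allele frequency during
#'   harmonization.
#' @param ld_rho,ld_block_size AR(1) dosage correlation within blocks of
#'   consecutive SNPs (`ld_block_size = 1` gives independent SNPs).
#' @param dag causal diagram: `"M_to_Y"`, `"M_to_S_to_Y"`, `"S_to_M_to_Y"`,
#'   `"pleiotropy"`, `"null"`, `"confounded"`.
#' @param theta1 exposure-to-mediator effect (mediation diagrams).
#' @param theta2 mediator-to-outcome effect.
#' @param theta3 direct exposure-to-outcome effect.
#' @param pleiotropy_fraction,pleiotropy_mean fraction of methylation
#'   instruments given a direct path to Y, and the mean of their direct
#'   effects (directional pleiotropy).
#' @param confounder_sd SD contribution of a shared confounder to each trait
#'   (0 disables; the `"confounded"` diagram defaults it to 0.5).
#' @param r2_methylation per-SNP variance-explained range for mQTLs.
#' @param r2_smoking per-SNP variance explained for smoking instruments.
#' @param r2_lung_function per-SNP variance explained for lung-function
#'   instruments (when any are configured).
#' @param region_n_variants,region_n_sample,region_r2,region_ld_rho,region_maf_range
#'   settings for colocalization region simulation ([simulate_region()]).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_sample1 = 846, n_sample2 = 50000,
                       n_instruments = c(methylation = 2, smoking = 20),
                       n_null_snps = 0, maf_range = c(0.1, 0.35),
                       ld_rho = 0, ld_block_size = 1,
                       dag = c("M_to_Y", "M_to_S_to_Y", "S_to_M_to_Y",
                               "pleiotropy", "null", "confounded"),
                       theta1 = 0.03, theta2 = 0.4, theta3 = 0.1,
                       pleiotropy_fraction = 0.3, pleiotropy_mean = 0.1,
                       confounder_sd = 0,
                       r2_methylation = c(0.10, 0.25), r2_smoking = 1e-3,
                       r2_lung_function = 1e-3,
                       region_n_variants = 200, region_n_sample = 2000,
                       region_r2 = 0.03, region_ld_rho = 0.5,
                       region_maf_range = c(0.05, 0.5)) {
  dag <- match.arg(dag)
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5)
    stop("maf_range must lie within [0.01, 0.5]")
  if (dag == "confounded" && confounder_sd == 0) confounder_sd <- 0.5
  structure(as.list(environment()), class = "sim_config")
}

ar1_chol <- function(p, rho) {
  if (p == 1) return(matrix(1))
  chol(rho^abs(outer(seq_len(p), seq_len(p), `-`)))
}

draw_dosages <- function(n, maf, rho, block_size) {
  p <- length(maf)
  if (rho == 0 || block_size <= 1) {
    return(matrix(stats::rbinom(n * p, 2, rep(maf, each = n)), nrow = n))
  }
  G <- matrix(0L, n, p)
  starts <- seq(1, p, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1, p)
    R <- ar1_chol(length(idx), rho)
    U <- stats::pnorm(matrix(stats::rnorm(n * length(idx)), n) %*% R)
    G[, idx] <- stats::qbinom(U, 2, rep(maf[idx], each = n))
  }
  G
}

#' Simulate genotype dosages for two non-overlapping samples
#'
#' Draws biallelic dosages in `{0, 1, 2}` from per-SNP binomial(2, maf)
#' margins, with an AR(1) latent-Gaussian correlation inside LD blocks.  The
#' first `n_sample1` rows form sample 1 and the rest sample 2.  Every SNP is
#' assigned effect/other alleles so that downstream summary statistics carry
#' consistent allele labels across samples.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return object of class `sim_genotypes`: dosage matrix `G`, `maf`,
#'   `variants` (IDs, coordinates, alleles), `roles` (instrument index sets
#'   per trait plus null SNPs), `sample` (1/2 per row), and `ld` (empirical
#'   correlation matrix as [ld_matrix()], computed when there are at most 500
#'   SNPs).
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  with_seed(seed, {
    n <- config$n_sample1 + config$n_sample2
    n_ins <- config$n_instruments
    p <- sum(n_ins) + config$n_null_snps
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    G <- draw_dosages(n, maf, config$ld_rho, config$ld_block_size)
    ea <- sample(ALLELES, p, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(ALLELES, a), 1), "")
    roles <- list()
    at <- 0
    for (tr in names(n_ins)) {
      roles[[tr]] <- at + seq_len(n_ins[[tr]])
      at <- at + n_ins[[tr]]
    }
    roles$null <- if (config$n_null_snps > 0) at + seq_len(config$n_null_snps)
    else integer()
    variants <- data.frame(
      variant_id = paste0("rs", seq_len(p)),
      chromosome = "1", position = 1000000L + seq_len(p) * 5000L,
      effect_allele = ea, other_allele = unname(oa),
      stringsAsFactors = FALSE)
    ld <- if (p <= 500)
      ld_matrix(variants$variant_id, stats::cor(G))
    else NULL
    structure(list(G = G, maf = maf, variants = variants, roles = roles,
                   sample = rep(1:2, c(config$n_sample1, config$n_sample2)),
                   ld = ld),
              class = "sim_genotypes")
  })
}

# Centered genetic component with per-SNP effects scaled so SNP j explains
# r2[j] of a unit-variance trait.
genetic_component <- function(geno, idx, r2) {
  if (length(idx) == 0) return(list(value = 0, gamma = numeric()))
  sd_g <- sqrt(2 * geno$maf[idx] * (1 - geno$maf[idx]))
  gamma <- sqrt(r2) / sd_g
  Gc <- sweep(geno$G[, idx, drop = FALSE], 2, 2 * geno$maf[idx])
  list(value = drop(Gc %*% gamma),
       gamma = stats::setNames(gamma, geno$variants$variant_id[idx]))
}

#' Simulate standardized traits under a causal diagram
#'
#' Builds methylation (M), smoking (S) and lung function (Y) for every
#' individual according to `config$dag`, with instrument effects scaled to
#' their target per-SNP variance explained and residual noise budgeted so
#' every trait has unit population variance (traits are mean-centered; effect
#' sizes are therefore in SD units).  The `pleiotropy` diagram adds direct
#' SNP-to-Y paths for a fraction of the methylation instruments.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param config the [sim_config()] used to generate them.
#' @param seed RNG seed (default `config$seed + 1`).
#' @return list with `phenotypes` (data.frame `methylation`, `smoking`,
#'   `lung_function`) and `truth` (a `truth_record`: the diagram, true
#'   theta1/theta2/theta3, total effect `theta3 + theta1*theta2`, true
#'   proportion mediated, and per-SNP instrument effects).
#' @export
simulate_traits <- function(genotypes, config, seed = config$seed + 1) {
  with_seed(seed, {
    n <- nrow(genotypes$G)
    cu <- config$confounder_sd
    u <- stats::rnorm(n)
    r2m <- config$r2_methylation
    r2s <- config$r2_smoking
    idxM <- genotypes$roles$methylation %||% integer()
    idxS <- genotypes$roles$smoking %||% integer()
    idxY <- genotypes$roles$lung_function %||% integer()
    r2_M <- if (length(r2m) == 2) stats::runif(length(idxM), r2m[1], r2m[2])
    else rep(r2m, length(idxM))
    r2_S <- if (length(r2s) == 2) stats::runif(length(idxS), r2s[1], r2s[2])
    else rep(r2s, length(idxS))
    gM <- genetic_component(genotypes, idxM, r2_M)
    gS <- genetic_component(genotypes, idxS, r2_S)
    gY <- genetic_component(genotypes, idxY,
                            rep(config$r2_lung_function, length(idxY)))

    make_trait <- function(sys) {
      v <- if (length(sys) == 1 && sys[1] == 0) 0 else stats::var(sys)
      y <- sys + stats::rnorm(n, 0, sqrt(max(1 - v, 0.02)))
      y - mean(y)
    }

    th1 <- config$theta1; th2 <- config$theta2; th3 <- config$theta3
    alpha <- NULL
    if (config$dag == "M_to_Y") {
      M <- make_trait(gM$value + cu * u)
      S <- make_trait(gS$value + cu * u)
      Y <- make_trait(th3 * M + gY$value + cu * u)
      th1 <- 0; th2 <- 0
    } else if (config$dag == "M_to_S_to_Y") {
      M <- make_trait(gM$value + cu * u)
      S <- make_trait(th1 * M + gS$value + cu * u)
      Y <- make_trait(th2 * S + th3 * M + gY$value + cu * u)
    } else if (config$dag == "S_to_M_to_Y") {
      S <- make_trait(gS$value + cu * u)
      M <- make_trait(th1 * S + gM$value + cu * u)
      Y <- make_trait(th2 * M + th3 * S + gY$value + cu * u)
    } else if (config$dag == "pleiotropy") {
      M <- make_trait(gM$value + cu * u)
      S <- make_trait(gS$value + cu * u)
      n_ple <- ceiling(config$pleiotropy_fraction * length(idxM))
      sel <- idxM[seq_len(n_ple)]
      alpha <- stats::rnorm(n_ple, config$pleiotropy_mean,
                            config$pleiotropy_mean / 2)
      gP <- genetic_component(genotypes, sel, alpha^2)
      gP$gamma <- sign(alpha) * gP$gamma
      gP$value <- drop(
        sweep(genotypes$G[, sel, drop = FALSE], 2, 2 * genotypes$maf[sel])
        %*% gP$gamma)
      Y <- make_trait(th3 * M + gP$value + gY$value + cu * u)
      th1 <- 0; th2 <- 0
    } else if (config$dag == "null") {
      M <- make_trait(gM$value)
      S <- make_trait(gS$value)
      Y <- make_trait(gY$value)
      th1 <- 0; th2 <- 0; th3 <- 0
    } else { # confounded
      M <- make_trait(gM$value + cu * u)
      S <- make_trait(gS$value + cu * u)
      Y <- make_trait(gY$value + cu * u)
      th1 <- 0; th2 <- 0; th3 <- 0
    }
    total <- th3 + th1 * th2
    truth <- structure(list(
      dag = config$dag, theta1 = th1, theta2 = th2, theta3 = th3,
      total = total,
      proportion_mediated = if (total != 0) th1 * th2 / total else NA_real_,
      gamma = list(methylation = gM$gamma, smoking = gS$gamma,
                   lung_function = gY$gamma),
      pleiotropy = alpha,
      causal_variants = NULL), class = "truth_record")
    list(phenotypes = data.frame(methylation = M, smoking = S,
                                 lung_function = Y),
         truth = truth)
  })
}

# Fast per-SNP simple linear regressions of y on every column of G.
snp_regressions <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  sigma2 <- pmax(syy - beta * sxy, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  list(beta = beta, se = se,
       pvalue = pmax(2 * stats::pt(-abs(beta / se), n - 2), 1e-300), n = n)
}

#' Per-SNP association summary statistics within one sample
#'
#' Runs a simple linear regression of each trait on each SNP within the
#' chosen sample only, emulating the per-SNP GWAS/mQTL regressions that
#' two-sample MR consumes.  Records carry consistent allele labels and the
#' within-sample effect-allele frequency.
#'
#' @param phenotypes data.frame of traits (rows = individuals).
#' @param genotypes a [simulate_genotypes()] result.
#' @param sample_id 1 or 2.
#' @return named list of `sumstats` data.frames, one per trait.
#' @export
summarize_associations <- function(phenotypes, genotypes, sample_id) {
  stopifnot(sample_id %in% c(1, 2))
  idx <- genotypes$sample == sample_id
  G <- genotypes$G[idx, , drop = FALSE]
  mono <- apply(G, 2, function(g) stats::var(g) == 0)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped from sample ", sample_id)
    G <- G[, !mono, drop = FALSE]
  }
  vi <- genotypes$variants[!mono, , drop = FALSE]
  rownames(vi) <- NULL
  eaf <- colMeans(G) / 2
  trait_types <- c(methylation = "methylation", smoking = "smoking",
                   lung_function = "lung_function",
                   expression = "expression")
  out <- lapply(names(phenotypes), function(tr) {
    r <- snp_regressions(G, phenotypes[[tr]][idx])
    as_sumstats(data.frame(
      variant_id = vi$variant_id, chromosome = vi$chromosome,
      position = vi$position, effect_allele = vi$effect_allele,
      other_allele = vi$other_allele, eaf = unname(eaf),
      beta = unname(r$beta), se = unname(r$se),
      pvalue = unname(r$pvalue), n = r$n,
      trait_id = tr,
      trait_type = unname(trait_types[tr]) %||% NA_character_,
      stringsAsFactors = FALSE))
  })
  stats::setNames(out, names(phenotypes))
}

#' One-call synthetic two-sample dataset
#'
#' Genotypes, traits and per-sample summary statistics in one deterministic
#' call: sample 1 provides the exposure-side associations (small methylation
#' study) and sample 2 the outcome side (large biobank).
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `phenotypes`, `truth`, `sample1`,
#'   `sample2` (each of the last two a named list of `sumstats`).
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genotypes(config)
  tr <- simulate_traits(geno, config)
  list(genotypes = geno, phenotypes = tr$phenotypes, truth = tr$truth,
       sample1 = summarize_associations(tr$phenotypes, geno, 1),
       sample2 = summarize_associations(tr$phenotypes, geno, 2))
}

#' Write the ground-truth record as a YAML sidecar
#' @param truth a `truth_record`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(lapply(unclass(truth), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}

#' Simulate a colocalization region under a sharing scenario
#'
#' Generates `region_n_variants` variants with AR(1) LD, places one causal
#' variant per sharing block of the scenario label (distinct variants across
#' blocks; traits absent from the label are unassociated), simulates the
#' three traits in independent samples of `region_n_sample` individuals each,
#' and returns per-variant summary statistics with the causal assignment
#' recorded.
#'
#' @param config a [sim_config()].
#' @param scenario one of the 15 configuration labels of
#'   [enumerate_configurations()] for traits a = methylation, b = expression,
#'   c = lung function (e.g. `"abc"`, `"ac,b"`, `"null"`).
#' @param seed RNG seed (default `config$seed`).
#' @return list with `region` (a [region_dataset()]) and `truth`
#'   (scenario, per-trait causal variant indices, per-variant r2).
#' @export
simulate_region <- function(config, scenario, seed = config$seed) {
  configs <- enumerate_configurations(3)
  labels <- vapply(configs, `[[`, "", "label")
  if (!scenario %in% labels)
    stop("unknown scenario label: ", scenario)
  blocks <- configs[[match(scenario, labels)]]$blocks
  with_seed(seed, {
    Q <- config$region_n_variants
    n <- config$region_n_sample
    maf <- stats::runif(Q, config$region_maf_range[1],
                        config$region_maf_range[2])
    causal_idx <- if (length(blocks) > 0) sample(Q, length(blocks))
    else integer()
    causal <- rep(NA_integer_, 3)
    for (b in seq_along(blocks)) causal[blocks[[b]]] <- causal_idx[b]
    betas <- ses <- matrix(NA_real_, Q, 3)
    for (t in 1:3) {
      G <- draw_dosages(n, maf, config$region_ld_rho, Q)
      if (!is.na(causal[t])) {
        g <- G[, causal[t]]
        y <- g * sqrt(config$region_r2) / stats::sd(g) +
          stats::rnorm(n, 0, sqrt(1 - config$region_r2))
      } else {
        y <- stats::rnorm(n)
      }
      r <- snp_regressions(G, y)
      betas[, t] <- r$beta
      ses[, t] <- r$se
    }
    start <- 1000000L
    region <- region_dataset(
      window = list(chromosome = "1", start = start,
                    end = start + (Q - 1L) * 2000L),
      variants = data.frame(variant_id = paste0("rs", seq_len(Q)),
                            position = start + (seq_len(Q) - 1L) * 2000L,
                            maf = pmin(maf, 1 - maf)),
      betas = betas, ses = ses, n = rep(n, 3))
    truth <- structure(list(
      dag = NA_character_, scenario = scenario,
      causal_variants = stats::setNames(causal, region$traits),
      region_r2 = config$region_r2), class = "truth_record")
    list(region = region, truth = truth)
  })
}
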