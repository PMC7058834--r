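test_that("Wakefield ABFs follow the closed form", {
  # null z shrinks below 1; vanishing prior gives 1
  expect_equal(wakefield_abf(0, 0.1, 0.15), sqrt(0.01 / 0.0325))
  expect_lt(wakefield_abf(0, 0.1, 0.15), 1)
  expect_equal(wakefield_abf(0.5, 0.1, 1e-8), 1, tolerance = 1e-6)
  # independent evaluation of the closed form at z = 5, W = 0.15^2
  V <- 0.01; W <- 0.0225; z <- 5
  manual <- sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W)))
  expect_equal(wakefield_abf(0.5, 0.1, 0.15), manual, tolerance = 1e-12)
  expect_equal(manual, 3.18e3, tolerance = 0.01)
  expect_equal(wakefield_abf(0.5, 0.1, 0.15, log = TRUE), log(manual),
               tolerance = 1e-12)
  # log-space evaluation survives |z| > 30
  expect_true(is.finite(wakefield_abf(5, 0.1, 0.15, log = TRUE)))
})

test_that("configuration enumeration matches the partition-count oracle", {
  expect_length(enumerate_configurations(1), count_configurations_oracle(1))
  expect_length(enumerate_configurations(2), count_configurations_oracle(2))
  cfg <- enumerate_configurations(3)
  expect_length(cfg, 15)
  expect_equal(count_configurations_oracle(3), 15)
  labels <- vapply(cfg, `[[`, "", "label")
  expect_equal(anyDuplicated(labels), 0L)
  expect_true(all(c("null", "abc", "ab,c", "a,b,c", "ac,b") %in% labels))
  expect_setequal(vapply(enumerate_configurations(2), `[[`, "", "label"),
                  c("null", "a", "b", "ab", "a,b"))
  expect_error(enumerate_configurations(4), "unsupported")
})

make_region <- function(Q, betas, ses, maf = rep(0.25, Q)) {
  region_dataset(window = list(chromosome = "1", start = 1e6,
                               end = 1e6 + (Q - 1) * 1000),
                 variants = data.frame(variant_id = paste0("rs", 1:Q),
                                       position = 1e6 + (1:Q - 1) * 1000,
                                       maf = maf),
                 betas = betas, ses = ses, n = rep(2000, 3))
}

test_that("posteriors match a brute-force distinct-assignment enumeration", {
  set.seed(59)
  Q <- 60
  betas <- matrix(rnorm(Q * 3, 0, 0.03), Q, 3)
  ses <- matrix(runif(Q * 3, 0.015, 0.03), Q, 3)
  region <- make_region(Q, betas, ses)
  fit <- moloc_posteriors(region)
  # oracle: per-configuration scores by explicit sums over distinct tuples
  p1 <- 1e-4; p2 <- 1e-6; p3 <- 1e-7
  bf <- sapply(1:3, function(t) wakefield_abf(betas[, t], ses[, t], 0.15))
  pri <- c(p1, p2, p3)
  score <- function(blocks) {
    if (length(blocks) == 0) return(1)
    fs <- lapply(blocks, function(b) apply(bf[, b, drop = FALSE], 1, prod))
    prior <- prod(pri[lengths(blocks)])
    if (length(blocks) == 1) return(prior * sum(fs[[1]]))
    if (length(blocks) == 2) {
      idx <- expand.grid(i = 1:Q, j = 1:Q)
      idx <- idx[idx$i != idx$j, ]
      return(prior * sum(fs[[1]][idx$i] * fs[[2]][idx$j]))
    }
    idx <- expand.grid(i = 1:Q, j = 1:Q, k = 1:Q)
    idx <- idx[idx$i != idx$j & idx$i != idx$k & idx$j != idx$k, ]
    prior * sum(fs[[1]][idx$i] * fs[[2]][idx$j] * fs[[3]][idx$k])
  }
  cfg <- enumerate_configurations(3)
  scores <- vapply(cfg, function(co) score(co$blocks), 0)
  oracle <- scores / sum(scores)
  names(oracle) <- vapply(cfg, `[[`, "", "label")
  expect_equal(fit$posteriors, oracle[names(fit$posteriors)],
               tolerance = 1e-9)
  expect_equal(sum(fit$posteriors), 1, tolerance = 1e-9)
})

test_that("signal-free regions put the null configuration on top", {
  Q <- 80
  region <- make_region(Q, matrix(0, Q, 3),
                        matrix(runif(Q * 3, 0.01, 0.03), Q, 3))
  fit <- moloc_posteriors(region)
  expect_equal(names(which.max(fit$posteriors)), "null")
  expect_equal(sum(fit$posteriors), 1, tolerance = 1e-9)
})

test_that("posteriors are invariant to variant order", {
  set.seed(61)
  Q <- 60
  betas <- matrix(rnorm(Q * 3, 0, 0.05), Q, 3)
  ses <- matrix(runif(Q * 3, 0.015, 0.03), Q, 3)
  r1 <- make_region(Q, betas, ses)
  perm <- sample(Q)
  r2 <- make_region(Q, betas[perm, ], ses[perm, ])
  expect_equal(moloc_posteriors(r2)$posteriors,
               moloc_posteriors(r1)$posteriors, tolerance = 1e-9)
})

test_that("shared and distinct causal variants are resolved as designed", {
  cfg <- sim_config(seed = 101)
  shared <- simulate_region(cfg, "abc")
  expect_equal(length(unique(shared$truth$causal_variants)), 1L)
  fit <- moloc_posteriors(shared$region)
  expect_gte(fit$ppa_three_way, 0.8)
  # methylation and lung function share; expression has its own variant
  part <- simulate_region(cfg, "ac,b", seed = 102)
  cv <- part$truth$causal_variants
  expect_equal(cv[["methylation"]], cv[["lung_function"]])
  expect_false(cv[["expression"]] == cv[["methylation"]])
  fit <- moloc_posteriors(part$region)
  expect_equal(names(which.max(fit$posteriors)), "ac,b")
  expect_lt(fit$ppa_three_way, 0.5)
  expect_gt(fit$ppa_meth_fev1, 0.8)
  expect_error(simulate_region(cfg, "xyz"), "unknown scenario")
})

test_that("dropping a null expression trait preserves the meth-FEV1 PPA", {
  # two-trait (5-configuration) posterior computed independently in the test
  two_trait_ppa <- function(region, p1 = 1e-4, p2 = 1e-6) {
    keep <- region$variants$maf >= 0.05
    bfa <- wakefield_abf(region$betas[keep, 1], region$ses[keep, 1], 0.15)
    bfc <- wakefield_abf(region$betas[keep, 3], region$ses[keep, 3], 0.15)
    Sa <- sum(bfa); Sc <- sum(bfc); Sac <- sum(bfa * bfc)
    scores <- c(null = 1, a = p1 * Sa, c = p1 * Sc, ac = p2 * Sac,
                `a,c` = p1^2 * (Sa * Sc - Sac))
    unname(scores["ac"] / sum(scores))
  }
  hits <- 0
  for (s in 1:5) {
    r <- simulate_region(sim_config(seed = 200 + s), "ac")$region
    ppa3 <- moloc_posteriors(r)$ppa_meth_fev1
    ppa2 <- two_trait_ppa(r)
    hits <- hits + (abs(ppa3 - ppa2) <= 0.05)
  }
  expect_gte(hits, 4)
})

test_that("region filters and the gene scan behave per the decision rules", {
  Q <- 60
  betas <- matrix(rnorm(Q * 3, 0, 0.02), Q, 3)
  ses <- matrix(0.02, Q, 3)
  sparse <- make_region(Q, betas, ses, maf = rep(0.01, Q))
  expect_error(moloc_posteriors(sparse), "qualifying variants")
  expect_error(region_dataset(list(chromosome = "1", start = 1, end = 3e6),
                              data.frame(variant_id = "rs1", position = 1,
                                         maf = 0.2),
                              matrix(0, 1, 3), matrix(1, 1, 3), rep(100, 3)),
               "2 Mb")

  cfg <- sim_config(seed = 301)
  colocalizing <- simulate_region(cfg, "abc")$region
  null_gene <- simulate_region(cfg, "ac", seed = 302)$region
  best <- best_gene_scan(list(GENE1 = null_gene, GENE2 = colocalizing))
  expect_equal(best$best_gene, "GENE2")
  expect_gte(best$ppa_three_way, 0.8)
  single <- best_gene_scan(list(ONLY = colocalizing))
  expect_equal(single$best_gene, "ONLY")
  expect_error(best_gene_scan(list(A = sparse, B = sparse)),
               "no testable gene")
})

test_that("moloc results serialize the full posterior vector", {
  r <- simulate_region(sim_config(seed = 404), "abc")
  fit <- moloc_posteriors(r$region)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_moloc(fit, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 17)  # 15 configurations + 2 summary PPAs
  expect_equal(sum(tab$posterior[1:15]), 1, tolerance = 1e-9)
})
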