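test_that("harmonize aligns, flips and excludes per the allele rules", {
  exposure <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                           c("A", "A", "A", "A", "A"),
                           c("G", "G", "T", "G", "G"),
                           beta = c(0.5, 0.5, 0.5, 0.5, 0.5), se = 0.1,
                           eaf = c(0.3, 0.3, 0.5, 0.3, 0.3), n = 846)
  outcome <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                          c("A", "G", "A", "C", "A"),
                          c("G", "A", "T", "T", "C"),
                          beta = c(0.1, 0.1, 0.1, 0.1, 0.1), se = 0.02,
                          eaf = c(0.3, 0.7, 0.5, 0.7, 0.3), n = 50000)
  h <- harmonize(exposure, outcome)
  # rs1 aligned as-is; rs2 swapped alleles flip the sign and the eaf;
  # rs4 strand-complement of a swap also flips
  expect_equal(h$snp, c("rs1", "rs2", "rs4"))
  expect_equal(h$beta_outcome, c(0.1, -0.1, -0.1))
  expect_equal(h$eaf_outcome, c(0.3, 0.3, 0.3))
  expect_equal(h$beta_exposure, rep(0.5, 3))
  # rs3 palindromic at eaf 0.5; rs5 irreconcilable alleles
  expect_setequal(h$exclusions$variant_id, c("rs3", "rs5"))
  expect_equal(h$exclusions$reason[h$exclusions$variant_id == "rs3"],
               "palindromic, ambiguous eaf")
  expect_equal(h$exclusions$reason[h$exclusions$variant_id == "rs5"],
               "allele mismatch")
})

test_that("palindromic SNPs survive only with informative, concordant eafs", {
  pal <- function(eaf_exp, eaf_out, out_ea = "A", out_oa = "T") {
    harmonize(make_records("rs1", "A", "T", 0.5, 0.1, eaf = eaf_exp),
              make_records("rs1", out_ea, out_oa, 0.1, 0.02, eaf = eaf_out))
  }
  h <- pal(0.1, 0.12)
  expect_equal(h$beta_outcome, 0.1)
  # textual swap plus concordant frequency: sign flips
  h <- pal(0.1, 0.9, out_ea = "T", out_oa = "A")
  expect_equal(h$beta_outcome, -0.1)
  expect_equal(h$eaf_outcome, 0.1)
  expect_error(pal(0.5, 0.5), "no SNPs survive")
  expect_error(pal(0.45, 0.45), "no SNPs survive")   # inside the 0.42 band
  expect_error(pal(0.1, 0.9), "no SNPs survive")     # discordant sides
  expect_error(pal(NA, 0.1), "no SNPs survive")      # missing eaf
  # a wider band rescues a clear 0.45 only if the limit allows it
  h <- harmonize(make_records("rs1", "A", "T", 0.5, 0.1, eaf = 0.3),
                 make_records("rs1", "A", "T", 0.1, 0.02, eaf = 0.32),
                 palindrome_eaf_limit = 0.35)
  expect_equal(nsnp(h), 1)
})

test_that("harmonize requires overlap and nonempty inputs", {
  a <- make_records("rs1", "A", "G", 0.5, 0.1)
  b <- make_records("rs2", "A", "G", 0.1, 0.02)
  expect_error(harmonize(a, b), "no overlapping")
  expect_error(harmonize(a[0, ], b), "nonempty")
})

test_that("harmonize is idempotent and invariant to outcome allele flips", {
  set.seed(77)
  L <- 40
  ea <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  oa <- vapply(seq_len(L), function(i) {
    if (i %% 5 == 0) chartr("ACGT", "TGCA", ea[i])  # palindromic every 5th
    else sample(setdiff(c("A", "C", "G", "T"),
                        c(ea[i], chartr("ACGT", "TGCA", ea[i]))), 1)
  }, "")
  eaf <- runif(L, 0.05, 0.35)
  exposure <- make_records(paste0("rs", 1:L), ea, oa, rnorm(L, 0, 0.3),
                           runif(L, 0.05, 0.2), eaf = eaf, n = 846)
  swap <- runif(L) < 0.5
  outcome <- make_records(paste0("rs", 1:L),
                          ifelse(swap, oa, ea), ifelse(swap, ea, oa),
                          beta = ifelse(swap, -1, 1) * rnorm(L, 0, 0.05),
                          se = runif(L, 0.01, 0.05),
                          eaf = ifelse(swap, 1 - eaf, eaf) +
                            rnorm(L, 0, 0.005),
                          n = 50000)
  h1 <- harmonize(exposure, outcome)

  # idempotence: feeding the harmonized output back changes nothing
  df <- as.data.frame(h1)
  exp2 <- make_records(df$variant_id, df$effect_allele, df$other_allele,
                       df$beta_exposure, df$se_exposure,
                       eaf = df$eaf_exposure, n = 846)
  out2 <- make_records(df$variant_id, df$effect_allele, df$other_allele,
                       df$beta_outcome, df$se_outcome,
                       eaf = df$eaf_outcome, n = 50000)
  h2 <- harmonize(exp2, out2)
  expect_equal(h2$snp, h1$snp)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)

  # relabelling outcome alleles (swap + sign flip + eaf complement) is a
  # no-op after harmonization
  flipped <- outcome
  flipped$effect_allele <- outcome$other_allele
  flipped$other_allele <- outcome$effect_allele
  flipped$beta <- -outcome$beta
  flipped$eaf <- 1 - outcome$eaf
  h3 <- harmonize(exposure, as_sumstats(flipped))
  expect_equal(h3$snp, h1$snp)
  expect_equal(h3$beta_outcome, h1$beta_outcome)
  expect_equal(h3$eaf_outcome, h1$eaf_outcome)
  expect_equal(h3$exclusions, h1$exclusions)
})

test_that("harmonized sets serialize with their exclusion report", {
  h <- harmonize(make_records(c("rs1", "rs2"), "A", c("G", "T"),
                              c(0.5, 0.4), 0.1, eaf = c(0.3, 0.5)),
                 make_records(c("rs1", "rs2"), "A", c("G", "T"),
                              c(0.1, 0.1), 0.02, eaf = c(0.3, 0.5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  excl <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path, excl)
  back <- read.delim(path)
  expect_equal(back$variant_id, "rs1")
  expect_equal(read.delim(excl)$reason, "palindromic, ambiguous eaf")
})
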