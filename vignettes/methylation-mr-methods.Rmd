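---
title: "Methods: two-sample MR, mediation and multi-trait colocalization for DNA methylation and lung function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation and multi-trait colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmr)
```

# The scientific problem

Smoking alters DNA methylation at thousands of CpG sites, and smoking
damages lung function. Whether methylation at smoking-associated CpGs
*causes* variation in lung function — or merely marks smoke exposure — is
the kind of question Mendelian randomization (MR) can address: genetic
variants associated with methylation (mQTLs) are assigned at conception,
so using them as instrumental variables breaks the confounding that vitiates
observational methylation–phenotype associations. `methylmr` implements the
complete summary-statistics workflow: two-sample MR with several estimators,
directionality testing, two mediation decompositions, pleiotropy
diagnostics, and three-trait Bayesian colocalization — together with a
synthetic-data generator that knows the truth, so every component's
frequentist behaviour is measurable.

# Models and estimators

## Two-sample MR

For SNP $j$, let $\hat\beta_{Pj}$ (SE $\sigma_{Pj}$) be its effect on the
exposure (SD of methylation per effect-allele copy, from the small
methylation study) and $\hat\beta_{Dj}$ (SE $\sigma_{Dj}$) its effect on the
outcome (SD of FEV1 per copy, from a large GWAS in a non-overlapping
sample). The per-SNP causal estimate is the Wald ratio
$\hat\theta_j = \hat\beta_{Dj}/\hat\beta_{Pj}$, with delta-method SE

- first order: $\sigma_{Dj}/|\hat\beta_{Pj}|$,
- second order:
  $\sqrt{\sigma_{Dj}^2/\hat\beta_{Pj}^2 +
  \hat\beta_{Dj}^2\sigma_{Pj}^2/\hat\beta_{Pj}^4}$.

First order is the package default for data analysis (it matches weighting
ratio estimates by the inverse variance of their outcome associations, the
convention of large-outcome-GWAS practice). The second order matters
whenever the exposure sample is much smaller than the outcome sample: at
$n_1 = 846$ versus $n_2 = 5\times10^4$ the exposure-SE term *dominates* the
ratio variance, and first-order intervals cover the truth far below nominal
(we measured ~47% at the default study conditions). The evaluation studies
therefore use `se_order = "second"`.

Multiple conditionally independent mQTLs are pooled by fixed-effects IVW:
$\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, $w_j = 1/\mathrm{se}_j^2$,
$\mathrm{se} = (\sum w_j)^{-1/2}$. A single instrument degrades gracefully
to the Wald ratio (and is labelled as such, the situation of 86% of real
CpGs). The meta-analysis form is the default; the regression form through
the origin is available via `ivw_correlated()` with an identity LD matrix
(the two coincide under first-order weights).

## Pleiotropy-robust estimators and diagnostics

*MR-Egger* regresses outcome effects on exposure effects with an
unconstrained intercept (weights $1/\sigma_{Dj}^2$), after re-orienting
SNPs so all exposure effects are non-negative — without that re-orientation
the intercept is not identified. The intercept estimates the average
directional pleiotropy; the slope is a pleiotropy-adjusted causal estimate
valid under the InSIDE assumption. Coefficient SEs use multiplicative
random-effects scaling with the residual SD floored at 1 (the field's
standard convention; a floor below 1 would claim better-than-chi-square
homogeneity).

The *weighted median* sorts ratio estimates, forms midpoint cumulative sums
of normalized weights $S_j = \sum_{k\le j} w_k - w_j/2$, and linearly
interpolates the ratio at $S = 1/2$; it is consistent when at least half
the weight comes from valid instruments. Its SE comes from a parametric
bootstrap (default `n_boot = 1000`; a seed is required for reproducibility,
and the caller's RNG stream is never disturbed).

For instruments in LD ($\rho^2 < 0.8$), `ivw_correlated()` runs generalized
least squares through the origin with
$\Omega_{ij} = \sigma_{Di}\sigma_{Dj}\rho_{ij}$. Pairs at $\rho^2 \ge 0.8$
are pruned greedily, worst pair first, dropping the member with the larger
exposure p-value; a surviving $|\rho| = 1$ pair is reported as a singular
covariance naming the pair.

*Cochran's Q* over per-SNP ratios uses first-order weights
$\hat\beta_{Pj}^2/\sigma_{Dj}^2$ or modified second-order weights that also
propagate the exposure SE; excess Q against $\chi^2_{L-1}$ flags
heterogeneity. The modified weights are the calibrated choice whenever
exposure effects carry noise — first-order Q over-rejects there (we measured
~10% size at $z_x \approx 5$–$10$), which is exactly why the modified form
exists.

The *MR-PRESSO global test* computes the observed residual sum of squares
under leave-one-out IVW slopes and compares it with parametric resamples
(outcome effects drawn about the leave-one-out fitted values, exposure
effects about their observed values), with the $+1$-corrected empirical
p-value, floor $1/(n_{\mathrm{sim}}+1)$. Because the resampling scheme
conditions on the *observed* exposure effects as truth, its size is exact
only as exposure noise vanishes; at realistic mQTL noise
($z_x \approx 10$–$25$) it drifts mildly conservative (measured size
0.033–0.041 at nominal 0.05). The calibration study therefore draws
exposure effects nearly noise-free — the regime in which the scheme's own
assumption holds — and this paragraph is the documentation of the drift.
Only the global test is provided; outlier removal and distortion testing
are out of scope.

The *Steiger test* converts per-instrument z-statistics to
$r^2 = z^2/(z^2+n-2)$, sums over conditionally independent instruments per
trait, and compares Fisher-transformed correlations:
$Z = (\mathrm{atanh}\,r_P - \mathrm{atanh}\,r_D)
/\sqrt{1/(n_P-3) + 1/(n_D-3)}$. The causal direction is read from which
trait's variance the instruments explain better. Note the small sample
dominates the variance of $Z$: with $r^2 = 3.3\%$ at $n = 846$ against
$0.04\%$ at $n = 3.2\times10^5$ the direction is unambiguous but
$p \approx 2\times10^{-6}$, not astronomically small. No correction for
extreme sample-size imbalance is applied; the documented caveat is that the
test can mis-orient when measurement error differs strongly between traits.

## Mediation

Writing $\theta_1$ for the exposure→mediator effect, $\theta_2$ for the
conditional mediator→outcome effect and $\theta_3$ for the direct effect,
the total effect decomposes as $\theta_3 + \theta_1\theta_2$. Two routes:

- *Product of coefficients* (two-step MR): indirect $=\theta_1\theta_2$,
  SE $\sqrt{\theta_2^2\mathrm{se}_1^2 + \theta_1^2\mathrm{se}_2^2}$. The
  covariance of $\hat\theta_1$ and $\hat\theta_2$ is taken as zero — in the
  two-step two-sample layout they come from non-overlapping samples.
- *Difference of coefficients*: indirect $=$ total $-$ direct, the direct
  effect from multivariable MR (weighted no-intercept regression of outcome
  effects on both exposures' effect columns). The SE assumes independence
  of total and direct, which share the outcome sample; the result object
  flags this assumption.

The proportion mediated $\theta_1\theta_2/(\theta_3+\theta_1\theta_2)$ is
always reported with a validity flag rather than suppressed: it is marked
invalid when the total is zero or the indirect effect has the opposite
sign. Conditional instrument strength in MVMR is reported as the Q-form
statistic from regressing one exposure's SNP effects on the other's
(weights $1/\mathrm{se}^2$), reported but never thresholded; the full
conditional-F machinery is out of scope.

## Multi-trait colocalization

For each variant and trait, the Wakefield approximate Bayes factor with a
normal effect prior of SD $W^{1/2}$:
$\mathrm{ABF} = \sqrt{V/(V+W)}\exp\!\big(z^2W/(2(V+W))\big)$, $V$ the
squared SE. A *configuration* assigns a subset of the three traits
(methylation, expression, lung function) to disjoint blocks, one causal
variant per block, distinct variants across blocks — 15 configurations for
three traits. Configuration scores sum, over assignments of distinct
variants to blocks, the products of per-block ABFs, weighted by per-variant
priors $p_1 = 10^{-4}$, $p_2 = 10^{-6}$, $p_3 = 10^{-7}$ for blocks of one,
two, three traits (the framework's recommended defaults; configurable).
Posteriors normalize over all 15; the headline PPA is the posterior of the
all-three-share configuration ("abc"), with the methylation–lung-function
sharing mass ($\{$ac, ac·b, abc$\}$) reported alongside, since published
PPAs do not always state which mass they quote. A PPA $\ge 80\%$ is the
conventional evidence threshold.

Regions are filtered to MAF $\ge 5\%$ and complete statistics; fewer than
50 qualifying variants is an error, mirroring the analysis rule. The gene
scan runs one region per candidate gene (transcription start within 1 Mb of
the CpG) and reports the maximum-PPA gene.

# Numerical choices

- All ABF arithmetic is in log space. Distinct-variant sums use exact
  inclusion–exclusion identities (e.g.
  $\sum_{u\ne v} f_ug_v = S_fS_g - S_{fg}$ and its three-block analogue)
  evaluated with a signed log-sum-exp; a total driven below zero by
  floating-point cancellation — possible only when a configuration's mass
  is negligible anyway — is clamped to zero before normalization.
  Exactness is verified in the tests against brute-force enumeration over
  all variant tuples on 60-variant regions.
- Harmonization resolves non-palindromic alleles by direct, swapped,
  complemented or complement-swapped matching; anything else is excluded as
  an allele mismatch. Palindromic variants are kept only when both
  frequencies are present, outside the ambiguity band
  ($[0.42, 0.58]$ by default) and on the same side of 0.5 after textual
  orientation; the band is the common two-sample convention, configurable.
- p-values absent from input tables are recomputed two-sided normal from
  beta/se (all source GWAS are large); supplied p-values are checked for
  consistency with beta/se to one significant figure, skipping tails below
  $10^{-10}$ where t- and normal-based values legitimately diverge.
- Empirical p-values use the $+1$ correction. Bonferroni thresholds are
  computed over the *realized* number of tests and displayed at two
  significant figures (full precision internally).
- Degenerate inputs error early with named reasons: zero exposure effect in
  a Wald ratio (weak instrument), fewer than 3 (Egger, median, MVMR) or 4
  (PRESSO) instruments, zero exposure-effect variance, collinear MVMR
  exposures, instrument sets whose summed $r^2$ reaches 1, singular LD
  covariances.

# The synthetic-data generator

`sim_config()` fixes the study conditions; they were chosen once, on the
following reasoning, and the evaluation studies run at these defaults.

- **Two non-overlapping samples**, $n_1 = 846$ (methylation study) and
  $n_2 = 50{,}000$ (outcome GWAS at desk scale), split *before* any
  regression.
- **mQTL instruments**: two per CpG, per-SNP $r^2 \sim U(0.10, 0.25)$.
  Real per-mQTL $r^2$ spans 2.9%–31.3% with mean F ≈ 109; the strong end of
  that range is deliberate, because in the $n_1 \ll n_2$ regime two-sample
  weak-instrument bias ($\approx 2\theta/\bar z^2$, toward the null) must
  sit an order below the Monte-Carlo SE for coverage statements to be about
  the intervals rather than the bias. At these defaults measured IVW
  coverage is ~94–97% with second-order SEs.
- **Effect sizes in SD units**: direct methylation→FEV1 effect
  $\theta_3 = 0.1$ (the magnitude of the largest published per-CpG
  effects); mediation diagram $\theta_1 = 0.03$ (methylation→smoking,
  small), $\theta_2 = 0.4$ (smoking→lung function, large), giving a true
  proportion mediated of 10.7%, inside the reported 7.85%–19.33% range.
- **Smoking instruments**: twenty SNPs at per-SNP $r^2 = 10^{-3}$, so their
  z-statistics at $n_2$ ($\approx 7$) match the genome-wide-significant
  range of real smoking-GWAS hits relative to *their* sample; they are
  selected and estimated in sample 2, mirroring their real origin in a
  462k-person GWAS rather than the 846-person methylation cohort.
- **MAF** $\sim U(0.10, 0.35)$: stopping short of 0.5 keeps strand-ambiguous
  variants resolvable by frequency, so harmonization never silently empties
  an instrument set in simulation.
- **LD**: latent-Gaussian AR(1) within blocks, binomial(2, maf) margins.
  Colocalization regions use 200 variants, $\rho = 0.5$, three independent
  samples of 2,000, causal-variant $r^2 = 3\%$.
- Traits are built in diagram order with residual noise budgeted against
  the empirical variance of the systematic part, so population variances
  are 1 and the configured $\theta$s are exact in SD units; traits are then
  mean-centred (sample SDs deviate from 1 only by sampling error).

What the generator does **not** emulate — and hence what green tests do not
certify about real data: array measurement error and cell-type
heterogeneity in methylation; real LD panels (AR(1) is a caricature);
selection-induced winner's curse when instruments are discovered in the
estimation sample (our evaluation instruments are "catalog" instruments,
solidly above the selection threshold); population stratification; and
sample overlap between studies.

# Evaluation studies and problem sizes

`evaluate_ivw_coverage()` (200 replicates), `evaluate_mediation_recovery()`
(200), `evaluate_q_calibration()` (2,000 summary-level nulls),
`evaluate_presso_calibration()` (100 × 1,000 resamples) and
`evaluate_coloc()` (200 regions) are exported so the tests and the
acceptance script exercise the same code paths. These sizes give binomial
95% bands of about ±3 percentage points on a 95% coverage target and ±4 on
a 5% size target, and complete in minutes on one CPU; they are the
package's chosen trade-off between Monte-Carlo resolution and a test suite
that runs routinely.

# Pipeline semantics

`mr_discovery()` Bonferroni-corrects over the exposures actually tested
(not the manifest size), routes one-instrument CpGs to the Wald ratio and
several-instrument CpGs to IVW, and records skips with reasons.
`mr_replication()` refuses to run without a discovery passing set (stage
ordering is structural), corrects over the passing count, and reports
whole-percent direction concordance. `bidirectional_mr()` combines forward
MR, reciprocal MR with independent outcome instruments, and Steiger into a
per-pair verdict. Reports are byte-stable given identical inputs: no
timestamps, seeds and a config hash embedded.

The pipeline is exposed as R functions and this vignette rather than a
shell executable: the package is a library its users drive from R scripts.

# Known limitations

- MR-Egger SEs and the GLS heterogeneity statistic follow fixed conventions
  (multiplicative random effects with floored residual SD; $Q$ with
  df $=L-1$); alternative conventions exist.
- The MR-PRESSO global test inherits the published scheme's mild
  conservatism under noisy exposure effects (documented above).
- Colocalization assumes at most one causal variant per trait per region;
  regions of extended high LD can push mass toward sharing configurations,
  so a high PPA in such regions is supportive, not demonstrative.
- Steiger directionality can mislead when the two traits' effective
  measurement precision differs grossly; no correction is attempted.
- MVMR is limited to two exposures, matching its mediation role here.
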