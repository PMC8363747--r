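---
title: "Summary-statistics causal inference at a cis-pQTL locus: methods and design"
author: "cisMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-statistics causal inference at a cis-pQTL locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisMR)
```

## The problem

A variant near a protein-coding gene that is strongly associated with the
circulating level of that protein (a *cis*-pQTL) can serve as an
instrumental variable for the protein: because alleles are assigned at
conception, the variant's association with a downstream outcome
(bone mineral density, fracture risk) is protected from the confounding
and reverse causation that plague observational protein-outcome
correlations. `cisMR` implements the summary-statistics machinery for
this design — two-sample Mendelian randomization (MR), Bayesian
colocalization, effect-size comparison and LD summaries — and applies it
to the RSPO3 locus, where the package ships the published per-variant
associations (`rspo3Fixture()`) and a recipe (`reproduceTable2()`) that
recomputes the published MR table from them.

## Mendelian randomization

### Wald ratio

For one instrument with exposure association $\hat\beta_{GX}$ (SE
$\sigma_{GX}$) and outcome association $\hat\beta_{GY}$ (SE
$\sigma_{GY}$), both per copy of the same effect allele, the causal
effect of one SD of exposure on the outcome is estimated by the Wald
ratio

$$\hat\beta_{MR} = \frac{\hat\beta_{GY}}{\hat\beta_{GX}},$$

the outcome effect weighted by the instrument's effect on the exposure.
Two standard errors are offered:

* `first_order` (default): $\sigma_{MR} = \sigma_{GY}/|\hat\beta_{GX}|$.
  The MR Z statistic then equals the outcome association's Z exactly, so
  the MR p-value *is* the outcome p-value. This is the estimator whose
  output matches the published table cell for cell: every published MR
  p-value equals the corresponding published outcome p-value, which
  identifies the first-order ratio as the estimator used there, and it is
  why `first_order` is the package default.
* `second_order`: adds the delta-method term for exposure uncertainty,
  $\sigma_{MR}^2 = \sigma_{GY}^2/\hat\beta_{GX}^2 +
  \hat\beta_{GY}^2\sigma_{GX}^2/\hat\beta_{GX}^4$. With a cis-pQTL
  Z of ~14 (0.325/0.023) the correction is negligible, but it is
  available for weaker instruments.

**P-value propagation.** Published summary tables round betas and SEs to
a few digits, so a p-value recomputed from the rounded Z need not agree
with the printed one (0.092/0.028 gives $p = 1.0\times10^{-3}$ where the
source, computed before rounding, printed $9.4\times10^{-4}$). Because
the first-order ratio preserves the outcome p-value exactly in theory,
`waldRatio()` carries a stored outcome p-value through unchanged under
`first_order` and only recomputes from Z when none is stored (or under
`second_order`). This is a deliberate deviation from forcing internal
$Z$/p consistency on inputs that are themselves rounded.

### IVW and heterogeneity

With $k$ instruments the fixed-effect inverse-variance-weighted estimate
combines the per-instrument ratios $b_i$ with variances $v_i$:

$$\hat\beta_{IVW} = \frac{\sum b_i/v_i}{\sum 1/v_i},\qquad
  \sigma_{IVW} = \Big(\sum 1/v_i\Big)^{-1/2},$$

with Cochran's $Q = \sum (b_i - \hat\beta_{IVW})^2/v_i$ on $k-1$ df.
Only the fixed-effect version is implemented: the primary analyses here
are single-instrument, where the fixed/random distinction vanishes, and
pleiotropy-robust estimators (MR-Egger, weighted median) are out of
scope. `bidirectionalMR()` simply runs IVW in both directions; evidence
of a forward effect with a null reverse effect argues against reverse
causation.

### Harmonization

`harmonize()` aligns each outcome association to the exposure's effect
allele: label swaps negate the effect and complement the frequency;
strand flips are resolved by complementing alleles. Palindromic variants
(A/T, C/G) cannot be oriented by labels, so effect-allele frequencies
are compared against 0.5; when both lie within 0.08 of 0.5 (the
`palindromicEafWindow`, configurable) orientation is refused. The window
matters only for external data — none of the three packaged RSPO3
variants is palindromic. Missing frequencies are tolerated; alignment
then relies on labels alone.

Odds-ratio inputs are converted with the exact normal quantile
($z_{0.975} = 1.959964\ldots$, never 1.96) so that
$\exp(\hat\beta \pm z\sigma)$ reproduces the printed interval to
machine precision. A printed p-value smaller than the smallest positive
double (one fixture cell prints $5.6\times10^{-336}$) is stored as
`5e-324` rather than 0.

## Colocalization

For each variant and trait, the Wakefield approximate Bayes factor
against the null is, in logs,

$$\log ABF = \tfrac12\left[\log(1-r) + r z^2\right],\qquad
  r = \frac{W}{W + V},$$

with $z^2 = \hat\beta^2/V$, $V$ the effect variance and $\sqrt W$ the
prior SD of a true effect (0.15 for quantitative traits, 0.2 for
case/control, configurable). Assuming at most one causal variant per
trait, the evidence for the five hypotheses is assembled in log space
(`logsumexp`), weighted by priors $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$ — the conventional defaults, since the source
analysis does not state its priors — and normalized by softmax. The H3
(two distinct causal variants) term requires
$\sum_{i\ne j} ABF_1^{(i)}ABF_2^{(j)}$, computed as the guarded
log-space difference
$\log\!\big(e^{S_1+S_2} - e^{S_{12}}\big)$ via `log1p`; when the shared
term reaches the total (a single variant, or numerically at underflow)
the H3 weight is $-\infty$, making $PP_{H3} = 0$ exact in the
single-variant case. Tests verify the log-space path against brute-force
enumeration for up to 4 variants at $10^{-9}$.

The published real-data colocalization ($PP_{H4} = 0.72$ between
circulating RSPO3 and trabecular vBMD) needs full locus-wide external
summary statistics that cannot be shipped, so the package instead
validates recovery on synthetic loci: a shared causal variant among 50
correlated null variants should, and in tests does, yield
$PP_{H4} > 0.9$ in at least 90% of replicates, while two causal variants
in weak LD ($r^2 < 0.05$) push mass onto H3. When only p-values are
available, `colocTrait()` reconstructs $V \approx 1/(2n\,f(1-f))$
(quantitative; case/control adds the case-fraction factor) — an
approximation, documented as such.

## Auxiliary statistics

`compareEffects()` is the two-sample Z-test
$z = (b_1-b_2)/\sqrt{\sigma_1^2+\sigma_2^2-2c_{12}}$ with $c_{12} = 0$
by default; the published comparisons were made between fracture ORs on
overlapping cohorts without a stated overlap correction, so the
covariance is exposed as a parameter rather than guessed. On the
published rounded inputs the forearm-vs-any-site comparison gives
$p \approx 6.5\times10^{-7}$, not the printed $1.6\times10^{-5}$ — the
printed value evidently reflects unrounded estimates and/or an overlap
adjustment, and is deliberately not asserted anywhere.

`ldFromHaplotypeFreqs()` computes $D = p_{AB}-p_Ap_B$, $D'$ (normalized
by the frequency-constrained maximum) and
$r^2 = D^2/(p_Ap_ap_Bp_b)$ from known haplotype frequencies or counts;
EM phasing of genotypes is out of scope.

## The synthetic locus generator

`simulateCohort()` draws two haplotypes per individual from an explicit
pool, inducing LD whose every pairwise coefficient is known in closed
form from the pool frequencies (`poolLD()`) — chosen over a Gaussian
copula precisely so LD assertions are closed-form. Phenotypes follow

```
bmdExog  = betaGB * g_bmd + N(0, sdBMD)
protein  = betaGP * g_causal + reverseBetaBP * bmdExog + N(0, sdProtein)
bmd      = betaPB * protein + bmdExog
fracture ~ Bernoulli(plogis(alpha0 + betaBF * bmd))
```

`reverseBetaBP` injects reverse causation through the feedback-free BMD
component, and the optional direct variant → BMD path (`bmdSnpIndex`,
`betaGB`) provides a valid reverse-direction instrument and the
distinct-causal-variant colocalization scenario. Defaults mirror the
studied locus: `betaGP = 0.33` per allele (≈0.32 SD after
standardization, cf. the pQTL beta 0.325), `betaPB = 0.3`,
`alpha0 = -2.2` (fracture prevalence ≈10%), and
`betaBF = -0.62`, so the implied protein → fracture odds ratio is ≈0.83
per SD — the magnitude of the published MR estimate. The default
6-variant pool gives the causal variant frequency 0.55 (cf. EAF 0.56)
with a correlated neighbour ($r^2 = 0.64$, $D' = 0.80$).

`cohortSumstats()` standardizes protein and BMD to unit SD before
regression so simulated betas are "per SD per effect allele" like the
published tables; fracture associations are per-variant logistic
regressions (IRLS, tolerance $10^{-8}$, 50 iterations; separation is
flagged with a missing SE, not penalized). Continuous-trait p-values use
the normal approximation to the t, immaterial at the simulated sample
sizes.

**What the generator does not emulate:** covariates (age, sex,
ancestry), mixed-model association, genome-wide polygenic background,
imputation uncertainty, and case/control ascertainment. Passing recovery
tests therefore demonstrate the estimators' correctness under the
assumed structural model, not robustness to those real-data features.

### Recovery truth and problem sizes

MR on standardized traits estimates
$\beta_{PB}\cdot sd(\text{protein})/sd(\text{BMD})$, which
`impliedTrueEffect()` evaluates in closed form from the pool (exact
under Hardy-Weinberg with independent haplotype draws); with the default
configuration this is 0.294 for `betaPB = 0.3`. `recoveryExperiment()`
measures bias, RMSE and CI coverage against that truth; replicate $r$
uses seed `seed + r`.

Validation sizes were chosen to make Monte-Carlo noise small relative to
the tolerances being checked: 500 replicates of $n = 20{,}000$ for
coverage (binomial SE ≈ 1%, checked against [0.93, 0.97]), 200
replicates for the colocalization recovery scenarios at $n = 3{,}000$
with 51 variants (per-trait $|z|$ at the causal variant ≈ 12 and ≈ 9),
and 200 replicates each for the null-recovery and $\sqrt n$ RMSE-scaling
checks. The deterministic table reproduction runs in well under a
second.

## Reproducing the published table

`reproduceTable2()` crosses the two cis-pQTL instruments (rs3734626,
exposure beta 0.325; rs2489623, 0.270) with seven outcomes, computing
each cell as a first-order Wald ratio from the packaged fixture and
rounding to the published 2-decimal precision. Twelve of fourteen cells
match exactly. The two hip-fracture cells do not (0.85 vs 0.84 and 0.86
vs 0.88): they are not recoverable from the rounded published inputs —
the source analysis used unrounded estimates — and are therefore
reported with a `known rounding discrepancy` note and excluded from the
match count rather than forced. The bidirectional analysis published for
this locus used 1107 genome-wide BMD instruments from external summary
statistics; the mechanism is implemented and validated on synthetic
instruments, but that real-data run is out of scope.

## Known limitations

* Single-causal-variant colocalization only (no SuSiE-style multiple
  signals), matching the source analysis's own restriction.
* No pleiotropy-robust MR estimators, proxy-variant lookup, VCF parsing
  or liftover.
* The effect-comparison test assumes known covariance between estimates;
  it does not estimate sample overlap.
* LD utilities require phased haplotype frequencies or counts.
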