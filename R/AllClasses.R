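#' @import methods
NULL

## Canonical summary-statistics columns. A set of variant-trait
## associations is a plain data.frame with these columns, one row per
## variant (the tabular idiom of GWAS summary files); the S4 layer starts
## at the harmonized instrument pair.
.SUMSTATS_COLS <- c("snp", "effect_allele", "other_allele", "eaf", "beta",
                    "se", "pval", "n", "n_cases", "n_controls", "trait",
                    "trait_type")

.TRAIT_TYPES <- c("quantitative", "case_control")

#' Harmonized exposure/outcome instrument pairs
#'
#' Holds row-aligned exposure and outcome summary statistics for one or
#' more instruments after allele harmonization, so that every effect is
#' expressed per copy of the same effect allele in both traits.
#'
#' @slot exposure data.frame of exposure associations (canonical columns).
#' @slot outcome data.frame of outcome associations, row-aligned with
#'   \code{exposure}.
#' @slot harmonized logical flag set by [harmonize()].
#'
#' @seealso [harmonize()], [waldRatio()], [ivwMR()]
#' @export
setClass("InstrumentPairs",
         representation(exposure = "data.frame",
                        outcome = "data.frame",
                        harmonized = "logical"))

setValidity("InstrumentPairs", function(object) {
  ex <- object@exposure
  ou <- object@outcome
  msg <- character()
  if (nrow(ex) != nrow(ou))
    msg <- c(msg, "exposure and outcome must have the same number of rows")
  need <- c("snp", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(ex)) || !all(need %in% names(ou)))
    msg <- c(msg, paste("missing canonical columns:",
                        paste(setdiff(need, intersect(names(ex), names(ou))),
                              collapse = ", ")))
  if (length(msg) == 0L && nrow(ex) > 0L) {
    if (!all(ex$snp == ou$snp))
      msg <- c(msg, "exposure and outcome snp ids are not aligned")
    if (isTRUE(object@harmonized) &&
        !all(ex$effect_allele == ou$effect_allele))
      msg <- c(msg, "harmonized pairs must share the effect allele")
    if (any(!is.na(ex$se) & ex$se <= 0) || any(!is.na(ou$se) & ou$se <= 0))
      msg <- c(msg, "standard errors must be positive")
  }
  if (length(object@harmonized) != 1L)
    msg <- c(msg, "harmonized must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Mendelian randomization result
#'
#' Causal-effect estimate from a Wald ratio or an inverse-variance-weighted
#' (IVW) combination of Wald ratios, on the linear (SD-outcome) or log-odds
#' (binary-outcome) scale, per SD of the exposure.
#'
#' @slot betaMR causal effect per SD increase in the exposure.
#' @slot seMR standard error of \code{betaMR}.
#' @slot ciLow,ciHigh confidence bounds at \code{level}.
#' @slot pval two-sided p-value.
#' @slot nInstruments number of instruments combined.
#' @slot method \code{"wald_ratio"} or \code{"ivw"}.
#' @slot outcomeScale \code{"linear"} or \code{"log_odds"}.
#' @slot level confidence level of the interval.
#' @slot qStat,qDf,qPval Cochran's Q heterogeneity statistic, degrees of
#'   freedom and chi-square p-value (\code{NA} with a single instrument).
#'
#' @seealso [waldRatio()], [ivwMR()], [toORScale()]
#' @export
setClass("MRResult",
         representation(betaMR = "numeric", seMR = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        pval = "numeric", nInstruments = "integer",
                        method = "character", outcomeScale = "character",
                        level = "numeric",
                        qStat = "numeric", qDf = "numeric",
                        qPval = "numeric"))

setValidity("MRResult", function(object) {
  msg <- character()
  scl <- function(x) length(x) == 1L
  if (!all(vapply(list(object@betaMR, object@seMR, object@ciLow,
                       object@ciHigh, object@pval, object@level), scl,
                  logical(1))))
    msg <- c(msg, "all numeric summary slots must have length 1")
  else {
    if (!is.finite(object@seMR) || object@seMR <= 0)
      msg <- c(msg, "seMR must be positive")
    if (!(object@ciLow < object@betaMR && object@betaMR < object@ciHigh))
      msg <- c(msg, "confidence bounds must bracket the estimate")
    if (!(object@pval > 0 && object@pval <= 1))
      msg <- c(msg, "pval must lie in (0, 1]")
  }
  if (!object@method %in% c("wald_ratio", "ivw"))
    msg <- c(msg, "method must be 'wald_ratio' or 'ivw'")
  if (!object@outcomeScale %in% c("linear", "log_odds"))
    msg <- c(msg, "outcomeScale must be 'linear' or 'log_odds'")
  if (object@nInstruments < 1L)
    msg <- c(msg, "nInstruments must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Per-locus association summary for one colocalization trait
#'
#' Aligned per-variant effects and effect variances for one trait across a
#' locus, plus the prior standard deviation of a true effect used by the
#' Wakefield approximate Bayes factor.
#'
#' @slot snpIds variant identifiers, in locus order.
#' @slot beta per-variant marginal effects.
#' @slot varbeta per-variant effect variances (squared standard errors).
#' @slot traitType \code{"quantitative"} or \code{"case_control"}.
#' @slot priorSd prior standard deviation of a nonzero effect.
#'
#' @seealso [colocTrait()], [colocABF()]
#' @export
setClass("ColocTrait",
         representation(snpIds = "character", beta = "numeric",
                        varbeta = "numeric", traitType = "character",
                        priorSd = "numeric"))

setValidity("ColocTrait", function(object) {
  msg <- character()
  n <- length(object@snpIds)
  if (n < 1L) msg <- c(msg, "at least one variant is required")
  if (length(object@beta) != n || length(object@varbeta) != n)
    msg <- c(msg, "beta and varbeta must match snpIds in length")
  if (any(!is.finite(object@varbeta)) || any(object@varbeta <= 0))
    msg <- c(msg, "all varbeta must be finite and positive")
  if (anyDuplicated(object@snpIds))
    msg <- c(msg, "snpIds must be unique")
  if (!object@traitType %in% .TRAIT_TYPES)
    msg <- c(msg, "traitType must be 'quantitative' or 'case_control'")
  if (length(object@priorSd) != 1L || !is.finite(object@priorSd) ||
      object@priorSd <= 0)
    msg <- c(msg, "priorSd must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Colocalization posterior summary
#'
#' Posterior probabilities of the five single-causal-variant hypotheses and
#' the per-variant log approximate Bayes factors they were computed from.
#' H0: no association with either trait; H1/H2: association with trait 1 /
#' trait 2 only; H3: two distinct causal variants; H4: one shared causal
#' variant.
#'
#' @slot pp named numeric, \code{PP.H0 ... PP.H4}, summing to 1.
#' @slot labf1,labf2 per-variant log approximate Bayes factors.
#' @slot snpIds variant identifiers.
#' @slot priors named numeric \code{(p1, p2, p12)}.
#'
#' @seealso [colocABF()]
#' @export
setClass("ColocResult",
         representation(pp = "numeric", labf1 = "numeric",
                        labf2 = "numeric", snpIds = "character",
                        priors = "numeric"))

setValidity("ColocResult", function(object) {
  msg <- character()
  if (length(object@pp) != 5L)
    msg <- c(msg, "pp must contain five hypothesis probabilities")
  else {
    if (any(object@pp < 0)) msg <- c(msg, "posterior probabilities must be >= 0")
    if (abs(sum(object@pp) - 1) > 1e-9)
      msg <- c(msg, "posterior probabilities must sum to 1")
  }
  if (length(object@labf1) != length(object@snpIds) ||
      length(object@labf2) != length(object@snpIds))
    msg <- c(msg, "labf vectors must match snpIds in length")
  if (length(object@priors) != 3L || any(object@priors <= 0) ||
      any(object@priors >= 1))
    msg <- c(msg, "priors must be three probabilities in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Synthetic cis-locus simulation configuration
#'
#' Defines a cohort simulation with the causal chain variant -> circulating
#' protein -> bone mineral density (BMD) -> fracture. Linkage
#' disequilibrium between the locus variants is induced by drawing each
#' individual's two haplotypes from an explicit haplotype pool, so every
#' pairwise LD coefficient is known in closed form from the pool
#' frequencies.
#'
#' @slot nIndividuals cohort size.
#' @slot haplotypes character vector of 0/1 strings, one per pool
#'   haplotype, all of the same length M (number of variants).
#' @slot hapFreqs haplotype frequencies, summing to 1.
#' @slot causalSnpIndex variant (1-based) with a direct effect on the
#'   protein.
#' @slot betaGP variant -> protein effect per allele copy, in raw protein
#'   units (protein noise has SD \code{sdProtein}).
#' @slot betaPB protein -> BMD effect, raw units.
#' @slot alpha0 logistic intercept of the fracture model.
#' @slot betaBF BMD -> fracture log-odds slope per raw BMD unit.
#' @slot reverseBetaBP optional reverse (BMD -> protein) effect acting on
#'   the feedback-free BMD component; default 0.
#' @slot bmdSnpIndex variant with a direct effect on BMD (for reverse-MR
#'   and distinct-causal-variant scenarios); 0 disables it.
#' @slot betaGB direct variant -> BMD effect per allele copy; default 0.
#' @slot sdProtein,sdBMD noise standard deviations.
#' @slot seed RNG seed making the simulation reproducible.
#'
#' @seealso [locusConfig()], [simulateCohort()]
#' @export
setClass("LocusConfig",
         representation(nIndividuals = "integer", haplotypes = "character",
                        hapFreqs = "numeric", causalSnpIndex = "integer",
                        betaGP = "numeric", betaPB = "numeric",
                        alpha0 = "numeric", betaBF = "numeric",
                        reverseBetaBP = "numeric", bmdSnpIndex = "integer",
                        betaGB = "numeric", sdProtein = "numeric",
                        sdBMD = "numeric", seed = "integer"))

setValidity("LocusConfig", function(object) {
  msg <- character()
  H <- object@haplotypes
  f <- object@hapFreqs
  if (length(H) < 2L)
    msg <- c(msg, "haplotype pool must contain at least two haplotypes")
  if (length(unique(nchar(H))) != 1L)
    msg <- c(msg, "all haplotypes must have the same length")
  if (any(!grepl("^[01]+$", H)))
    msg <- c(msg, "haplotypes must be strings over {0,1}")
  if (length(f) != length(H))
    msg <- c(msg, "one frequency per haplotype is required")
  else {
    if (any(f < 0)) msg <- c(msg, "haplotype frequencies must be >= 0")
    if (abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, "haplotype frequencies must sum to 1")
  }
  if (object@nIndividuals < 2L)
    msg <- c(msg, "nIndividuals must be >= 2")
  M <- nchar(H[1])
  if (object@causalSnpIndex < 1L || object@causalSnpIndex > M)
    msg <- c(msg, "causalSnpIndex out of range")
  if (object@bmdSnpIndex < 0L || object@bmdSnpIndex > M)
    msg <- c(msg, "bmdSnpIndex out of range")
  pars <- c(object@betaGP, object@betaPB, object@alpha0, object@betaBF,
            object@reverseBetaBP, object@betaGB, object@sdProtein,
            object@sdBMD)
  if (any(!is.finite(pars)))
    msg <- c(msg, "all effect parameters must be finite")
  if (object@sdProtein < 0 || object@sdBMD < 0)
    msg <- c(msg, "noise SDs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Simulated cohort
#'
#' Individual-level data produced by [simulateCohort()]: allele counts and
#' the protein, BMD and fracture phenotypes (protein and BMD on their raw
#' generative scale; [cohortSumstats()] standardizes before testing).
#'
#' @slot genotypes n x M integer matrix of allele counts in \{0,1,2\}.
#' @slot protein,bmd length-n continuous phenotypes.
#' @slot fracture length-n binary (0/1) outcome.
#'
#' @seealso [simulateCohort()], [cohortSumstats()]
#' @export
setClass("Cohort",
         representation(genotypes = "matrix", protein = "numeric",
                        bmd = "numeric", fracture = "integer"))

setValidity("Cohort", function(object) {
  msg <- character()
  n <- nrow(object@genotypes)
  if (length(object@protein) != n || length(object@bmd) != n ||
      length(object@fracture) != n)
    msg <- c(msg, "phenotype lengths must match the genotype row count")
  if (!all(object@genotypes %in% 0:2))
    msg <- c(msg, "genotypes must be allele counts in {0,1,2}")
  if (!all(object@fracture %in% 0:1))
    msg <- c(msg, "fracture must be binary 0/1")
  if (length(msg)) msg else TRUE
})
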