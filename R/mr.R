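#' @include AllClasses.R AllGenerics.R harmonize.R
NULL

.mrResult <- function(beta, se, pval, n, method, scale, level,
                      qStat = NA_real_, qDf = NA_real_,
                      qPval = NA_real_) {
  z <- zQuantile(level)
  new("MRResult", betaMR = beta, seMR = se,
      ciLow = beta - z * se, ciHigh = beta + z * se,
      pval = max(pval, .Machine$double.xmin),
      nInstruments = as.integer(n), method = method, outcomeScale = scale,
      level = level, qStat = qStat, qDf = qDf, qPval = qPval)
}

.outcomeScale <- function(outcome) {
  if (identical(outcome$trait_type, "case_control")) "log_odds" else "linear"
}

.checkHarmonized <- function(pairs) {
  if (!is(pairs, "InstrumentPairs"))
    stop("pairs must be an InstrumentPairs object; run harmonize() first",
         call. = FALSE)
  if (!pairs@harmonized)
    stop("instrument pairs are not harmonized", call. = FALSE)
}

## Per-instrument Wald ratio and its variance.
.waldComponents <- function(ex, ou, seMode) {
  if (any(ex$beta == 0))
    stop("exposure beta is zero: the Wald ratio is undefined",
         call. = FALSE)
  if (any(is.na(ex$se)) || any(is.na(ou$se)))
    stop("instruments with missing standard errors cannot be used",
         call. = FALSE)
  b <- ou$beta / ex$beta
  v <- switch(seMode,
    first_order = ou$se^2 / ex$beta^2,
    second_order = ou$se^2 / ex$beta^2 +
      ou$beta^2 * ex$se^2 / ex$beta^4)
  list(b = b, v = v)
}

#' Single-instrument Wald-ratio Mendelian randomization
#'
#' Estimates the causal effect of the exposure on the outcome from one
#' genetic instrument as the ratio of the outcome and exposure
#' associations: `beta_mr = beta_outcome / beta_exposure`, the outcome
#' effect weighted by the instrument's effect on the exposure. With
#' `seMode = "first_order"` the standard error is
#' `se_outcome / |beta_exposure|`, so the MR Z statistic (and hence the
#' p-value) equals that of the outcome association; the outcome's stored
#' p-value, when present, is therefore carried through unchanged.
#' `"second_order"` adds the delta-method term for exposure-effect
#' uncertainty and recomputes the p-value from the Z statistic.
#'
#' @param pairs a harmonized [InstrumentPairs-class] with exactly one
#'   instrument.
#' @param seMode `"first_order"` (default) or `"second_order"`.
#' @param level confidence level for the interval (default 0.95).
#' @return an [MRResult-class]; `outcomeScale` is `"log_odds"` when the
#'   outcome is a case/control trait (use [toORScale()] for odds ratios).
#' @examples
#' ex <- variantAssociation("rs3734626", "T", "C", beta = 0.325,
#'                          se = 0.023, trait = "circulating_rspo3")
#' ou <- variantAssociation("rs3734626", "T", "C", or = 0.94,
#'                          ci_low = 0.93, ci_high = 0.95, pval = 1.8e-20,
#'                          trait = "fracture_any_site",
#'                          trait_type = "case_control")
#' res <- waldRatio(harmonize(ex, ou))
#' toORScale(res)   # odds ratio per SD of circulating protein
#' @export
setMethod("waldRatio", "InstrumentPairs",
          function(pairs, seMode = c("first_order", "second_order"),
                   level = 0.95) {
  seMode <- match.arg(seMode)
  .checkHarmonized(pairs)
  if (nrow(pairs@exposure) != 1L)
    stop("waldRatio expects a single instrument; use ivwMR() for several",
         call. = FALSE)
  ex <- pairs@exposure
  ou <- pairs@outcome
  w <- .waldComponents(ex, ou, seMode)
  se <- sqrt(w$v)
  pval <- if (seMode == "first_order" && !is.na(ou$pval))
    ou$pval else twoSidedP(w$b, se)
  .mrResult(w$b, se, pval, 1L, "wald_ratio", .outcomeScale(ou), level)
})

#' Inverse-variance-weighted Mendelian randomization
#'
#' Combines per-instrument Wald ratios `b_i` with variances `v_i` as the
#' fixed-effect weighted mean `sum(b_i/v_i) / sum(1/v_i)` with standard
#' error `sqrt(1 / sum(1/v_i))`. With two or more instruments Cochran's Q,
#' `sum((b_i - beta)^2 / v_i)` on `n - 1` degrees of freedom, quantifies
#' heterogeneity between the per-instrument estimates. With a single
#' instrument the result reduces to [waldRatio()] in every numeric field.
#'
#' @inheritParams waldRatio
#' @param pairs a harmonized [InstrumentPairs-class] (one or more
#'   instruments).
#' @return an [MRResult-class] with heterogeneity slots filled when the
#'   number of instruments is at least 2.
#' @export
setMethod("ivwMR", "InstrumentPairs",
          function(pairs, seMode = c("first_order", "second_order"),
                   level = 0.95) {
  seMode <- match.arg(seMode)
  .checkHarmonized(pairs)
  ex <- pairs@exposure
  ou <- pairs@outcome
  n <- nrow(ex)
  if (n < 1L) stop("at least one instrument is required", call. = FALSE)
  w <- .waldComponents(ex, ou, seMode)
  wt <- 1 / w$v
  beta <- sum(w$b * wt) / sum(wt)
  se <- sqrt(1 / sum(wt))
  if (n == 1L) {
    pval <- if (seMode == "first_order" && !is.na(ou$pval))
      ou$pval else twoSidedP(beta, se)
    return(.mrResult(beta, se, pval, 1L, "ivw", .outcomeScale(ou), level))
  }
  q <- sum((w$b - beta)^2 * wt)
  qDf <- n - 1
  .mrResult(beta, se, twoSidedP(beta, se), n, "ivw",
            .outcomeScale(ou[1, , drop = FALSE]), level,
            qStat = q, qDf = qDf,
            qPval = stats::pchisq(q, qDf, lower.tail = FALSE))
})

#' Bidirectional Mendelian randomization
#'
#' Runs [ivwMR()] in both causal directions: exposure -> outcome with the
#' forward instruments and outcome -> exposure with the reverse
#' instruments. A null reverse estimate argues against reverse causation
#' driving the forward association.
#'
#' @param forwardPairs,reversePairs harmonized [InstrumentPairs-class]
#'   objects for the two directions.
#' @inheritParams waldRatio
#' @return list with elements `forward` and `reverse`, each an
#'   [MRResult-class].
#' @export
bidirectionalMR <- function(forwardPairs, reversePairs,
                            seMode = c("first_order", "second_order"),
                            level = 0.95) {
  seMode <- match.arg(seMode)
  list(forward = ivwMR(forwardPairs, seMode = seMode, level = level),
       reverse = ivwMR(reversePairs, seMode = seMode, level = level))
}

#' Present a log-odds MR result on the odds-ratio scale
#'
#' @param x an [MRResult-class] with `outcomeScale == "log_odds"`.
#' @param level confidence level for the reported interval (default the
#'   result's own level).
#' @return named numeric `c(or, ci_low, ci_high)` with
#'   `or = exp(beta_mr)` and bounds `exp(beta_mr -/+ z * se_mr)`.
#' @export
toORScale <- function(x, level = x@level) {
  stopifnot(is(x, "MRResult"))
  if (x@outcomeScale != "log_odds")
    stop("result is on the linear scale; odds ratios are undefined",
         call. = FALSE)
  z <- zQuantile(level)
  c(or = exp(x@betaMR),
    ci_low = exp(x@betaMR - z * x@seMR),
    ci_high = exp(x@betaMR + z * x@seMR))
}

#' @rdname mr-accessors
#' @export
setMethod("mrBeta", "MRResult", function(x) x@betaMR)
#' @rdname mr-accessors
#' @export
setMethod("mrSE", "MRResult", function(x) x@seMR)
#' @rdname mr-accessors
#' @export
setMethod("mrCI", "MRResult",
          function(x) c(ci_low = x@ciLow, ci_high = x@ciHigh))
#' @rdname mr-accessors
#' @export
setMethod("mrPval", "MRResult", function(x) x@pval)
#' @rdname mr-accessors
#' @export
setMethod("nInstruments", "MRResult", function(x) x@nInstruments)
#' @rdname mr-accessors
#' @export
setMethod("qStats", "MRResult",
          function(x) c(q_stat = x@qStat, q_df = x@qDf, q_pval = x@qPval))

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult (%s, %d instrument%s, %s outcome)\n",
              object@method, object@nInstruments,
              if (object@nInstruments > 1) "s" else "",
              object@outcomeScale))
  cat(sprintf("  beta = %.4g (se %.4g), %d%% CI [%.4g, %.4g], p = %.3g\n",
              object@betaMR, object@seMR, round(object@level * 100),
              object@ciLow, object@ciHigh, object@pval))
  if (object@outcomeScale == "log_odds") {
    orci <- toORScale(object)
    cat(sprintf("  OR = %.3g, %d%% CI [%.3g, %.3g]\n", orci[1],
                round(object@level * 100), orci[2], orci[3]))
  }
  if (!is.na(object@qStat))
    cat(sprintf("  Cochran's Q = %.4g on %d df, p = %.3g\n",
                object@qStat, as.integer(object@qDf), object@qPval))
})
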