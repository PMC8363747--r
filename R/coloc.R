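#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a colocalization trait from per-variant summaries
#'
#' Builds the per-locus input for [colocABF()] either from effects and
#' their variances directly, or from p-values with allele frequencies and
#' sample sizes. The second route reconstructs `varbeta` with the standard
#' approximation `1 / (2 n maf (1-maf))` for quantitative traits, with an
#' extra factor `cf (1-cf)` (case fraction) for case/control traits, and
#' sets `beta = z * sqrt(varbeta)` from the two-sided normal quantile of
#' the p-value; the sign of beta is immaterial for the Bayes factors.
#'
#' @param snp variant identifiers (unique, locus order).
#' @param beta,varbeta per-variant effects and effect variances (se^2).
#' @param pval,maf,n alternative input route (used when `beta`/`varbeta`
#'   are `NULL`): p-values, minor-allele frequencies and sample sizes.
#' @param caseFraction proportion of cases, required for the p-value route
#'   of a case/control trait.
#' @param traitType `"quantitative"` or `"case_control"`.
#' @param priorSd prior standard deviation of a true effect; defaults to
#'   0.15 for quantitative and 0.2 for case/control traits.
#' @return a [ColocTrait-class].
#' @export
colocTrait <- function(snp, beta = NULL, varbeta = NULL, pval = NULL,
                       maf = NULL, n = NULL, caseFraction = NULL,
                       traitType = c("quantitative", "case_control"),
                       priorSd = NULL) {
  traitType <- match.arg(traitType)
  if (is.null(priorSd))
    priorSd <- if (traitType == "quantitative") 0.15 else 0.2
  if (is.null(beta) || is.null(varbeta)) {
    if (is.null(pval) || is.null(maf) || is.null(n))
      stop("supply beta + varbeta, or pval + maf + n", call. = FALSE)
    if (traitType == "case_control") {
      if (is.null(caseFraction))
        stop("caseFraction is required for the case_control p-value route",
             call. = FALSE)
      cf <- caseFraction
    } else cf <- NULL
    if (any(maf <= 0 | maf >= 1))
      stop("maf must lie strictly inside (0, 1)", call. = FALSE)
    varbeta <- 1 / (2 * n * maf * (1 - maf))
    if (!is.null(cf)) varbeta <- varbeta / (cf * (1 - cf))
    z <- stats::qnorm(pval / 2, lower.tail = FALSE)
    beta <- z * sqrt(varbeta)
  }
  new("ColocTrait", snpIds = as.character(snp), beta = as.numeric(beta),
      varbeta = as.numeric(varbeta), traitType = traitType,
      priorSd = priorSd)
}

#' Wakefield log approximate Bayes factor
#'
#' For one variant with estimated effect `beta` and variance `varbeta`,
#' under a normal prior with standard deviation `priorSd` on a true effect,
#' the approximate Bayes factor against the null satisfies
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)` with `z^2 = beta^2 / varbeta`
#' and shrinkage `r = priorSd^2 / (priorSd^2 + varbeta)`.
#'
#' @param beta estimated effect(s).
#' @param varbeta effect variance(s), > 0.
#' @param priorSd prior standard deviation of a true effect.
#' @return numeric vector of log approximate Bayes factors.
#' @examples
#' logABF(0.5, 0.01, 0.15)
#' @export
logABF <- function(beta, varbeta, priorSd) {
  if (any(!is.finite(varbeta)) || any(varbeta <= 0))
    stop("varbeta must be finite and positive", call. = FALSE)
  if (any(priorSd < 0))
    stop("priorSd must be non-negative", call. = FALSE)
  r <- priorSd^2 / (priorSd^2 + varbeta)
  0.5 * (log1p(-r) + r * beta^2 / varbeta)
}

#' Bayesian colocalization by approximate Bayes factors
#'
#' Tests whether two traits share one causal variant at a locus, assuming
#' at most one causal variant per trait. Per-variant log approximate Bayes
#' factors ([logABF()]) for each trait are combined, in log space, into the
#' evidence for five hypotheses: H0 (no association), H1/H2 (association
#' with one trait only), H3 (two distinct causal variants) and H4 (one
#' shared causal variant), weighted by the prior probabilities `p1`, `p2`
#' (a variant is causal for trait 1 / trait 2) and `p12` (causal for
#' both). The H3 sum over ordered pairs of distinct variants is evaluated
#' as a guarded log-space subtraction; with a single variant it is exactly
#' zero.
#'
#' @param trait1,trait2 [ColocTrait-class] objects over the same variants
#'   in the same order (intersect and align beforehand).
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @return a [ColocResult-class]; see [posteriorProb()].
#' @examples
#' t1 <- colocTrait("rs1", beta = 0.5, varbeta = 0.0025)
#' t2 <- colocTrait("rs1", beta = 0.4, varbeta = 0.0025)
#' posteriorProb(colocABF(t1, t2))
#' @export
colocABF <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(is(trait1, "ColocTrait"), is(trait2, "ColocTrait"))
  pri <- c(p1 = p1, p2 = p2, p12 = p12)
  if (any(pri <= 0) || any(pri >= 1))
    stop("priors must lie strictly inside (0, 1)", call. = FALSE)
  if (!identical(trait1@snpIds, trait2@snpIds))
    stop("traits must cover the same variants in the same order",
         call. = FALSE)

  l1 <- logABF(trait1@beta, trait1@varbeta, trait1@priorSd)
  l2 <- logABF(trait2@beta, trait2@varbeta, trait2@priorSd)
  s1 <- logSumExp(l1)
  s2 <- logSumExp(l2)
  s12 <- logSumExp(l1 + l2)

  lH <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = NA_real_,
          H4 = log(p12) + s12)
  # sum over ordered pairs i != j: exp(s1 + s2) - exp(s12), in log space;
  # underflow (shared term >= total, e.g. a single variant) means no mass
  # on distinct pairs
  gap <- s12 - (s1 + s2)
  lH["H3"] <- if (gap >= 0) -Inf else
    log(p1) + log(p2) + s1 + s2 + log1p(-exp(gap))

  m <- max(lH)
  pp <- exp(lH - m)
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.", names(lH))

  new("ColocResult", pp = pp, labf1 = l1, labf2 = l2,
      snpIds = trait1@snpIds, priors = pri)
}

#' @rdname coloc-accessors
#' @export
setMethod("posteriorProb", "ColocResult", function(x) x@pp)

#' @rdname coloc-accessors
#' @export
setMethod("logABFs", "ColocResult", function(x) {
  m <- cbind(labf1 = x@labf1, labf2 = x@labf2)
  rownames(m) <- x@snpIds
  m
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult over", length(object@snpIds), "variants\n")
  cat("  priors: p1 =", object@priors[["p1"]],
      " p2 =", object@priors[["p2"]],
      " p12 =", object@priors[["p12"]], "\n")
  print(round(object@pp, 4))
  top <- object@snpIds[which.max(object@labf1 + object@labf2)]
  cat("  top shared-evidence variant:", top, "\n")
})
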