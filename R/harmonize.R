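#' @include AllClasses.R AllGenerics.R sumstats.R
NULL

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complementAllele <- function(a) {
  parts <- strsplit(a, "", fixed = TRUE)
  vapply(parts, function(p) {
    if (!all(p %in% names(.COMPLEMENT)))
      return(NA_character_)
    paste(.COMPLEMENT[p], collapse = "")
  }, character(1))
}

isPalindromic <- function(effect_allele, other_allele) {
  comp <- complementAllele(effect_allele)
  !is.na(comp) & comp == other_allele
}

#' Flip a variant association to the opposite effect allele
#'
#' Re-expresses an association per copy of the current other allele: the
#' alleles are swapped, the effect sign is negated and the effect-allele
#' frequency becomes its complement. Flipping twice restores the original
#' record.
#'
#' @param x canonical summary-statistics data.frame (any number of rows).
#' @param rows which rows to flip (default all).
#' @return the data.frame with the selected rows flipped.
#' @export
flipAssociation <- function(x, rows = seq_len(nrow(x))) {
  ea <- x$effect_allele[rows]
  x$effect_allele[rows] <- x$other_allele[rows]
  x$other_allele[rows] <- ea
  x$beta[rows] <- -x$beta[rows]
  x$eaf[rows] <- 1 - x$eaf[rows]
  x
}

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' Aligns outcome associations so that both members of each instrument pair
#' report their effect per copy of the same allele. Outcomes whose effect
#' allele equals the exposure's other allele are flipped
#' ([flipAssociation()]); strand flips are resolved by complementing the
#' outcome alleles. Palindromic variants (A/T or C/G) are oriented by
#' comparing effect-allele frequencies against 0.5; when both frequencies
#' fall within `palindromicEafWindow` of 0.5 the orientation is
#' undecidable and an error is raised. Harmonization is idempotent.
#'
#' @param exposure,outcome canonical summary-statistics data.frames;
#'   variants are matched by `snp`. Alternatively pass an already
#'   harmonized [InstrumentPairs-class] as `exposure` (returned unchanged).
#' @param palindromicEafWindow half-width of the ambiguity window around
#'   an effect-allele frequency of 0.5 (default 0.08).
#' @return an [InstrumentPairs-class] with `harmonized = TRUE`, one row per
#'   variant shared between the two tables, in exposure order.
#' @examples
#' ex <- variantAssociation("rs3734626", "T", "C", eaf = 0.56,
#'                          beta = 0.325, se = 0.023)
#' ou <- variantAssociation("rs3734626", "C", "T", eaf = 0.47,
#'                          beta = 0.0619, se = 0.002)
#' harmonize(ex, ou)   # outcome flipped to the T allele
#' @export
harmonize <- function(exposure, outcome,
                      palindromicEafWindow = 0.08) {
  if (is(exposure, "InstrumentPairs")) {
    if (!missing(outcome))
      stop("pass either two tables or one InstrumentPairs", call. = FALSE)
    if (!exposure@harmonized)
      return(harmonize(exposure@exposure, exposure@outcome,
                       palindromicEafWindow))
    return(exposure)
  }
  validateSumstats(exposure)
  validateSumstats(outcome)
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L)
    stop("no shared variants between exposure and outcome", call. = FALSE)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]
  rownames(ex) <- rownames(ou) <- NULL

  for (i in seq_along(shared)) {
    eaE <- ex$effect_allele[i]; oaE <- ex$other_allele[i]
    eaO <- ou$effect_allele[i]; oaO <- ou$other_allele[i]

    sameSet <- setequal(c(eaO, oaO), c(eaE, oaE))
    if (!sameSet) {
      eaC <- complementAllele(eaO); oaC <- complementAllele(oaO)
      if (!is.na(eaC) && setequal(c(eaC, oaC), c(eaE, oaE))) {
        ou$effect_allele[i] <- eaO <- eaC
        ou$other_allele[i] <- oaO <- oaC
      } else {
        stop("allele mismatch for ", shared[i], ": exposure ", eaE, "/",
             oaE, " vs outcome ", ou$effect_allele[i], "/",
             ou$other_allele[i], call. = FALSE)
      }
    }

    if (isPalindromic(eaE, oaE)) {
      fE <- ex$eaf[i]; fO <- ou$eaf[i]
      if (!is.na(fE) && !is.na(fO)) {
        if (abs(fE - 0.5) < palindromicEafWindow &&
            abs(fO - 0.5) < palindromicEafWindow)
          stop("palindromic variant ", shared[i], " with effect-allele ",
               "frequencies too close to 0.5 to orient (window ",
               palindromicEafWindow, ")", call. = FALSE)
        # align labels first, then use frequency concordance to detect a
        # strand misread (for A/T and C/G the labels alone cannot); the
        # misread is corrected by negating the effect and frequency while
        # keeping the labels, which a flip-plus-complement amounts to
        if (eaO == oaE) ou <- flipAssociation(ou, i)
        if ((ex$eaf[i] - 0.5) * (ou$eaf[i] - 0.5) < 0) {
          ou$beta[i] <- -ou$beta[i]
          ou$eaf[i] <- 1 - ou$eaf[i]
        }
      } else if (eaO == oaE) {
        ou <- flipAssociation(ou, i)
      }
    } else if (eaO == oaE) {
      ou <- flipAssociation(ou, i)
    }
  }
  new("InstrumentPairs", exposure = ex, outcome = ou, harmonized = TRUE)
}

#' @rdname pair-accessors
#' @export
setMethod("exposure", "InstrumentPairs", function(x) x@exposure)

#' @rdname pair-accessors
#' @export
setMethod("outcome", "InstrumentPairs", function(x) x@outcome)

#' @rdname pair-accessors
#' @export
setMethod("isHarmonized", "InstrumentPairs", function(x) x@harmonized)

setMethod("show", "InstrumentPairs", function(object) {
  cat("InstrumentPairs with", nrow(object@exposure), "instrument(s),",
      if (object@harmonized) "harmonized" else "NOT harmonized", "\n")
  df <- data.frame(snp = object@exposure$snp,
                   alleles = paste0(object@exposure$effect_allele, "/",
                                    object@exposure$other_allele),
                   beta_exposure = object@exposure$beta,
                   se_exposure = object@exposure$se,
                   beta_outcome = object@outcome$beta,
                   se_outcome = object@outcome$se)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("...", nrow(df) - 10, "more\n")
})
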