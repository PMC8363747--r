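#' @include AllClasses.R
NULL

#' @rdname waldRatio
#' @export
setGeneric("waldRatio", function(pairs, ...) standardGeneric("waldRatio"))

#' @rdname ivwMR
#' @export
setGeneric("ivwMR", function(pairs, ...) standardGeneric("ivwMR"))

#' Accessors for MR results
#'
#' Extract the causal-effect estimate, its standard error, the confidence
#' bounds, the p-value, the instrument count and the heterogeneity
#' statistics from an [MRResult-class].
#'
#' @param x an [MRResult-class].
#' @return `mrBeta`, `mrSE`, `mrPval` return single numbers; `mrCI` a named
#'   numeric of length 2; `nInstruments` an integer; `qStats` a named
#'   numeric `(q_stat, q_df, q_pval)` (all `NA` for a single instrument).
#' @examples
#' pr <- harmonize(
#'   variantAssociation("rs1", "T", "C", beta = 0.3, se = 0.02),
#'   variantAssociation("rs1", "T", "C", beta = 0.09, se = 0.03))
#' res <- waldRatio(pr)
#' mrBeta(res)
#' mrCI(res)
#' @name mr-accessors
NULL

#' @rdname mr-accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname mr-accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))
#' @rdname mr-accessors
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))
#' @rdname mr-accessors
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))
#' @rdname mr-accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))
#' @rdname mr-accessors
#' @export
setGeneric("qStats", function(x) standardGeneric("qStats"))

#' Accessors for colocalization results
#'
#' @param x a [ColocResult-class].
#' @return `posteriorProb` returns the named vector `PP.H0 ... PP.H4`;
#'   `logABFs` a two-column matrix of per-variant log approximate Bayes
#'   factors (rownames are variant ids).
#' @name coloc-accessors
NULL

#' @rdname coloc-accessors
#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))
#' @rdname coloc-accessors
#' @export
setGeneric("logABFs", function(x) standardGeneric("logABFs"))

#' Accessors for harmonized instrument pairs
#'
#' @param x an [InstrumentPairs-class].
#' @return `exposure` / `outcome` return the row-aligned association
#'   data.frames; `isHarmonized` the harmonization flag.
#' @name pair-accessors
NULL

#' @rdname pair-accessors
#' @export
setGeneric("exposure", function(x) standardGeneric("exposure"))
#' @rdname pair-accessors
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))
#' @rdname pair-accessors
#' @export
setGeneric("isHarmonized", function(x) standardGeneric("isHarmonized"))

#' Accessors for simulated cohorts
#'
#' @param x a [Cohort-class].
#' @return `genotypes` the n x M allele-count matrix; `phenotypes` a
#'   data.frame with columns `protein`, `bmd`, `fracture`.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname cohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
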