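#' @include utils.R
NULL

#' Z-test comparing two effect sizes
#'
#' Tests whether two estimated effects differ:
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2 - 2 cov12)` with a two-sided normal
#' p-value. The default `cov12 = 0` assumes independent estimates; pass a
#' positive covariance when the two effects were estimated on overlapping
#' samples.
#'
#' @param b1,se1 first effect and its standard error (log scale for odds
#'   ratios).
#' @param b2,se2 second effect and its standard error.
#' @param cov12 covariance between the two estimates (default 0).
#' @return list with `z`, `pval` (two-sided), and the inputs.
#' @examples
#' fa <- orCiToBetaSe(0.88, 0.86, 0.91)  # distal forearm fractures
#' an <- orCiToBetaSe(0.95, 0.94, 0.96)  # fracture at any bone site
#' compareEffects(fa$beta, fa$se, an$beta, an$se)
#' @export
compareEffects <- function(b1, se1, b2, se2, cov12 = 0) {
  stopifnot(length(b1) == 1L, length(b2) == 1L)
  if (se1 <= 0 || se2 <= 0)
    stop("standard errors must be positive", call. = FALSE)
  v <- se1^2 + se2^2 - 2 * cov12
  if (v <= 0)
    stop("variance of the difference is non-positive; check cov12",
         call. = FALSE)
  z <- (b1 - b2) / sqrt(v)
  list(z = z, pval = 2 * stats::pnorm(-abs(z)),
       b1 = b1, se1 = se1, b2 = b2, se2 = se2, cov12 = cov12)
}

#' Linkage-disequilibrium summaries from haplotype frequencies
#'
#' Computes the raw disequilibrium coefficient
#' `D = p_AB - p_A * p_B`, its normalized magnitude `D'` (D divided by its
#' maximum attainable magnitude given the allele frequencies) and the
#' squared allelic correlation
#' `r^2 = D^2 / (p_A p_a p_B p_b)` from the four two-locus haplotype
#' frequencies. Alleles are labelled A/a at the first locus and B/b at the
#' second.
#'
#' @param p_AB,p_Ab,p_aB,p_ab haplotype frequencies (>= 0, summing to 1
#'   within 1e-9). Raw haplotype counts may be passed instead; they are
#'   normalized to frequencies.
#' @return list with `d`, `d_prime`, `r2`, the marginal allele frequencies
#'   `p_A`, `p_B`, and the input haplotype frequencies.
#' @examples
#' ldFromHaplotypeFreqs(0.4, 0.1, 0.1, 0.4)
#' @export
ldFromHaplotypeFreqs <- function(p_AB, p_Ab, p_aB, p_ab) {
  p <- c(p_AB, p_Ab, p_aB, p_ab)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0))
    stop("four finite non-negative haplotype frequencies are required",
         call. = FALSE)
  tot <- sum(p)
  if (tot <= 0)
    stop("haplotype frequencies are all zero", call. = FALSE)
  if (abs(tot - 1) > 1e-9) {
    if (tot > 1 + 1e-9) p <- p / tot  # counts: normalize
    else stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  pA <- p[1] + p[2]
  pB <- p[1] + p[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("both loci must be polymorphic", call. = FALSE)
  pa <- 1 - pA
  pb <- 1 - pB
  d <- p[1] - pA * pB
  dmax <- if (d > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  dprime <- if (d == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (pA * pa * pB * pb)
  list(d = d, d_prime = dprime, r2 = r2, p_A = pA, p_B = pB,
       p_AB = p[1], p_Ab = p[2], p_aB = p[3], p_ab = p[4])
}
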