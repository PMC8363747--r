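#' @include AllClasses.R AllGenerics.R assoc-stats.R sumstats.R mr.R
NULL

## Fixed default haplotype pool: 6 variants, 8 haplotypes. Variant 3 (the
## default causal variant) has pool allele frequency 0.55 and a correlated
## neighbour at variant 4, so the locus carries realistic LD while every
## pairwise coefficient stays available in closed form via poolLD().
.DEFAULT_POOL <- list(
  haplotypes = c("000000", "100100", "011110", "010010",
                 "001101", "110011", "011010", "101111"),
  freqs = c(0.30, 0.05, 0.35, 0.05, 0.10, 0.05, 0.05, 0.05))

#' Synthetic cis-locus configuration
#'
#' Builds a [LocusConfig-class] describing the simulated causal chain
#' variant -> circulating protein -> BMD -> fracture. The defaults emulate
#' the magnitudes of a strong cis-pQTL locus: a variant -> protein effect
#' of 0.33 per allele (about 0.32 SD after standardization), a protein ->
#' BMD effect of 0.3, and a BMD -> fracture slope chosen so the implied
#' protein -> fracture odds ratio is about 0.83 per SD at a baseline
#' fracture prevalence near 10%.
#'
#' @param nIndividuals cohort size (default 20000).
#' @param haplotypes,hapFreqs haplotype pool (0/1 strings and their
#'   frequencies); defaults to a fixed 6-variant, 8-haplotype pool.
#' @param causalSnpIndex variant with the protein effect (default 3).
#' @param betaGP variant -> protein effect per allele copy (default 0.33).
#' @param betaPB protein -> BMD effect (default 0.3).
#' @param alpha0 fracture-model intercept (default -2.2, prevalence ~10%).
#' @param betaBF BMD -> fracture log-odds slope (default -0.62).
#' @param reverseBetaBP reverse BMD -> protein effect on the feedback-free
#'   BMD component (default 0).
#' @param bmdSnpIndex variant with a direct BMD effect, 0 for none.
#' @param betaGB direct variant -> BMD effect per allele copy (default 0).
#' @param sdProtein,sdBMD noise standard deviations (default 1).
#' @param seed RNG seed (default 42).
#' @return a validated [LocusConfig-class].
#' @examples
#' cfg <- locusConfig(nIndividuals = 1000, seed = 7)
#' cohort <- simulateCohort(cfg)
#' @export
locusConfig <- function(nIndividuals = 20000L,
                        haplotypes = .DEFAULT_POOL$haplotypes,
                        hapFreqs = .DEFAULT_POOL$freqs,
                        causalSnpIndex = 3L, betaGP = 0.33, betaPB = 0.3,
                        alpha0 = -2.2, betaBF = -0.62,
                        reverseBetaBP = 0, bmdSnpIndex = 0L, betaGB = 0,
                        sdProtein = 1, sdBMD = 1, seed = 42L) {
  new("LocusConfig", nIndividuals = as.integer(nIndividuals),
      haplotypes = haplotypes, hapFreqs = hapFreqs,
      causalSnpIndex = as.integer(causalSnpIndex), betaGP = betaGP,
      betaPB = betaPB, alpha0 = alpha0, betaBF = betaBF,
      reverseBetaBP = reverseBetaBP,
      bmdSnpIndex = as.integer(bmdSnpIndex), betaGB = betaGB,
      sdProtein = sdProtein, sdBMD = sdBMD, seed = as.integer(seed))
}

#' Read a locus configuration from a YAML or key-value file
#'
#' Fields are the arguments of [locusConfig()]; omitted fields take the
#' defaults.
#'
#' @param path path to a YAML file.
#' @return a [LocusConfig-class].
#' @export
readLocusConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(locusConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(locusConfig, vals)
}

.poolMatrix <- function(haplotypes) {
  m <- do.call(rbind, lapply(strsplit(haplotypes, "", fixed = TRUE),
                             as.integer))
  colnames(m) <- paste0("snp", seq_len(ncol(m)))
  m
}

#' Pool-implied allele frequencies and pairwise LD
#'
#' `poolAlleleFreqs` returns the frequency of the '1' allele at every
#' variant implied by the haplotype pool; `poolLD` the exact two-locus LD
#' summaries ([ldFromHaplotypeFreqs()]) between two variants.
#'
#' @param haplotypes haplotype pool (0/1 strings).
#' @param hapFreqs haplotype frequencies.
#' @param i,j variant indices (1-based).
#' @return `poolAlleleFreqs`: numeric vector; `poolLD`: see
#'   [ldFromHaplotypeFreqs()].
#' @export
poolAlleleFreqs <- function(haplotypes, hapFreqs) {
  H <- .poolMatrix(haplotypes)
  as.numeric(crossprod(H, hapFreqs))
}

#' @rdname poolAlleleFreqs
#' @export
poolLD <- function(haplotypes, hapFreqs, i, j) {
  H <- .poolMatrix(haplotypes)
  ai <- H[, i]; aj <- H[, j]
  ldFromHaplotypeFreqs(sum(hapFreqs[ai == 1 & aj == 1]),
                       sum(hapFreqs[ai == 1 & aj == 0]),
                       sum(hapFreqs[ai == 0 & aj == 1]),
                       sum(hapFreqs[ai == 0 & aj == 0]))
}

#' Generate a random haplotype pool with decaying LD
#'
#' Founder haplotypes are built as a two-state Markov chain along the
#' variants: each haplotype's allele at variant m copies its allele at
#' variant m-1 with probability `1 - switchProb`, so nearby variants are
#' correlated and LD decays with distance. Monomorphic variants are
#' repaired by flipping one haplotype. Haplotype frequencies are drawn from
#' a symmetric Dirichlet.
#'
#' @param nSnps number of variants.
#' @param nHaplotypes pool size (default 20).
#' @param switchProb per-step allele switch probability (default 0.1).
#' @param seed RNG seed.
#' @return list with `haplotypes` (0/1 strings) and `freqs`.
#' @export
randomHaplotypePool <- function(nSnps, nHaplotypes = 20L,
                                switchProb = 0.1, seed = 1L) {
  stopifnot(nSnps >= 1L, nHaplotypes >= 2L,
            switchProb > 0, switchProb < 1)
  withSeed(seed, {
    H <- matrix(0L, nHaplotypes, nSnps)
    H[, 1] <- stats::rbinom(nHaplotypes, 1L, 0.5)
    if (nSnps > 1L)
      for (m in 2:nSnps) {
        flip <- stats::rbinom(nHaplotypes, 1L, switchProb)
        H[, m] <- ifelse(flip == 1L, 1L - H[, m - 1], H[, m - 1])
      }
    for (m in seq_len(nSnps)) {
      if (all(H[, m] == H[1, m]))
        H[sample(nHaplotypes, 1L), m] <- 1L - H[1, m]
    }
    f <- stats::rgamma(nHaplotypes, shape = 2)
    f <- f / sum(f)
    list(haplotypes = apply(H, 1, paste, collapse = ""), freqs = f)
  })
}

#' Simulate a cohort from a cis-locus configuration
#'
#' Each individual receives two haplotypes drawn independently from the
#' pool (so genotypes are in Hardy-Weinberg proportions with the pool's LD
#' structure). Phenotypes follow the structural model
#' \preformatted{
#'   bmdExog  = betaGB * g_bmd + N(0, sdBMD)
#'   protein  = betaGP * g_causal + reverseBetaBP * bmdExog
#'              + N(0, sdProtein)
#'   bmd      = betaPB * protein + bmdExog
#'   fracture ~ Bernoulli(plogis(alpha0 + betaBF * bmd))
#' }
#' where `bmdExog` is the feedback-free BMD component, so a nonzero
#' `reverseBetaBP` injects reverse (BMD -> protein) causation without a
#' feedback loop. The draw is fully reproducible from `config@seed`.
#'
#' @param config a [LocusConfig-class].
#' @return a [Cohort-class].
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "LocusConfig"))
  validObject(config)
  H <- .poolMatrix(config@haplotypes)
  if (sum(config@hapFreqs > 0) < 2L)
    stop("degenerate haplotype pool: every variant would be monomorphic",
         call. = FALSE)
  n <- config@nIndividuals
  withSeed(config@seed, {
    i1 <- sample.int(nrow(H), n, replace = TRUE, prob = config@hapFreqs)
    i2 <- sample.int(nrow(H), n, replace = TRUE, prob = config@hapFreqs)
    g <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
    gB <- if (config@bmdSnpIndex > 0L) g[, config@bmdSnpIndex] else 0
    bmdExog <- config@betaGB * gB + stats::rnorm(n, 0, config@sdBMD)
    protein <- config@betaGP * g[, config@causalSnpIndex] +
      config@reverseBetaBP * bmdExog +
      stats::rnorm(n, 0, config@sdProtein)
    bmd <- config@betaPB * protein + bmdExog
    fracture <- stats::rbinom(n, 1L,
                              stats::plogis(config@alpha0 +
                                            config@betaBF * bmd))
    new("Cohort", genotypes = g, protein = as.numeric(protein),
        bmd = as.numeric(bmd), fracture = as.integer(fracture))
  })
}

## Closed-form simple linear regression of y on x (slope, SE, normal p).
.linearAssoc <- function(x, y, n = length(y)) {
  xm <- mean(x)
  sxx <- sum(x * x) - n * xm * xm
  if (sxx <= 0) return(c(beta = NA_real_, se = NA_real_, pval = NA_real_))
  ym <- mean(y)
  sxy <- sum(x * y) - n * xm * ym
  syy <- sum(y * y) - n * ym * ym
  beta <- sxy / sxx
  sigma2 <- max(syy - beta * sxy, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  c(beta = beta, se = se, pval = twoSidedP(beta, se))
}

## Per-variant logistic regression via IRLS (epsilon 1e-8, up to 50
## iterations); separation or non-convergence yields a flagged (NA-se) row.
.logisticAssoc <- function(x, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                control = stats::glm.control(
                                  epsilon = 1e-8, maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(c(beta = NA_real_, se = NA_real_, pval = NA_real_))
  co <- summary(fit)$coefficients
  if (nrow(co) < 2L || !is.finite(co[2, 2]) || co[2, 2] > 100)
    return(c(beta = co[2, 1], se = NA_real_, pval = NA_real_))
  c(beta = co[2, 1], se = co[2, 2], pval = twoSidedP(co[2, 1], co[2, 2]))
}

#' Per-variant association summary statistics for a simulated cohort
#'
#' Computes one variant-trait association per polymorphic variant, in the
#' canonical summary-statistics table of [variantAssociation()].
#' Continuous traits (protein, BMD) are standardized to zero mean and unit
#' SD and regressed on allele count by simple linear regression, so betas
#' are in SD units per effect allele with two-sided normal p-values. The
#' binary fracture trait is fitted per variant by logistic regression
#' (iteratively reweighted least squares, tolerance 1e-8, at most 50
#' iterations); betas are on the log-odds scale, and variants where the fit
#' fails to converge or separates are returned with `se = NA` and a
#' warning. Monomorphic variants are skipped with a warning. The simulated
#' '1' allele is labelled `A`, the '0' allele `G`.
#'
#' @param cohort a [Cohort-class].
#' @param trait `"protein"`, `"bmd"` or `"fracture"`.
#' @return canonical summary-statistics data.frame, one row per usable
#'   variant.
#' @export
cohortSumstats <- function(cohort, trait = c("protein", "bmd",
                                             "fracture")) {
  stopifnot(is(cohort, "Cohort"))
  trait <- match.arg(trait)
  g <- cohort@genotypes
  n <- nrow(g)
  mono <- apply(g, 2, function(col) length(unique(col)) == 1L)
  if (any(mono)) {
    warning("skipping monomorphic variant(s): ",
            paste(colnames(g)[mono], collapse = ", "), call. = FALSE)
    g <- g[, !mono, drop = FALSE]
  }
  if (ncol(g) == 0L)
    stop("no polymorphic variants in the cohort", call. = FALSE)

  if (trait == "fracture") {
    y <- cohort@fracture
    est <- t(apply(g, 2, .logisticAssoc, y = y))
    if (any(is.na(est[, "se"])))
      warning("logistic fit failed to converge (or separated) for: ",
              paste(rownames(est)[is.na(est[, "se"])], collapse = ", "),
              call. = FALSE)
    traitType <- "case_control"
    nCases <- sum(y == 1L); nControls <- sum(y == 0L)
  } else {
    y <- if (trait == "protein") cohort@protein else cohort@bmd
    y <- (y - mean(y)) / stats::sd(y)
    est <- t(apply(g, 2, .linearAssoc, y = y, n = n))
    traitType <- "quantitative"
    nCases <- NA_real_; nControls <- NA_real_
  }
  data.frame(snp = colnames(g), effect_allele = "A", other_allele = "G",
             eaf = as.numeric(colMeans(g) / 2),
             beta = est[, "beta"], se = est[, "se"], pval = est[, "pval"],
             n = n, n_cases = nCases, n_controls = nControls,
             trait = trait, trait_type = traitType,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Model-implied standardized protein-to-BMD effect
#'
#' The MR estimand on the scale of [cohortSumstats()] (both traits
#' standardized) is `betaPB * sd(protein) / sd(bmd)`. Both SDs follow in
#' closed form from the configuration, using the exact pool-implied
#' genotype variances and covariance (Hardy-Weinberg, independent
#' haplotype draws). This equals the Wald/IVW estimand at the causal
#' variant provided that variant has no pathway to BMD other than the
#' protein (i.e. `betaGB = 0` or zero pool LD between the causal and the
#' direct-BMD variant).
#'
#' @param config a [LocusConfig-class].
#' @return the standardized protein -> BMD effect.
#' @export
impliedTrueEffect <- function(config) {
  stopifnot(is(config, "LocusConfig"))
  f <- poolAlleleFreqs(config@haplotypes, config@hapFreqs)
  fA <- f[config@causalSnpIndex]
  varGa <- 2 * fA * (1 - fA)
  if (config@bmdSnpIndex > 0L && config@betaGB != 0) {
    fB <- f[config@bmdSnpIndex]
    varGb <- 2 * fB * (1 - fB)
    dd <- poolLD(config@haplotypes, config@hapFreqs,
                 config@causalSnpIndex, config@bmdSnpIndex)$d
    covG <- 2 * dd
  } else {
    varGb <- 0; covG <- 0
  }
  varExog <- config@betaGB^2 * varGb + config@sdBMD^2
  covGaExog <- config@betaGB * covG
  varP <- config@betaGP^2 * varGa +
    config@reverseBetaBP^2 * varExog +
    2 * config@betaGP * config@reverseBetaBP * covGaExog +
    config@sdProtein^2
  covPExog <- config@betaGP * covGaExog + config@reverseBetaBP * varExog
  varB <- config@betaPB^2 * varP + varExog + 2 * config@betaPB * covPExog
  config@betaPB * sqrt(varP / varB)
}

#' Parameter-recovery experiment for the MR pipeline
#'
#' Repeatedly simulates a cohort, computes protein and BMD summary
#' statistics at the causal variant, runs MR (Wald ratio or IVW), and
#' compares the estimate with the model-implied standardized protein ->
#' BMD effect ([impliedTrueEffect()]). Replicate r uses seed
#' `config@seed + r`.
#'
#' @param config a [LocusConfig-class] with nonzero `betaGP`.
#' @param nReplicates number of simulated cohorts.
#' @param estimator `"wald"` or `"ivw"` (identical at a single
#'   instrument).
#' @param level confidence level for the coverage assessment.
#' @return list with `trueEffect`, `bias` (mean estimate minus truth),
#'   `rmse`, `coverage` (fraction of CIs covering the truth), `mcse`
#'   (Monte-Carlo SE of the mean estimate), and the per-replicate
#'   `estimates` and `ses`.
#' @export
recoveryExperiment <- function(config, nReplicates = 100L,
                               estimator = c("wald", "ivw"),
                               level = 0.95) {
  stopifnot(is(config, "LocusConfig"))
  estimator <- match.arg(estimator)
  if (config@betaGP == 0)
    stop("recovery requires a nonzero variant -> protein effect",
         call. = FALSE)
  truth <- impliedTrueEffect(config)
  z <- zQuantile(level)
  est <- se <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    cfg <- config
    cfg@seed <- config@seed + r
    cohort <- simulateCohort(cfg)
    x <- cohort@genotypes[, config@causalSnpIndex]
    p <- (cohort@protein - mean(cohort@protein)) / stats::sd(cohort@protein)
    b <- (cohort@bmd - mean(cohort@bmd)) / stats::sd(cohort@bmd)
    ap <- .linearAssoc(x, p)
    ab <- .linearAssoc(x, b)
    # first-order Wald ratio at the single causal instrument (what ivwMR
    # reduces to); kept inline so replicates stay cheap
    est[r] <- ab[["beta"]] / ap[["beta"]]
    se[r] <- ab[["se"]] / abs(ap[["beta"]])
  }
  cover <- mean(truth >= est - z * se & truth <= est + z * se)
  list(trueEffect = truth, bias = mean(est) - truth,
       rmse = sqrt(mean((est - truth)^2)), coverage = cover,
       mcse = stats::sd(est) / sqrt(nReplicates),
       estimates = est, ses = se, estimator = estimator)
}

#' @rdname cohort-accessors
#' @export
setMethod("genotypes", "Cohort", function(x) x@genotypes)

#' @rdname cohort-accessors
#' @export
setMethod("phenotypes", "Cohort", function(x)
  data.frame(protein = x@protein, bmd = x@bmd, fracture = x@fracture))

setMethod("show", "Cohort", function(object) {
  cat("Cohort:", nrow(object@genotypes), "individuals,",
      ncol(object@genotypes), "variants\n")
  cat(sprintf("  fracture prevalence %.3f; protein SD %.3f; BMD SD %.3f\n",
              mean(object@fracture), stats::sd(object@protein),
              stats::sd(object@bmd)))
})

setMethod("show", "LocusConfig", function(object) {
  cat("LocusConfig:", object@nIndividuals, "individuals,",
      nchar(object@haplotypes[1]), "variants,",
      length(object@haplotypes), "pool haplotypes\n")
  cat(sprintf(paste0("  causal variant %d: betaGP = %.3g; betaPB = %.3g;",
                     " betaBF = %.3g; alpha0 = %.3g\n"),
              object@causalSnpIndex, object@betaGP, object@betaPB,
              object@betaBF, object@alpha0))
  if (object@reverseBetaBP != 0)
    cat("  reverse BMD -> protein effect:", object@reverseBetaBP, "\n")
  if (object@bmdSnpIndex > 0L)
    cat("  direct BMD variant", object@bmdSnpIndex, "with betaGB =",
        object@betaGB, "\n")
  cat("  seed:", object@seed, "\n")
})
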