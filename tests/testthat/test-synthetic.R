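test_that("simulation is bit-identical under a fixed seed", {
  cfg <- locusConfig(nIndividuals = 500, seed = 77)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(genotypes(a), genotypes(b))
  expect_identical(phenotypes(a), phenotypes(b))
  c2 <- simulateCohort(locusConfig(nIndividuals = 500, seed = 78))
  expect_false(identical(phenotypes(a)$protein, phenotypes(c2)$protein))
})

test_that("simulated allele frequencies match the pool", {
  cfg <- locusConfig(nIndividuals = 10000, seed = 8)
  cohort <- simulateCohort(cfg)
  fPool <- poolAlleleFreqs(cfg@haplotypes, cfg@hapFreqs)
  fObs <- colMeans(genotypes(cohort)) / 2
  # 2n haplotype draws per variant
  se <- sqrt(fPool * (1 - fPool) / (2 * cfg@nIndividuals))
  expect_true(all(abs(fObs - fPool) < 3 * se))
})

test_that("genotype LD matches the closed-form pool LD", {
  cfg <- locusConfig(nIndividuals = 10000, seed = 9)
  g <- genotypes(simulateCohort(cfg))
  for (pair in list(c(3, 4), c(1, 3), c(2, 3))) {
    pool <- poolLD(cfg@haplotypes, cfg@hapFreqs, pair[1], pair[2])
    # under HWE the genotype correlation estimates the haplotype r
    rObs <- cor(g[, pair[1]], g[, pair[2]])
    expect_lt(abs(rObs^2 - pool$r2), 0.04)
  }
})

test_that("a null model yields nominal type-I error across variants", {
  hits <- 0L; tests <- 0L
  for (r in 1:100) {
    cfg <- locusConfig(nIndividuals = 1000, betaGP = 0, betaPB = 0,
                       betaBF = 0, seed = 900 + r)
    cohort <- simulateCohort(cfg)
    for (tr in c("protein", "bmd", "fracture")) {
      ss <- cohortSumstats(cohort, tr)
      z <- ss$beta / ss$se
      hits <- hits + sum(abs(z) > 3.29, na.rm = TRUE)
      tests <- tests + sum(!is.na(z))
    }
  }
  # |z| > 3.29 is the two-sided 0.1% point; observed rate stays near it
  expect_lt(hits / tests, 0.004)
})

test_that("a trait equal to the allele count is a perfect association", {
  cfg <- locusConfig(nIndividuals = 1000, seed = 10)
  cohort <- simulateCohort(cfg)
  g <- genotypes(cohort)
  perfect <- new("Cohort", genotypes = g, protein = as.numeric(g[, 3]),
                 bmd = cohort@bmd, fracture = cohort@fracture)
  ss <- cohortSumstats(perfect, "protein")
  # after standardization the slope is 1/SD(allele count) and p ~ 0
  expect_equal(ss$beta[ss$snp == "snp3"], 1 / sd(g[, 3]),
               tolerance = 1e-8)
  expect_lt(ss$pval[ss$snp == "snp3"], 1e-200)
})

test_that("permuted traits give uniform association p-values", {
  cfg <- locusConfig(nIndividuals = 500, seed = 12)
  cohort <- simulateCohort(cfg)
  g <- genotypes(cohort)
  set.seed(13)
  p <- numeric(500)
  for (i in seq_len(500)) {
    perm <- new("Cohort", genotypes = g,
                protein = sample(cohort@protein), bmd = cohort@bmd,
                fracture = cohort@fracture)
    ss <- cohortSumstats(perm, "protein")
    p[i] <- ss$pval[ss$snp == "snp3"]
  }
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("logistic summary statistics match an independent Newton fit", {
  # 20-row hand-checkable dataset
  x <- c(0, 0, 0, 1, 1, 1, 2, 2, 0, 1, 2, 0, 1, 1, 0, 2, 1, 0, 1, 0)
  y <- c(0, 0, 1, 0, 1, 1, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 1, 0, 0, 0)
  g <- cbind(snp1 = x, snp2 = c(rep(0:1, 10)))
  cohort <- new("Cohort", genotypes = g, protein = rnorm(20),
                bmd = rnorm(20), fracture = as.integer(y))
  ss <- cohortSumstats(cohort, "fracture")
  oracle <- newtonLogistic(x, y)
  expect_equal(ss$beta[ss$snp == "snp1"], oracle[["beta"]],
               tolerance = 1e-6)
  expect_equal(ss$se[ss$snp == "snp1"], oracle[["se"]], tolerance = 1e-6)
  expect_identical(ss$trait_type[1], "case_control")
  expect_equal(ss$n_cases[1], sum(y))
})

test_that("separated logistic fits are flagged rather than reported", {
  g <- cbind(snp1 = c(rep(0L, 10), rep(2L, 10)),
             snp2 = rep(0:1, 10))
  cohort <- new("Cohort", genotypes = g, protein = rnorm(20),
                bmd = rnorm(20),
                fracture = c(rep(0L, 10), rep(1L, 10)))  # separation
  expect_warning(ss <- cohortSumstats(cohort, "fracture"),
                 "converge|separated")
  expect_true(is.na(ss$se[ss$snp == "snp1"]))
})

test_that("monomorphic variants are skipped with a warning", {
  cfg <- locusConfig(nIndividuals = 50, haplotypes = c("01", "11"),
                     hapFreqs = c(0.5, 0.5), causalSnpIndex = 1,
                     seed = 14)
  cohort <- simulateCohort(cfg)
  expect_warning(ss <- cohortSumstats(cohort, "protein"), "monomorphic")
  expect_false("snp2" %in% ss$snp)
})

test_that("continuous summary statistics agree with lm", {
  cfg <- locusConfig(nIndividuals = 400, seed = 15)
  cohort <- simulateCohort(cfg)
  ss <- cohortSumstats(cohort, "bmd")
  y <- scale(phenotypes(cohort)$bmd)[, 1]
  for (j in c(1, 3, 6)) {
    fit <- summary(lm(y ~ genotypes(cohort)[, j]))$coefficients
    row <- ss[ss$snp == paste0("snp", j), ]
    expect_equal(row$beta, fit[2, 1], tolerance = 1e-10)
    expect_equal(row$se, fit[2, 2], tolerance = 1e-10)
  }
})

test_that("null protein->BMD effect is recovered as zero", {
  cfg <- locusConfig(nIndividuals = 2000, betaPB = 0, seed = 100)
  rec <- recoveryExperiment(cfg, nReplicates = 200)
  expect_identical(rec$trueEffect, 0)
  expect_lt(abs(rec$bias), 2 * rec$mcse)
})

test_that("RMSE shrinks like 1/sqrt(n)", {
  r1 <- recoveryExperiment(locusConfig(nIndividuals = 2000, seed = 200),
                           nReplicates = 200)
  r2 <- recoveryExperiment(locusConfig(nIndividuals = 4000, seed = 300),
                           nReplicates = 200)
  expect_gt(r2$rmse / r1$rmse, 0.6)
  expect_lt(r2$rmse / r1$rmse, 0.85)
})

test_that("configuration round-trips through a YAML file", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("nIndividuals: 123", "seed: 9", "betaGP: 0.4",
               "causalSnpIndex: 2"), f)
  cfg <- readLocusConfig(f)
  expect_identical(cfg@nIndividuals, 123L)
  expect_identical(cfg@causalSnpIndex, 2L)
  expect_equal(cfg@betaGP, 0.4)
  writeLines(c("nIndividuals: 10", "bogus: 1"), f)
  expect_error(readLocusConfig(f), "unknown configuration")
})

test_that("degenerate haplotype pools are rejected", {
  expect_error(locusConfig(haplotypes = c("0101"), hapFreqs = 1),
               "at least two")
  expect_error(simulateCohort(
    locusConfig(haplotypes = c("01", "10"), hapFreqs = c(1, 0),
                causalSnpIndex = 1)), "degenerate")
})

test_that("random haplotype pools are polymorphic with decaying LD", {
  pool <- randomHaplotypePool(30, nHaplotypes = 25, seed = 5)
  f <- poolAlleleFreqs(pool$haplotypes, pool$freqs)
  expect_true(all(f > 0 & f < 1))
  expect_equal(sum(pool$freqs), 1, tolerance = 1e-12)
  near <- poolLD(pool$haplotypes, pool$freqs, 10, 11)$r2
  far <- poolLD(pool$haplotypes, pool$freqs, 1, 30)$r2
  expect_gt(near, far)
})
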