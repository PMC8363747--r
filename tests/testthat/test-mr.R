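pqtl <- variantAssociation("rs3734626", "T", "C", eaf = 0.56,
                           beta = 0.325, se = 0.023,
                           trait = "circulating_rspo3")

test_that("Wald ratio reproduces the published fracture and vBMD cells", {
  fr <- variantAssociation("rs3734626", "T", "C", or = 0.94,
                           ci_low = 0.93, ci_high = 0.95, pval = 1.8e-20,
                           trait = "fracture_any_site",
                           trait_type = "case_control")
  res <- waldRatio(harmonize(pqtl, fr))
  expect_identical(res@outcomeScale, "log_odds")
  expect_equal(round(toORScale(res)[["or"]], 2), 0.83)

  tb <- variantAssociation("rs3734626", "T", "C", beta = 0.092,
                           se = 0.028, pval = 9.4e-4,
                           trait = "trabecular_vbmd")
  res2 <- waldRatio(harmonize(pqtl, tb))
  expect_equal(round(mrBeta(res2), 2), 0.28)
  expect_equal(round(mrSE(res2), 2), 0.09)
  expect_equal(mrBeta(res2), 0.283076923077, tolerance = 1e-9)
  expect_equal(mrSE(res2), 0.086153846154, tolerance = 1e-9)
})

test_that("a null outcome gives a null ratio with p = 1", {
  pr <- pairsFromRatios(b = 0, v = 0.01, exposureBeta = 0.4)
  res <- waldRatio(pr)
  expect_identical(mrBeta(res), 0)
  expect_identical(mrPval(res), 1)
})

test_that("first-order Wald preserves the outcome Z and p", {
  ou <- qtAssoc("rs1", beta = 0.06, se = 0.02)
  ex <- qtAssoc("rs1", beta = 0.3, se = 0.04)
  res <- waldRatio(harmonize(ex, ou))
  # |Z| identical to the outcome association's
  expect_equal(abs(mrBeta(res) / mrSE(res)), abs(0.06 / 0.02),
               tolerance = 1e-12)
  expect_equal(mrPval(res), 2 * pnorm(-3), tolerance = 1e-12)
  # a stored outcome p-value is carried through unchanged
  ou2 <- variantAssociation("rs1", "A", "G", beta = 0.06, se = 0.02,
                            pval = 2.9e-3)
  res2 <- waldRatio(harmonize(ex, ou2))
  expect_identical(mrPval(res2), 2.9e-3)
  # ... but not under the second-order standard error
  res3 <- waldRatio(harmonize(ex, ou2), seMode = "second_order")
  expect_equal(mrPval(res3), 2 * pnorm(-abs(mrBeta(res3) / mrSE(res3))),
               tolerance = 1e-12)
})

test_that("second-order SE adds the delta-method exposure term", {
  be <- 0.3; seE <- 0.04; bo <- 0.06; seO <- 0.02
  res <- waldRatio(harmonize(qtAssoc("rs1", be, seE),
                             qtAssoc("rs1", bo, seO)),
                   seMode = "second_order")
  expect_equal(mrSE(res),
               sqrt(seO^2 / be^2 + bo^2 * seE^2 / be^4),
               tolerance = 1e-12)
  expect_gt(mrSE(res),
            mrSE(waldRatio(harmonize(qtAssoc("rs1", be, seE),
                                     qtAssoc("rs1", bo, seO)))))
})

test_that("a zero exposure effect is rejected", {
  nullExposure <- new("InstrumentPairs",
                      exposure = qtAssoc("rs1", 0, 0.1),
                      outcome = qtAssoc("rs1", 0.1, 0.1),
                      harmonized = TRUE)
  expect_error(waldRatio(nullExposure), "undefined|zero")
  expect_error(waldRatio(new("InstrumentPairs",
                             exposure = qtAssoc("rs1", 0.3, 0.1),
                             outcome = qtAssoc("rs1", 0.1, 0.1),
                             harmonized = FALSE)),
               "not harmonized")
})

test_that("IVW with one instrument equals the Wald ratio in every field", {
  pr <- pairsFromRatios(b = 0.25, v = 0.02, exposureBeta = 0.33)
  w <- waldRatio(pr)
  iv <- ivwMR(pr)
  for (f in c("betaMR", "seMR", "ciLow", "ciHigh", "pval", "level"))
    expect_identical(slot(iv, f), slot(w, f))
  expect_identical(iv@method, "ivw")
  expect_true(is.na(iv@qStat))
})

test_that("two opposite equal-precision instruments cancel", {
  cc <- 0.3; v <- 0.01
  iv <- ivwMR(pairsFromRatios(b = c(cc, -cc), v = c(v, v)))
  expect_equal(mrBeta(iv), 0, tolerance = 1e-12)
  expect_equal(qStats(iv)[["q_stat"]], 2 * cc^2 / v, tolerance = 1e-12)
  expect_identical(qStats(iv)[["q_df"]], 1)
})

test_that("three-instrument IVW matches the hand-computed sums", {
  iv <- ivwMR(pairsFromRatios(b = c(0.2, 0.3, 0.1),
                              v = c(0.01, 0.04, 0.01)))
  # weights 100, 25, 100: beta = 37.5/225, se = 1/15, Q = 1 on 2 df
  expect_equal(mrBeta(iv), 0.1666666667, tolerance = 1e-9)
  expect_equal(mrSE(iv), 0.0666666667, tolerance = 1e-9)
  expect_equal(qStats(iv)[["q_stat"]], 1.0, tolerance = 1e-9)
  expect_equal(qStats(iv)[["q_pval"]], 0.60653066, tolerance = 1e-7)
})

test_that("IVW estimate is scale-equivariant and bracketed by the ratios", {
  set.seed(21)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    b <- rnorm(m, 0.2, 0.3)
    v <- runif(m, 0.005, 0.05)
    ex <- qtAssoc(paste0("rs", 1:m), beta = runif(m, 0.2, 0.5),
                  se = runif(m, 0.01, 0.05))
    ou <- qtAssoc(paste0("rs", 1:m), beta = b * ex$beta,
                  se = sqrt(v) * ex$beta)
    iv <- ivwMR(harmonize(ex, ou))
    expect_gte(mrBeta(iv), min(b) - 1e-12)
    expect_lte(mrBeta(iv), max(b) + 1e-12)
    # rescale the exposure by c > 0
    cc <- runif(1, 0.5, 3)
    ex2 <- ex; ex2$beta <- ex$beta * cc; ex2$se <- ex$se * cc
    iv2 <- ivwMR(harmonize(ex2, ou))
    expect_equal(mrBeta(iv2), mrBeta(iv) / cc, tolerance = 1e-10)
    expect_equal(mrSE(iv2), mrSE(iv) / cc, tolerance = 1e-10)
    expect_equal(mrPval(iv2), mrPval(iv), tolerance = 1e-10)
  }
})

test_that("odds-ratio presentation inverts the log-odds scale", {
  fr <- variantAssociation("rs2489623", "C", "T", or = 0.89,
                           ci_low = 0.86, ci_high = 0.92,
                           trait = "fracture_distal_forearm",
                           trait_type = "case_control")
  ex <- variantAssociation("rs2489623", "C", "T", beta = 0.270,
                           se = 0.025, trait = "circulating_rspo3")
  res <- waldRatio(harmonize(ex, fr))
  expect_equal(round(toORScale(res)[["or"]], 2), 0.65)

  mk <- function(beta, se) {
    pr <- harmonize(
      variantAssociation("rs1", "A", "G", beta = 1, se = 0.1),
      variantAssociation("rs1", "A", "G", beta = beta, se = se,
                         trait_type = "case_control"))
    waldRatio(pr)
  }
  z <- qnorm(0.975)
  orci <- toORScale(mk(log(2), 0.1))
  expect_equal(orci[["or"]], 2, tolerance = 1e-12)
  expect_equal(orci[["ci_low"]], 2 * exp(-z * 0.1), tolerance = 1e-12)
  expect_equal(orci[["ci_high"]], 2 * exp(z * 0.1), tolerance = 1e-12)
  # null effect maps to OR exactly 1; linear results have no OR scale
  expect_identical(toORScale(mk(0, 0.1))[["or"]], 1)
  lin <- waldRatio(harmonize(qtAssoc("rs1", 1, 0.1),
                             qtAssoc("rs1", 0.2, 0.1)))
  expect_error(toORScale(lin), "linear")
})

test_that("bidirectional MR is a pair of IVW runs", {
  fwd <- pairsFromRatios(b = c(0.2, 0.25), v = c(0.01, 0.02))
  rev <- pairsFromRatios(b = c(0.01, -0.02), v = c(0.01, 0.02))
  bi <- bidirectionalMR(fwd, rev)
  expect_identical(mrBeta(bi$forward), mrBeta(ivwMR(fwd)))
  expect_identical(mrBeta(bi$reverse), mrBeta(ivwMR(rev)))
  # identical inputs give identical results
  same <- bidirectionalMR(fwd, fwd)
  expect_identical(mrBeta(same$forward), mrBeta(same$reverse))
  # single-instrument lists reduce to Wald ratios
  f1 <- pairsFromRatios(0.3, 0.01)
  bi1 <- bidirectionalMR(f1, f1)
  expect_identical(mrBeta(bi1$forward), mrBeta(waldRatio(f1)))
})

test_that("bidirectional MR on a simulated causal chain finds no reverse effect", {
  # two exactly independent variants: one drives the protein, one drives
  # BMD directly, so each direction has a valid instrument
  pool <- list(h = c("11", "10", "01", "00"),
               f = c(0.275, 0.225, 0.275, 0.225))
  nrep <- 40
  fwdEst <- revP <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- locusConfig(nIndividuals = 8000, haplotypes = pool$h,
                       hapFreqs = pool$f, causalSnpIndex = 2,
                       bmdSnpIndex = 1, betaGB = 0.3, betaPB = 0.3,
                       seed = 5000 + r)
    cohort <- simulateCohort(cfg)
    sp <- cohortSumstats(cohort, "protein")
    sb <- cohortSumstats(cohort, "bmd")
    bi <- bidirectionalMR(
      harmonize(sp[sp$snp == "snp2", ], sb[sb$snp == "snp2", ]),
      harmonize(sb[sb$snp == "snp1", ], sp[sp$snp == "snp1", ]))
    fwdEst[r] <- mrBeta(bi$forward)
    revP[r] <- mrPval(bi$reverse)
    if (r == 1) truth <- impliedTrueEffect(cfg)
  }
  expect_lt(abs(mean(fwdEst) - truth), 0.02)
  expect_lt(abs(mean(fwdEst) - 0.3), 0.05)
  expect_gte(mean(revP > 0.05), 0.9)
})
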