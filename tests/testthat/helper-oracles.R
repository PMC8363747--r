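# Independent oracles used to check package computations. These stay
# deliberately naive (direct sums, plain Newton iterations) and share no
# code with the implementation.

# Colocalization posterior probabilities by direct (non-log) summation
# over all single-variant configurations. Feasible for small |labf|.
bruteColoc <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  B1 <- exp(labf1)
  B2 <- exp(labf2)
  m <- length(B1)
  w3 <- 0
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (i != j) w3 <- w3 + B1[i] * B2[j]
  w <- c(H0 = 1,
         H1 = p1 * sum(B1),
         H2 = p2 * sum(B2),
         H3 = p1 * p2 * w3,
         H4 = p12 * sum(B1 * B2))
  pp <- w / sum(w)
  names(pp) <- paste0("PP.", names(w))
  pp
}

# Logistic regression of y on x by straight Newton-Raphson on the
# log-likelihood; returns slope and its standard error.
newtonLogistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W)
    step <- solve(H, crossprod(X, y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  c(beta = unname(b[2]), se = unname(se[2]))
}

# Quantitative variant association row without a stored p-value (so MR
# p-values are recomputed from Z rather than carried through).
qtAssoc <- function(snp, beta, se, ea = "A", oa = "G", eaf = NA_real_,
                    trait = "qt") {
  variantAssociation(snp, ea, oa, eaf = eaf, beta = beta, se = se,
                     trait = trait, trait_type = "quantitative")
}

# Harmonized InstrumentPairs carrying prescribed per-instrument Wald
# ratios b_i and first-order variances v_i (exposure beta fixed at 1).
pairsFromRatios <- function(b, v, exposureBeta = 1) {
  snp <- paste0("rs", seq_along(b))
  ex <- qtAssoc(snp, beta = rep(exposureBeta, length(b)),
                se = rep(0.1, length(b)), trait = "exposure")
  ou <- qtAssoc(snp, beta = b * exposureBeta,
                se = sqrt(v) * abs(exposureBeta), trait = "outcome")
  harmonize(ex, ou)
}
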