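test_that("restricted likelihood matches the error-contrast oracle", {
  for (seed in 1:3) {
    inst <- gremlInstance(n = 25, m = 40, h2 = 0.5, seed = seed)
    # compare likelihood differences: the contrast route carries a
    # theta-free constant relative to the profile form
    pars <- list(c(0.5, 0.5), c(0.2, 0.9), c(1.3, 0.4))
    ours <- vapply(pars, function(p)
      remlLogLik(p[1], p[2], inst$y, inst$X, inst$A), 0)
    oracle <- vapply(pars, function(p)
      remlContrastLogLik(p[1], p[2], inst$y, inst$X, inst$A), 0)
    expect_equal(diff(ours), diff(oracle), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("sigma_g^2 = 0 reduces to the fixed-effects-only model", {
  inst <- gremlInstance(n = 30, m = 50, h2 = 0.5, seed = 4)
  llA <- remlLogLik(0, 0.7, inst$y, inst$X, inst$A)
  llI <- remlLogLik(0, 0.7, inst$y, inst$X, matrix(0, 30, 30))
  expect_equal(llA, llI, tolerance = 1e-10)
  # singular V is an error
  expect_error(remlLogLik(1, 0, inst$y, inst$X,
                          tcrossprod(inst$Z[, 1:5]) / 5), "positive definite")
})

test_that("EM and AI iterations never decrease the restricted likelihood", {
  for (seed in 5:8) {
    inst <- gremlInstance(n = 120, m = 150, h2 = 0.4, seed = seed)
    fit <- fitUnivariateGREML(inst$y, inst$X, inst$A)
    expect_true(fit@converged)
    expect_true(all(diff(fit@loglik) >= -1e-8))
  }
})

test_that("GREML recovers the generating heritability", {
  inst <- gremlInstance(n = 800, m = 1000, h2 = 0.6, seed = 9)
  fit <- fitUnivariateGREML(inst$y, inst$X, inst$A)
  expect_true(fit@converged)
  expect_lt(abs(fit@h2 - 0.6), 3 * fit@seH2)
  expect_gt(fit@seH2, 0)
  # final likelihood agrees with the dense Cholesky evaluation
  expect_equal(tail(fit@loglik, 1),
               remlLogLik(fit@sigmaG2, fit@sigmaE2, inst$y, inst$X, inst$A),
               tolerance = 1e-6)
})

test_that("estimates are invariant to shifting y and reparameterizing X", {
  inst <- gremlInstance(n = 200, m = 250, h2 = 0.5, seed = 10)
  f0 <- fitUnivariateGREML(inst$y, inst$X, inst$A, tol = 1e-9)
  f1 <- fitUnivariateGREML(inst$y + 100, inst$X, inst$A, tol = 1e-9)
  X2 <- inst$X %*% matrix(c(2, 1, 0, -3), 2, 2)    # invertible recombination
  f2 <- fitUnivariateGREML(inst$y, X2, inst$A, tol = 1e-9)
  expect_equal(f0@h2, f1@h2, tolerance = 1e-6)
  expect_equal(f0@h2, f2@h2, tolerance = 1e-6)
  expect_equal(f0@sigmaG2, f2@sigmaG2, tolerance = 1e-6)
})

test_that("SNP-effects model and GRM model are the same likelihood surface", {
  inst <- gremlInstance(n = 150, m = 100, h2 = 0.5, seed = 11)
  m <- 100
  fA <- fitUnivariateGREML(inst$y, inst$X, inst$A, tol = 1e-10)
  # V = ZZ' sigma_u^2 + I sigma_e^2 corresponds to A* = ZZ' = M * A, with
  # sigma_g^2 = M sigma_u^2 and h2 = M sigma_u^2 / (M sigma_u^2 + sigma_e^2)
  fZ <- fitUnivariateGREML(inst$y, inst$X, tcrossprod(inst$Z), tol = 1e-10)
  sigmaG2FromU <- m * fZ@sigmaG2
  expect_equal(fA@sigmaG2, sigmaG2FromU, tolerance = 1e-6)
  expect_equal(fA@h2, sigmaG2FromU / (sigmaG2FromU + fZ@sigmaE2),
               tolerance = 1e-7)
  expect_equal(tail(fA@loglik, 1), tail(fZ@loglik, 1), tolerance = 1e-8)
})

test_that("an identity GRM is flagged as unidentifiable", {
  set.seed(12)
  n <- 60
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  expect_warning(fitUnivariateGREML(y, X, diag(n)), "identifiable")
  expect_error(fitUnivariateGREML(y, cbind(X, X[, 2]), diag(n)),
               "rank deficient")
})

test_that("estimator is unbiased over replicates", {
  h2hat <- se <- numeric(30)
  for (r in seq_len(30)) {
    inst <- gremlInstance(n = 200, m = 300, h2 = 0.5, seed = 100 + r)
    fit <- fitUnivariateGREML(inst$y, inst$X, inst$A)
    h2hat[r] <- fit@h2
  }
  mcse <- sd(h2hat) / sqrt(30)
  expect_lt(abs(mean(h2hat) - 0.5), 2 * mcse + 0.02)
})

test_that("BLUP of additive effects matches the closed-form equation", {
  inst <- gremlInstance(n = 20, m = 30, h2 = 0.5, seed = 13)
  fit <- fitUnivariateGREML(inst$y, inst$X, inst$A)
  g <- blupAdditive(fit, inst$y, inst$X, inst$A)
  # independent dense evaluation of sigma_g^2 A V^-1 (y - X beta)
  V <- inst$A * fit@sigmaG2 + diag(fit@sigmaE2, 20)
  gOracle <- fit@sigmaG2 * inst$A %*% solve(V) %*%
    (inst$y - inst$X %*% fit@beta)
  expect_equal(unname(g), unname(drop(gOracle)), tolerance = 1e-10)

  # zero genetic variance: g is identically zero
  fit0 <- fit; fit0@sigmaG2 <- 0
  expect_true(all(blupAdditive(fit0, inst$y, inst$X, inst$A) == 0))
  expect_error(blupAdditive(fit, inst$y[-1], inst$X, inst$A), "mismatch")
})

test_that("BLUP recovers true additive values at moderate scale", {
  inst <- gremlInstance(n = 800, m = 1000, h2 = 0.6, seed = 14)
  fit <- fitUnivariateGREML(inst$y, inst$X, inst$A)
  g <- blupAdditive(fit, inst$y, inst$X, inst$A)
  expect_gt(cor(g, inst$g), 0.3)
})

test_that("SNP-effect BLUPs satisfy Z a = g and sigma_u^2 = sigma_g^2 / M", {
  inst <- gremlInstance(n = 150, m = 120, h2 = 0.5, seed = 15)
  fit <- fitUnivariateGREML(inst$y, inst$X, inst$A)
  g <- blupAdditive(fit, inst$y, inst$X, inst$A)
  a <- blupSnpEffects(fit, inst$Z, inst$y, inst$X, A = inst$A)
  expect_equal(drop(inst$Z %*% a), unname(g), tolerance = 1e-8)
  # an inconsistent GRM is rejected
  expect_error(blupSnpEffects(fit, inst$Z, inst$y, inst$X,
                              A = inst$A + 0.01), "inconsistent")
  # a pure-noise phenotype yields near-zero effects
  set.seed(16)
  yNull <- rnorm(150)
  fitN <- suppressWarnings(fitUnivariateGREML(yNull, inst$X, inst$A))
  aN <- blupSnpEffects(fitN, inst$Z, yNull, inst$X)
  expect_lt(mean(abs(aN)), 0.05)
})
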