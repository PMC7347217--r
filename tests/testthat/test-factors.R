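# factor-structured multivariate normal sample
simFactorData <- function(n, loadings, phi = NULL, seed = 1) {
  k <- ncol(loadings)
  if (is.null(phi)) phi <- diag(k)
  withr::with_seed(seed, {
    f <- matrix(rnorm(n * k), n) %*% chol(phi)
    u <- sqrt(pmax(1 - rowSums((loadings %*% phi) * loadings), 1e-6))
    f %*% t(loadings) + matrix(rnorm(n * nrow(loadings)), n) %*% diag(u)
  })
}

test_that("kaiser rule retains no factors from an identity matrix", {
  expect_equal(kaiserRetain(diag(10)), 0)
  m <- pafExtract(diag(10))
  expect_equal(m@nFactors, 0L)
  expect_equal(m@eigenvalues, rep(1, 10))
})

test_that("principal axis factoring recovers a one-factor structure", {
  L <- matrix(0.8, 5, 1)
  X <- simFactorData(5000, L, seed = 51)
  m <- pafExtract(cor(X))
  expect_equal(m@nFactors, 1L)
  expect_equal(unname(m@loadings[, 1]), rep(0.8, 5), tolerance = 0.05)
  expect_equal(unname(m@communalities), rep(0.64, 5), tolerance = 0.08)
  expect_true(m@converged)
})

test_that("variance explained equals the reduced-matrix eigenvalue share", {
  L <- cbind(c(rep(0.7, 4), rep(0, 4)), c(rep(0, 4), rep(0.6, 4)))
  X <- simFactorData(2000, L, seed = 52)
  R <- cor(X)
  m <- pafExtract(R, nFactors = 2)
  Rr <- R; diag(Rr) <- m@communalities
  ev <- eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(m@varianceExplained), ev[1:2] / nrow(R),
               tolerance = 1e-8)
  expect_equal(colSums(m@loadings^2) / nrow(R), m@varianceExplained)
})

test_that("paf rejects invalid input and flags non-convergence", {
  expect_error(pafExtract(matrix(c(1, 2, 2, 1), 2)), "semidefinite")
  expect_error(pafExtract(matrix(1:6, 2, 3)), "symmetric")
  L <- matrix(0.8, 5, 1)
  X <- simFactorData(500, L, seed = 53)
  expect_warning(pafExtract(cor(X), nFactors = 1, maxIter = 2L),
                 "did not converge")
})

test_that("promax keeps simple structure and detects factor correlation", {
  # perfect simple structure: loadings unchanged up to sign/permutation
  L <- cbind(c(rep(0.8, 4), rep(0, 4)), c(rep(0, 4), rep(0.7, 4)))
  X <- simFactorData(5000, L, seed = 54)
  m <- promaxRotate(pafExtract(cor(X), nFactors = 2))
  big <- abs(m@loadings) > 0.3
  expect_equal(colSums(big), c(F1 = 4, F2 = 4))
  expect_equal(m@rotation, "promax")
  # orthogonal truth: factor correlation near zero
  expect_lt(max(abs(m@factorCorr[upper.tri(m@factorCorr)])), 0.1)
  # correlated truth: inter-factor r recovered
  phi <- matrix(c(1, .4, .4, 1), 2)
  Xc <- simFactorData(5000, L, phi = phi, seed = 55)
  mc <- promaxRotate(pafExtract(cor(Xc), nFactors = 2))
  expect_equal(abs(mc@factorCorr[1, 2]), 0.4, tolerance = 0.1)
  # single factor: identity rotation
  m1 <- pafExtract(cor(simFactorData(500, matrix(0.8, 5, 1), seed = 56)),
                   nFactors = 1)
  expect_equal(promaxRotate(m1)@loadings, m1@loadings)
})

test_that("model reconstruction approximates the correlation matrix", {
  L <- cbind(c(rep(0.75, 5), rep(0, 5)), c(rep(0, 5), rep(0.65, 5)))
  phi <- matrix(c(1, .3, .3, 1), 2)
  X <- simFactorData(3000, L, phi = phi, seed = 57)
  R <- cor(X)
  m <- promaxRotate(pafExtract(R, nFactors = 2))
  rec <- m@loadings %*% m@factorCorr %*% t(m@loadings)
  diag(rec) <- 1
  expect_lte(max(abs(rec - R)), 0.1)
})

test_that("regression and Bartlett scores agree and have known variance", {
  L <- cbind(c(rep(0.9, 5), rep(0, 5)), c(rep(0, 5), rep(0.9, 5)))
  X <- simFactorData(4000, L, seed = 58)
  m <- promaxRotate(pafExtract(cor(X), nFactors = 2))
  sr <- factorScores(X, m, "regression")
  sb <- factorScores(X, m, "bartlett")
  expect_true(all(diag(cor(sr, sb)) > 0.9))
  # Bartlett scores are conditionally unbiased: variance 1 + estimation
  # error, close to 1 for high-communality designs
  expect_equal(unname(apply(sb, 2, var)), c(1, 1), tolerance = 0.1)
  # closed-form check of the Bartlett error variance 1/(L' Psi^-1 L)
  errVar <- 1 / (5 * 0.9^2 / (1 - 0.9^2))
  expect_equal(unname(apply(sb, 2, var)), rep(1 + errVar, 2),
               tolerance = 0.1)
  # orthonormal-loading toy case: both methods coincide up to scaling
  I3 <- diag(3)
  toyM <- new("FactorModel", loadings = I3 * sqrt(0.999),
              communalities = rep(0.999, 3), factorCorr = diag(3),
              eigenvalues = rep(1, 3), varianceExplained = rep(0.333, 3),
              nFactors = 3L, rotation = "none", converged = TRUE)
  set.seed(59)
  toyX <- matrix(rnorm(6000), 2000)
  s1 <- factorScores(toyX, toyM, "regression")
  s2 <- factorScores(toyX, toyM, "bartlett")
  # weights coincide up to scaling as n grows (sample R -> identity)
  expect_true(all(abs(diag(cor(s1, s2)) - 1) < 1e-2))
})

test_that("the kaiser rule recovers nine planted factors at survey scale", {
  L <- ninefactorLoadings()
  X <- simFactorData(1189, L, seed = 60)
  k <- kaiserRetain(cor(X))
  expect_gte(k, 8); expect_lte(k, 10)
  m <- promaxRotate(pafExtract(cor(X)))
  sr <- factorScores(X, m, "regression")
  sb <- factorScores(X, m, "bartlett")
  expect_true(all(diag(cor(sr, sb)) > 0.9))
})
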