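test_that("closed-form ridge agrees with a numerical-optimization oracle", {
  set.seed(12)
  X <- matrix(rnorm(60), 20)
  y <- ifelse(rowSums(X) + rnorm(20) > 0, 1, -1)
  for (alpha in c(0.1, 1, 100)) {
    fit <- twinherit:::.ridgeFit(X, y, alpha)
    loss <- function(par) {
      sum((y - par[1] - X %*% par[-1])^2) + alpha * sum(par[-1]^2)
    }
    opt <- optim(rep(0, 4), loss, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(unname(c(fit$b, fit$w)), opt$par, tolerance = 1e-5)
  }
  # shrinkage: coefficient norm decreases monotonically in alpha
  norms <- sapply(c(0.01, 1, 100, 1e4, 1e6), function(a)
    sqrt(sum(twinherit:::.ridgeFit(X, y, a)$w^2)))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 1e-3)
})

test_that("univariate weights rank features by isolation signal", {
  set.seed(13)
  n <- 200
  lab <- rep(c(1, -1), each = n / 2)
  sep <- ifelse(lab == 1, 0.2, 2) + runif(n, 0, 0.1)   # separating feature
  flat <- runif(n, 0, 1)                               # uninformative
  ps <- makePairset(cbind(sep = sep, flat = flat), lab)
  w <- univariateWeights(ps, runConfig(nIterations = 20, seed = 2))
  expect_gt(w$mean[w$feature == "sep"], w$mean[w$feature == "flat"])
  expect_lt(w$mean[w$feature == "flat"], 0.2)
  # informative features carry negative raw slopes: MZ differences are
  # smaller and MZ is the +1 class
  expect_lt(w$mean_signed[w$feature == "sep"], 0)
})

test_that("ridge accuracy is at chance on a zero-heritability cohort", {
  specs <- varianceSpecs(sprintf("m%02d", 1:12), e2 = 1)
  ch <- simulateCohort(cohortDesign(12, 150, 90, seed = 120), specs)
  ps <- buildPairFeatures(ch)
  r <- ridgeClassify(ps, runConfig(nIterations = 300, seed = 5,
                                   strictSplit = TRUE), alpha = 100)
  expect_lt(abs(r$performance$meanAccuracy - 0.5), 0.02)
  # the reference protocol (oversample before the split) leaks duplicated
  # minority rows into the test side and sits above chance even with no
  # signal -- the reason chance-level checks use the strict split
  rLeak <- ridgeClassify(ps, runConfig(nIterations = 100, seed = 5),
                         alpha = 100)
  expect_gt(rLeak$performance$meanAccuracy, 0.5)
  expect_true(r$performance$ci95[1] < 0.5 & r$performance$ci95[2] > 0.5)
})

test_that("the most heritable measure earns the top ridge weight", {
  a2 <- c(0.8, rep(0, 5))
  specs <- varianceSpecs(sprintf("m%02d", 1:6), a2 = a2, e2 = 1 - a2)
  ch <- simulateCohort(cohortDesign(6, 250, 150, seed = 121), specs)
  ps <- buildPairFeatures(ch)
  r <- ridgeClassify(ps, runConfig(nIterations = 40, nAlphaIterations = 15,
                                   seed = 6))
  expect_equal(which.max(r$weights$mean), 1L)
  expect_true(r$alpha %in% runConfig()@alphaGrid)
  expect_equal(sum(r$alphaCounts), 15)
})

test_that("random forest importances normalize and detect chance", {
  specs <- varianceSpecs(sprintf("m%02d", 1:6), e2 = 1)
  ch <- simulateCohort(cohortDesign(6, 80, 50, seed = 122), specs)
  ps <- buildPairFeatures(ch)
  f <- rfClassify(ps, runConfig(nIterations = 60, seed = 7,
                                strictSplit = TRUE))
  expect_equal(sum(f$weights$mean), 1, tolerance = 1e-10)
  expect_lt(abs(f$performance$meanAuc - 0.5), 0.07)
  expect_lt(abs(f$performance$meanAccuracy - 0.5), 0.07)
})

test_that("random forest finds variance-coded signal that ridge cannot", {
  set.seed(14)
  n <- 400
  lab <- rep(c(1, -1), each = n / 2)
  # equal class means, different spread: linearly inseparable
  f1 <- ifelse(lab == 1, runif(n, 0.9, 1.1),
               ifelse(runif(n) < 0.5, runif(n, 0, 0.2), runif(n, 1.8, 2)))
  noise <- matrix(runif(n * 3), n)
  ps <- makePairset(cbind(f1, noise), lab)
  cfg <- runConfig(nIterations = 40, seed = 8)
  rf <- rfClassify(ps, cfg)
  rd <- ridgeClassify(ps, cfg, alpha = 1)
  expect_gt(rf$performance$meanAccuracy, rd$performance$meanAccuracy + 0.15)
  expect_equal(which.max(rf$weights$mean), 1L)
})

test_that("duplicated feature columns share their weight", {
  a2 <- c(0.7, 0.5, 0.2, 0)
  specs <- varianceSpecs(sprintf("m%d", 1:4), a2 = a2, e2 = 1 - a2)
  ch <- simulateCohort(cohortDesign(4, 300, 200, seed = 123), specs)
  ps <- buildPairFeatures(ch)
  dup <- makePairset(cbind(ps@features, m1copy = ps@features[, 1]),
                     ps@labels)
  cfg <- runConfig(nIterations = 25, seed = 9)
  rd <- ridgeClassify(dup, cfg, alpha = 10)
  w1 <- rd$weights$mean[rd$weights$feature == "m1"]
  w2 <- rd$weights$mean[rd$weights$feature == "m1copy"]
  expect_lt(abs(w1 - w2) / max(w1, w2), 0.1)

  rfSingle <- rfClassify(ps, cfg)
  rfDup <- rfClassify(dup, cfg)
  single <- rfSingle$weights$mean[rfSingle$weights$feature == "m1"]
  split2 <- sum(rfDup$weights$mean[rfDup$weights$feature %in%
                                     c("m1", "m1copy")])
  expect_lt(abs(split2 - single), 0.15)
})

test_that("haufe transform maps weights to activation patterns", {
  w <- c(1, 0)
  expect_equal(haufeTransform(w, diag(2))$pattern, w)
  expect_equal(haufeTransform(w, matrix(c(1, .5, .5, 1), 2))$pattern,
               c(1, 0.5))
  # suppressor: f2 carries no signal but cancels noise shared with f1;
  # its decoder weight is large, its activation pattern small
  set.seed(15)
  n <- 2000
  s <- rnorm(n); noise <- rnorm(n)
  f1 <- s + noise; f2 <- noise
  X <- cbind(f1, f2)
  fit <- twinherit:::.ridgeFit(X, s, 0.01)
  expect_gt(abs(fit$w[2]), 0.5)      # big suppressor weight
  p <- haufeTransform(fit$w, cov(X))
  expect_lt(p$absPattern[2], 0.2 * abs(fit$w[2]))
  expect_gt(p$absPattern[1], p$absPattern[2])
  expect_error(haufeTransform(c(1, 2, 3), diag(2)), "dimension")
})

test_that("performance summaries follow the bootstrap p rules", {
  s <- summarizePerformance(rep(0.5, 10))
  expect_equal(s$bootstrapP, 1)        # "equal to or lower than" counts ties
  s <- summarizePerformance(c(0.4, 0.6, 0.6, 0.6))
  expect_equal(s$bootstrapP, 0.25)
  s <- summarizePerformance(runif(1000, 0.6, 0.9))
  expect_equal(s$bootstrapP, 0.001)    # reported as "< 1/n"
  expect_false(s$pExact)
  expect_true(s$ci95[1] <= s$ci95[2])
  s <- summarizePerformance(c(0.6, 0.7), aucs = c(0.8, 0.9))
  expect_equal(s$meanAuc, 0.85)
})

test_that("classifier runs are bit-reproducible from the seed", {
  ps <- signalPairset(a2 = c(0.6, 0.3, 0), nMZ = 60, nDZ = 40, seed = 16)
  cfg <- runConfig(nIterations = 10, nAlphaIterations = 5, seed = 17)
  expect_identical(ridgeClassify(ps, cfg), ridgeClassify(ps, cfg))
  expect_identical(rfClassify(ps, cfg), rfClassify(ps, cfg))
  expect_identical(univariateWeights(ps, cfg), univariateWeights(ps, cfg))
})

test_that("oob tuning shows plateau, depth underfit and mtry ordering", {
  # strongly inter-correlated features via shared genetic factors
  G <- matrix(0.95, 16, 16); diag(G) <- 1
  specs <- varianceSpecs(sprintf("m%d", 1:16), a2 = 0.6, e2 = 0.4)
  ch <- simulateCohort(cohortDesign(16, 100, 70, geneticCorr = G,
                                    seed = 124), specs)
  ps <- buildPairFeatures(ch)
  tune <- rfTune(ps, nTreesGrid = c(20L, 100L), depthGrid = c(1L, 5L),
                 nReps = 25L, seed = 18)
  tab <- tune$table
  oob <- function(param, value, mf)
    tab$oob_accuracy[tab$param == param & tab$value %in% value &
                       tab$max_features == mf]
  # more trees never hurts beyond noise
  expect_gte(oob("n_trees", 100, "sqrt"), oob("n_trees", 20, "sqrt") - 0.02)
  # a depth-1 stump underfits relative to depth 5
  expect_lt(oob("max_depth", 1, "sqrt"), oob("max_depth", 5, "sqrt"))
  # considering all features at every split decorrelates the trees least
  # and is the worst policy when features are correlated (trees sweep,
  # unlimited depth)
  expect_lt(oob("n_trees", 100, "all"), oob("n_trees", 100, "sqrt"))
  expect_lt(oob("n_trees", 100, "all"), oob("n_trees", 100, "log2"))
  expect_true(tune$recommended$maxFeatures %in% c("sqrt", "log2"))
})
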