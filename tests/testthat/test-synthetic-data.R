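test_that("expected twin correlations follow the component sharing rules", {
  cases <- list(
    list(a2 = .5, c2 = .2, d2 = 0, e2 = .3, rMZ = 0.7, rDZ = 0.45),
    list(a2 = 0, c2 = 0, d2 = 0, e2 = 1, rMZ = 0, rDZ = 0),
    list(a2 = .4, c2 = 0, d2 = .2, e2 = .4, rMZ = 0.6, rDZ = 0.25)
  )
  for (cs in cases) {
    sp <- varianceSpecs("m", a2 = cs$a2, c2 = cs$c2, d2 = cs$d2, e2 = cs$e2)
    ex <- expectedTwinCorrelations(sp)
    expect_equal(ex$rMZ, cs$rMZ)
    expect_equal(ex$rDZ, cs$rDZ)
  }
})

test_that("variance spec invariants are enforced", {
  expect_error(varianceSpecs("m", a2 = 0.5, e2 = 0.4), "sum to 1")
  expect_error(varianceSpecs("m", a2 = 0.2, c2 = 0.3, d2 = 0.2, e2 = 0.3),
               "ACE or ADE")
  expect_error(varianceSpecs("m", a2 = -0.1, e2 = 1.1), "non-negative")
  expect_error(varianceSpecs("m", e2 = 1, reliability = 0), "reliability")
  expect_error(varianceSpecs(c("m", "m"), e2 = 1), "unique")
})

test_that("design validation rejects bad correlation matrices", {
  bad <- matrix(c(1, 2, 2, 1), 2)        # not a correlation (off-diag > 1,
  expect_error(cohortDesign(2, 10, 10, geneticCorr = bad), "semidefinite")
  asym <- matrix(c(1, .2, .4, 1), 2)
  expect_error(cohortDesign(2, 10, 10, geneticCorr = asym), "symmetric")
  expect_error(cohortDesign(2, 10, 10, nRetest = 100), "nRetest")
})

test_that("within-pair correlations converge to the sharing coefficients", {
  # pure additive: 1.0 within MZ, 0.5 within DZ
  spA <- varianceSpecs("m", a2 = 1, e2 = 0)
  chA <- simulateCohort(cohortDesign(1, 5000, 5000, seed = 11), spA)
  tcA <- twinCorrelations(chA)
  expect_gt(tcA$rMZ, 0.9999)
  expect_lt(abs(tcA$rDZ - 0.5), 0.02)

  # pure dominance: 1.0 within MZ, 0.25 within DZ
  spD <- varianceSpecs("m", d2 = 1, e2 = 0)
  chD <- simulateCohort(cohortDesign(1, 2000, 5000, seed = 12), spD)
  tcD <- twinCorrelations(chD)
  expect_gt(tcD$rMZ, 0.9999)
  expect_lt(abs(tcD$rDZ - 0.25), 0.02)

  # pure unique environment: uncorrelated for both zygosities
  spE <- varianceSpecs("m", e2 = 1)
  chE <- simulateCohort(cohortDesign(1, 5000, 5000, seed = 13), spE)
  tcE <- twinCorrelations(chE)
  expect_equal(tcE$rMZ, 0, tolerance = 0.05)
  expect_equal(tcE$rDZ, 0, tolerance = 0.05)

  # mixed ACE / ADE specs within 3 standard errors at 5000 pairs
  specs <- varianceSpecs(c("ace", "ade"), a2 = c(.5, .4), c2 = c(.2, 0),
                         d2 = c(0, .2), e2 = c(.3, .4))
  ch <- simulateCohort(cohortDesign(2, 5000, 5000, seed = 14), specs)
  tc <- twinCorrelations(ch)
  ex <- expectedTwinCorrelations(specs)
  se <- function(r) (1 - r^2) / sqrt(5000)
  expect_true(all(abs(tc$rMZ - ex$rMZ) < 3 * se(ex$rMZ)))
  expect_true(all(abs(tc$rDZ - ex$rDZ) < 3 * se(ex$rDZ)))
})

test_that("retest correlation converges to the reliability target", {
  specs <- varianceSpecs(c("hi", "lo"), a2 = 0.4, e2 = 0.6,
                         reliability = c(0.9, 0.6))
  ch <- simulateCohort(cohortDesign(2, 300, 200, nUnrelated = 200,
                                    nRetest = 1000, seed = 21), specs)
  rt <- retestMatrix(ch)
  rel <- retestReliability(phenoMatrix(ch)[rownames(rt), ], rt)
  expect_equal(unname(rel), c(0.9, 0.6), tolerance = 0.03)
})

test_that("cross-measure genetic correlation is imposed on A components", {
  G <- matrix(c(1, .6, .6, 1), 2)
  specs <- varianceSpecs(c("a", "b"), a2 = 1, e2 = 0)
  ch <- simulateCohort(cohortDesign(2, 0, 0, nUnrelated = 10000,
                                    geneticCorr = G, seed = 22), specs)
  # with a2 = 1 the phenotype IS the A component
  expect_equal(cor(phenoMatrix(ch))[1, 2], 0.6, tolerance = 0.03)
})

test_that("identical seed and design reproduce the cohort bit-exactly", {
  specs <- varianceSpecs(c("x", "y"), a2 = .3, e2 = .7, reliability = .8)
  d <- cohortDesign(2, 30, 20, nUnrelated = 10, nRetest = 15, seed = 33)
  c1 <- simulateCohort(d, specs)
  c2 <- simulateCohort(d, specs)
  expect_identical(phenoMatrix(c1), phenoMatrix(c2))
  expect_identical(retestMatrix(c1), retestMatrix(c2))
  expect_identical(subjectData(c1), subjectData(c2))
  c3 <- simulateCohort(cohortDesign(2, 30, 20, nUnrelated = 10,
                                    nRetest = 15, seed = 34), specs)
  expect_false(identical(phenoMatrix(c1), phenoMatrix(c3)))
})

test_that("twins share family id, age and sex; retest ids exist", {
  ch <- smallCohort()
  sd <- subjectData(ch)
  for (z in c("MZ", "DZ")) {
    pr <- twinPairs(ch, z)
    expect_true(all(sd$family_id[pr[, 1]] == sd$family_id[pr[, 2]]))
    expect_true(all(sd$sex[pr[, 1]] == sd$sex[pr[, 2]]))
    expect_true(all(sd$age[pr[, 1]] == sd$age[pr[, 2]]))
  }
  expect_true(all(rownames(retestMatrix(ch)) %in% sd$subject_id))
  expect_true(validObject(ch))
})

test_that("cohort CSV/JSON round trip preserves the data", {
  ch <- smallCohort(nMZ = 10, nDZ = 6, nNT = 4, nRetest = 5, M = 3,
                    reliability = 0.8)
  dir <- withr::local_tempdir()
  writeCohort(ch, dir)
  expect_setequal(list.files(dir),
                  c("phenotypes.csv", "retest.csv", "truth.json"))
  back <- readCohort(dir)
  expect_equal(phenoMatrix(back), phenoMatrix(ch), tolerance = 1e-12)
  expect_equal(retestMatrix(back), retestMatrix(ch), tolerance = 1e-12)
  expect_equal(subjectData(back), subjectData(ch))
  expect_equal(measureData(back)$a2, measureData(ch)$a2)
  expect_equal(geneticCorr(back), geneticCorr(ch))
})

test_that("covariate-effect recipe injects recoverable age/sex effects", {
  specs <- varianceSpecs("m", e2 = 1)
  ch <- simulateCohort(cohortDesign(1, 0, 0, nUnrelated = 1000, seed = 5),
                       specs, covariateEffects = list(age = 0.3))
  sd <- subjectData(ch)
  expect_gt(cor(phenoMatrix(ch)[, 1], sd$age), 0.5)
})
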