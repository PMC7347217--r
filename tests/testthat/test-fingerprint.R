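test_that("euclidean distance matches a brute-force oracle", {
  expect_equal(euclideanDistance(1:5, 1:5), 0)
  expect_equal(euclideanDistance(c(3, 4, rep(0, 35)), rep(0, 37)), 5)
  set.seed(10)
  for (i in 1:5) {
    p <- rnorm(37); q <- rnorm(37)
    brute <- 0
    for (j in 1:37) brute <- brute + (p[j] - q[j])^2
    expect_equal(euclideanDistance(p, q), sqrt(brute), tolerance = 1e-12)
    expect_equal(euclideanDistance(p, q), euclideanDistance(q, p))
  }
  expect_error(euclideanDistance(1:3, 1:4), "length")
})

test_that("identification ranks the true match pessimistically on ties", {
  cand <- rbind(a = c(0, 0), b = c(1, 0), c = c(2, 0))
  tgt <- rbind(t1 = c(0.1, 0))
  r <- identifyTargets(tgt, cand, truth = c(t1 = "a"))
  expect_equal(r@ranks, 1L)
  expect_equal(r@accuracy, 1)
  # tie with the true match counts as a failure (worst tied rank)
  tgt2 <- rbind(t1 = c(0.5, 0))
  r2 <- identifyTargets(tgt2, cand, truth = c(t1 = "a"))
  expect_equal(r2@ranks, 2L)
  expect_equal(r2@nCorrect, 0L)
  # single candidate is trivially rank 1
  r3 <- identifyTargets(tgt, cand[1, , drop = FALSE], truth = c(t1 = "a"))
  expect_equal(r3@accuracy, 1)
  expect_error(identifyTargets(tgt, cand, truth = c(t1 = "zz")), "absent")
})

test_that("noiseless retest gives perfect self-identification", {
  ch <- smallCohort(nMZ = 50, nDZ = 30, nNT = 40, nRetest = 30,
                    reliability = 1)
  r <- fingerprintSelf(ch, nPerm = 0)
  expect_equal(r@accuracy, 1)
  expect_equal(r@medianRank, 1)
})

test_that("scrambled truth maps drop accuracy to chance", {
  set.seed(20)
  n <- 400
  cand <- matrix(rnorm(n * 6), n, dimnames = list(sprintf("s%03d", 1:n)))
  tgt <- cand + matrix(rnorm(n * 6, sd = 0.1), n)
  rownames(tgt) <- rownames(cand)
  scram <- setNames(sample(rownames(cand)), rownames(tgt))
  r <- identifyTargets(tgt, cand, truth = scram)
  # chance level 1/n: expected ~1 correct out of 400
  expect_lt(r@accuracy, 0.02)
})

test_that("permutation null has the matching-problem mean and p-value rules", {
  ch <- smallCohort(nMZ = 40, nDZ = 30, nNT = 60, nRetest = 40,
                    reliability = 1, seed = 55)
  r <- fingerprintSelf(ch, nPerm = 1000, seed = 9)
  # observed (perfect) exceeds every permutation: reported < 1/1000
  expect_equal(r@pValue, 0.001)
  expect_false(r@pExact)
  # matching-problem expectation: shuffling a bijective truth map has one
  # fixed point on average, regardless of the number of targets
  expect_equal(mean(r@nullMaxCorrect), 1, tolerance = 0.15)
  # an observation of 0 correct has p = 1: every permutation count is >= 0
  cand <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  tgt <- rbind(t1 = c(0.1, 0))
  r0 <- permutationNull(tgt, cand, truth = c(t1 = "c"), nPerm = 200,
                        seed = 1)
  expect_equal(r0@nCorrect, 0L)
  expect_equal(r0@pValue, 1)
})

test_that("permutation p-values are super-uniform under a scrambled truth", {
  set.seed(30)
  n <- 60
  cand <- matrix(rnorm(n * 4), n, dimnames = list(sprintf("s%02d", 1:n)))
  ps <- replicate(60, {
    scram <- setNames(sample(rownames(cand)), rownames(cand))
    tgt <- cand + matrix(rnorm(n * 4, sd = 0.3), n)
    rownames(tgt) <- rownames(cand)
    permutationNull(tgt, cand, scram, nPerm = 100,
                    seed = sample.int(1e6, 1))@pValue
  })
  # under the null, P(p <= x) <= x (+ Monte Carlo slack)
  for (x in c(0.1, 0.25, 0.5))
    expect_lte(mean(ps <= x), x + 3 * sqrt(x * (1 - x) / 60))
})

test_that("self-identification degrades with retest noise, twin below self", {
  grid <- c(1.0, 0.8, 0.6, 0.4)
  accSelf <- sapply(1:3, function(s) {
    sapply(grid, function(rel) {
      ch <- smallCohort(nMZ = 80, nDZ = 50, nNT = 100, nRetest = 40,
                        a2 = 0.6, M = 8, reliability = rel, seed = 200 + s)
      fingerprintSelf(ch, nPerm = 0)@accuracy
    })
  })
  avg <- rowMeans(accSelf)
  expect_true(all(diff(avg) <= 0))
  expect_equal(avg[1], 1)

  # MZ-twin identification cannot beat self-identification when e2 > 0
  diffs <- sapply(1:3, function(s) {
    ch <- smallCohort(nMZ = 80, nDZ = 50, nNT = 100, nRetest = 40,
                      a2 = 0.6, M = 8, reliability = 1, seed = 300 + s)
    fingerprintSelf(ch, nPerm = 0)@accuracy -
      fingerprintTwin(ch, nPerm = 0)@accuracy
  })
  expect_gte(mean(diffs), 0)
})
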