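# shared simulation fixtures, built in code at test time

# small mixed-zygosity cohort with moderate heritability
smallCohort <- function(nMZ = 60, nDZ = 40, nNT = 20, nRetest = 20,
                        a2 = 0.5, c2 = 0, M = 4, reliability = 1,
                        seed = 101) {
  specs <- varianceSpecs(sprintf("m%02d", seq_len(M)), a2 = a2, c2 = c2,
                         e2 = 1 - a2 - c2, reliability = reliability,
                         domain = rep_len(c("task", "questionnaire"), M))
  simulateCohort(cohortDesign(M, nMZ, nDZ, nUnrelated = nNT,
                              nRetest = nRetest, seed = seed), specs)
}

# pair set with a graded additive-genetic signal across features
signalPairset <- function(a2 = seq(0, 0.8, length.out = 12), nMZ = 300,
                          nDZ = 200, seed = 7) {
  M <- length(a2)
  specs <- varianceSpecs(sprintf("m%02d", seq_len(M)), a2 = a2, e2 = 1 - a2)
  buildPairFeatures(
    simulateCohort(cohortDesign(M, nMZ, nDZ, seed = seed), specs))
}

# hand-built PairFeatureSet
makePairset <- function(features, labels) {
  new("PairFeatureSet", features = as.matrix(features), labels = labels,
      pairIds = sprintf("F%03d", seq_along(labels)))
}

# 37-measure, 9-factor loading plan mirroring a battery with ~4 indicators
# per latent construct
ninefactorLoadings <- function(loading = 0.75) {
  L <- matrix(0, 37, 9)
  idx <- rep(1:9, length.out = 37)
  for (j in 1:37) L[j, idx[j]] <- loading
  L
}
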