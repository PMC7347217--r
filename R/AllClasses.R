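#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor var sd qnorm pnorm lm coef residuals rnorm runif
#'   median quantile rbinom optim setNames complete.cases aggregate
#'   cov varimax predict
#' @importFrom utils head write.csv read.csv
NULL

#' TwinCohort: phenotypes plus twin-family structure
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a measures x
#' subjects phenotype matrix (assay `"phenotypes"`), subject metadata
#' (`subject_id`, `family_id`, `zygosity` in MZ/DZ/NT, `age`, `sex`) in
#' `colData`, and per-measure variance fractions (`a2`, `c2`, `d2`, `e2`,
#' `reliability`, `domain`) in `rowData`. Two extra slots carry the retest
#' occasion and the additive-genetic cross-measure correlation used by the
#' simulator.
#'
#' @slot retest matrix, measures x retest-subjects; column names are subject
#'   ids present in the cohort. May have zero columns.
#' @slot geneticCorr numeric matrix, the measures x measures correlation
#'   imposed on the additive genetic components (identity when unknown).
#'
#' @export
setClass("TwinCohort",
  contains = "SummarizedExperiment",
  slots = c(retest = "matrix", geneticCorr = "matrix")
)

setValidity("TwinCohort", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "family_id", "zygosity", "age", "sex")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  if (!all(cd$zygosity %in% c("MZ", "DZ", "NT")))
    msg <- c(msg, "zygosity must be one of MZ, DZ, NT")
  if (anyDuplicated(cd$subject_id))
    msg <- c(msg, "duplicated subject_id")
  ph <- SummarizedExperiment::assay(object, "phenotypes")
  if (anyNA(ph)) msg <- c(msg, "phenotypes contain missing values")
  for (z in c("MZ", "DZ")) {
    fams <- cd$family_id[cd$zygosity == z]
    if (length(fams) && any(table(fams) != 2L))
      msg <- c(msg, sprintf("%s families must contain exactly two subjects", z))
  }
  rt <- object@retest
  if (ncol(rt) > 0) {
    if (is.null(colnames(rt)) || !all(colnames(rt) %in% cd$subject_id))
      msg <- c(msg, "retest columns must be named by cohort subject ids")
    if (nrow(rt) != nrow(ph))
      msg <- c(msg, "retest must have one row per measure")
    if (anyNA(rt)) msg <- c(msg, "retest contains missing values")
  }
  g <- object@geneticCorr
  if (nrow(g) != nrow(ph) || ncol(g) != nrow(ph))
    msg <- c(msg, "geneticCorr dimension must equal the number of measures")
  rd <- SummarizedExperiment::rowData(object)
  needr <- c("a2", "c2", "d2", "e2", "reliability", "domain")
  if (!all(needr %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(needr, collapse = ", ")))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' PairFeatureSet: twin-pair absolute difference features
#'
#' One row per twin pair of absolute z-scored phenotype differences, with
#' class labels +1 (MZ) and -1 (DZ). This is the input to the MZ-vs-DZ
#' classifiers whose feature weights serve as qualitative heritability
#' estimates.
#'
#' @slot features numeric matrix, pairs x measures, all entries >= 0.
#' @slot labels numeric vector in \{+1, -1\}: +1 = MZ, -1 = DZ.
#' @slot pairIds character vector of family ids, one per row.
#' @export
setClass("PairFeatureSet",
  slots = c(features = "matrix", labels = "numeric", pairIds = "character")
)

setValidity("PairFeatureSet", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@features))
    msg <- c(msg, "one label per feature row required")
  if (length(object@pairIds) != nrow(object@features))
    msg <- c(msg, "one pair id per feature row required")
  if (!all(object@labels %in% c(-1, 1)))
    msg <- c(msg, "labels must be +1 (MZ) or -1 (DZ)")
  if (any(object@features < 0))
    msg <- c(msg, "absolute-difference features must be non-negative")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' IdentificationResult: fingerprinting outcome
#'
#' Result of nearest-neighbour identification of targets among candidates:
#' per-target competition ranks of the true match (distance ties resolved
#' pessimistically), accuracy = fraction ranked first, and optionally the
#' permutation null of the number correct.
#'
#' @slot nTargets integer.
#' @slot nCorrect integer, targets whose true match was the strict nearest.
#' @slot accuracy numeric fraction.
#' @slot ranks integer vector, rank of the true match per target.
#' @slot medianRank,meanRank numeric.
#' @slot nullMaxCorrect numeric, per-permutation number correct (empty when
#'   no permutation test was run).
#' @slot pValue numeric, permutation p-value (NA when not computed); never 0,
#'   reported as 1/n_perm with `pExact = FALSE` when no null draw reached the
#'   observed count.
#' @slot pExact logical, FALSE when pValue is the "< 1/n_perm" upper bound.
#' @export
setClass("IdentificationResult",
  slots = c(nTargets = "integer", nCorrect = "integer", accuracy = "numeric",
            ranks = "integer", medianRank = "numeric", meanRank = "numeric",
            nullMaxCorrect = "numeric", pValue = "numeric", pExact = "logical")
)

setValidity("IdentificationResult", function(object) {
  msg <- character()
  if (length(object@ranks) != object@nTargets)
    msg <- c(msg, "one rank per target required")
  if (any(object@ranks < 1L))
    msg <- c(msg, "ranks start at 1")
  if (object@nCorrect != sum(object@ranks == 1L))
    msg <- c(msg, "nCorrect must equal the number of rank-1 targets")
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GeneticCorrelationMatrix: bivariate genetic/environmental decomposition
#'
#' Genetic (`rhoG`), environmental (`rhoE`) and phenotypic (`rhoP`)
#' correlation matrices over measure pairs, with a logical `mask` marking
#' cells where the decomposition is undefined (heritability of either trait
#' outside (0,1)) and a log of clamping/truncation events.
#'
#' @slot rhoG,rhoE,rhoP numeric matrices.
#' @slot mask logical matrix, TRUE where the cell is undefined.
#' @slot events data.frame logging clamped rhoG cells and truncated h2
#'   inputs (columns: measure_a, measure_b, event, value).
#' @slot h2 numeric vector, the per-measure heritabilities used (after
#'   truncation), NA where out of range.
#' @export
setClass("GeneticCorrelationMatrix",
  slots = c(rhoG = "matrix", rhoE = "matrix", rhoP = "matrix",
            mask = "matrix", events = "data.frame", h2 = "numeric")
)

setValidity("GeneticCorrelationMatrix", function(object) {
  d <- dim(object@rhoG)
  if (!identical(d, dim(object@rhoE)) || !identical(d, dim(object@rhoP)) ||
      !identical(d, dim(object@mask)))
    return("rhoG, rhoE, rhoP and mask must share dimensions")
  ok <- !object@mask
  g <- object@rhoG[ok]
  if (length(g) && any(abs(g) > 1 + 1e-8))
    return("unmasked rhoG entries must lie in [-1, 1]")
  TRUE
})

#' FactorModel: exploratory factor analysis solution
#'
#' Loadings, communalities and factor correlations from principal axis
#' factoring, optionally Promax-rotated (oblique).
#'
#' @slot loadings numeric matrix, measures x factors (pattern matrix after
#'   oblique rotation).
#' @slot communalities numeric vector in [0, 1).
#' @slot factorCorr numeric matrix, factor x factor correlations (identity
#'   for unrotated/orthogonal solutions).
#' @slot eigenvalues numeric, descending eigenvalues of the *original*
#'   correlation matrix (the Kaiser/scree basis).
#' @slot varianceExplained numeric, sum of squared loadings per factor
#'   divided by the number of measures (computed before rotation).
#' @slot nFactors integer.
#' @slot rotation character: "none" or "promax".
#' @slot converged logical.
#' @export
setClass("FactorModel",
  slots = c(loadings = "matrix", communalities = "numeric",
            factorCorr = "matrix", eigenvalues = "numeric",
            varianceExplained = "numeric", nFactors = "integer",
            rotation = "character", converged = "logical")
)

setValidity("FactorModel", function(object) {
  msg <- character()
  if (ncol(object@loadings) != object@nFactors)
    msg <- c(msg, "loadings must have nFactors columns")
  if (any(object@communalities < -1e-8 | object@communalities >= 1 + 1e-8))
    msg <- c(msg, "communalities must lie in [0, 1)")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' RunConfig: classifier run configuration
#'
#' Iteration and hyper-parameter settings for the MZ-vs-DZ classification
#' pipeline. Defaults are the reference protocol: 1000 bootstrap iterations
#' of oversample / 70-30 split / fit, ridge alpha grid
#' (200, 100, 10, 1, 0.1, 0.01, 0.001), a 100-tree depth-5 random forest
#' with sqrt(M) features per split.
#'
#' @slot nIterations integer, bootstrap iterations.
#' @slot testFraction numeric in (0,1), held-out fraction per iteration.
#' @slot alphaGrid numeric, candidate ridge penalties (selection order =
#'   grid order on ties).
#' @slot nAlphaIterations integer, iterations of the alpha-selection phase.
#' @slot cvFolds integer, folds of the internal alpha-selection CV.
#' @slot rfTrees,rfMaxDepth integer.
#' @slot rfMaxFeatures character: "sqrt", "log2" or "all".
#' @slot strictSplit logical; FALSE (reference protocol) oversamples before
#'   the train/test split, so duplicated minority rows may appear on both
#'   sides and held-out accuracy absorbs a memorization component; TRUE
#'   splits the original pairs first and then balances each side
#'   separately, giving a leakage-free estimate whose chance level is
#'   exactly 50%.
#' @slot seed integer.
#' @export
setClass("RunConfig",
  slots = c(nIterations = "integer", testFraction = "numeric",
            alphaGrid = "numeric", nAlphaIterations = "integer",
            cvFolds = "integer", rfTrees = "integer", rfMaxDepth = "integer",
            rfMaxFeatures = "character", strictSplit = "logical",
            seed = "integer")
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must lie in (0, 1)")
  if (length(object@alphaGrid) == 0 || any(object@alphaGrid < 0))
    msg <- c(msg, "alphaGrid must be non-empty and non-negative")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (!object@rfMaxFeatures %in% c("sqrt", "log2", "all"))
    msg <- c(msg, "rfMaxFeatures must be sqrt, log2 or all")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn RunConfig-class Constructor with reference-protocol defaults.
#' @param nIterations,testFraction,alphaGrid,nAlphaIterations,cvFolds
#'   see slots.
#' @param rfTrees,rfMaxDepth,rfMaxFeatures,strictSplit,seed see slots.
#' @return A validated `RunConfig`.
#' @export
runConfig <- function(nIterations = 1000L, testFraction = 0.3,
                      alphaGrid = c(200, 100, 10, 1, 0.1, 0.01, 0.001),
                      nAlphaIterations = nIterations, cvFolds = 5L,
                      rfTrees = 100L, rfMaxDepth = 5L,
                      rfMaxFeatures = "sqrt", strictSplit = FALSE,
                      seed = 1L) {
  new("RunConfig", nIterations = as.integer(nIterations),
      testFraction = testFraction, alphaGrid = alphaGrid,
      nAlphaIterations = as.integer(nAlphaIterations),
      cvFolds = as.integer(cvFolds), rfTrees = as.integer(rfTrees),
      rfMaxDepth = as.integer(rfMaxDepth), rfMaxFeatures = rfMaxFeatures,
      strictSplit = strictSplit, seed = as.integer(seed))
}
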