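#' Column-wise z-scoring
#'
#' Standardizes every measure to zero mean and unit variance over the full
#' set of subjects supplied (the reference protocol scales over the whole
#' cohort before any train/test split; pass subsets explicitly for
#' split-safe scaling).
#'
#' @param x numeric matrix, subjects x measures.
#' @return Matrix of the same shape with each column at mean 0, sd 1.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("zscore needs at least 2 subjects")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Residualize measures on demographic covariates
#'
#' Per measure, the least-squares residual after regressing on the design
#' `[1, age, sex, age*sex, age^2, age^2*sex]` -- the covariate set used
#' before the genetic-correlation decomposition.
#'
#' @param x numeric matrix, subjects x measures.
#' @param age,sex numeric covariate vectors, one entry per subject.
#' @return Residual matrix of the same shape.
#' @export
residualize <- function(x, age, sex) {
  x <- as.matrix(x)
  if (length(age) != nrow(x) || length(sex) != nrow(x))
    stop("covariates must be present for all subjects")
  design <- cbind(intercept = 1, age = age, sex = sex, age_sex = age * sex,
                  age2 = age^2, age2_sex = age^2 * sex)
  q <- qr(design)
  if (q$rank < ncol(design)) {
    drop <- colnames(design)[q$pivot[(q$rank + 1):ncol(design)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  x - design %*% qr.coef(q, x)
}

#' Rank-based inverse normal (Blom) transform
#'
#' Maps values to normal quantiles of their ranks,
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, with average ranks for ties. The
#' transform is monotone in the input and yields an approximately standard
#' normal margin.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @return Transformed vector of the same length.
#' @examples
#' inverseNormalTransform(c(10, 20, 30))
#' @export
inverseNormalTransform <- function(values) {
  if (length(unique(values)) < 3)
    stop("inverse normal transform needs at least 3 distinct values")
  r <- rank(values, ties.method = "average")
  qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Build the twin-pair classification features
#'
#' One row per twin pair: the absolute difference of the two twins' full-
#' cohort z-scored phenotypes, per measure. MZ pairs are labelled +1, DZ
#' pairs -1. Swapping the twins within a pair leaves the row unchanged.
#'
#' @param cohort a [TwinCohort-class] with at least one pair of each
#'   zygosity.
#' @return A [PairFeatureSet-class].
#' @export
buildPairFeatures <- function(cohort) {
  z <- zscore(phenoMatrix(cohort))
  sd <- subjectData(cohort)
  mz <- twinPairs(cohort, "MZ"); dz <- twinPairs(cohort, "DZ")
  if (nrow(mz) == 0 || nrow(dz) == 0)
    stop("need at least one MZ and one DZ pair")
  rows <- rbind(mz, dz)
  feats <- abs(z[rows[, 1], , drop = FALSE] - z[rows[, 2], , drop = FALSE])
  rownames(feats) <- NULL
  new("PairFeatureSet", features = feats,
      labels = c(rep(1, nrow(mz)), rep(-1, nrow(dz))),
      pairIds = sd$family_id[rows[, 1]])
}

#' Pair features from an arbitrary score matrix
#'
#' Same construction as [buildPairFeatures()] but on externally supplied
#' subject scores (e.g. factor scores) with explicit subject metadata.
#'
#' @param scores subjects x features matrix, rows named/ordered as
#'   `subjects$subject_id`.
#' @param subjects data.frame with `subject_id`, `family_id`, `zygosity`.
#' @return A [PairFeatureSet-class].
#' @export
pairFeaturesFromScores <- function(scores, subjects) {
  cohort <- twinCohort(t(as.matrix(scores)),
                       data.frame(subject_id = subjects$subject_id,
                                  family_id = subjects$family_id,
                                  zygosity = subjects$zygosity,
                                  age = 0, sex = 0,
                                  stringsAsFactors = FALSE))
  buildPairFeatures(cohort)
}

#' Oversample the minority class to balance a PairFeatureSet
#'
#' Resamples the minority class with replacement until it matches the
#' majority count; majority rows are left untouched. With the reference
#' design (149 MZ / 90 DZ pairs) this brings the DZ class up to 149.
#'
#' @param pairset a [PairFeatureSet-class] with both classes present.
#' @param seed optional integer; when given, resampling is done under this
#'   seed without disturbing the caller's RNG stream.
#' @return A balanced [PairFeatureSet-class].
#' @export
oversampleBalance <- function(pairset, seed = NULL) {
  lab <- pairset@labels
  if (length(unique(lab)) < 2) stop("both classes must be present")
  nPlus <- sum(lab == 1); nMinus <- sum(lab == -1)
  if (nPlus == nMinus) return(pairset)
  minority <- if (nPlus < nMinus) 1 else -1
  nMaj <- max(nPlus, nMinus)
  minIdx <- which(lab == minority)
  draw <- function() minIdx[sample.int(length(minIdx), nMaj, replace = TRUE)]
  take <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  keep <- c(which(lab != minority), take)
  new("PairFeatureSet", features = pairset@features[keep, , drop = FALSE],
      labels = lab[keep], pairIds = pairset@pairIds[keep])
}

#' @describeIn PairFeatureSet-class compact summary.
#' @param object a `PairFeatureSet`.
#' @export
setMethod("show", "PairFeatureSet", function(object) {
  cat("PairFeatureSet:", nrow(object@features), "pairs x",
      ncol(object@features), "features (",
      sum(object@labels == 1), "MZ /", sum(object@labels == -1), "DZ )\n")
})

#' Write pair features as TSV
#'
#' Header `pair_id`, `label`, then one column per measure.
#'
#' @param pairset a [PairFeatureSet-class].
#' @param path output file.
#' @return Invisibly `path`.
#' @export
writePairFeatures <- function(pairset, path) {
  df <- cbind(data.frame(pair_id = pairset@pairIds, label = pairset@labels),
              as.data.frame(pairset@features))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
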