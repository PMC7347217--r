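#' Euclidean distance between two profile vectors
#'
#' Plain L2 distance \eqn{\sqrt{\sum_i (p_i - q_i)^2}} between two subjects'
#' standardized measure profiles.
#'
#' @param p,q numeric vectors of equal length.
#' @return Non-negative scalar; zero iff the profiles are identical.
#' @export
euclideanDistance <- function(p, q) {
  if (length(p) != length(q)) stop("profile lengths differ")
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("profiles must be finite")
  sqrt(sum((p - q)^2))
}

# targets x candidates distance matrix
.distanceMatrix <- function(targets, candidates) {
  tn <- rowSums(targets^2)
  cn <- rowSums(candidates^2)
  d2 <- outer(tn, cn, "+") - 2 * tcrossprod(targets, candidates)
  sqrt(pmax(d2, 0))
}

# per-target rank of the true candidate under pessimistic (worst tied
# rank) competition ranking; excludeSelf drops the candidate sharing the
# target's id
.identifyRanks <- function(D, truth, excludeSelf) {
  targets <- rownames(D)
  vapply(seq_along(targets), function(i) {
    d <- setNames(D[i, ], colnames(D))
    if (excludeSelf) d <- d[names(d) != targets[i]]
    dTrue <- d[[truth[[targets[i]]]]]
    sum(d <= dTrue)
  }, integer(1))
}

#' Identify targets among candidates by nearest profile
#'
#' For each target profile, candidate profiles are ranked by ascending
#' Euclidean distance and the rank of the true match recorded. Ranking is
#' strict competition ranking with pessimistic ties: a candidate tied with
#' the true match pushes it to the worst tied rank, so a tie at the minimum
#' counts as a failure. Accuracy is the fraction of targets whose true
#' match is the strict nearest candidate.
#'
#' For self-identification the target's own original profile stays among
#' the candidates; for co-twin identification set `excludeSelf = TRUE` so
#' the target subject is removed from the candidate pool (only the twin
#' remains to be found).
#'
#' @param targets numeric matrix (targets x measures) with rownames =
#'   target subject ids.
#' @param candidates numeric matrix (candidates x measures) with rownames =
#'   candidate subject ids.
#' @param truth named character vector mapping each target id to its true
#'   candidate id.
#' @param excludeSelf logical, drop the candidate named like the target.
#' @return An [IdentificationResult-class] (no permutation null; see
#'   [permutationNull()]).
#' @export
identifyTargets <- function(targets, candidates, truth, excludeSelf = FALSE) {
  targets <- as.matrix(targets); candidates <- as.matrix(candidates)
  if (is.null(rownames(targets)) || is.null(rownames(candidates)))
    stop("targets and candidates must have subject-id rownames")
  miss <- setdiff(truth[rownames(targets)], rownames(candidates))
  if (length(miss) || anyNA(truth[rownames(targets)]))
    stop("truth ids absent from candidates: ",
         paste(miss, collapse = ", "))
  D <- .distanceMatrix(targets, candidates)
  dimnames(D) <- list(rownames(targets), rownames(candidates))
  ranks <- .identifyRanks(D, truth, excludeSelf)
  nCorrect <- sum(ranks == 1L)
  new("IdentificationResult",
      nTargets = nrow(targets), nCorrect = nCorrect,
      accuracy = nCorrect / nrow(targets), ranks = ranks,
      medianRank = median(ranks), meanRank = mean(ranks),
      nullMaxCorrect = numeric(0), pValue = NA_real_, pExact = NA)
}

#' Permutation null for identification accuracy
#'
#' Shuffles the target-to-truth mapping `nPerm` times and recomputes the
#' number of correct (rank-1) identifications each time, giving the chance
#' distribution of the observed count. The p-value is
#' `#(null >= observed) / nPerm`; when no permutation reaches the observed
#' count it is reported as the upper bound `1/nPerm` with `pExact = FALSE`
#' (printed as "< 1/nPerm"), never exactly zero.
#'
#' @inheritParams identifyTargets
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed for the shuffles.
#' @return An [IdentificationResult-class] with the observed ranks plus
#'   `nullMaxCorrect`, `pValue` and `pExact` filled in.
#' @export
permutationNull <- function(targets, candidates, truth, excludeSelf = FALSE,
                            nPerm = 1000L, seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  obs <- identifyTargets(targets, candidates, truth, excludeSelf)
  targets <- as.matrix(targets); candidates <- as.matrix(candidates)
  D <- .distanceMatrix(targets, candidates)
  dimnames(D) <- list(rownames(targets), rownames(candidates))
  # the strict nearest candidate per target (NA when tied at the minimum,
  # which can never score under pessimistic ranking)
  best <- vapply(rownames(D), function(tid) {
    d <- setNames(D[tid, ], colnames(D))
    if (excludeSelf) d <- d[names(d) != tid]
    m <- which(d == min(d))
    if (length(m) == 1L) names(d)[m] else NA_character_
  }, character(1))
  truthVals <- unname(truth[rownames(D)])
  nullCounts <- withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(i) {
      sum(best == sample(truthVals), na.rm = TRUE)
    }, numeric(1))
  })
  count <- sum(nullCounts >= obs@nCorrect)
  new("IdentificationResult",
      nTargets = obs@nTargets, nCorrect = obs@nCorrect,
      accuracy = obs@accuracy, ranks = obs@ranks,
      medianRank = obs@medianRank, meanRank = obs@meanRank,
      nullMaxCorrect = nullCounts,
      pValue = if (count == 0) 1 / nPerm else count / nPerm,
      pExact = count > 0)
}

#' Cohort-level fingerprinting
#'
#' `fingerprintSelf` re-identifies the retest subjects among all subjects'
#' original z-scored profiles (the target's own original profile remains a
#' candidate). `fingerprintTwin` identifies each MZ subject's co-twin among
#' all other subjects (the target itself excluded). Retest profiles are
#' standardized with the original cohort's column means and SDs so both
#' occasions live on the same scale.
#'
#' @param cohort a [TwinCohort-class]; `fingerprintSelf` requires a retest
#'   occasion.
#' @param nPerm permutations for the null (0 skips the permutation test).
#' @param seed integer seed.
#' @return An [IdentificationResult-class].
#' @export
fingerprintSelf <- function(cohort, nPerm = 1000L, seed = 1L) {
  rt <- retestMatrix(cohort)
  if (nrow(rt) == 0) stop("cohort has no retest data")
  ph <- phenoMatrix(cohort)
  mu <- colMeans(ph); sds <- apply(ph, 2, sd)
  z <- sweep(sweep(ph, 2, mu), 2, sds, "/")
  zr <- sweep(sweep(rt, 2, mu), 2, sds, "/")
  truth <- setNames(rownames(zr), rownames(zr))
  if (nPerm > 0)
    permutationNull(zr, z, truth, excludeSelf = FALSE, nPerm = nPerm,
                    seed = seed)
  else identifyTargets(zr, z, truth, excludeSelf = FALSE)
}

#' @rdname fingerprintSelf
#' @export
fingerprintTwin <- function(cohort, nPerm = 1000L, seed = 1L) {
  z <- zscore(phenoMatrix(cohort))
  mz <- twinPairs(cohort, "MZ")
  if (nrow(mz) == 0) stop("cohort has no MZ pairs")
  ids <- rownames(z)
  targetsIdx <- c(mz[, 1], mz[, 2])
  truth <- setNames(ids[c(mz[, 2], mz[, 1])], ids[targetsIdx])
  targets <- z[targetsIdx, , drop = FALSE]
  if (nPerm > 0)
    permutationNull(targets, z, truth, excludeSelf = TRUE, nPerm = nPerm,
                    seed = seed)
  else identifyTargets(targets, z, truth, excludeSelf = TRUE)
}

#' @describeIn IdentificationResult-class compact summary.
#' @param object an `IdentificationResult`.
#' @export
setMethod("show", "IdentificationResult", function(object) {
  cat(sprintf("IdentificationResult: %d/%d correct (%.1f%%)\n",
              object@nCorrect, object@nTargets, 100 * object@accuracy))
  cat(sprintf("  median rank %.1f, mean rank %.1f\n",
              object@medianRank, object@meanRank))
  if (!is.na(object@pValue)) {
    lab <- if (isFALSE(object@pExact)) sprintf("< %.4g", object@pValue)
           else sprintf("= %.4g", object@pValue)
    cat(sprintf("  permutation p %s (%d permutations)\n", lab,
                length(object@nullMaxCorrect)))
  }
})

#' Identification report as a data.frame
#'
#' @param result an [IdentificationResult-class].
#' @param ids optional target ids for the rows.
#' @return data.frame with per-target rank and success flag.
#' @export
identificationReport <- function(result, ids = NULL) {
  data.frame(
    target = if (is.null(ids)) seq_len(result@nTargets) else ids,
    rank = result@ranks,
    correct = result@ranks == 1L
  )
}
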