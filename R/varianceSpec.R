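#' Per-measure variance-component specification
#'
#' Builds the simulator's ground-truth table: one row per measure with the
#' fractions of phenotypic variance due to additive genetics (`a2`), common
#' environment (`c2`), non-additive/dominance genetics (`d2`) and unique
#' environment (`e2`), plus a test-retest reliability target and a domain
#' label. Fractions must be non-negative and sum to 1; `c2` and `d2` cannot
#' both be positive for the same measure (the classical twin design fits
#' either an ACE or an ADE model per trait, never ACDE, because only three
#' of the four components are identifiable from MZ/DZ correlations alone).
#'
#' @param measureId character, unique measure names.
#' @param a2,c2,d2,e2 numeric fractions, recycled to the same length.
#' @param reliability numeric in (0, 1], target test-retest correlation.
#' @param domain character, `"task"` or `"questionnaire"`.
#' @return A validated `data.frame` with columns `measure_id`, `a2`, `c2`,
#'   `d2`, `e2`, `reliability`, `domain`.
#' @examples
#' varianceSpecs(c("m1", "m2"), a2 = c(0.5, 0.4), c2 = c(0.2, 0),
#'               d2 = c(0, 0.2), e2 = c(0.3, 0.4))
#' @export
varianceSpecs <- function(measureId, a2 = 0, c2 = 0, d2 = 0,
                          e2 = 1 - a2 - c2 - d2, reliability = 1,
                          domain = "task") {
  n <- length(measureId)
  specs <- data.frame(
    measure_id = as.character(measureId),
    a2 = rep_len(a2, n), c2 = rep_len(c2, n),
    d2 = rep_len(d2, n), e2 = rep_len(e2, n),
    reliability = rep_len(reliability, n),
    domain = rep_len(domain, n),
    stringsAsFactors = FALSE
  )
  validateVarianceSpecs(specs)
  specs
}

#' Validate a variance-specification table
#'
#' @param specs data.frame as returned by [varianceSpecs()].
#' @return Invisibly `specs`; stops with an informative message on the first
#'   violated invariant.
#' @export
validateVarianceSpecs <- function(specs) {
  need <- c("measure_id", "a2", "c2", "d2", "e2", "reliability", "domain")
  if (!all(need %in% colnames(specs)))
    stop("specs must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(specs$measure_id))
    stop("measure ids must be unique")
  fr <- as.matrix(specs[, c("a2", "c2", "d2", "e2")])
  if (any(fr < -1e-12))
    stop("variance fractions must be non-negative")
  bad <- abs(rowSums(fr) - 1) > 1e-12
  if (any(bad))
    stop("variance fractions must sum to 1 for: ",
         paste(specs$measure_id[bad], collapse = ", "))
  both <- specs$c2 * specs$d2 > 1e-12
  if (any(both))
    stop("c2 and d2 cannot both be positive (ACE or ADE, not ACDE) for: ",
         paste(specs$measure_id[both], collapse = ", "))
  if (any(specs$reliability <= 0 | specs$reliability > 1))
    stop("reliability must lie in (0, 1]")
  if (!all(specs$domain %in% c("task", "questionnaire")))
    stop("domain must be 'task' or 'questionnaire'")
  invisible(specs)
}

#' Expected within-pair twin correlations under the variance model
#'
#' Closed forms implied by the four-component decomposition: the additive
#' genetic component correlates 1.0 within MZ and 0.5 within DZ pairs, the
#' dominance component 1.0 and 0.25, the common environment 1.0 for both,
#' and the unique environment 0 for both. Hence
#' \deqn{r_{MZ} = a^2 + d^2 + c^2, \qquad
#'       r_{DZ} = 0.5\,a^2 + 0.25\,d^2 + c^2.}
#'
#' @param specs variance-specification table ([varianceSpecs()]).
#' @return data.frame with columns `measure_id`, `rMZ`, `rDZ`.
#' @examples
#' expectedTwinCorrelations(varianceSpecs("m", a2 = 0.5, c2 = 0.2, e2 = 0.3))
#' @export
expectedTwinCorrelations <- function(specs) {
  validateVarianceSpecs(specs)
  data.frame(
    measure_id = specs$measure_id,
    rMZ = specs$a2 + specs$d2 + specs$c2,
    rDZ = 0.5 * specs$a2 + 0.25 * specs$d2 + specs$c2,
    stringsAsFactors = FALSE
  )
}

#' Cohort design for the twin simulator
#'
#' @param nMeasures integer, number of phenotypic measures.
#' @param nMZPairs,nDZPairs integer, twin-pair counts.
#' @param nUnrelated integer, singleton (non-twin) subjects.
#' @param nRetest integer, subjects receiving a second (retest) occasion;
#'   drawn from the MZ twins first, mirroring the usual retest subsample.
#' @param geneticCorr optional measures x measures correlation matrix
#'   imposed on the additive genetic components (identity by default). Must
#'   be symmetric, unit-diagonal and positive semidefinite.
#' @param envCorr optional correlation matrix for the unique-environment
#'   components (identity by default).
#' @param seed integer seed; all simulator randomness flows from it.
#' @return A list of class `"CohortDesign"`.
#' @export
cohortDesign <- function(nMeasures, nMZPairs, nDZPairs, nUnrelated = 0L,
                         nRetest = 0L, geneticCorr = NULL, envCorr = NULL,
                         seed = 1L) {
  nMeasures <- as.integer(nMeasures)
  if (is.null(geneticCorr)) geneticCorr <- diag(nMeasures)
  if (is.null(envCorr)) envCorr <- diag(nMeasures)
  design <- structure(list(
    nMeasures = nMeasures, nMZPairs = as.integer(nMZPairs),
    nDZPairs = as.integer(nDZPairs), nUnrelated = as.integer(nUnrelated),
    nRetest = as.integer(nRetest), geneticCorr = geneticCorr,
    envCorr = envCorr, seed = as.integer(seed)
  ), class = "CohortDesign")
  validateCohortDesign(design)
  design
}

.checkCorrMatrix <- function(m, n, what) {
  if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
    stop(what, " must be a ", n, "x", n, " matrix")
  if (max(abs(m - t(m))) > 1e-10) stop(what, " must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10) stop(what, " must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop(what, " must be positive semidefinite")
  invisible(m)
}

validateCohortDesign <- function(design) {
  with(design, {
    if (nMeasures < 1L) stop("nMeasures must be >= 1")
    if (nMZPairs < 0L || nDZPairs < 0L || nUnrelated < 0L)
      stop("counts must be non-negative")
    total <- 2L * (nMZPairs + nDZPairs) + nUnrelated
    if (nRetest > total) stop("nRetest exceeds the total number of subjects")
    .checkCorrMatrix(geneticCorr, nMeasures, "geneticCorr")
    .checkCorrMatrix(envCorr, nMeasures, "envCorr")
  })
  invisible(design)
}

#' Correlation matrix from a factor-loading recipe
#'
#' Convenience for planting latent-factor structure in the simulator:
#' builds \eqn{R = \Lambda\Lambda^\top} with the diagonal completed to 1
#' (the remainder treated as factor-unique variance), i.e. the correlation
#' matrix of measures loading on orthogonal latent factors.
#'
#' @param loadings measures x factors matrix; each row's sum of squares
#'   must be <= 1.
#' @return A valid correlation matrix.
#' @export
factorCorrMatrix <- function(loadings) {
  loadings <- as.matrix(loadings)
  h2 <- rowSums(loadings^2)
  if (any(h2 > 1 + 1e-12))
    stop("row sums of squared loadings must not exceed 1")
  r <- tcrossprod(loadings)
  diag(r) <- 1
  r
}
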