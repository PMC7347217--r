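#' Double-entry twin correlation
#'
#' Pearson correlation over twin pairs with each pair entered in both
#' orders, i.e. `cor(c(x, y), c(y, x))`. Double entry makes the estimate
#' invariant to within-pair ordering and brings it close to the intraclass
#' correlation.
#'
#' @param pairs two-column numeric matrix, one row per twin pair.
#' @return Scalar correlation.
#' @export
twinCorrelation <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  x <- c(pairs[, 1], pairs[, 2]); y <- c(pairs[, 2], pairs[, 1])
  if (sd(x) == 0) stop("zero variance across pairs")
  cor(x, y)
}

#' Falconer heritability with ACE/ADE model selection
#'
#' Applies the classical moment rules to a pair of twin correlations:
#' \itemize{
#'   \item `rMZ < rDZ`: no genetic model fits; model `"NONE"`, the
#'     (negative) Falconer value `2*(rMZ - rDZ)` is returned flagged.
#'   \item `rMZ <= 2*rDZ`: dominance assumed negligible (ACE model),
#'     `h2 = 2*(rMZ - rDZ)` (the boundary `rMZ = 2*rDZ` classifies as ACE).
#'   \item `rMZ > 2*rDZ`: common environment assumed negligible (ADE
#'     model); the headline `h2` is `rMZ` itself, which absorbs both
#'     additive and non-additive genetic variance. The Falconer-form value
#'     is reported alongside (`h2Falconer`) since either convention
#'     appears in practice.
#' }
#'
#' @param rMZ,rDZ twin correlations in [-1, 1].
#' @return list with `h2` (headline estimate), `model` ("ACE", "ADE" or
#'   "NONE") and `h2Falconer` = `2*(rMZ - rDZ)` always.
#' @examples
#' falconer(0.5, 0.25)  # ACE, h2 = 0.5
#' falconer(0.6, 0.2)   # ADE, h2 = rMZ = 0.6
#' falconer(0.2, 0.3)   # NONE, h2 = -0.2
#' @export
falconer <- function(rMZ, rDZ) {
  if (abs(rMZ) > 1 || abs(rDZ) > 1)
    stop("correlations must lie in [-1, 1]")
  hF <- 2 * (rMZ - rDZ)
  if (rMZ < rDZ) list(h2 = hF, model = "NONE", h2Falconer = hF)
  else if (rMZ <= 2 * rDZ) list(h2 = hF, model = "ACE", h2Falconer = hF)
  else list(h2 = rMZ, model = "ADE", h2Falconer = hF)
}

#' Per-measure test-retest reliability
#'
#' Pearson correlation between the two occasions, per measure.
#'
#' @param test,retest numeric matrices, matched subjects x measures.
#' @return Named numeric vector of correlations.
#' @export
retestReliability <- function(test, retest) {
  test <- as.matrix(test); retest <- as.matrix(retest)
  if (!all(dim(test) == dim(retest)))
    stop("test and retest must be matched subjects x measures")
  if (nrow(test) < 3) stop("need at least 3 matched subjects")
  vapply(seq_len(ncol(test)), function(j) {
    if (sd(test[, j]) == 0 || sd(retest[, j]) == 0)
      stop("zero variance in measure ", j)
    cor(test[, j], retest[, j])
  }, numeric(1)) |> setNames(colnames(test))
}

#' Disattenuate heritability for measurement unreliability
#'
#' Divides an estimate by the measure's test-retest reliability. Values
#' above 1 are possible when reliability is poor and are flagged: very low
#' reliability can inflate the corrected value artificially.
#'
#' @param h2 numeric estimate(s).
#' @param reliability positive reliability value(s).
#' @return numeric vector with attribute `"inflated"` (logical) marking
#'   corrected values above 1.
#' @export
disattenuate <- function(h2, reliability) {
  if (any(reliability <= 0)) stop("reliability must be positive")
  out <- h2 / reliability
  attr(out, "inflated") <- out > 1
  out
}

#' Per-measure twin correlations for a cohort
#'
#' @param cohort a [TwinCohort-class] with pairs of both zygosities.
#' @return data.frame with `measure_id`, `rMZ`, `rDZ`.
#' @export
twinCorrelations <- function(cohort) {
  ph <- phenoMatrix(cohort)
  mz <- twinPairs(cohort, "MZ"); dz <- twinPairs(cohort, "DZ")
  if (nrow(mz) < 3 || nrow(dz) < 3)
    stop("need at least 3 pairs of each zygosity")
  data.frame(
    measure_id = colnames(ph),
    rMZ = vapply(seq_len(ncol(ph)), function(j)
      twinCorrelation(cbind(ph[mz[, 1], j], ph[mz[, 2], j])), numeric(1)),
    rDZ = vapply(seq_len(ncol(ph)), function(j)
      twinCorrelation(cbind(ph[dz[, 1], j], ph[dz[, 2], j])), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Classical heritability profile of a cohort
#'
#' Computes per-measure MZ/DZ double-entry correlations, applies
#' [falconer()] model selection, and (when a retest occasion exists)
#' appends empirical test-retest reliability and the disattenuated
#' estimate. Twin correlations are invariant to affine rescaling of the
#' raw measures, so the profile needs no prior standardization.
#'
#' @param cohort a [TwinCohort-class].
#' @return data.frame with columns `measure_id`, `domain`, `rMZ`, `rDZ`,
#'   `model`, `h2`, `h2_falconer`, `reliability`, `h2_disattenuated`,
#'   `inflated`, `method` (= "falconer").
#' @export
falconerProfile <- function(cohort) {
  tc <- twinCorrelations(cohort)
  md <- measureData(cohort)
  fits <- Map(falconer, tc$rMZ, tc$rDZ)
  out <- data.frame(
    measure_id = tc$measure_id,
    domain = md$domain[match(tc$measure_id, md$measure_id)],
    rMZ = tc$rMZ, rDZ = tc$rDZ,
    model = vapply(fits, `[[`, character(1), "model"),
    h2 = vapply(fits, `[[`, numeric(1), "h2"),
    h2_falconer = vapply(fits, `[[`, numeric(1), "h2Falconer"),
    reliability = NA_real_, h2_disattenuated = NA_real_, inflated = NA,
    method = "falconer",
    stringsAsFactors = FALSE
  )
  rt <- retestMatrix(cohort)
  if (nrow(rt) >= 3) {
    rel <- retestReliability(phenoMatrix(cohort)[rownames(rt), , drop = FALSE],
                             rt)
    out$reliability <- rel[out$measure_id]
    da <- disattenuate(out$h2, out$reliability)
    out$h2_disattenuated <- as.numeric(da)
    out$inflated <- attr(da, "inflated")
  }
  out
}
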