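#' Cross-twin cross-trait correlations
#'
#' Double-entered correlation of twin 1's trait a with twin 2's trait b
#' within pairs of one zygosity. The MZ-DZ contrast of this quantity
#' identifies the genetic covariance between the traits: with standardized
#' traits the additive genetic cross-covariance contributes fully to the
#' MZ value and half to the DZ value, so
#' `genetic_cov = 2 * (ctct_MZ - ctct_DZ)`.
#'
#' @param a,b numeric two-column matrices (twin1, twin2), one row per pair,
#'   for trait a and trait b respectively.
#' @return Scalar double-entry cross correlation, or NA when a variance is
#'   degenerate.
#' @export
crossTwinCrossTrait <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 2)
    stop("a and b must be matched two-column pair matrices")
  if (nrow(a) < 3) stop("need at least 3 pairs")
  x <- c(a[, 1], a[, 2]); y <- c(b[, 2], b[, 1])
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Decompose a phenotypic correlation into genetic and environmental parts
#'
#' Under the bivariate variance-components model the phenotypic
#' correlation of two traits splits as
#' \deqn{\rho_P = \sqrt{h^2_a h^2_b}\,\rho_G +
#'       \sqrt{(1-h^2_a)(1-h^2_b)}\,\rho_E,}
#' where \eqn{h^2_a, h^2_b} are the traits' heritabilities. Given the
#' genetic covariance from the cross-twin cross-trait contrast,
#' `rhoG = geneticCov / sqrt(h2a*h2b)` (clamped to [-1, 1]) and `rhoE` is
#' solved from the display above. When no clamping occurs the
#' recomposition reproduces `rhoP` exactly.
#'
#' @param rhoP phenotypic correlation.
#' @param h2a,h2b heritabilities in (0, 1).
#' @param geneticCov genetic covariance estimate,
#'   `2 * (ctct_MZ - ctct_DZ)`.
#' @return list with `rhoG`, `rhoE` and logical `clamped`.
#' @export
decomposeCorrelation <- function(rhoP, h2a, h2b, geneticCov) {
  if (h2a <= 0 || h2a >= 1 || h2b <= 0 || h2b >= 1)
    stop("h2a and h2b must lie strictly inside (0, 1)")
  g <- sqrt(h2a * h2b)
  rhoG <- geneticCov / g
  clamped <- abs(rhoG) > 1
  rhoG <- min(1, max(-1, rhoG))
  rhoE <- (rhoP - g * rhoG) / sqrt((1 - h2a) * (1 - h2b))
  list(rhoG = rhoG, rhoE = rhoE, clamped = clamped)
}

#' Bivariate genetic correlation matrix for a cohort
#'
#' For every measure pair: standardizes, residualizes on the demographic
#' covariates, applies the rank-based inverse normal transform, then
#' estimates the genetic correlation by the cross-twin cross-trait moment
#' contrast and decomposes the phenotypic correlation via
#' [decomposeCorrelation()]. Heritability inputs are the cohort's Falconer
#' estimates: cells where either trait's h2 falls outside (0, 1) are
#' masked; in-range values are truncated into [0.01, 0.99] (logged) before
#' use. rhoG values beyond [-1, 1] are clamped and logged rather than
#' erroring.
#'
#' @param cohort a [TwinCohort-class] with pairs of both zygosities.
#' @return A [GeneticCorrelationMatrix-class].
#' @export
geneticCorrelationMatrix <- function(cohort) {
  ph <- phenoMatrix(cohort)
  sdta <- subjectData(cohort)
  z <- zscore(ph)
  if (length(unique(sdta$age)) > 1 && length(unique(sdta$sex)) > 1)
    z <- residualize(z, sdta$age, sdta$sex)
  z <- apply(z, 2, inverseNormalTransform)
  rownames(z) <- rownames(ph)

  M <- ncol(z)
  measures <- colnames(z)
  mz <- twinPairs(cohort, "MZ"); dz <- twinPairs(cohort, "DZ")

  h2raw <- vapply(seq_len(M), function(j) {
    rMZ <- twinCorrelation(cbind(z[mz[, 1], j], z[mz[, 2], j]))
    rDZ <- twinCorrelation(cbind(z[dz[, 1], j], z[dz[, 2], j]))
    falconer(rMZ, rDZ)$h2
  }, numeric(1))
  events <- data.frame(measure_a = character(0), measure_b = character(0),
                       event = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
  h2 <- h2raw
  h2[h2raw <= 0 | h2raw >= 1] <- NA_real_
  trunc <- which(!is.na(h2) & (h2 < 0.01 | h2 > 0.99))
  for (j in trunc) {
    events <- rbind(events, data.frame(
      measure_a = measures[j], measure_b = NA_character_,
      event = "h2_truncated", value = h2raw[j]))
    h2[j] <- min(0.99, max(0.01, h2[j]))
  }

  rhoP <- cor(z)
  rhoG <- matrix(NA_real_, M, M, dimnames = list(measures, measures))
  rhoE <- rhoG
  mask <- matrix(TRUE, M, M, dimnames = list(measures, measures))
  for (a in seq_len(M)) {
    if (is.na(h2[a])) next
    mask[a, a] <- FALSE; rhoG[a, a] <- 1; rhoE[a, a] <- 1
    for (b in seq_len(M)) {
      if (b <= a || is.na(h2[b])) next
      ctMZ <- crossTwinCrossTrait(cbind(z[mz[, 1], a], z[mz[, 2], a]),
                                  cbind(z[mz[, 1], b], z[mz[, 2], b]))
      ctDZ <- crossTwinCrossTrait(cbind(z[dz[, 1], a], z[dz[, 2], a]),
                                  cbind(z[dz[, 1], b], z[dz[, 2], b]))
      if (is.na(ctMZ) || is.na(ctDZ)) next
      dec <- decomposeCorrelation(rhoP[a, b], h2[a], h2[b],
                                  2 * (ctMZ - ctDZ))
      rhoG[a, b] <- rhoG[b, a] <- dec$rhoG
      rhoE[a, b] <- rhoE[b, a] <- dec$rhoE
      mask[a, b] <- mask[b, a] <- FALSE
      if (dec$clamped)
        events <- rbind(events, data.frame(
          measure_a = measures[a], measure_b = measures[b],
          event = "rhoG_clamped", value = dec$rhoG))
    }
  }
  new("GeneticCorrelationMatrix", rhoG = rhoG, rhoE = rhoE, rhoP = rhoP,
      mask = mask, events = events, h2 = setNames(h2, measures))
}

#' @describeIn GeneticCorrelationMatrix-class compact summary.
#' @param object a `GeneticCorrelationMatrix`.
#' @export
setMethod("show", "GeneticCorrelationMatrix", function(object) {
  M <- nrow(object@rhoG)
  off <- !object@mask & upper.tri(object@rhoG)
  cat("GeneticCorrelationMatrix:", M, "measures,",
      sum(off), "of", M * (M - 1) / 2, "pairs defined\n")
  if (nrow(object@events))
    cat("  events:", paste(table(object@events$event), collapse = " / "),
        "(truncated h2 / clamped rhoG)\n")
})

#' Long-format export of a genetic correlation matrix
#'
#' @param gcm a [GeneticCorrelationMatrix-class].
#' @return data.frame with one row per unordered measure pair: `measure_a`,
#'   `measure_b`, `rho_p`, `rho_g`, `rho_e`, `masked`.
#' @export
geneticCorrelationLong <- function(gcm) {
  M <- nrow(gcm@rhoG)
  idx <- which(upper.tri(gcm@rhoG), arr.ind = TRUE)
  data.frame(
    measure_a = rownames(gcm@rhoG)[idx[, 1]],
    measure_b = colnames(gcm@rhoG)[idx[, 2]],
    rho_p = gcm@rhoP[idx], rho_g = gcm@rhoG[idx], rho_e = gcm@rhoE[idx],
    masked = gcm@mask[idx],
    stringsAsFactors = FALSE
  )
}
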