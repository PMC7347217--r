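#' Kaiser retention count
#'
#' Number of eigenvalues of the (unreduced) correlation matrix strictly
#' greater than 1. An identity correlation matrix retains zero factors:
#' all its eigenvalues equal 1 exactly.
#'
#' @param R correlation matrix.
#' @return Integer factor count.
#' @export
kaiserRetain <- function(R) {
  sum(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 1)
}

#' Principal axis factoring
#'
#' Iterated eigendecomposition of the communality-reduced correlation
#' matrix. Initial communalities are the squared multiple correlations
#' \eqn{1 - 1/\mathrm{diag}(R^{-1})}; each iteration replaces the diagonal
#' of R by the current communalities, takes the leading `nFactors`
#' eigenvectors scaled by the square roots of their eigenvalues as
#' loadings, and updates communalities to the loading row sums of squares,
#' until the largest communality change falls below `tol` (default 1e-4,
#' capped at `maxIter` iterations, warning and last iterate on
#' non-convergence). Heywood communalities are clipped to 0.999 with a
#' warning. The number of factors defaults to the Kaiser rule applied to
#' the eigenvalues of the *original* correlation matrix (strictly > 1).
#'
#' @param R correlation matrix (symmetric, unit diagonal, positive
#'   semidefinite).
#' @param nFactors integer, or NULL for the Kaiser rule.
#' @param tol convergence tolerance on communalities.
#' @param maxIter iteration cap.
#' @return An unrotated [FactorModel-class]. `varianceExplained` is the
#'   per-factor sum of squared loadings divided by the number of measures.
#' @export
pafExtract <- function(R, nFactors = NULL, tol = 1e-4, maxIter = 100L) {
  R <- as.matrix(R)
  M <- nrow(R)
  if (ncol(R) != M || max(abs(R - t(R))) > 1e-8)
    stop("R must be a symmetric correlation matrix")
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) < -1e-8)
    stop("R is not positive semidefinite")
  if (is.null(colnames(R))) colnames(R) <- sprintf("m%02d", seq_len(M))
  evOrig <- sort(eig$values, decreasing = TRUE)
  if (is.null(nFactors)) nFactors <- sum(evOrig > 1)
  nFactors <- as.integer(nFactors)
  if (nFactors == 0L) {
    return(new("FactorModel",
               loadings = matrix(numeric(0), M, 0,
                                 dimnames = list(colnames(R), NULL)),
               communalities = setNames(rep(0, M), colnames(R)),
               factorCorr = matrix(numeric(0), 0, 0),
               eigenvalues = evOrig,
               varianceExplained = numeric(0), nFactors = 0L,
               rotation = "none", converged = TRUE))
  }
  if (nFactors > M) stop("more factors than measures")

  Rinv <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-8, M)))
  h2 <- pmin(pmax(1 - 1 / diag(Rinv), 0), 0.999)
  converged <- FALSE
  heywood <- FALSE
  L <- NULL
  for (i in seq_len(maxIter)) {
    Rr <- R; diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    L <- e$vectors[, seq_len(nFactors), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(nFactors)], 0)), nFactors)
    h2new <- rowSums(L^2)
    if (any(h2new >= 1)) {
      heywood <- TRUE
      h2new <- pmin(h2new, 0.999)
    }
    if (max(abs(h2new - h2)) < tol) {
      h2 <- h2new; converged <- TRUE; break
    }
    h2 <- h2new
  }
  if (heywood)
    warning("Heywood case: communalities clipped to 0.999")
  if (!converged)
    warning("principal axis factoring did not converge in ", maxIter,
            " iterations; returning the last iterate")
  # final decomposition at the reported communalities, so loadings,
  # communalities and variance shares describe one reduced matrix
  Rr <- R; diag(Rr) <- h2
  e <- eigen(Rr, symmetric = TRUE)
  L <- e$vectors[, seq_len(nFactors), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(nFactors)], 0)), nFactors)
  # sign convention: largest |loading| per factor is positive
  flip <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2, ifelse(flip == 0, 1, flip), "*")
  dimnames(L) <- list(colnames(R), sprintf("F%d", seq_len(nFactors)))
  new("FactorModel", loadings = L,
      communalities = setNames(h2, colnames(R)),
      factorCorr = diag(nFactors), eigenvalues = evOrig,
      varianceExplained = colSums(L^2) / M, nFactors = nFactors,
      rotation = "none", converged = converged)
}

#' Promax (oblique) rotation
#'
#' Varimax pre-rotation (with Kaiser normalization) followed by the power
#' target \eqn{Q = \Lambda |\Lambda|^{\kappa-1}} and an oblique Procrustes
#' fit, allowing correlated factors. Returns the rotated pattern matrix
#' and the factor correlation matrix. With a single factor the rotation is
#' the identity.
#'
#' @param model an unrotated [FactorModel-class].
#' @param kappa promax power (default 4).
#' @return A [FactorModel-class] with `rotation = "promax"`.
#' @export
promaxRotate <- function(model, kappa = 4) {
  if (model@nFactors < 2) {
    model@rotation <- "promax"
    return(model)
  }
  vm <- varimax(model@loadings)
  A <- unclass(vm$loadings)
  Q <- A * abs(A)^(kappa - 1)
  U <- qr.coef(qr(A), Q)
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), ncol(U))
  P <- A %*% U
  Phi <- solve(crossprod(U))
  # re-normalize so factors keep unit variance
  s <- sqrt(diag(Phi))
  Phi <- Phi / (s %o% s)
  dimnames(P) <- dimnames(model@loadings)
  dimnames(Phi) <- list(colnames(P), colnames(P))
  out <- model
  out@loadings <- P
  out@factorCorr <- Phi
  out@rotation <- "promax"
  out
}

#' Factor scores by the regression or Bartlett method
#'
#' Regression (Thurstone) scores use the weight matrix
#' \eqn{B = R^{-1}\Lambda\Phi} (structure matrix premultiplied by the
#' inverse observed correlation matrix); Bartlett scores use the
#' uniqueness-weighted least-squares weights
#' \eqn{B = \Psi^{-1}\Lambda(\Lambda^\top\Psi^{-1}\Lambda)^{-1}} with
#' \eqn{\Psi = \mathrm{diag}(1 - h^2)}. Scores are `Z %*% B` on the
#' z-scored data. A singular correlation matrix is ridge-stabilized
#' (1e-8 on the diagonal) with a warning.
#'
#' @param data subjects x measures matrix on the model's measure set (raw;
#'   z-scored internally).
#' @param model a [FactorModel-class].
#' @param method "regression" or "bartlett".
#' @return subjects x factors score matrix.
#' @export
factorScores <- function(data, model, method = c("regression", "bartlett")) {
  method <- match.arg(method)
  Z <- zscore(as.matrix(data))
  if (ncol(Z) != nrow(model@loadings))
    stop("data columns must match the model's measures")
  L <- model@loadings
  Phi <- if (length(model@factorCorr)) model@factorCorr else diag(ncol(L))
  if (method == "regression") {
    R <- cor(Z)
    Rinv <- tryCatch(solve(R), error = function(e) {
      warning("singular correlation matrix; ridge-stabilized inverse used")
      solve(R + diag(1e-8, ncol(R)))
    })
    B <- Rinv %*% L %*% Phi
  } else {
    psi <- pmax(1 - model@communalities, 1e-6)
    Li <- L / psi
    B <- Li %*% solve(crossprod(L, Li))
  }
  scores <- Z %*% B
  colnames(scores) <- colnames(L)
  rownames(scores) <- rownames(data)
  scores
}

#' @describeIn FactorModel-class compact summary.
#' @param object a `FactorModel`.
#' @export
setMethod("show", "FactorModel", function(object) {
  cat("FactorModel:", nrow(object@loadings), "measures,", object@nFactors,
      "factors (", object@rotation, "rotation )\n")
  if (object@nFactors > 0)
    cat(sprintf("  variance explained: %.1f%%\n",
                100 * sum(object@varianceExplained)))
})
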