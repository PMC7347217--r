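#' Spearman rank-correlation matrix across heritability profiles
#'
#' Agreement between heritability estimates from different methods
#' (e.g. Falconer, univariate |slope|, ridge |coefficient|, random-forest
#' importance) over the same measures. Ties get average ranks; a constant
#' profile yields masked (NA) entries.
#'
#' @param profiles named list of equal-length numeric vectors (k >= 2).
#' @return k x k symmetric matrix with unit diagonal.
#' @export
spearmanMatrix <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  lens <- lengths(profiles)
  if (length(unique(lens)) != 1) stop("profiles must have equal length")
  x <- do.call(cbind, profiles)
  const <- apply(x, 2, function(v) sd(v) == 0)
  out <- suppressWarnings(cor(x, method = "spearman"))
  out[const, ] <- NA_real_; out[, const] <- NA_real_
  diag(out) <- ifelse(const, NA_real_, 1)
  out
}

#' Permutation test for a domain difference in mean heritability
#'
#' Observed statistic: the absolute difference between the mean estimate
#' of the two domains (e.g. task vs questionnaire measures). Null: domain
#' labels are randomly reassigned preserving the group sizes; with 15 task
#' measures out of 37 the full label space has choose(37, 15) =
#' 9,364,199,760 assignments, so it is approximated by Monte Carlo
#' sampling (`nPerm` draws). The p-value is `#(null >= observed)/nPerm`
#' (two-sided through the absolute statistic), reported as the `1/nPerm`
#' upper bound with `pExact = FALSE` when no draw reaches the observed
#' value -- never exactly zero.
#'
#' @param estimates numeric vector, one value per measure.
#' @param domains character vector with exactly two distinct non-empty
#'   levels.
#' @param nPerm Monte Carlo permutations.
#' @param seed integer seed.
#' @return list with `observed`, `domainMeans`, `pValue`, `pExact`,
#'   `nullStats`, `nPerm` and `labelSpaceSize` (the exact number of
#'   distinct assignments).
#' @export
domainPermutationTest <- function(estimates, domains, nPerm = 100000L,
                                  seed = 1L) {
  lev <- unique(domains)
  if (length(lev) != 2) stop("exactly two domains required")
  if (length(estimates) != length(domains))
    stop("one domain label per estimate required")
  n1 <- sum(domains == lev[1])
  if (n1 == 0 || n1 == length(domains)) stop("both domains must be non-empty")
  m <- tapply(estimates, domains, mean)
  observed <- abs(m[[lev[1]]] - m[[lev[2]]])
  n <- length(estimates)
  total <- sum(estimates)
  nullStats <- withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(i) {
      s1 <- sum(estimates[sample.int(n, n1)])
      abs(s1 / n1 - (total - s1) / (n - n1))
    }, numeric(1))
  })
  count <- sum(nullStats >= observed)
  list(observed = unname(observed),
       domainMeans = setNames(as.numeric(m), names(m)),
       pValue = if (count == 0) 1 / nPerm else count / nPerm,
       pExact = count > 0,
       nullStats = nullStats, nPerm = nPerm,
       labelSpaceSize = choose(n, n1))
}

#' Domain tests across several heritability profiles
#'
#' Runs [domainPermutationTest()] for each profile (the family of four:
#' classical plus three model-weight profiles, in typical use) and reports
#' both uncorrected and Bonferroni-adjusted p-values, clearly labelled:
#' the uncorrected values test each profile's own hypothesis, the adjusted
#' ones account for testing the family.
#'
#' @param profiles named list of numeric vectors (one value per measure).
#' @param domains character vector of domain labels.
#' @param nPerm,seed passed to [domainPermutationTest()].
#' @return data.frame with one row per profile: observed statistic, domain
#'   means, `p_uncorrected`, `p_exact`, `p_bonferroni`.
#' @export
domainTestFamily <- function(profiles, domains, nPerm = 100000L, seed = 1L) {
  res <- lapply(seq_along(profiles), function(i)
    domainPermutationTest(profiles[[i]], domains, nPerm = nPerm,
                          seed = seed + i))
  lev <- unique(domains)
  data.frame(
    profile = names(profiles),
    observed = vapply(res, `[[`, numeric(1), "observed"),
    mean_domain1 = vapply(res, function(r) r$domainMeans[[lev[1]]], numeric(1)),
    mean_domain2 = vapply(res, function(r) r$domainMeans[[lev[2]]], numeric(1)),
    p_uncorrected = vapply(res, `[[`, numeric(1), "pValue"),
    p_exact = vapply(res, `[[`, logical(1), "pExact"),
    p_bonferroni = pmin(1, vapply(res, `[[`, numeric(1), "pValue") *
                          length(profiles)),
    stringsAsFactors = FALSE
  )
}
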