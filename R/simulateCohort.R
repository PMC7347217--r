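## Twin-cohort simulator: every subject's phenotype is a weighted sum of
## four standard-normal components with the classical twin sharing pattern
## (A shared 1.0 within MZ / 0.5 within DZ, D 1.0 / 0.25, C 1.0 / 1.0,
## E unshared).

# factor L with L %*% t(L) = corr, tolerant of singular (PSD) matrices
.corrFactor <- function(corr) {
  e <- eigen(corr, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(corr))
}

# n draws from MVN(0, corr) given its factor, returned n x M
.mvnDraw <- function(n, fac) {
  matrix(rnorm(n * ncol(fac)), n) %*% t(fac)
}

#' Simulate a twin cohort with known variance components
#'
#' Generates phenotypes for `nMZPairs` monozygotic pairs, `nDZPairs`
#' dizygotic pairs and `nUnrelated` singletons under the four-component
#' model: for measure \eqn{j}, the phenotype is
#' \eqn{\sqrt{a^2_j}A + \sqrt{c^2_j}C + \sqrt{d^2_j}D + \sqrt{e^2_j}E}
#' with standard-normal components. A correlates 1.0 within MZ and 0.5
#' within DZ pairs, D 1.0 and 0.25, C is identical within a family and E is
#' subject-specific. Cross-measure correlation `geneticCorr` is imposed on
#' the A components only (and `envCorr`, identity by default, on E); C and
#' D are independent across measures.
#'
#' Retest rows are generated for the first `nRetest` subjects (MZ twins
#' first) as `reliability * phenotype + sqrt(1 - reliability^2) * noise`,
#' with occasion noise independent of E, so the expected test-retest
#' correlation equals each measure's `reliability`.
#'
#' Age (uniform on 22--35) and sex are generated independent of the
#' phenotypes unless `covariateEffects` supplies per-measure linear effects
#' (`list(age = ..., sex = ...)`, each length-M), which are added to the
#' phenotypes to exercise residualization.
#'
#' All randomness derives from `design$seed`; the same design and specs
#' reproduce the cohort bit-exactly.
#'
#' @param design a [cohortDesign()].
#' @param specs a [varianceSpecs()] table with `design$nMeasures` rows.
#' @param covariateEffects optional list with numeric `age` and/or `sex`
#'   slopes per measure.
#' @return A [TwinCohort-class] object.
#' @examples
#' specs <- varianceSpecs(c("m1", "m2"), a2 = c(0.6, 0.3), e2 = c(0.4, 0.7))
#' ch <- simulateCohort(cohortDesign(2, nMZPairs = 20, nDZPairs = 10), specs)
#' @export
simulateCohort <- function(design, specs, covariateEffects = NULL) {
  validateCohortDesign(design)
  validateVarianceSpecs(specs)
  if (nrow(specs) != design$nMeasures)
    stop("specs must have one row per measure (", design$nMeasures, ")")
  M <- design$nMeasures
  nMZ <- design$nMZPairs; nDZ <- design$nDZPairs; nNT <- design$nUnrelated
  n <- 2L * (nMZ + nDZ) + nNT

  withr::with_seed(design$seed, {
    gFac <- .corrFactor(design$geneticCorr)
    eFac <- .corrFactor(design$envCorr)

    A <- matrix(0, n, M); D <- matrix(0, n, M); C <- matrix(0, n, M)
    famId <- character(n); zyg <- character(n)

    idx <- 0L; fam <- 0L
    if (nMZ > 0L) {
      Ash <- .mvnDraw(nMZ, gFac)
      Dsh <- matrix(rnorm(nMZ * M), nMZ)
      Csh <- matrix(rnorm(nMZ * M), nMZ)
      for (p in seq_len(nMZ)) {
        fam <- fam + 1L
        rows <- idx + 1:2
        A[rows, ] <- rep(1, 2) %o% Ash[p, ]
        D[rows, ] <- rep(1, 2) %o% Dsh[p, ]
        C[rows, ] <- rep(1, 2) %o% Csh[p, ]
        famId[rows] <- sprintf("F%04d", fam); zyg[rows] <- "MZ"
        idx <- idx + 2L
      }
    }
    if (nDZ > 0L) {
      Ash <- .mvnDraw(nDZ, gFac)
      Au1 <- .mvnDraw(nDZ, gFac); Au2 <- .mvnDraw(nDZ, gFac)
      Dsh <- matrix(rnorm(nDZ * M), nDZ)
      Du1 <- matrix(rnorm(nDZ * M), nDZ); Du2 <- matrix(rnorm(nDZ * M), nDZ)
      Csh <- matrix(rnorm(nDZ * M), nDZ)
      for (p in seq_len(nDZ)) {
        fam <- fam + 1L
        rows <- idx + 1:2
        A[rows[1], ] <- sqrt(0.5) * Ash[p, ] + sqrt(0.5) * Au1[p, ]
        A[rows[2], ] <- sqrt(0.5) * Ash[p, ] + sqrt(0.5) * Au2[p, ]
        D[rows[1], ] <- sqrt(0.25) * Dsh[p, ] + sqrt(0.75) * Du1[p, ]
        D[rows[2], ] <- sqrt(0.25) * Dsh[p, ] + sqrt(0.75) * Du2[p, ]
        C[rows, ] <- rep(1, 2) %o% Csh[p, ]
        famId[rows] <- sprintf("F%04d", fam); zyg[rows] <- "DZ"
        idx <- idx + 2L
      }
    }
    if (nNT > 0L) {
      rows <- idx + seq_len(nNT)
      A[rows, ] <- .mvnDraw(nNT, gFac)
      D[rows, ] <- matrix(rnorm(nNT * M), nNT)
      C[rows, ] <- matrix(rnorm(nNT * M), nNT)
      famId[rows] <- sprintf("F%04d", fam + seq_len(nNT)); zyg[rows] <- "NT"
    }
    E <- .mvnDraw(n, eFac)

    w <- sqrt(as.matrix(specs[, c("a2", "c2", "d2", "e2")]))
    pheno <- A %*% diag(w[, "a2"], M) + C %*% diag(w[, "c2"], M) +
      D %*% diag(w[, "d2"], M) + E %*% diag(w[, "e2"], M)
    colnames(pheno) <- specs$measure_id

    subjectId <- sprintf("S%04d", seq_len(n))
    rownames(pheno) <- subjectId
    age <- round(runif(n, 22, 35))
    sex <- rbinom(n, 1L, 0.5)
    # twins share age and sex (same birth; same-sex pairs as in confirmed
    # twin samples)
    for (f in unique(famId[zyg != "NT"])) {
      rows <- which(famId == f)
      age[rows] <- age[rows[1]]; sex[rows] <- sex[rows[1]]
    }
    if (!is.null(covariateEffects)) {
      if (!is.null(covariateEffects$age))
        pheno <- pheno + (age - mean(age)) %o% rep_len(covariateEffects$age, M)
      if (!is.null(covariateEffects$sex))
        pheno <- pheno + (sex - mean(sex)) %o% rep_len(covariateEffects$sex, M)
    }

    retest <- matrix(numeric(0), nrow = M, ncol = 0,
                     dimnames = list(specs$measure_id, NULL))
    if (design$nRetest > 0L) {
      ord <- order(match(zyg, c("MZ", "DZ", "NT")))
      ids <- subjectId[ord][seq_len(design$nRetest)]
      rel <- specs$reliability
      noise <- matrix(rnorm(design$nRetest * M), design$nRetest)
      rt <- pheno[ids, , drop = FALSE] %*% diag(rel, M) +
        noise %*% diag(sqrt(1 - rel^2), M)
      retest <- t(rt)
      dimnames(retest) <- list(specs$measure_id, ids)
    }

    subjects <- data.frame(subject_id = subjectId, family_id = famId,
                           zygosity = zyg, age = age, sex = sex,
                           stringsAsFactors = FALSE)
    twinCohort(t(pheno), subjects, specs, retest = retest,
               geneticCorr = design$geneticCorr)
  })
}

#' Construct a TwinCohort from its parts
#'
#' @param phenotypes measures x subjects numeric matrix (rownames =
#'   measure ids, colnames = subject ids).
#' @param subjects data.frame with columns `subject_id`, `family_id`,
#'   `zygosity`, `age`, `sex`, one row per phenotype column.
#' @param specs per-measure metadata ([varianceSpecs()] table, or NULL for
#'   placeholder metadata when the truth is unknown).
#' @param retest measures x retest-subjects matrix (columns named by
#'   subject id), or NULL.
#' @param geneticCorr measures x measures matrix, or NULL for identity.
#' @return A validated [TwinCohort-class].
#' @export
twinCohort <- function(phenotypes, subjects, specs = NULL, retest = NULL,
                       geneticCorr = NULL) {
  phenotypes <- as.matrix(phenotypes)
  M <- nrow(phenotypes)
  if (is.null(rownames(phenotypes)))
    rownames(phenotypes) <- sprintf("m%02d", seq_len(M))
  if (is.null(specs))
    specs <- data.frame(measure_id = rownames(phenotypes), a2 = NA_real_,
                        c2 = NA_real_, d2 = NA_real_, e2 = NA_real_,
                        reliability = NA_real_, domain = NA_character_,
                        stringsAsFactors = FALSE)
  if (is.null(retest))
    retest <- matrix(numeric(0), nrow = M, ncol = 0,
                     dimnames = list(rownames(phenotypes), NULL))
  if (is.null(geneticCorr)) geneticCorr <- diag(M)
  colnames(phenotypes) <- subjects$subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(phenotypes = phenotypes),
    colData = S4Vectors::DataFrame(subjects, row.names = subjects$subject_id),
    rowData = S4Vectors::DataFrame(specs[, setdiff(colnames(specs),
                                                   "measure_id"),
                                         drop = FALSE],
                                   row.names = specs$measure_id)
  )
  new("TwinCohort", se, retest = retest, geneticCorr = geneticCorr)
}

#' @describeIn TwinCohort-class subjects x measures phenotype matrix.
#' @param cohort,object a `TwinCohort`.
#' @export
phenoMatrix <- function(cohort) t(SummarizedExperiment::assay(cohort, "phenotypes"))

#' @describeIn TwinCohort-class retest-subjects x measures matrix (0 rows
#'   when no retest occasion exists).
#' @export
retestMatrix <- function(cohort) t(cohort@retest)

#' @describeIn TwinCohort-class subject metadata as a plain data.frame.
#' @export
subjectData <- function(cohort)
  as.data.frame(SummarizedExperiment::colData(cohort))

#' @describeIn TwinCohort-class per-measure metadata (variance fractions,
#'   reliability, domain) with the measure id as first column.
#' @export
measureData <- function(cohort) {
  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  cbind(data.frame(measure_id = rownames(rd), stringsAsFactors = FALSE), rd)
}

#' @describeIn TwinCohort-class the additive-genetic cross-measure
#'   correlation matrix used by the simulator.
#' @export
geneticCorr <- function(cohort) cohort@geneticCorr

#' @describeIn TwinCohort-class two-column matrix of subject indices, one
#'   row per twin pair of the requested zygosity.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @export
twinPairs <- function(cohort, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  sd <- subjectData(cohort)
  keep <- which(sd$zygosity == zygosity)
  if (!length(keep)) return(matrix(integer(0), ncol = 2))
  sp <- split(keep, sd$family_id[keep])
  out <- do.call(rbind, lapply(sp, function(x) x[1:2]))
  colnames(out) <- c("twin1", "twin2")
  out
}

#' @describeIn TwinCohort-class compact summary.
#' @export
setMethod("show", "TwinCohort", function(object) {
  sd <- subjectData(object)
  cat("TwinCohort:", nrow(object), "measures x", ncol(object), "subjects\n")
  cat("  MZ pairs:", sum(sd$zygosity == "MZ") / 2,
      " DZ pairs:", sum(sd$zygosity == "DZ") / 2,
      " singletons:", sum(sd$zygosity == "NT"), "\n")
  cat("  retest subjects:", ncol(object@retest), "\n")
})

#' Write a cohort to plain-text files
#'
#' Writes `phenotypes.csv` (columns `subject_id`, `family_id`, `zygosity`,
#' `age`, `sex`, then one column per measure), `retest.csv` (`subject_id`
#' plus measures; present even when empty) and `truth.json` (the variance
#' specs and genetic correlation).
#'
#' @param cohort a [TwinCohort-class].
#' @param dir output directory, created if needed.
#' @return Invisibly the directory path.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ph <- cbind(subjectData(cohort), as.data.frame(phenoMatrix(cohort)))
  write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  rt <- retestMatrix(cohort)
  rtdf <- cbind(data.frame(subject_id = rownames(rt)), as.data.frame(rt))
  write.csv(rtdf, file.path(dir, "retest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(specs = measureData(cohort), genetic_corr = geneticCorr(cohort)),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `phenotypes.csv` and optionally
#'   `retest.csv` / `truth.json`.
#' @return A [TwinCohort-class].
#' @export
readCohort <- function(dir) {
  ph <- read.csv(file.path(dir, "phenotypes.csv"), stringsAsFactors = FALSE)
  meta <- c("subject_id", "family_id", "zygosity", "age", "sex")
  subjects <- ph[, meta]
  mat <- t(as.matrix(ph[, setdiff(colnames(ph), meta), drop = FALSE]))
  colnames(mat) <- subjects$subject_id
  specs <- NULL; gcorr <- NULL
  truthPath <- file.path(dir, "truth.json")
  if (file.exists(truthPath)) {
    truth <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    specs <- truth$specs
    if (!is.null(truth$genetic_corr)) gcorr <- as.matrix(truth$genetic_corr)
  }
  retest <- NULL
  rtPath <- file.path(dir, "retest.csv")
  if (file.exists(rtPath)) {
    rt <- read.csv(rtPath, stringsAsFactors = FALSE)
    if (nrow(rt) > 0) {
      retest <- t(as.matrix(rt[, setdiff(colnames(rt), "subject_id"),
                               drop = FALSE]))
      colnames(retest) <- rt$subject_id
    }
  }
  twinCohort(mat, subjects, specs = specs, retest = retest,
             geneticCorr = gcorr)
}
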