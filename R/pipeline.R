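#' Pipeline configuration
#'
#' Either a simulation design (`design` + `specs`) or a cohort directory
#' (`inputDir`, as written by [writeCohort()]) must be supplied. Stage
#' toggles select which analyses run; the factor-level rerun repeats the
#' classical and classifier-weight heritability estimation on factor
#' scores, including the dual-score (regression + Bartlett) robustness
#' run.
#'
#' @param design a [cohortDesign()], or NULL when loading from disk.
#' @param specs a [varianceSpecs()] table matching `design`.
#' @param inputDir directory with cohort CSVs, or NULL when simulating.
#' @param stages character subset of c("fingerprint", "heritability",
#'   "genecorr", "mlweights", "factors", "stats").
#' @param mlConfig a [runConfig()] for the classifier stages.
#' @param nFactors integer or NULL (Kaiser rule).
#' @param nPermIdentify permutations for the fingerprint null.
#' @param nPermDomain Monte Carlo permutations for the domain test.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param outputDir optional directory; when set, [runPipeline()] writes
#'   the report bundle there.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(design = NULL, specs = NULL, inputDir = NULL,
                           stages = c("fingerprint", "heritability",
                                      "genecorr", "mlweights", "factors",
                                      "stats"),
                           mlConfig = runConfig(), nFactors = NULL,
                           nPermIdentify = 1000L, nPermDomain = 100000L,
                           seed = 1L, outputDir = NULL) {
  if (is.null(design) && is.null(inputDir))
    stop("either a simulation design or an input directory is required")
  structure(list(design = design, specs = specs, inputDir = inputDir,
                 stages = stages, mlConfig = mlConfig, nFactors = nFactors,
                 nPermIdentify = as.integer(nPermIdentify),
                 nPermDomain = as.integer(nPermDomain),
                 seed = as.integer(seed), outputDir = outputDir),
            class = "PipelineConfig")
}

# deterministic per-stage seeds derived from the global seed
.stageSeeds <- function(seed) {
  nm <- c("simulate", "fingerprint", "heritability", "genecorr",
          "mlweights", "factors", "stats")
  withr::with_seed(seed, setNames(sample.int(2^31 - 2, length(nm)), nm))
}

.mlStage <- function(pairset, config, seed) {
  cfg <- config
  cfg@seed <- as.integer(seed %% (2^31 - 1))
  uni <- univariateWeights(pairset, cfg)
  ridge <- ridgeClassify(pairset, cfg)
  rf <- rfClassify(pairset, cfg)
  list(univariate = uni, ridge = ridge, rf = rf)
}

#' Run the full twin-heritability pipeline
#'
#' Simulates (or loads) a cohort, then in order: fingerprinting (self
#' mode when retest data exist, twin mode always), the classical Falconer
#' heritability profile, the bivariate genetic correlation matrix, the
#' three-classifier weight profiles, factor extraction with the
#' factor-level rerun (Falconer + three classifiers + Spearman agreement
#' on regression factor scores, plus the dual regression+Bartlett score
#' run), and the cross-method Spearman matrix with domain permutation
#' tests. Identical config and seed reproduce the bundle exactly.
#'
#' @param config a [pipelineConfig()].
#' @return A nested list (`cohort`, one entry per executed stage, and
#'   `seeds`); written to `config$outputDir` when set.
#' @export
runPipeline <- function(config) {
  seeds <- .stageSeeds(config$seed)
  report <- list(seeds = seeds, log = character())
  note <- function(...) {
    report$log <<- c(report$log, sprintf(...))
  }

  cohort <- if (!is.null(config$design)) {
    design <- config$design
    design$seed <- as.integer(seeds[["simulate"]] %% (2^31 - 1))
    note("simulated cohort under stage seed %d", design$seed)
    simulateCohort(design, config$specs)
  } else {
    note("loaded cohort from %s", config$inputDir)
    readCohort(config$inputDir)
  }
  report$cohort <- cohort

  run <- function(stage) stage %in% config$stages

  if (run("fingerprint")) {
    fp <- list()
    if (ncol(cohort@retest) > 0)
      fp$self <- fingerprintSelf(cohort, nPerm = config$nPermIdentify,
                                 seed = seeds[["fingerprint"]])
    else note("no retest data: self-identification skipped")
    fp$twin <- fingerprintTwin(cohort, nPerm = config$nPermIdentify,
                               seed = seeds[["fingerprint"]] + 1)
    report$fingerprint <- fp
  }

  profile <- NULL
  if (run("heritability") || run("stats")) {
    profile <- falconerProfile(cohort)
    if (all(is.na(profile$reliability)))
      note("no retest data: disattenuation skipped")
    report$heritability <- profile
  }

  if (run("genecorr"))
    report$genecorr <- geneticCorrelationMatrix(cohort)

  ml <- NULL
  if (run("mlweights") || run("stats")) {
    pairset <- buildPairFeatures(cohort)
    ml <- .mlStage(pairset, config$mlConfig, seeds[["mlweights"]])
    report$mlweights <- ml
  }

  if (run("factors")) {
    ph <- phenoMatrix(cohort)
    model <- promaxRotate(pafExtract(cor(ph), nFactors = config$nFactors))
    fa <- list(model = model)
    if (model@nFactors >= 2) {
      scReg <- factorScores(ph, model, "regression")
      scBart <- factorScores(ph, model, "bartlett")
      fa$scoreAgreement <- vapply(seq_len(ncol(scReg)), function(k)
        cor(scReg[, k], scBart[, k]), numeric(1))
      sdta <- subjectData(cohort)
      psReg <- pairFeaturesFromScores(scReg, sdta)
      fa$ml <- .mlStage(psReg, config$mlConfig, seeds[["factors"]])
      # classical heritability of the factor scores
      fcoh <- twinCohort(t(scReg), sdta)
      fa$heritability <- falconerProfile(fcoh)
      fa$spearman <- spearmanMatrix(list(
        falconer = fa$heritability$h2,
        univariate = fa$ml$univariate$mean,
        ridge = fa$ml$ridge$weights$mean,
        rf = fa$ml$rf$weights$mean))
      # dual score sets: correlated-feature robustness
      dual <- cbind(scReg, scBart)
      colnames(dual) <- c(paste0(colnames(scReg), "_reg"),
                          paste0(colnames(scBart), "_bart"))
      psDual <- pairFeaturesFromScores(dual, sdta)
      cfgDual <- config$mlConfig
      cfgDual@seed <- as.integer((seeds[["factors"]] + 1) %% (2^31 - 1))
      fa$dual <- list(ridge = ridgeClassify(psDual, cfgDual),
                      rf = rfClassify(psDual, cfgDual))
    } else {
      note("fewer than 2 factors retained: factor-level rerun skipped")
    }
    report$factors <- fa
  }

  if (run("stats")) {
    profiles <- list(falconer = profile$h2,
                     univariate = ml$univariate$mean,
                     ridge = ml$ridge$weights$mean,
                     rf = ml$rf$weights$mean)
    report$stats <- list(
      spearman = spearmanMatrix(profiles),
      domainTests = if (length(unique(profile$domain)) == 2)
        domainTestFamily(profiles, profile$domain,
                         nPerm = config$nPermDomain,
                         seed = seeds[["stats"]])
      else NULL
    )
    if (length(unique(profile$domain)) != 2)
      note("cohort has a single measure domain: domain test skipped")
  }

  if (!is.null(config$outputDir)) writeReportBundle(report, config$outputDir)
  report
}

#' Write a pipeline report bundle
#'
#' TSV/CSV/JSON files: the heritability profile, weight profiles, Spearman
#' and genetic-correlation matrices, identification summaries, domain
#' tests, the simulation truth (when available) and the run log with all
#' stage seeds.
#'
#' @param report list returned by [runPipeline()].
#' @param dir output directory, created if needed.
#' @return Invisibly `dir`.
#' @export
writeReportBundle <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wtsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wmat <- function(m, f) utils::write.table(
    data.frame(id = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)

  if (!is.null(report$cohort)) {
    writeCohort(report$cohort, file.path(dir, "cohort"))
  }
  if (!is.null(report$heritability))
    wtsv(report$heritability, "heritability_falconer.tsv")
  if (!is.null(report$mlweights)) {
    wtsv(rbind(report$mlweights$univariate,
               report$mlweights$ridge$weights,
               report$mlweights$rf$weights), "weight_profiles.tsv")
    perf <- list(ridge = report$mlweights$ridge$performance,
                 rf = report$mlweights$rf$performance,
                 ridge_alpha = report$mlweights$ridge$alpha)
    jsonlite::write_json(perf, file.path(dir, "performance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$genecorr)) {
    wmat(report$genecorr@rhoG, "rho_g.tsv")
    wmat(report$genecorr@rhoE, "rho_e.tsv")
    wmat(report$genecorr@mask * 1, "rho_mask.tsv")
    wtsv(geneticCorrelationLong(report$genecorr), "rho_long.tsv")
  }
  if (!is.null(report$fingerprint)) {
    fpSummary <- lapply(report$fingerprint, function(r) list(
      n_targets = r@nTargets, n_correct = r@nCorrect,
      accuracy = r@accuracy, median_rank = r@medianRank,
      mean_rank = r@meanRank, p_value = r@pValue, p_exact = r@pExact))
    jsonlite::write_json(fpSummary, file.path(dir, "fingerprint.json"),
                         auto_unbox = TRUE, digits = NA)
    for (mode in names(report$fingerprint))
      wtsv(identificationReport(report$fingerprint[[mode]]),
           paste0("fingerprint_", mode, ".tsv"))
  }
  if (!is.null(report$factors) && !is.null(report$factors$model)) {
    m <- report$factors$model
    if (m@nFactors > 0) {
      wmat(m@loadings, "factor_loadings.tsv")
      wtsv(data.frame(eigenvalue = m@eigenvalues), "eigenvalues.tsv")
    }
    if (!is.null(report$factors$heritability))
      wtsv(report$factors$heritability, "factor_heritability.tsv")
    if (!is.null(report$factors$spearman))
      wmat(report$factors$spearman, "factor_spearman.tsv")
  }
  if (!is.null(report$stats)) {
    wmat(report$stats$spearman, "spearman.tsv")
    if (!is.null(report$stats$domainTests))
      wtsv(report$stats$domainTests, "domain_tests.tsv")
  }
  writeLines(c(sprintf("stage seeds: %s",
                       paste(names(report$seeds), report$seeds,
                             sep = "=", collapse = " ")),
               report$log), file.path(dir, "run_log.txt"))
  invisible(dir)
}
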