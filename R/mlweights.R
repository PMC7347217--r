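## MZ-vs-DZ pair classification. Feature weights of the fitted models act
## as qualitative per-measure heritability estimates: under the classical
## model, a more heritable measure separates MZ from DZ pair differences
## more strongly, so it earns a larger absolute weight / importance.

# ridge least squares of y (+/-1) on X with unpenalized intercept
.ridgeFit <- function(X, y, alpha) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  w <- solve(crossprod(Xc) + diag(alpha, ncol(X)), crossprod(Xc, y - ym))
  list(w = drop(w), b = ym - sum(xm * drop(w)))
}

.ridgePredict <- function(fit, X) {
  s <- drop(X %*% fit$w) + fit$b
  ifelse(s >= 0, 1, -1)
}

# stratified train/test split of indices by label
.stratifiedSplit <- function(labels, testFraction) {
  test <- unlist(lapply(unique(labels), function(l) {
    idx <- which(labels == l)
    sample(idx, max(1L, round(testFraction * length(idx))))
  }))
  list(train = setdiff(seq_along(labels), test), test = test)
}

# k-fold CV classification accuracy per alpha; ties keep grid order
.cvSelectAlpha <- function(X, y, grid, folds) {
  n <- length(y)
  fold <- sample(rep_len(seq_len(folds), n))
  acc <- vapply(grid, function(a) {
    mean(vapply(seq_len(folds), function(k) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- .ridgeFit(X[tr, , drop = FALSE], y[tr], a)
      mean(.ridgePredict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(acc)]
}

# one iteration's balanced train/test data; redraws degenerate splits
.iterationData <- function(pairset, config, counter) {
  for (try in 1:100) {
    if (config@strictSplit) {
      sp <- .stratifiedSplit(pairset@labels, config@testFraction)
      trainSet <- new("PairFeatureSet",
                      features = pairset@features[sp$train, , drop = FALSE],
                      labels = pairset@labels[sp$train],
                      pairIds = pairset@pairIds[sp$train])
      bal <- oversampleBalance(trainSet)
      testSet <- new("PairFeatureSet",
                     features = pairset@features[sp$test, , drop = FALSE],
                     labels = pairset@labels[sp$test],
                     pairIds = pairset@pairIds[sp$test])
      balTest <- oversampleBalance(testSet)
      out <- list(xTrain = bal@features, yTrain = bal@labels,
                  xTest = balTest@features, yTest = balTest@labels)
    } else {
      bal <- oversampleBalance(pairset)
      sp <- .stratifiedSplit(bal@labels, config@testFraction)
      out <- list(xTrain = bal@features[sp$train, , drop = FALSE],
                  yTrain = bal@labels[sp$train],
                  xTest = bal@features[sp$test, , drop = FALSE],
                  yTest = bal@labels[sp$test])
    }
    if (length(unique(out$yTrain)) == 2 && length(unique(out$yTest)) == 2)
      return(out)
    counter$redraws <- counter$redraws + 1L
  }
  stop("could not draw a non-degenerate split in 100 attempts")
}

#' Univariate OLS feature weights
#'
#' Per feature, an ordinary least-squares regression of the +/-1 class
#' label on that single feature (with intercept), repeated over bootstrap
#' iterations of \{oversample-balance, train/test split, fit on training
#' rows\}. The absolute slope measures the feature's maximal contribution
#' in isolation; for informative features the raw slope is expected to be
#' negative (MZ pair differences are smaller, and MZ is the +1 class).
#'
#' @param pairset a [PairFeatureSet-class].
#' @param config a [runConfig()].
#' @return data.frame with per-feature `mean` and `sd` of the absolute
#'   slope across iterations, `mean_signed` (raw slope mean), and
#'   `method = "univariate"`.
#' @export
univariateWeights <- function(pairset, config = runConfig()) {
  M <- ncol(pairset@features)
  counter <- new.env(); counter$redraws <- 0L
  withr::with_seed(config@seed, {
    absW <- matrix(NA_real_, config@nIterations, M)
    rawW <- absW
    for (it in seq_len(config@nIterations)) {
      dat <- .iterationData(pairset, config, counter)
      yc <- dat$yTrain - mean(dat$yTrain)
      for (j in seq_len(M)) {
        x <- dat$xTrain[, j]
        vx <- var(x)
        if (vx == 0) {
          warning("constant feature ", j, " in iteration ", it,
                  "; weight set to 0")
          rawW[it, j] <- 0
        } else {
          rawW[it, j] <- cov(x, yc) / vx
        }
      }
      absW[it, ] <- abs(rawW[it, ])
    }
    data.frame(
      feature = colnames(pairset@features),
      mean = colMeans(absW), sd = apply(absW, 2, sd),
      mean_signed = colMeans(rawW),
      method = "univariate", stringsAsFactors = FALSE
    )
  })
}

#' Ridge classification of MZ vs DZ pairs
#'
#' Two-phase protocol. Phase 1 selects the penalty: over
#' `nAlphaIterations` iterations of \{balance, split\}, a `cvFolds`-fold
#' cross-validation on the training rows scores every penalty in
#' `alphaGrid` and the per-iteration winners are tallied; the modal value
#' becomes the single final alpha. Phase 2 re-runs `nIterations` of
#' \{balance, 70/30 split, fit the L2-penalized linear classifier on +/-1
#' labels at the final alpha\}, recording held-out accuracy and absolute
#' coefficients.
#'
#' @param pairset a [PairFeatureSet-class] with >= 2 features.
#' @param config a [runConfig()].
#' @param alpha optional fixed penalty; skips phase 1.
#' @return list with `performance` (see [summarizePerformance()]),
#'   `weights` (data.frame feature/mean/sd/mean_signed/method), `alpha`
#'   (the penalty used), `alphaCounts` (phase-1 tally, NULL when fixed) and
#'   `degenerateRedraws`.
#' @export
ridgeClassify <- function(pairset, config = runConfig(), alpha = NULL) {
  if (ncol(pairset@features) < 2) stop("need at least 2 features")
  counter <- new.env(); counter$redraws <- 0L
  alphaCounts <- NULL
  withr::with_seed(config@seed, {
    if (is.null(alpha)) {
      picks <- vapply(seq_len(config@nAlphaIterations), function(it) {
        dat <- .iterationData(pairset, config, counter)
        .cvSelectAlpha(dat$xTrain, dat$yTrain, config@alphaGrid,
                       config@cvFolds)
      }, numeric(1))
      alphaCounts <- table(factor(picks, levels = config@alphaGrid))
      alpha <- config@alphaGrid[which.max(alphaCounts)]
    }
    M <- ncol(pairset@features)
    accs <- numeric(config@nIterations)
    absW <- matrix(NA_real_, config@nIterations, M)
    rawW <- absW
    for (it in seq_len(config@nIterations)) {
      dat <- .iterationData(pairset, config, counter)
      fit <- .ridgeFit(dat$xTrain, dat$yTrain, alpha)
      accs[it] <- mean(.ridgePredict(fit, dat$xTest) == dat$yTest)
      rawW[it, ] <- fit$w
      absW[it, ] <- abs(fit$w)
    }
    list(
      performance = summarizePerformance(accs),
      weights = data.frame(feature = colnames(pairset@features),
                           mean = colMeans(absW), sd = apply(absW, 2, sd),
                           mean_signed = colMeans(rawW),
                           method = "ridge", stringsAsFactors = FALSE),
      alpha = alpha, alphaCounts = alphaCounts,
      degenerateRedraws = counter$redraws
    )
  })
}

.rangerMtry <- function(maxFeatures, M) {
  switch(maxFeatures,
         sqrt = max(1L, floor(sqrt(M))),
         log2 = max(1L, floor(log2(M))),
         all = M)
}

#' Random-forest classification of MZ vs DZ pairs
#'
#' `nIterations` of \{balance, split, fit a `rfTrees`-tree forest of depth
#' `rfMaxDepth` considering `rfMaxFeatures` features per split\}, recording
#' held-out accuracy, ROC AUC and Gini mean-decrease-impurity feature
#' importances (normalized to sum to 1 per iteration, so importances are
#' comparable across iterations).
#'
#' @inheritParams ridgeClassify
#' @return list with `performance` (including `meanAuc`/`sdAuc`),
#'   `weights` (mean/sd of normalized importances, `method = "rf"`) and
#'   `degenerateRedraws`.
#' @export
rfClassify <- function(pairset, config = runConfig()) {
  if (ncol(pairset@features) < 2) stop("need at least 2 features")
  M <- ncol(pairset@features)
  counter <- new.env(); counter$redraws <- 0L
  withr::with_seed(config@seed, {
    accs <- numeric(config@nIterations)
    aucs <- numeric(config@nIterations)
    imps <- matrix(NA_real_, config@nIterations, M)
    for (it in seq_len(config@nIterations)) {
      dat <- .iterationData(pairset, config, counter)
      df <- as.data.frame(dat$xTrain)
      df$.label <- factor(dat$yTrain, levels = c(-1, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = config@rfTrees, max.depth = config@rfMaxDepth,
        mtry = .rangerMtry(config@rfMaxFeatures, M),
        importance = "impurity", probability = TRUE,
        num.threads = 1, seed = sample.int(.Machine$integer.max, 1)
      )
      prob <- predict(fit, data = as.data.frame(dat$xTest),
                      num.threads = 1)$predictions[, "1"]
      accs[it] <- mean(ifelse(prob >= 0.5, 1, -1) == dat$yTest)
      aucs[it] <- as.numeric(pROC::auc(
        response = factor(dat$yTest, levels = c(-1, 1)), predictor = prob,
        quiet = TRUE, direction = "<"))
      imp <- fit$variable.importance
      imps[it, ] <- imp / sum(imp)
    }
    list(
      performance = summarizePerformance(accs, aucs),
      weights = data.frame(feature = colnames(pairset@features),
                           mean = colMeans(imps), sd = apply(imps, 2, sd),
                           mean_signed = NA_real_,
                           method = "rf", stringsAsFactors = FALSE),
      degenerateRedraws = counter$redraws
    )
  })
}

#' Out-of-bag hyper-parameter sweep for the random forest
#'
#' Two one-dimensional sweeps of mean out-of-bag (OOB) accuracy, each run
#' for the three `max_features` policies (sqrt, log2, all): (a) number of
#' trees over `nTreesGrid` at unlimited depth, and (b) maximum depth over
#' `depthGrid` (NA = unlimited) at 100 trees. Every cell averages `nReps`
#' refits, re-balancing the pair set each time. A recommended setting is
#' the smallest tree count / depth whose OOB accuracy is within
#' `plateauTol` of that sweep's best, under the best `max_features` policy.
#'
#' @param pairset a [PairFeatureSet-class] (>= 30 pairs recommended).
#' @param nTreesGrid integer grid for the tree-count sweep.
#' @param depthGrid integer grid for the depth sweep; NA means unlimited.
#' @param maxFeaturesOptions subset of c("sqrt", "log2", "all").
#' @param nReps refits per cell.
#' @param plateauTol accuracy slack defining the plateau.
#' @param seed integer seed.
#' @return list with `table` (param, value, max_features, oob_accuracy) and
#'   `recommended` (nTrees, maxDepth, maxFeatures).
#' @export
rfTune <- function(pairset, nTreesGrid = seq(20L, 160L, by = 20L),
                   depthGrid = c(1:10, NA),
                   maxFeaturesOptions = c("sqrt", "log2", "all"),
                   nReps = 100L, plateauTol = 0.005, seed = 1L) {
  M <- ncol(pairset@features)
  oobCell <- function(trees, depth, mf) {
    mean(vapply(seq_len(nReps), function(r) {
      bal <- oversampleBalance(pairset)
      df <- as.data.frame(bal@features)
      df$.label <- factor(bal@labels, levels = c(-1, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = trees, max.depth = if (is.na(depth)) 0 else depth,
        mtry = .rangerMtry(mf, M), num.threads = 1,
        seed = sample.int(.Machine$integer.max, 1)
      )
      1 - fit$prediction.error
    }, numeric(1)))
  }
  withr::with_seed(seed, {
    rows <- list()
    for (mf in maxFeaturesOptions) {
      for (tr in nTreesGrid)
        rows[[length(rows) + 1]] <- data.frame(
          param = "n_trees", value = tr, max_features = mf,
          oob_accuracy = oobCell(tr, NA, mf))
      for (dp in depthGrid)
        rows[[length(rows) + 1]] <- data.frame(
          param = "max_depth", value = dp, max_features = mf,
          oob_accuracy = oobCell(100L, dp, mf))
    }
    tab <- do.call(rbind, rows)
    byMf <- aggregate(oob_accuracy ~ max_features, tab, mean)
    bestMf <- byMf$max_features[which.max(byMf$oob_accuracy)]
    pick <- function(param) {
      sub <- tab[tab$param == param & tab$max_features == bestMf, ]
      ok <- sub$oob_accuracy >= max(sub$oob_accuracy) - plateauTol
      sub$value[ok][which.min(sub$value[ok])]
    }
    list(table = tab,
         recommended = list(nTrees = pick("n_trees"),
                            maxDepth = pick("max_depth"),
                            maxFeatures = bestMf))
  })
}

#' Forward-model (activation-pattern) transform of classifier weights
#'
#' Converts backward-model decoder weights into the activation pattern of
#' the corresponding forward model: `pattern = featureCovariance %*% w`
#' (up to a positive scale). Unlike raw multivariate weights, activation
#' patterns do not assign large values to noise-suppressor features, which
#' makes them safer to interpret as per-feature signal strength.
#'
#' @param weights numeric vector of decoder weights.
#' @param featureCovariance square PSD matrix, dimension = length(weights).
#' @return list with `pattern` and `absPattern`.
#' @export
haufeTransform <- function(weights, featureCovariance) {
  featureCovariance <- as.matrix(featureCovariance)
  if (nrow(featureCovariance) != ncol(featureCovariance) ||
      nrow(featureCovariance) != length(weights))
    stop("featureCovariance must be square with dimension = #weights")
  p <- drop(featureCovariance %*% weights)
  list(pattern = p, absPattern = abs(p))
}

#' Summarize a bootstrap accuracy distribution
#'
#' Mean accuracy, 95% percentile confidence interval (2.5th / 97.5th), and
#' the bootstrap p-value: the fraction of iterations with test accuracy
#' equal to or below 50%, the chance level of a balanced binary problem.
#' A zero count is reported as the upper bound `1/n` with `pExact = FALSE`
#' (printed "< 1/n"), never exactly zero.
#'
#' @param accuracies numeric vector of per-iteration test accuracies.
#' @param aucs optional numeric vector of per-iteration ROC AUCs.
#' @return list with `meanAccuracy`, `ci95`, `bootstrapP`, `pExact`, `n`,
#'   and (when given) `meanAuc`, `sdAuc`.
#' @export
summarizePerformance <- function(accuracies, aucs = NULL) {
  if (length(accuracies) < 2) stop("need at least 2 accuracy values")
  n <- length(accuracies)
  count <- sum(accuracies <= 0.5)
  out <- list(
    meanAccuracy = mean(accuracies),
    ci95 = unname(quantile(accuracies, c(0.025, 0.975))),
    bootstrapP = if (count == 0) 1 / n else count / n,
    pExact = count > 0,
    n = n
  )
  if (!is.null(aucs)) {
    out$meanAuc <- mean(aucs)
    out$sdAuc <- sd(aucs)
  }
  out
}
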