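## md5 of the trial matrix for report provenance (binary-stable)
.inputHash <- function(M) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(as.vector(M), f)
  unname(tools::md5sum(f))
}

#' Run the full decomposition pipeline and collect the report
#'
#' Orchestrates assemble -> whiten -> PCA scoring -> iterative SVM
#' decomposition -> complement PCA -> ICA -> effect sizes, and returns a
#' machine-readable report: per-basis-vector classification rates,
#' significance flags and explained-variance fractions for the PCA, SVM and
#' ICA bases, the effect sizes of the best classifying PCA vector, the
#' first SVM vector and the ICA discriminant, the iteration log, and full
#' provenance (input hash, seeds, threshold mode, SVM cost, package
#' version).  Two runs with identical inputs and seeds produce identical
#' reports.
#'
#' @param trials list of preprocessed \linkS4class{TrialRecord}s, or an
#'   already assembled (raw or whitened) \linkS4class{KinematicExperiment}.
#' @param rule \linkS4class{ClassifiabilityRule} shared by every stage.
#' @param cost SVM box constraint C.
#' @param icaSeed seed for the ICA initialization.
#' @param icaAlgorithm \code{"infomax"} or \code{"fastica"}.
#' @param maxPcaVectors how many leading PCA vectors to score by LOSO
#'   classification (default: all up to rank, capped at 30).
#' @param maxIter cap on SVM iterations (default: rank).
#' @param degenerate whitening policy for zero-variance variables.
#' @return a nested list report (see Details); the fitted objects are
#'   attached in the \code{objects} element.
#' @export
runPipeline <- function(trials, rule = classifiabilityRule(), cost = 1,
                        icaSeed = 1L, icaAlgorithm = "infomax",
                        maxPcaVectors = 30L, maxIter = NULL,
                        degenerate = c("error", "zero")) {
  ke <- if (is(trials, "KinematicExperiment")) trials
        else assembleMatrix(trials)
  if (!isWhitened(ke)) ke <- whiten(ke, degenerate = match.arg(degenerate))
  cd <- trialInfo(ke)
  labels <- as.character(cd$condition)
  subjects <- as.character(cd$subject)

  pca <- pcaBasis(ke)
  kScan <- min(length(pca), maxPcaVectors)
  pcaRates <- losoRates(ke, vectors = seq_len(kScan), rule = rule,
                        fullBasis = pca)
  pcaSplit <- classifyingPcaSpace(pca, pcaRates)
  bestPca <- NULL
  if (length(pcaSplit$classifying) > 0L) {
    cls <- pcaSplit$classifying
    best <- which.max(cls@rates)
    proj <- drop(trialMatrix(ke) %*% cls@vectors[, best])
    bestPca <- list(index = pcaRates$index[pcaRates$significant][best],
                    rate = cls@rates[best],
                    effectSize = cohensD(proj, labels),
                    normal = tryCatch(
                      all(normalityGate(proj, labels)),
                      error = function(e) NA))
  }

  dec <- svmDecompose(ke, rule = rule, cost = cost, maxIter = maxIter)
  svmB <- svmBasis(dec)
  firstSvm <- NULL
  if (length(svmB) > 0L) {
    proj <- drop(trialMatrix(ke) %*% svmB@vectors[, 1L])
    firstSvm <- list(rate = svmB@rates[1L], effectSize = svmB@effectSize[1L],
                     varianceFraction = svmB@varianceFraction[1L],
                     normal = tryCatch(all(normalityGate(proj, labels)),
                                       error = function(e) NA))
  }

  ica <- NULL; icaInfo <- NULL
  if (length(svmB) > 0L) {
    ica <- icaInSubspace(ke, dec, seed = icaSeed, algorithm = icaAlgorithm,
                         rule = rule)
    idx <- icaDiscriminantIndex(ica)
    icaInfo <- list(
      nVectors = ncol(icaVectors(ica)),
      rates = ica@rates, significant = ica@significant,
      discriminantIndex = if (length(idx)) idx else NA_integer_,
      discriminantRate = if (length(idx)) ica@rates[idx] else NA_real_,
      discriminantEffectSize = if (length(idx)) ica@effectSize[idx]
                               else NA_real_,
      discriminantVarianceFraction = if (length(idx))
        explainedVariance(icaVectors(ica)[, idx, drop = FALSE], ke)
        else NA_real_,
      seed = ica@seed, algorithm = ica@algorithm,
      converged = ica@converged)
  }

  report <- list(
    schema = "gaitSubspace-report/1",
    provenance = list(
      package = as.character(packageVersion("gaitSubspace")),
      inputHash = .inputHash(trialMatrix(ke)),
      thresholdMode = rule@mode, alpha = rule@alpha,
      successProb = rule@successProb, svmCost = cost,
      icaSeed = as.integer(icaSeed), icaAlgorithm = icaAlgorithm),
    data = list(nTrials = ncol(ke), nVariables = nrow(ke),
                nSubjects = length(unique(subjects)),
                conditions = sort(unique(labels)),
                markers = indexMap(ke)@markers,
                timepoints = indexMap(ke)@timepoints),
    pca = list(scanned = kScan, perVector = pcaRates,
               nClassifying = length(pcaSplit$classifying),
               best = bestPca),
    svm = list(nVectors = length(svmB),
               rates = svmB@rates,
               varianceFractions = svmB@varianceFraction,
               svmSpaceVariance = sum(svmB@varianceFraction),
               meanRate = if (length(svmB)) mean(svmB@rates) else NA_real_,
               first = firstSvm,
               iterationLog = iterationLog(dec),
               termination = dec@termination),
    ica = icaInfo)
  report$objects <- list(experiment = ke, pcaBasis = pca,
                         pcaSpaces = pcaSplit, decomposition = dec, ica = ica)
  report
}

#' Write a pipeline report to JSON
#'
#' Serializes the report (without the fitted R objects) to pretty-printed
#' JSON.
#'
#' @param report result of [runPipeline()].
#' @param file output path.
#' @export
writeReport <- function(report, file) {
  report$objects <- NULL
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns", force = TRUE)
  invisible(file)
}
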