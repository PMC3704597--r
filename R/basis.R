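#' @rdname basisVectors
#' @export
setMethod("basisVectors", "OrthonormalBasis", function(x) x@vectors)

#' @rdname basisScores
#' @export
setMethod("basisScores", "OrthonormalBasis", function(x) x@scores)

#' @rdname basisRates
#' @export
setMethod("basisRates", "OrthonormalBasis", function(x) x@rates)

#' @rdname basisSignificant
#' @export
setMethod("basisSignificant", "OrthonormalBasis", function(x) x@significant)

#' @rdname varianceFractions
#' @export
setMethod("varianceFractions", "OrthonormalBasis", function(x)
  x@varianceFraction)

#' @describeIn OrthonormalBasis-class number of basis vectors.
#' @param x an \linkS4class{OrthonormalBasis}.
#' @export
setMethod("length", "OrthonormalBasis", function(x) ncol(x@vectors))

#' @describeIn OrthonormalBasis-class subset to a set of vectors (order
#'   preserved).
#' @param i integer or logical index of vectors to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "OrthonormalBasis", function(x, i, j, ..., drop = FALSE) {
  OrthonormalBasis(vectors = x@vectors[, i, drop = FALSE],
                   scores = x@scores[i], varianceFraction = x@varianceFraction[i],
                   rates = x@rates[i], significant = x@significant[i],
                   effectSize = x@effectSize[i], kind = x@kind)
})

setMethod("show", "OrthonormalBasis", function(object) {
  n <- length(object)
  cat(sprintf("OrthonormalBasis (%s): %d vector(s) in %d dimensions\n",
              object@kind, n, nrow(object@vectors)))
  if (n > 0L) {
    k <- min(n, 8L)
    df <- data.frame(varFraction = signif(object@varianceFraction[1:k], 3L),
                     rate = signif(object@rates[1:k], 3L),
                     significant = object@significant[1:k],
                     effectSize = signif(object@effectSize[1:k], 3L))
    print(df)
    if (n > k) cat("  ... and", n - k, "more\n")
  }
})

setMethod("show", "Discriminant", function(object) {
  cat(sprintf("Discriminant in %d dimensions (%s vs %s)\n",
              length(object@direction), object@positiveLevel,
              object@negativeLevel))
  if (nrow(object@folds) > 0L)
    cat(sprintf("  LOSO: %d folds, rate %.1f%%%s\n", nrow(object@folds),
                100 * object@rate,
                if (isTRUE(object@significant)) " (significant)" else ""))
})

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf("DecompositionResult: SVM space dim %d, complement dim %d (%s)\n",
              length(object@svmBasis), length(object@complementBasis),
              object@termination))
  cat(sprintf("  SVM-space variance fraction: %.4f\n",
              sum(object@svmBasis@varianceFraction)))
  if (length(object@svmBasis) > 0L)
    cat(sprintf("  mean classification rate: %.1f%%\n",
                100 * mean(object@svmBasis@rates)))
})

setMethod("show", "IcaResult", function(object) {
  cat(sprintf("IcaResult (%s, seed %d): %d vector(s)\n", object@algorithm,
              object@seed, ncol(object@vectors)))
  if (length(object@discriminantIndex))
    cat(sprintf("  discriminant: vector %d (rate %.1f%%, |d| = %.2f)\n",
                object@discriminantIndex,
                100 * object@rates[object@discriminantIndex],
                object@effectSize[object@discriminantIndex]))
  else cat("  no significant discriminant\n")
})

setMethod("show", "ClassifiabilityRule", function(object) {
  cat(sprintf("ClassifiabilityRule: mode \"%s\", alpha %g, p %g\n",
              object@mode, object@alpha, object@successProb))
})

#' @rdname svmBasis
#' @export
setMethod("svmBasis", "DecompositionResult", function(x) x@svmBasis)

#' @rdname complementBasis
#' @export
setMethod("complementBasis", "DecompositionResult", function(x)
  x@complementBasis)

#' @rdname iterationLog
#' @export
setMethod("iterationLog", "DecompositionResult", function(x) x@iterationLog)

#' @rdname jointBasis
#' @export
setMethod("jointBasis", "DecompositionResult", function(x)
  cbind(x@svmBasis@vectors, x@complementBasis@vectors))

#' @rdname icaVectors
#' @export
setMethod("icaVectors", "IcaResult", function(x) x@vectors)

#' @rdname icaDiscriminantIndex
#' @export
setMethod("icaDiscriminantIndex", "IcaResult", function(x)
  x@discriminantIndex)
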