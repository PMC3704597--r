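#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay "assay<-" colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pbinom sd var splinefun rnorm rt setNames cor cor.test
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Layout of the trial-by-variable kinematic matrix
#'
#' Describes how the time-resolved 3-D marker positions of one trial are
#' concatenated into a single row vector: marker-major, then axis (x, y, z),
#' then normalized time.  For the default configuration of 13 markers,
#' 3 axes and 101 time points a trial occupies 13 x 3 x 101 = 3939 columns.
#' All user-facing indices are 1-based.
#'
#' @slot markers integer, number of markers.
#' @slot axes integer, number of spatial axes (3).
#' @slot timepoints integer, number of normalized time points per waveform.
#' @export
setClass("KinematicLayout",
  representation(markers = "integer", axes = "integer", timepoints = "integer"),
  prototype(markers = 13L, axes = 3L, timepoints = 101L))

setValidity("KinematicLayout", function(object) {
  if (length(object@markers) != 1L || object@markers < 1L)
    return("'markers' must be a single positive integer")
  if (length(object@axes) != 1L || object@axes < 1L)
    return("'axes' must be a single positive integer")
  if (length(object@timepoints) != 1L || object@timepoints < 1L)
    return("'timepoints' must be a single positive integer")
  TRUE
})

#' @param markers,axes,timepoints layout dimensions.
#' @return A \code{KinematicLayout} object.
#' @rdname KinematicLayout-class
#' @examples
#' lay <- KinematicLayout()          # 13 markers x 3 axes x 101 time points
#' nVariables(lay)                   # 3939
#' @export
KinematicLayout <- function(markers = 13L, axes = 3L, timepoints = 101L) {
  new("KinematicLayout", markers = as.integer(markers),
      axes = as.integer(axes), timepoints = as.integer(timepoints))
}

#' A single kinematic trial
#'
#' One trial's time-resolved marker positions (frames x markers x axes, in
#' meters before height normalization) together with its identifying key and
#' an optional vertical ground-reaction-force trace used for stance-phase
#' detection.
#'
#' @slot subject character scalar, subject identifier.
#' @slot condition character scalar, one of the two condition names.
#' @slot trial integer scalar, trial index within subject and condition.
#' @slot positions numeric array, frames x markers x axes.
#' @slot sampleRate numeric scalar, Hz.
#' @slot force numeric vector of vertical force in newtons (may be empty).
#' @export
setClass("TrialRecord",
  representation(subject = "character", condition = "character",
                 trial = "integer", positions = "array",
                 sampleRate = "numeric", force = "numeric"))

setValidity("TrialRecord", function(object) {
  d <- dim(object@positions)
  if (length(d) != 3L) return("'positions' must be a frames x markers x axes array")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    return("'sampleRate' must be a single positive number")
  if (length(object@subject) != 1L || length(object@condition) != 1L ||
      length(object@trial) != 1L || object@trial < 1L)
    return("'subject', 'condition' and 'trial' must be scalars (trial >= 1)")
  TRUE
})

#' @param subject,condition,trial trial key.
#' @param positions frames x markers x axes numeric array.
#' @param sampleRate sampling rate in Hz.
#' @param force optional vertical force trace in newtons.
#' @return A \code{TrialRecord}.
#' @rdname TrialRecord-class
#' @export
TrialRecord <- function(subject, condition, trial, positions,
                        sampleRate = 240, force = numeric(0)) {
  new("TrialRecord", subject = as.character(subject),
      condition = as.character(condition), trial = as.integer(trial),
      positions = positions, sampleRate = as.numeric(sampleRate),
      force = as.numeric(force))
}

trialKeyString <- function(x)
  sprintf("subject=%s condition=%s trial=%d", x@subject, x@condition, x@trial)

#' Container for the assembled trial-by-variable matrix
#'
#' Extends \linkS4class{SummarizedExperiment}: the assay holds the variables
#' (rows) by trials (columns) matrix, \code{colData} carries the trial keys
#' (subject, condition, trial).  The layout, the whitening state and the
#' per-subject whitening statistics (means and standard deviations used for
#' de-whitening and metric reconstruction) travel with the object.
#'
#' @slot layout a \linkS4class{KinematicLayout}.
#' @slot whitened logical, whether per-subject whitening has been applied.
#' @slot subjectStats list with elements \code{mean} and \code{sd}
#'   (variables x subjects matrices) and \code{degenerate} (integer vector of
#'   zero-variance column indices, usually empty); empty list before
#'   whitening.
#' @export
setClass("KinematicExperiment",
  contains = "SummarizedExperiment",
  representation(layout = "KinematicLayout", whitened = "logical",
                 subjectStats = "list"),
  prototype(whitened = FALSE, subjectStats = list()))

setValidity("KinematicExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "condition", "trial")
  if (!all(need %in% colnames(cd)))
    return("colData must contain 'subject', 'condition' and 'trial'")
  if (nrow(object) != nVariables(object@layout))
    return(sprintf("assay has %d rows but the layout implies %d variables",
                   nrow(object), nVariables(object@layout)))
  key <- paste(cd$subject, cd$condition, cd$trial)
  if (anyDuplicated(key))
    return("(subject, condition, trial) keys must be unique")
  if (length(unique(cd$condition)) > 2L)
    return("'condition' takes more than two distinct values")
  TRUE
})

#' Ordered orthonormal basis of (a subspace of) the data space
#'
#' Unit vectors stored as columns, each annotated with a variance score
#' (PCA eigenvalue scale, \code{NA} where not applicable), the fraction of
#' total variance it explains, its leave-one-subject-out classification rate
#' (fraction of classifiable subjects, \code{NA} when not scored), the
#' subject-level significance flag, and Cohen's d effect size of the
#' condition projections (\code{NA} when not computed).
#'
#' @slot vectors numeric matrix, variables x n.
#' @slot scores numeric, per-vector variance score.
#' @slot varianceFraction numeric, fraction of total variance per vector.
#' @slot rates numeric, per-vector classification rate in [0, 1].
#' @slot significant logical, subject-level significance of the rate.
#' @slot effectSize numeric, per-vector |Cohen's d|.
#' @slot kind character, one of "pca", "svm", "complement".
#' @export
setClass("OrthonormalBasis",
  representation(vectors = "matrix", scores = "numeric",
                 varianceFraction = "numeric", rates = "numeric",
                 significant = "logical", effectSize = "numeric",
                 kind = "character"))

setValidity("OrthonormalBasis", function(object) {
  V <- object@vectors
  n <- ncol(V)
  for (nm in c("scores", "varianceFraction", "rates", "effectSize"))
    if (length(slot(object, nm)) != n)
      return(sprintf("'%s' must have one entry per vector", nm))
  if (length(object@significant) != n)
    return("'significant' must have one entry per vector")
  if (n > 0L) {
    G <- crossprod(V)
    if (max(abs(diag(G) - 1)) > 1e-10)
      return("basis vectors must have unit norm (tolerance 1e-10)")
    if (n > 1L && max(abs(G[upper.tri(G)])) > 1e-8)
      return("basis vectors must be pairwise orthogonal (tolerance 1e-8)")
    sc <- object@scores
    if (object@kind %in% c("pca", "complement") && !anyNA(sc) &&
        any(diff(sc) > 1e-8 * max(abs(sc), 1)))
      return("PCA variance scores must be non-increasing")
  }
  TRUE
})

OrthonormalBasis <- function(vectors, scores = rep(NA_real_, ncol(vectors)),
                             varianceFraction = rep(NA_real_, ncol(vectors)),
                             rates = rep(NA_real_, ncol(vectors)),
                             significant = rep(NA, ncol(vectors)),
                             effectSize = rep(NA_real_, ncol(vectors)),
                             kind = "pca") {
  new("OrthonormalBasis", vectors = vectors, scores = as.numeric(scores),
      varianceFraction = as.numeric(varianceFraction),
      rates = as.numeric(rates), significant = as.logical(significant),
      effectSize = as.numeric(effectSize), kind = kind)
}

#' A linear SVM discriminant
#'
#' The unit direction in data space obtained from a linear-kernel SVM (the
#' weighted sum of support vectors, normalized), together with the decision
#' bias, the normalization factor linking the kernel-sum decision function
#' to the dot product with the unit direction, and -- for leave-one-subject-out
#' fits -- the per-fold directions and classifiability bookkeeping.
#'
#' The decision value of a trial row \code{x} is
#' \code{normFactor * sum(x * direction) + bias}; trials with positive
#' decision value are assigned to \code{positiveLevel}.
#'
#' @slot direction numeric unit vector in data space.
#' @slot bias numeric decision offset.
#' @slot normFactor numeric, norm of the unnormalized discriminant.
#' @slot positiveLevel,negativeLevel character, condition labels on either
#'   side of the separating plane.
#' @slot folds data.frame with one row per held-out subject (columns
#'   \code{subject}, \code{correct}, \code{total}, \code{classifiable},
#'   \code{cosineToMean}); zero rows for a single fit.
#' @slot foldDirections numeric matrix, variables x folds (sign-aligned).
#' @slot rate numeric, fraction of classifiable subjects (\code{NA} for a
#'   single fit).
#' @slot significant logical, subject-level binomial significance.
#' @slot effectSize numeric, |Cohen's d| of the condition projections.
#' @export
setClass("Discriminant",
  representation(direction = "numeric", bias = "numeric",
                 normFactor = "numeric", positiveLevel = "character",
                 negativeLevel = "character", folds = "data.frame",
                 foldDirections = "matrix", rate = "numeric",
                 significant = "logical", effectSize = "numeric"))

setValidity("Discriminant", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-10)
    return("'direction' must be a unit vector (tolerance 1e-10)")
  TRUE
})

#' Result of the iterative SVM decomposition
#'
#' Bundles the SVM-space basis (iteratively extracted classifying
#' discriminants), the PCA basis of the final orthogonal complement, the
#' per-iteration log (including the final rejected iteration), the
#' discriminant objects themselves, and the statistical rule and SVM cost
#' under which the decomposition was run.
#'
#' @slot svmBasis,complementBasis \linkS4class{OrthonormalBasis}.
#' @slot discriminants list of \linkS4class{Discriminant}, one per accepted
#'   vector plus the final rejected one.
#' @slot iterationLog data.frame: iteration, rate, nClassifiable, nSubjects,
#'   significant, accepted.
#' @slot rule the \linkS4class{ClassifiabilityRule} used.
#' @slot cost numeric, SVM box constraint C.
#' @slot termination character: "rate-drop", "rank-exhausted" or "max-iter".
#' @export
setClass("DecompositionResult",
  representation(svmBasis = "OrthonormalBasis",
                 complementBasis = "OrthonormalBasis",
                 discriminants = "list", iterationLog = "data.frame",
                 rule = "ANY", cost = "numeric", termination = "character"))

#' ICA basis of the SVM space
#'
#' Result of running ICA on the coordinates of the trials within the SVM
#' space.  The recovered base vectors are mapped back to data space and unit
#' normalized; they span the SVM space but are generally not orthogonal.
#' Vectors are ordered by decreasing classification rate, so the ICA
#' discriminant -- when one exists -- is the first vector.
#'
#' Conventions: with \code{Y} the trials x m matrix of SVM-space coordinates,
#' sources are \code{S = Y \%*\% t(unmixing)} and \code{Y = S \%*\% t(mixing)}
#' with \code{mixing = solve(unmixing)}.
#'
#' @slot vectors numeric matrix, variables x m: unit base vectors in data
#'   space (images of the mixing columns).
#' @slot svmVectors numeric matrix, variables x m: the orthonormal SVM basis
#'   the ICA was run in.
#' @slot mixing,unmixing m x m transforms in SVM-space coordinates.
#' @slot rates,effectSize numeric per vector; \code{significant} logical.
#' @slot discriminantIndex integer: index of the selected discriminant
#'   (length 0 when no vector classifies significantly).
#' @slot seed integer random seed used for the ICA initialization.
#' @slot algorithm character, "infomax" or "fastica".
#' @slot converged logical; \code{iterations} integer.
#' @export
setClass("IcaResult",
  representation(vectors = "matrix", svmVectors = "matrix",
                 mixing = "matrix", unmixing = "matrix", rates = "numeric",
                 significant = "logical", effectSize = "numeric",
                 discriminantIndex = "integer", seed = "integer",
                 algorithm = "character", converged = "logical",
                 iterations = "integer"))

#' Binomial classifiability rule
#'
#' Encapsulates the one-sided binomial tests used throughout: a held-out
#' subject is classifiable when enough of its trials are assigned correctly,
#' and a classification rate is significant when enough subjects are
#' classifiable, both under Binomial(n, 0.5) at level alpha.
#'
#' Two modes exist.  \code{"exact"} computes the smallest count whose exact
#' upper-tail probability is at most alpha.  \code{"paper"} (the default
#' elsewhere) additionally pins the historically printed counts 25-of-40
#' trials and 8-of-11 subjects, which sit one below the exact thresholds
#' (26 and 9); for any other n it falls back to the exact computation.
#'
#' @slot mode character, "paper" or "exact".
#' @slot alpha numeric significance level.
#' @slot successProb numeric chance success probability (0.5).
#' @export
setClass("ClassifiabilityRule",
  representation(mode = "character", alpha = "numeric",
                 successProb = "numeric"))

setValidity("ClassifiabilityRule", function(object) {
  if (!object@mode %in% c("paper", "exact"))
    return("'mode' must be \"paper\" or \"exact\"")
  if (object@alpha <= 0 || object@alpha >= 1) return("'alpha' must be in (0, 1)")
  if (object@successProb <= 0 || object@successProb >= 1)
    return("'successProb' must be in (0, 1)")
  TRUE
})

#' Planted ground truth of a synthetic data set
#'
#' The condition-effect directions planted by the synthetic generator,
#' expressed both on the raw (meter) scale and as unit vectors in the
#' whitened variable space (computed from the realized per-subject whitening
#' statistics), against which recovered subspaces are scored.
#'
#' @slot directions variables x k matrix of unit vectors in whitened space.
#' @slot rawDirections variables x k matrix of unit vectors on the raw scale.
#' @slot amplitudes numeric, between-condition amplitude of each component
#'   (raw scale, same units as the generated positions).
#' @slot components data.frame describing each planted component
#'   (marker, axis, center, width, amplitude).
#' @export
setClass("SyntheticTruth",
  representation(directions = "matrix", rawDirections = "matrix",
                 amplitudes = "numeric", components = "data.frame"))
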