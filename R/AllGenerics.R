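#' Number of variables implied by a layout
#'
#' @param x a \linkS4class{KinematicLayout} or
#'   \linkS4class{KinematicExperiment}.
#' @return integer, markers x axes x timepoints.
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))

#' Trial-by-variable matrix of a KinematicExperiment
#'
#' @param x a \linkS4class{KinematicExperiment}.
#' @return numeric matrix with one row per trial and one column per variable
#'   (the transpose of the stored assay).
#' @export
setGeneric("trialMatrix", function(x) standardGeneric("trialMatrix"))

#' Trial metadata (subject, condition, trial) of a KinematicExperiment
#' @param x a \linkS4class{KinematicExperiment}.
#' @return a \code{DataFrame} aligned to the matrix rows.
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' Whitening state of a KinematicExperiment
#' @param x a \linkS4class{KinematicExperiment}.
#' @return logical scalar.
#' @export
setGeneric("isWhitened", function(x) standardGeneric("isWhitened"))

#' Per-subject whitening statistics
#' @param x a \linkS4class{KinematicExperiment}.
#' @return list with variables x subjects matrices \code{mean} and \code{sd}
#'   and the integer vector \code{degenerate}; empty list before whitening.
#' @export
setGeneric("subjectStats", function(x) standardGeneric("subjectStats"))

#' Layout of a KinematicExperiment
#' @param x a \linkS4class{KinematicExperiment}.
#' @return the \linkS4class{KinematicLayout}.
#' @export
setGeneric("indexMap", function(x) standardGeneric("indexMap"))

#' Per-subject whitening of the assembled matrix
#'
#' @param x a raw (unwhitened) \linkS4class{KinematicExperiment}.
#' @param ... further arguments (see methods).
#' @return the whitened object with subject statistics attached.
#' @export
setGeneric("whiten", function(x, ...) standardGeneric("whiten"))

#' Undo per-subject whitening
#' @param x a whitened \linkS4class{KinematicExperiment}.
#' @param ... further arguments.
#' @return the de-whitened (raw scale) object.
#' @export
setGeneric("unwhiten", function(x, ...) standardGeneric("unwhiten"))

#' Extract the waveform block of one marker/axis
#' @param x a \linkS4class{KinematicExperiment}.
#' @param marker,axis 1-based indices.
#' @param ... further arguments (see methods).
#' @export
setGeneric("extractWaveform",
           function(x, marker, axis, ...) standardGeneric("extractWaveform"))

#' Basis vectors as a variables x n matrix
#' @param x an \linkS4class{OrthonormalBasis}.
#' @export
setGeneric("basisVectors", function(x) standardGeneric("basisVectors"))

#' Per-vector variance scores of a basis
#' @param x an \linkS4class{OrthonormalBasis}.
#' @export
setGeneric("basisScores", function(x) standardGeneric("basisScores"))

#' Per-vector classification rates of a basis
#' @param x an \linkS4class{OrthonormalBasis}.
#' @export
setGeneric("basisRates", function(x) standardGeneric("basisRates"))

#' Per-vector significance flags of a basis
#' @param x an \linkS4class{OrthonormalBasis}.
#' @export
setGeneric("basisSignificant", function(x) standardGeneric("basisSignificant"))

#' Per-vector explained-variance fractions of a basis
#' @param x an \linkS4class{OrthonormalBasis}.
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))

#' SVM-space basis of a decomposition
#' @param x a \linkS4class{DecompositionResult}.
#' @export
setGeneric("svmBasis", function(x) standardGeneric("svmBasis"))

#' Complement PCA basis of a decomposition
#' @param x a \linkS4class{DecompositionResult}.
#' @export
setGeneric("complementBasis", function(x) standardGeneric("complementBasis"))

#' Iteration log of a decomposition
#' @param x a \linkS4class{DecompositionResult}.
#' @export
setGeneric("iterationLog", function(x) standardGeneric("iterationLog"))

#' Joint (SVM + complement) orthonormal basis
#' @param x a \linkS4class{DecompositionResult}.
#' @return variables x n matrix, SVM vectors first.
#' @export
setGeneric("jointBasis", function(x) standardGeneric("jointBasis"))

#' ICA base vectors in data space
#' @param x an \linkS4class{IcaResult}.
#' @export
setGeneric("icaVectors", function(x) standardGeneric("icaVectors"))

#' Index of the selected ICA discriminant
#' @param x an \linkS4class{IcaResult}.
#' @return integer index, or \code{integer(0)} when no ICA vector reaches a
#'   significant classification rate.
#' @export
setGeneric("icaDiscriminantIndex",
           function(x) standardGeneric("icaDiscriminantIndex"))
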