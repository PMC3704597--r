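#' Map (marker, axis, time) to a column of the assembled matrix
#'
#' The assembled matrix concatenates, per trial, the full time course of
#' marker 1 along x, then marker 1 along y, then z, then marker 2 along x,
#' and so on.  Under the 1-based convention used everywhere in reporting,
#' \deqn{col(m, a, t) = (m-1) \cdot A \cdot T + (a-1) \cdot T + t}
#' with \eqn{A} axes and \eqn{T} time points per block.  For the default
#' layout, (marker 3, axis 3, time 39) maps to column 847.
#'
#' All three index arguments are vectorized and recycled.
#'
#' @param layout a \linkS4class{KinematicLayout}.
#' @param marker,axis,time 1-based indices.
#' @return integer column index (vectorized).
#' @seealso [variableInfo()] for the inverse map.
#' @examples
#' variableIndex(KinematicLayout(), 3, 3, 39)   # 847
#' variableInfo(KinematicLayout(), 847)
#' @export
variableIndex <- function(layout, marker, axis, time) {
  stopifnot(is(layout, "KinematicLayout"))
  n <- max(length(marker), length(axis), length(time))
  marker <- rep_len(as.integer(marker), n)
  axis <- rep_len(as.integer(axis), n)
  time <- rep_len(as.integer(time), n)
  if (any(marker < 1L | marker > layout@markers))
    stop("'marker' out of range 1..", layout@markers)
  if (any(axis < 1L | axis > layout@axes))
    stop("'axis' out of range 1..", layout@axes)
  if (any(time < 1L | time > layout@timepoints))
    stop("'time' out of range 1..", layout@timepoints)
  (marker - 1L) * layout@axes * layout@timepoints +
    (axis - 1L) * layout@timepoints + time
}

#' Recover (marker, axis, time) from a column index
#'
#' Inverse of [variableIndex()]; the round trip is the identity for every
#' valid column.
#'
#' @param layout a \linkS4class{KinematicLayout}.
#' @param column 1-based column index (vectorized).
#' @return data.frame with columns \code{marker}, \code{axis}, \code{time}.
#' @export
variableInfo <- function(layout, column) {
  stopifnot(is(layout, "KinematicLayout"))
  column <- as.integer(column)
  if (any(column < 1L | column > nVariables(layout)))
    stop("'column' out of range 1..", nVariables(layout))
  z <- column - 1L
  blk <- layout@axes * layout@timepoints
  data.frame(marker = z %/% blk + 1L,
             axis = (z %% blk) %/% layout@timepoints + 1L,
             time = z %% layout@timepoints + 1L)
}

#' @rdname nVariables
#' @export
setMethod("nVariables", "KinematicLayout", function(x)
  x@markers * x@axes * x@timepoints)

#' @rdname nVariables
#' @export
setMethod("nVariables", "KinematicExperiment", function(x)
  nVariables(x@layout))

setMethod("show", "KinematicLayout", function(object) {
  cat(sprintf("KinematicLayout: %d markers x %d axes x %d timepoints = %d variables\n",
              object@markers, object@axes, object@timepoints,
              nVariables(object)))
})
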