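#' Reconstruct the movement component living in a subspace
#'
#' Projects every whitened trial onto the given orthonormal vectors, sums
#' the contributions, and maps the result back to the metric scale: each
#' variable is multiplied by the trial's subject's standard deviation and
#' the subject's mean is added, restoring marker positions in the original
#' coordinate system.  With the full joint basis this reproduces the
#' preprocessed trajectories exactly; with an empty vector set it returns
#' each subject's mean trajectory.
#'
#' @param x a whitened \linkS4class{KinematicExperiment}.
#' @param vectors unit, mutually orthogonal vectors in columns (an
#'   \linkS4class{OrthonormalBasis}, a \linkS4class{DecompositionResult}'s
#'   SVM basis via [svmBasis()], or a plain matrix); may have zero columns.
#' @param stats whitening statistics (defaults to \code{subjectStats(x)}).
#' @return a raw-scale \linkS4class{KinematicExperiment} holding the
#'   reconstructed component.
#' @export
reconstructMovement <- function(x, vectors, stats = subjectStats(x)) {
  stopifnot(is(x, "KinematicExperiment"))
  if (!isWhitened(x)) stop("matrix must be whitened")
  if (length(stats) == 0L) stop("missing subject statistics for de-whitening")
  E <- if (is(vectors, "OrthonormalBasis")) vectors@vectors else as.matrix(vectors)
  if (ncol(E) > 0L) {
    G <- crossprod(E)
    if (max(abs(G - diag(ncol(E)))) > 1e-8)
      stop("'vectors' must be unit-norm and mutually orthogonal")
  }
  M <- trialMatrix(x)
  comp <- if (ncol(E) == 0L) matrix(0, nrow(M), ncol(M))
          else (M %*% E) %*% t(E)
  subj <- as.character(trialInfo(x)$subject)
  for (s in unique(subj)) {
    rows <- which(subj == s)
    sdv <- stats$sd[, s]
    sdv[!(sdv > 0 & is.finite(sdv))] <- 0
    comp[rows, ] <- sweep(sweep(comp[rows, , drop = FALSE], 2L, sdv, "*"),
                          2L, stats$mean[, s], "+")
  }
  SummarizedExperiment::assay(x) <- t(comp)
  x@whitened <- FALSE
  x@subjectStats <- list()
  x
}

#' Condition-averaged trajectories with per-time-point spread
#'
#' @param x a raw-scale \linkS4class{KinematicExperiment} (typically a
#'   reconstruction).
#' @return list: \code{condition} (the two labels), \code{mean} and
#'   \code{sd} (condition x variable matrices), \code{layout}.
#' @export
conditionAverage <- function(x) {
  stopifnot(is(x, "KinematicExperiment"))
  M <- trialMatrix(x)
  cond <- as.character(trialInfo(x)$condition)
  lv <- sort(unique(cond))
  if (length(lv) != 2L) stop("both conditions must be present")
  mean <- t(vapply(lv, function(l) colMeans(M[cond == l, , drop = FALSE]),
                   numeric(ncol(M))))
  sd <- t(vapply(lv, function(l) apply(M[cond == l, , drop = FALSE], 2L, sd),
                 numeric(ncol(M))))
  rownames(mean) <- rownames(sd) <- lv
  list(condition = lv, mean = mean, sd = sd, layout = indexMap(x))
}

#' Export per-frame stick-figure tables for the two conditions
#'
#' Produces one row per (time point, condition, marker) with the two plane
#' coordinates, suitable for superimposed stick-figure display.  The
#' between-condition differences are amplified: each condition's deviation
#' from the two-condition grand mean at that time point is multiplied by
#' the magnification factor (factor 1 leaves coordinates unchanged; factor
#' 5 reproduces the published display convention).
#'
#' @param avg result of [conditionAverage()].
#' @param plane \code{"sagittal"} or \code{"frontal"}.
#' @param magnification positive amplification of condition differences
#'   (default 5).
#' @param planeAxes named list mapping plane names to the two axis indices
#'   (defaults: sagittal = c(1, 3), frontal = c(2, 3) -- forward/vertical
#'   and lateral/vertical under the x = forward, y = lateral, z = vertical
#'   laboratory convention).
#' @param file optional CSV path (header
#'   \code{time_index,condition,marker,coord1,coord2}).
#' @return the long data.frame, invisibly when written to \code{file}.
#' @export
exportFrames <- function(avg, plane = c("sagittal", "frontal"),
                         magnification = 5,
                         planeAxes = list(sagittal = c(1L, 3L),
                                          frontal = c(2L, 3L)),
                         file = NULL) {
  plane <- match.arg(plane, choices = names(planeAxes))
  if (magnification <= 0) stop("'magnification' must be positive")
  ax <- planeAxes[[plane]]
  lay <- avg$layout
  grand <- colMeans(avg$mean)
  amp <- sweep(sweep(avg$mean, 2L, grand), 1:2, magnification, "*")
  amp <- sweep(amp, 2L, grand, "+")
  rows <- expand.grid(time_index = seq_len(lay@timepoints),
                      condition = avg$condition,
                      marker = seq_len(lay@markers),
                      stringsAsFactors = FALSE)
  getCoord <- function(a) {
    cols <- variableIndex(lay, rows$marker, a, rows$time_index)
    amp[cbind(match(rows$condition, avg$condition), cols)]
  }
  out <- data.frame(time_index = rows$time_index, condition = rows$condition,
                    marker = rows$marker, coord1 = getCoord(ax[1L]),
                    coord2 = getCoord(ax[2L]))
  out <- out[order(out$time_index, out$condition, out$marker), ]
  rownames(out) <- NULL
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
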