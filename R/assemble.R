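#' Assemble preprocessed trials into the trial-by-variable matrix
#'
#' Joins the time-dependent 3-D coordinates of all markers of each trial into
#' one row vector (marker-major, then axis, then time; see
#' [variableIndex()]) and stacks the rows of all trials.  With the default
#' configuration of 11 subjects x 2 conditions x 20 trials, 13 markers and
#' 101 normalized time points this yields a 440 x 3939 matrix.
#'
#' @param trials list of preprocessed \linkS4class{TrialRecord} objects, all
#'   with identical marker/axis counts and exactly \code{layout@timepoints}
#'   frames.
#' @param layout a \linkS4class{KinematicLayout}; inferred from the first
#'   trial when \code{NULL}.
#' @return a raw (unwhitened) \linkS4class{KinematicExperiment}.
#' @examples
#' sim <- generateSynthetic(syntheticConfig(subjects = 3, markers = 2,
#'                                          trialsPerCondition = 4, seed = 1))
#' ke <- assembleMatrix(sim$trials)
#' dim(trialMatrix(ke))   # 24 trials x 606 variables
#' @export
assembleMatrix <- function(trials, layout = NULL) {
  if (length(trials) == 0L) stop("empty input: no trials to assemble")
  d1 <- dim(trials[[1L]]@positions)
  if (is.null(layout))
    layout <- KinematicLayout(markers = d1[2L], axes = d1[3L],
                              timepoints = d1[1L])
  want <- c(layout@timepoints, layout@markers, layout@axes)
  values <- matrix(NA_real_, nrow = length(trials), ncol = nVariables(layout))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    d <- dim(tr@positions)
    if (!all(d == want))
      stop(sprintf(
        "trial shape mismatch (%s): got %d frames x %d markers x %d axes, expected %d x %d x %d",
        trialKeyString(tr), d[1L], d[2L], d[3L], want[1L], want[2L], want[3L]))
    # positions is frames x markers x axes; the row layout is marker-major,
    # so permute to time-within-axis-within-marker before flattening
    values[i, ] <- as.vector(aperm(tr@positions, c(1L, 3L, 2L)))
  }
  cd <- S4Vectors::DataFrame(
    subject = vapply(trials, function(t) t@subject, ""),
    condition = vapply(trials, function(t) t@condition, ""),
    trial = vapply(trials, function(t) t@trial, 1L))
  if (length(unique(cd$condition)) != 2L)
    stop("'condition' must take exactly two distinct values across the data set")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(positions = t(values)), colData = cd)
  new("KinematicExperiment", se, layout = layout, whitened = FALSE,
      subjectStats = list())
}

#' Low-level constructor from a ready-made matrix
#'
#' Wraps an existing trial-by-variable matrix (for example one read from an
#' external file, or a toy example) into a
#' \linkS4class{KinematicExperiment} without going through trial records.
#'
#' @param values numeric matrix, trials x variables.
#' @param subjects,conditions,trials per-row metadata (trial indices default
#'   to a running count within subject x condition).
#' @param layout a \linkS4class{KinematicLayout} whose variable count
#'   matches \code{ncol(values)}.
#' @param whitened logical flag.
#' @param stats subject statistics list (see [subjectStats()]).
#' @return a \linkS4class{KinematicExperiment}.
#' @export
kinematicExperiment <- function(values, subjects, conditions, trials = NULL,
                                layout = NULL, whitened = FALSE,
                                stats = list()) {
  values <- as.matrix(values)
  if (is.null(layout))
    layout <- KinematicLayout(markers = 1L, axes = 1L,
                              timepoints = ncol(values))
  if (is.null(trials)) {
    key <- paste(subjects, conditions)
    trials <- stats::ave(seq_along(key), key, FUN = seq_along)
  }
  cd <- S4Vectors::DataFrame(subject = as.character(subjects),
                             condition = as.character(conditions),
                             trial = as.integer(trials))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(positions = t(values)), colData = cd)
  new("KinematicExperiment", se, layout = layout, whitened = whitened,
      subjectStats = stats)
}

#' @rdname trialMatrix
#' @export
setMethod("trialMatrix", "KinematicExperiment", function(x)
  t(SummarizedExperiment::assay(x)))

#' @rdname trialInfo
#' @export
setMethod("trialInfo", "KinematicExperiment", function(x)
  SummarizedExperiment::colData(x))

#' @rdname isWhitened
#' @export
setMethod("isWhitened", "KinematicExperiment", function(x) x@whitened)

#' @rdname subjectStats
#' @export
setMethod("subjectStats", "KinematicExperiment", function(x) x@subjectStats)

#' @rdname indexMap
#' @export
setMethod("indexMap", "KinematicExperiment", function(x) x@layout)

setMethod("show", "KinematicExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("KinematicExperiment: %d trials x %d variables (%s)\n",
              ncol(object), nrow(object),
              if (object@whitened) "whitened" else "raw"))
  cat(sprintf("  %d subjects, conditions: %s\n",
              length(unique(cd$subject)),
              paste(sort(unique(cd$condition)), collapse = " / ")))
  show(object@layout)
})

#' Whiten each variable within each subject
#'
#' For every subject and every variable, subtracts that subject's mean over
#' all of its trials and conditions pooled and divides by the corresponding
#' sample standard deviation (n - 1 denominator), so that within every
#' subject block each variable has zero mean and unit standard deviation.
#' The per-subject statistics are retained for de-whitening and for the
#' metric movement reconstruction.
#'
#' @param x a raw \linkS4class{KinematicExperiment}; every subject needs at
#'   least two trials.
#' @param degenerate what to do with zero-variance subject/variable cells:
#'   \code{"error"} (default) or \code{"zero"} (whitened entries set to 0 and
#'   the affected columns recorded in \code{subjectStats(x)$degenerate}).
#' @return the whitened \linkS4class{KinematicExperiment}.
#' @export
setMethod("whiten", "KinematicExperiment",
          function(x, degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  if (x@whitened) stop("matrix is already whitened")
  M <- trialMatrix(x)
  cd <- SummarizedExperiment::colData(x)
  subj <- as.character(cd$subject)
  us <- unique(subj)
  p <- ncol(M)
  mu <- matrix(NA_real_, p, length(us), dimnames = list(NULL, us))
  sig <- matrix(NA_real_, p, length(us), dimnames = list(NULL, us))
  degcols <- integer(0)
  W <- M
  for (s in us) {
    rows <- which(subj == s)
    if (length(rows) < 2L)
      stop("subject '", s, "' has fewer than 2 trials; cannot whiten")
    B <- M[rows, , drop = FALSE]
    m <- colMeans(B)
    sdv <- sqrt(colSums(sweep(B, 2L, m)^2) / (length(rows) - 1L))
    bad <- which(sdv <= 0 | !is.finite(sdv))
    if (length(bad)) {
      if (degenerate == "error")
        stop("degenerate variable(s) with zero standard deviation for subject '",
             s, "': column(s) ", paste(utils::head(bad, 5L), collapse = ", "),
             if (length(bad) > 5L) ", ..." else "")
      degcols <- union(degcols, bad)
    }
    sdsafe <- ifelse(sdv > 0 & is.finite(sdv), sdv, 1)
    W[rows, ] <- sweep(sweep(B, 2L, m), 2L, sdsafe, "/")
    if (length(bad)) W[rows, bad] <- 0
    mu[, s] <- m
    sig[, s] <- sdv
  }
  SummarizedExperiment::assay(x) <- t(W)
  x@whitened <- TRUE
  x@subjectStats <- list(mean = mu, sd = sig, degenerate = sort(degcols))
  x
})

#' De-whiten a whitened matrix back to the raw scale
#'
#' Multiplies each subject's rows by that subject's per-variable standard
#' deviation and adds back the per-variable mean, inverting [whiten()] to
#' numerical precision.
#'
#' @param x a whitened \linkS4class{KinematicExperiment}.
#' @return the raw-scale \linkS4class{KinematicExperiment} (whitening
#'   statistics are dropped).
#' @export
setMethod("unwhiten", "KinematicExperiment", function(x) {
  if (!x@whitened) stop("matrix is not whitened")
  st <- x@subjectStats
  W <- trialMatrix(x)
  subj <- as.character(SummarizedExperiment::colData(x)$subject)
  for (s in unique(subj)) {
    rows <- which(subj == s)
    sdv <- st$sd[, s]
    sdv[!(sdv > 0 & is.finite(sdv))] <- 1
    W[rows, ] <- sweep(sweep(W[rows, , drop = FALSE], 2L, sdv, "*"),
                       2L, st$mean[, s], "+")
  }
  SummarizedExperiment::assay(x) <- t(W)
  x@whitened <- FALSE
  x@subjectStats <- list()
  x
})

#' @describeIn extractWaveform Returns the trials x timepoints matrix of the
#'   contiguous columns holding (marker, axis); with
#'   \code{byCondition = TRUE}, per-condition mean and per-time-point SD.
#' @param byCondition logical; average over trials within condition.
#' @export
setMethod("extractWaveform", "KinematicExperiment",
          function(x, marker, axis, byCondition = FALSE) {
  lay <- x@layout
  cols <- variableIndex(lay, marker, axis, seq_len(lay@timepoints))
  M <- trialMatrix(x)[, cols, drop = FALSE]
  colnames(M) <- NULL
  if (!byCondition) return(M)
  cond <- as.character(SummarizedExperiment::colData(x)$condition)
  lv <- sort(unique(cond))
  list(condition = lv,
       mean = t(vapply(lv, function(l) colMeans(M[cond == l, , drop = FALSE]),
                       numeric(ncol(M)))),
       sd = t(vapply(lv, function(l) apply(M[cond == l, , drop = FALSE], 2L, sd),
                     numeric(ncol(M)))))
})
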