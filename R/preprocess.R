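#' Detect stance phase from a vertical ground-reaction-force trace
#'
#' Initial contact is the first frame at or above the force threshold;
#' toe-off is the last frame of the contiguous supra-threshold episode that
#' begins at contact.  A warning is raised when further supra-threshold
#' episodes follow (the first is used).
#'
#' @param force numeric vector of vertical force in newtons, sampled on the
#'   kinematic frame clock.
#' @param threshold force threshold in newtons (default 15).
#' @return integer vector \code{c(contact, toeoff)} (1-based frames).
#' @examples
#' detectStance(c(0, 5, 20, 600, 400, 10, 0))   # frames 3 and 5
#' @export
detectStance <- function(force, threshold = 15) {
  if (length(force) == 0L) stop("empty force trace")
  if (threshold <= 0) stop("'threshold' must be positive")
  above <- force >= threshold
  if (!any(above)) stop("no frame reaches the ", threshold, " N threshold; no stance detected")
  contact <- which(above)[1L]
  run <- which(!above[contact:length(force)])
  toeoff <- if (length(run) == 0L) length(force) else contact + run[1L] - 2L
  if (toeoff < length(force) && any(above[(toeoff + 1L):length(force)]))
    warning("multiple supra-threshold episodes in force trace; using the first")
  if (contact >= toeoff)
    stop("stance episode shorter than 2 frames (contact ", contact,
         ", toe-off ", toeoff, ")")
  c(contact = contact, toeoff = toeoff)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Filters each channel with a low-pass Butterworth filter of the stated net
#' order.  By default the filter is applied forward and backward
#' (zero-phase, no temporal shift of features) with the per-pass order
#' halved, so that the net response has the requested order -- the standard
#' practice for kinematic trajectories.  Set \code{zeroPhase = FALSE} for a
#' single causal pass at the full order.
#'
#' @param x numeric vector or matrix (channels in columns).
#' @param cutoff cutoff frequency in Hz (default 12).
#' @param order net filter order, even (default 4).
#' @param sampleRate sampling rate in Hz (default 240).
#' @param zeroPhase logical, forward-backward application (default TRUE).
#' @return filtered series, same shape as \code{x}.
#' @export
lowpassFilter <- function(x, cutoff = 12, order = 4, sampleRate = 240,
                          zeroPhase = TRUE) {
  if (cutoff <= 0 || cutoff >= sampleRate / 2)
    stop("'cutoff' must lie strictly between 0 and the Nyquist frequency")
  if (order < 2 || order %% 2 != 0) stop("'order' must be a positive even integer")
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 3L * order) stop("series too short for order-", order, " filtering")
  passOrder <- if (zeroPhase) order / 2 else order
  bf <- signal::butter(passOrder, W = cutoff / (sampleRate / 2), type = "low")
  # odd-reflection padding long enough for the start-up transient (set by
  # the slowest filter pole) to die out before the retained samples
  r <- max(Mod(polyroot(rev(bf$a))))
  pad <- min(n - 1L, max(3L * order,
                         if (r < 1) ceiling(log(1e-13) / log(r)) else n - 1L))
  f1 <- function(v) {
    vp <- c(2 * v[1L] - v[(pad + 1L):2L], v,
            2 * v[n] - v[(n - 1L):(n - pad)])
    out <- if (zeroPhase) signal::filtfilt(bf, vp)
           else as.numeric(signal::filter(bf, vp))
    out[(pad + 1L):(pad + n)]
  }
  if (is.matrix(x)) apply(x, 2L, f1) else f1(x)
}

#' Resample a stance segment to equidistant normalized time points
#'
#' Cubic-spline interpolation of each channel at \code{timepoints}
#' equidistant instants spanning the segment; the first and last output
#' samples coincide with the segment endpoints (contact and toe-off).
#'
#' @param segment numeric vector or matrix (frames x channels).
#' @param timepoints number of output samples (default 101).
#' @param method interpolation: \code{"spline"} (default) or \code{"linear"}.
#' @return vector or matrix with \code{timepoints} rows.
#' @export
timeNormalize <- function(segment, timepoints = 101L,
                          method = c("spline", "linear")) {
  method <- match.arg(method)
  vec <- !is.matrix(segment)
  if (vec) segment <- matrix(segment, ncol = 1L)
  n <- nrow(segment)
  if (n < 2L) stop("segment must contain at least 2 frames")
  at <- seq(1, n, length.out = timepoints)
  out <- apply(segment, 2L, function(v) {
    if (method == "spline") splinefun(seq_len(n), v, method = "fmm")(at)
    else stats::approx(seq_len(n), v, xout = at)$y
  })
  if (vec) drop(out) else out
}

#' Center a trial on the pelvis and normalize to body height
#'
#' Shifts the horizontal (transversal-plane) coordinates by the centroid of
#' the pelvis marker set (per frame by default, or by the trial-mean
#' centroid), shifts the vertical coordinates by a constant so that the
#' floor -- the lowest marker position of the trial -- lies at zero, and
#' divides all coordinates by the subject's height, giving dimensionless
#' positions.
#'
#' @param trial a \linkS4class{TrialRecord}.
#' @param pelvisMarkers integer indices of the pelvis markers.
#' @param height subject height in meters.
#' @param verticalAxis which axis is vertical (default 3).
#' @param centerMode \code{"per-frame"} (default) or \code{"per-trial"}.
#' @return the centered, height-normalized \linkS4class{TrialRecord}.
#' @export
centerAndScale <- function(trial, pelvisMarkers = 1:4, height,
                           verticalAxis = 3L,
                           centerMode = c("per-frame", "per-trial")) {
  centerMode <- match.arg(centerMode)
  if (length(pelvisMarkers) == 0L) stop("'pelvisMarkers' must be non-empty")
  if (height <= 0) stop("'height' must be positive")
  P <- trial@positions
  horizontal <- setdiff(seq_len(dim(P)[3L]), verticalAxis)
  for (a in horizontal) {
    cen <- rowMeans(P[, pelvisMarkers, a, drop = FALSE])
    if (centerMode == "per-trial") cen <- rep(mean(cen), dim(P)[1L])
    P[, , a] <- P[, , a] - cen
  }
  P[, , verticalAxis] <- P[, , verticalAxis] - min(P[, , verticalAxis])
  trial@positions <- P / height
  trial
}

#' Preprocess one raw trial to a stance-phase, normalized TrialRecord
#'
#' Fixed pipeline order: low-pass filter the full trajectories, crop to the
#' stance phase detected from the force trace, resample to 101 equidistant
#' time points, then center on the pelvis and normalize to height.
#' Filtering precedes cropping so that filter edge effects fall outside the
#' analyzed segment.  If the force trace is sampled faster than the
#' kinematics it is decimated to the kinematic frame clock by nearest-frame
#' lookup before thresholding.
#'
#' @param trial a raw \linkS4class{TrialRecord} with a force trace (or
#'   \code{force} supplied separately).
#' @param force optional force trace overriding \code{trial@force}.
#' @param height subject height in meters (1 disables height scaling).
#' @param pelvisMarkers pelvis marker set for centering.
#' @param cutoff,order filter parameters (12 Hz, net order 4).
#' @param stanceThreshold force threshold in newtons (15).
#' @param timepoints output samples per waveform (101).
#' @param verticalAxis,centerMode passed to [centerAndScale()].
#' @return a preprocessed \linkS4class{TrialRecord} with
#'   \code{timepoints} frames and no force trace.
#' @export
preprocessTrial <- function(trial, force = NULL, height = 1,
                            pelvisMarkers = 1:4, cutoff = 12, order = 4,
                            stanceThreshold = 15, timepoints = 101L,
                            verticalAxis = 3L,
                            centerMode = c("per-frame", "per-trial")) {
  if (is.null(force)) force <- trial@force
  if (length(force) == 0L)
    stop("no force trace for trial (", trialKeyString(trial),
         "); stance detection requires force data")
  P <- trial@positions
  d <- dim(P)
  nf <- d[1L]
  if (length(force) != nf) {
    idx <- round(seq(1L, length(force), length.out = nf))
    force <- force[idx]
  }
  flat <- matrix(P, nrow = nf)
  flat <- lowpassFilter(flat, cutoff = cutoff, order = order,
                        sampleRate = trial@sampleRate)
  st <- detectStance(force, stanceThreshold)
  seg <- flat[st[1L]:st[2L], , drop = FALSE]
  seg <- timeNormalize(seg, timepoints = timepoints)
  out <- trial
  out@positions <- array(seg, dim = c(timepoints, d[2L], d[3L]))
  out@force <- numeric(0)
  centerAndScale(out, pelvisMarkers = pelvisMarkers, height = height,
                 verticalAxis = verticalAxis, centerMode = centerMode)
}

#' @describeIn preprocessTrial preprocess a list of trials; \code{heights}
#'   may be a named vector keyed by subject.
#' @param trials list of raw \linkS4class{TrialRecord}s.
#' @param heights named numeric vector of subject heights, or a scalar.
#' @param ... passed on to \code{preprocessTrial}.
#' @export
preprocessTrials <- function(trials, heights = 1, ...) {
  lapply(trials, function(tr) {
    h <- if (length(heights) == 1L && is.null(names(heights))) heights
         else heights[[tr@subject]]
    preprocessTrial(tr, height = h, ...)
  })
}
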