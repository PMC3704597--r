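#' Configuration of the synthetic dichotomous gait generator
#'
#' Describes a synthetic data set shaped like the motivating experiment:
#' \code{subjects} x 2 conditions x \code{trialsPerCondition} trials, each
#' trial a \code{markers} x 3 x \code{timepoints} stance-phase trajectory
#' (defaults 11 x 2 x 20, 13 markers, 101 points -> a 440 x 3939 matrix).
#' Each trial is built as base waveform x subject amplitude factor + trial
#' noise + a condition-signed planted effect.
#'
#' @param subjects number of subjects (default 11).
#' @param trialsPerCondition trials per subject and condition (default 20).
#' @param markers number of markers (default 13).
#' @param timepoints normalized time points (default 101).
#' @param sampleRate Hz, used only by raw-mode output (default 240).
#' @param subjectEffectSd SD of the multiplicative between-subject
#'   amplitude variation (default 0.1, i.e. 10\%).
#' @param trialNoiseSd within-subject additive noise SD per variable, in
#'   the base-waveform units (default 0.01, i.e. 1 cm on meter-scale
#'   waveforms).
#' @param effects data.frame of planted condition-effect components with
#'   columns \code{marker}, \code{axis}, \code{center}, \code{width},
#'   \code{amplitude}: a Gaussian bump in normalized time on one
#'   marker/axis whose full between-condition amplitude is
#'   \code{amplitude}.  The default plants one component on marker 3,
#'   vertical axis, centered at 39\% of stance (time point 39 for 101
#'   points) with width \code{timepoints/10} and amplitude
#'   10 x \code{trialNoiseSd} (signal-to-noise ratio 10).  Use
#'   \code{amplitude = 0} (or \code{effects = NULL}) for null,
#'   label-exchangeable data.
#' @param heavyTails logical; t(3)-distributed trial noise instead of
#'   Gaussian (ICA stress testing).
#' @param conditions the two condition names.
#' @param seed integer seed.
#' @return a list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(subjects = 11L, trialsPerCondition = 20L,
                            markers = 13L, timepoints = 101L,
                            sampleRate = 240, subjectEffectSd = 0.1,
                            trialNoiseSd = 0.01,
                            effects = data.frame(marker = min(3L, markers),
                                                 axis = 3L,
                                                 center = max(1L, round(0.39 * timepoints)),
                                                 width = max(2, timepoints / 10),
                                                 amplitude = 10 * trialNoiseSd),
                            heavyTails = FALSE,
                            conditions = c("visco", "elastic"), seed = 1L) {
  if (is.null(effects))
    effects <- data.frame(marker = integer(0), axis = integer(0),
                          center = integer(0), width = numeric(0),
                          amplitude = numeric(0))
  stopifnot(subjects >= 1L, trialsPerCondition >= 1L, markers >= 1L,
            timepoints >= 2L, sampleRate > 0, subjectEffectSd >= 0,
            trialNoiseSd >= 0, length(conditions) == 2L)
  if (nrow(effects)) {
    if (any(effects$amplitude < 0)) stop("effect amplitudes must be >= 0")
    if (any(effects$center < 1 | effects$center > timepoints))
      stop("effect centers must lie within [1, timepoints]")
    if (any(effects$marker < 1 | effects$marker > markers) ||
        any(effects$axis < 1 | effects$axis > 3))
      stop("effect marker/axis out of range")
  }
  structure(list(subjects = as.integer(subjects),
                 trialsPerCondition = as.integer(trialsPerCondition),
                 markers = as.integer(markers),
                 timepoints = as.integer(timepoints),
                 sampleRate = sampleRate, subjectEffectSd = subjectEffectSd,
                 trialNoiseSd = trialNoiseSd, effects = effects,
                 heavyTails = heavyTails, conditions = conditions,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

## deterministic smooth base waveform for (marker, axis): a constant offset
## plus two low-frequency sinusoids whose amplitudes/phases vary with the
## marker/axis index (not with the seed)
.baseWaveform <- function(marker, axis, tnorm) {
  a1 <- 0.15 + 0.05 * ((marker * 3 + axis) %% 5)
  a2 <- 0.05 + 0.02 * ((marker + 2 * axis) %% 4)
  ph1 <- 0.4 * marker + 0.9 * axis
  ph2 <- 0.7 * marker - 0.3 * axis
  off <- 0.1 * marker + 0.2 * axis
  off + a1 * sin(pi * tnorm + ph1) + a2 * sin(2 * pi * tnorm + ph2)
}

.effectShape <- function(center, width, timepoints) {
  t <- seq_len(timepoints)
  exp(-(t - center)^2 / (2 * width^2))
}

#' Generate synthetic dichotomous kinematic trials with known ground truth
#'
#' Deterministic given the seed.  Per trial, each marker/axis waveform is
#' the smooth base waveform scaled by that subject's multiplicative random
#' amplitude factor, plus independent per-variable trial noise, plus -- on
#' the effect marker/axis only -- half the planted Gaussian-bump amplitude
#' with opposite signs in the two conditions.  Subject factors multiply the
#' waveforms (rather than shifting them) so that per-subject whitening does
#' not trivially remove the between-subject structure.  In raw mode the
#' trials additionally carry frame-rate trajectories spanning contact to
#' toe-off plus sub-threshold padding and a half-sine vertical force trace
#' (peak about 1.5 kN), so the preprocessing chain can be exercised end to
#' end.
#'
#' The returned \linkS4class{SyntheticTruth} expresses each planted
#' component both as a raw-scale unit vector (the bump) and as a unit
#' vector in the whitened variable space, computed from the realized
#' per-subject whitening statistics of the generated data set -- the
#' direction the condition effect actually occupies after whitening, which
#' is what a recovered discriminant should align with.
#'
#' @param config a [syntheticConfig()].
#' @param rawMode logical; also emit frame-rate trajectories and force.
#' @return list with \code{trials} (list of \linkS4class{TrialRecord}),
#'   \code{truth} (\linkS4class{SyntheticTruth}) and \code{config}.
#' @examples
#' sim <- generateSynthetic(syntheticConfig(subjects = 3, markers = 2,
#'                                          trialsPerCondition = 3, seed = 2))
#' length(sim$trials)    # 3 subjects x 2 conditions x 3 trials = 18
#' @export
generateSynthetic <- function(config = syntheticConfig(), rawMode = FALSE) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  tp <- config$timepoints
  mk <- config$markers
  tnorm <- seq(0, 1, length.out = tp)
  lay <- KinematicLayout(markers = mk, axes = 3L, timepoints = tp)

  base <- array(0, dim = c(tp, mk, 3L))
  for (m in seq_len(mk)) for (a in 1:3)
    base[, m, a] <- .baseWaveform(m, a, tnorm)

  eff <- array(0, dim = c(tp, mk, 3L))       # full between-condition difference
  for (i in seq_len(nrow(config$effects))) {
    e <- config$effects[i, ]
    eff[, e$marker, e$axis] <- eff[, e$marker, e$axis] +
      e$amplitude * .effectShape(e$center, e$width, tp)
  }

  subjFac <- array(1 + rnorm(config$subjects * mk * 3L,
                             sd = config$subjectEffectSd),
                   dim = c(config$subjects, mk, 3L))

  trials <- list()
  for (s in seq_len(config$subjects)) {
    sb <- sweep(base, c(2L, 3L), subjFac[s, , ], "*")
    for (ci in 1:2) {
      sgn <- if (ci == 1L) 0.5 else -0.5
      for (tr in seq_len(config$trialsPerCondition)) {
        noise <- if (config$heavyTails)
          array(rt(tp * mk * 3L, df = 3) / sqrt(3) * config$trialNoiseSd,
                dim = dim(base))
        else array(rnorm(tp * mk * 3L, sd = config$trialNoiseSd),
                   dim = dim(base))
        pos <- sb + sgn * eff + noise
        rec <- TrialRecord(subject = sprintf("S%02d", s),
                           condition = config$conditions[ci], trial = tr,
                           positions = pos, sampleRate = config$sampleRate)
        if (rawMode) rec <- .toRawTrial(rec, config)
        trials[[length(trials) + 1L]] <- rec
      }
    }
  }

  truth <- .syntheticTruth(config, lay, eff, trials, rawMode)
  list(trials = trials, truth = truth, config = config)
}

## expand a normalized trial to a frame-rate one with padding + force trace
.toRawTrial <- function(rec, config) {
  stanceSec <- 0.25
  nStance <- max(round(stanceSec * config$sampleRate), config$timepoints)
  pad <- 24L                         # 0.1 s of flight padding at 240 Hz
  tp <- config$timepoints
  P <- rec@positions
  d <- dim(P)
  flat <- matrix(P, nrow = tp)
  at <- seq(1, tp, length.out = nStance)
  up <- apply(flat, 2L, function(v) splinefun(seq_len(tp), v, "fmm")(at))
  full <- rbind(matrix(rep(up[1L, ], each = pad), nrow = pad),
                up,
                matrix(rep(up[nStance, ], each = pad), nrow = pad))
  # supra-threshold over the whole stance so contact/toe-off fall exactly
  # on the first/last stance frame (loading and unloading are steep)
  force <- c(rep(0, pad),
             1500 * sin(pi * seq(0.005, 0.995, length.out = nStance)),
             rep(0, pad))
  rec@positions <- array(full, dim = c(nStance + 2L * pad, d[2L], d[3L]))
  rec@force <- force
  rec
}

.syntheticTruth <- function(config, lay, eff, trials, rawMode) {
  k <- nrow(config$effects)
  p <- nVariables(lay)
  raw <- matrix(0, p, max(k, 0L))
  for (i in seq_len(k)) {
    e <- config$effects[i, ]
    v <- numeric(p)
    cols <- variableIndex(lay, e$marker, e$axis, seq_len(config$timepoints))
    v[cols] <- e$amplitude * .effectShape(e$center, e$width, config$timepoints)
    raw[, i] <- v
  }
  amps <- if (k) config$effects$amplitude else numeric(0)
  wdir <- raw
  if (k && any(colSums(raw^2) > 0) && !rawMode && config$subjects >= 1L &&
      config$trialsPerCondition * 2L >= 2L) {
    ke <- whiten(assembleMatrix(trials, layout = lay), degenerate = "zero")
    sds <- subjectStats(ke)$sd
    invsd <- rowMeans(1 / pmax(sds, .Machine$double.eps))
    wdir <- raw * invsd
  }
  nz <- colSums(raw^2) > 0
  raw[, nz] <- sweep(raw[, nz, drop = FALSE], 2L,
                     sqrt(colSums(raw[, nz, drop = FALSE]^2)), "/")
  wdir[, nz] <- sweep(wdir[, nz, drop = FALSE], 2L,
                      sqrt(colSums(wdir[, nz, drop = FALSE]^2)), "/")
  new("SyntheticTruth", directions = wdir, rawDirections = raw,
      amplitudes = as.numeric(amps), components = config$effects)
}

#' Alignment of a recovered subspace with the planted truth
#'
#' For each planted direction, the |cosine| between the direction and its
#' orthogonal projection onto the recovered subspace (1 = fully contained,
#' 0 = orthogonal), plus the principal angles between the truth span and
#' the recovered span.
#'
#' @param result the recovered subspace: a
#'   \linkS4class{DecompositionResult} (SVM basis), \linkS4class{IcaResult}
#'   (span of the ICA vectors), \linkS4class{OrthonormalBasis}, or a plain
#'   matrix of basis vectors in columns.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return list: \code{scores} (|cosine| per planted direction),
#'   \code{principalAnglesDeg}.
#' @export
truthAlignment <- function(result, truth) {
  B <- if (is(result, "DecompositionResult")) result@svmBasis@vectors
       else if (is(result, "IcaResult")) result@vectors
       else if (is(result, "OrthonormalBasis")) result@vectors
       else as.matrix(result)
  W <- truth@directions
  if (nrow(B) != nrow(W))
    stop("dimension mismatch: recovered space has ", nrow(B),
         " variables, truth has ", nrow(W))
  if (ncol(B) == 0L)
    return(list(scores = rep(0, ncol(W)),
                principalAnglesDeg = rep(90, ncol(W))))
  Bq <- qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
  scores <- sqrt(colSums(crossprod(Bq, W)^2))
  Wq <- qr.Q(qr(W))[, seq_len(qr(W)$rank), drop = FALSE]
  sv <- svd(crossprod(Bq, Wq))$d
  list(scores = pmin(scores, 1),
       principalAnglesDeg = acos(pmin(pmax(sv, 0), 1)) * 180 / pi)
}
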