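#' Construct a classifiability rule
#'
#' @param mode \code{"paper"} (default; pins the printed 25-of-40 trial and
#'   8-of-11 subject thresholds, exact elsewhere) or \code{"exact"} (exact
#'   one-sided binomial thresholds throughout).
#' @param alpha significance level (default 0.05).
#' @param successProb chance success probability (default 0.5).
#' @return a \linkS4class{ClassifiabilityRule}.
#' @examples
#' classifiabilityRule("exact")
#' @export
classifiabilityRule <- function(mode = c("paper", "exact"), alpha = 0.05,
                                successProb = 0.5) {
  new("ClassifiabilityRule", mode = match.arg(mode), alpha = alpha,
      successProb = successProb)
}

#' Exact one-sided binomial success threshold
#'
#' Smallest count k such that P(X >= k) <= alpha for X ~ Binomial(n, p):
#' the minimal number of successes that is significantly better than chance.
#'
#' @param n number of Bernoulli trials.
#' @param alpha significance level.
#' @param p chance success probability.
#' @return integer threshold, or \code{NA} when even k = n is not significant
#'   (e.g. n = 4 at alpha 0.05, where the minimal tail is 1/16).
#' @examples
#' binomialThreshold(40)   # 26
#' binomialThreshold(11)   # 9
#' binomialThreshold(5)    # 5 (tail 1/32 = 0.03125)
#' @export
binomialThreshold <- function(n, alpha = 0.05, p = 0.5) {
  if (n < 1L || alpha <= 0 || alpha >= 1 || p <= 0 || p >= 1)
    stop("need n >= 1, 0 < alpha < 1 and 0 < p < 1")
  tail <- pbinom(seq_len(n) - 1L, n, p, lower.tail = FALSE)
  k <- which(tail <= alpha)
  if (length(k) == 0L) NA_integer_ else as.integer(min(k))
}

## printed counts pinned by paper-compat mode: n -> threshold
.paperTrialThresholds <- c("40" = 25L)
.paperSubjectThresholds <- c("11" = 8L)

#' Trial-level threshold of a rule
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @param n number of trials of the held-out subject.
#' @return minimal correct-trial count deemed classifiable (\code{NA} when
#'   unreachable).
#' @export
trialThreshold <- function(rule, n) {
  key <- as.character(n)
  if (rule@mode == "paper" && rule@alpha == 0.05 && rule@successProb == 0.5 &&
      key %in% names(.paperTrialThresholds))
    return(.paperTrialThresholds[[key]])
  binomialThreshold(n, rule@alpha, rule@successProb)
}

#' Subject-level threshold of a rule
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @param n number of subjects.
#' @return minimal classifiable-subject count for a significant rate.
#' @export
subjectThreshold <- function(rule, n) {
  key <- as.character(n)
  if (rule@mode == "paper" && rule@alpha == 0.05 && rule@successProb == 0.5 &&
      key %in% names(.paperSubjectThresholds))
    return(.paperSubjectThresholds[[key]])
  binomialThreshold(n, rule@alpha, rule@successProb)
}

#' Is a held-out subject classifiable?
#'
#' @param correct number of correctly assigned trials.
#' @param total number of trials of the subject.
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @return logical.
#' @examples
#' subjectClassifiable(25, 40, classifiabilityRule("paper"))   # TRUE
#' subjectClassifiable(25, 40, classifiabilityRule("exact"))   # FALSE
#' @export
subjectClassifiable <- function(correct, total, rule = classifiabilityRule()) {
  if (total < 1L) stop("'total' must be >= 1")
  if (correct < 0L || correct > total) stop("need 0 <= correct <= total")
  thr <- trialThreshold(rule, total)
  !is.na(thr) && correct >= thr
}

#' Classification rate over subjects with subject-level significance
#'
#' The classification rate is the fraction of held-out subjects whose trials
#' passed the trial-level binomial test; it is significant when the number
#' of classifiable subjects itself exceeds the subject-level binomial
#' threshold.
#'
#' @param classifiable logical vector, one flag per subject.
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @return list with \code{rate}, \code{significant}, \code{nClassifiable},
#'   \code{nSubjects}.
#' @examples
#' classificationRate(rep(c(TRUE, FALSE), c(8, 3)))   # 8/11 = 72.7%, significant
#' @export
classificationRate <- function(classifiable, rule = classifiabilityRule()) {
  n <- length(classifiable)
  if (n < 1L) stop("need at least one subject")
  k <- sum(classifiable)
  thr <- subjectThreshold(rule, n)
  list(rate = k / n, significant = !is.na(thr) && k >= thr,
       nClassifiable = k, nSubjects = n)
}

#' Cohen's d effect size of projections
#'
#' Absolute standardized mean difference of the two groups,
#' \eqn{d = |m_1 - m_2| / s_p} with the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#'
#' @param values numeric vector of projections.
#' @param labels two-level grouping aligned to \code{values}.
#' @return |d|.
#' @examples
#' cohensD(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))   # 2
#' @export
cohensD <- function(values, labels) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("'labels' must have exactly two levels")
  g1 <- values[labels == lv[1L]]
  g2 <- values[labels == lv[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("both groups need at least 2 values")
  sp <- sqrt(((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
             (length(g1) + length(g2) - 2))
  if (sp <= 0) stop("zero pooled standard deviation; effect size undefined")
  abs(mean(g1) - mean(g2)) / sp
}

#' Normality gate for effect-size reporting
#'
#' Lilliefors (Kolmogorov-Smirnov with estimated mean and SD) test per
#' group.  The effect size is still reported when a group fails, but the
#' failure is flagged.
#'
#' @param values numeric vector.
#' @param labels optional two-level grouping; when \code{NULL} the whole
#'   vector is tested as one group.
#' @param alpha significance level.
#' @return named logical vector, \code{TRUE} = normality not rejected;
#'   p-values attached as attribute \code{"p.value"}.
#' @export
normalityGate <- function(values, labels = NULL, alpha = 0.05) {
  groups <- if (is.null(labels)) list(all = values)
            else split(values, as.character(labels))
  if (any(vapply(groups, length, 1L) < 5L))
    stop("each group needs at least 5 values for the Lilliefors test")
  p <- vapply(groups, function(g) nortest::lillie.test(g)$p.value, 1)
  structure(p > alpha, p.value = p)
}

## 1-D midpoint assignment: threshold halfway between the training-condition
## mean projections, positive side = condition with the larger training mean.
## Returns predicted labels for testProj; NULL signals degenerate training.
.assign1d <- function(trainProj, trainLabels, testProj) {
  lv <- sort(unique(as.character(trainLabels)))
  m <- vapply(lv, function(l) mean(trainProj[trainLabels == l]), 1)
  if (!all(is.finite(m)) || m[1L] == m[2L]) return(NULL)
  thr <- mean(m)
  upper <- lv[which.max(m)]
  lower <- lv[which.min(m)]
  ifelse(testProj > thr, upper, lower)
}

#' Leave-one-subject-out classification rate of a fixed 1-D projection
#'
#' Scores a single direction in data space by its held-out classification
#' performance: for each subject in turn, the decision threshold is placed
#' at the midpoint of the remaining subjects' two condition-mean projections
#' (oriented so the larger training mean is the positive side), the held-out
#' subject's trials are assigned, and the trial-level binomial rule decides
#' classifiability.  The rate aggregates over subjects as in
#' [classificationRate()].  This is the shared scoring rule for PCA and ICA
#' vectors.
#'
#' @param projections numeric vector, one projection per trial.
#' @param labels condition labels per trial.
#' @param subjects subject identifiers per trial.
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @return list: \code{rate}, \code{significant}, \code{nClassifiable},
#'   \code{nSubjects}, \code{perSubject} data.frame.
#' @export
losoProjectRate <- function(projections, labels, subjects,
                            rule = classifiabilityRule()) {
  labels <- as.character(labels)
  subjects <- as.character(subjects)
  us <- unique(subjects)
  if (length(us) < 2L) stop("need at least two subjects")
  per <- lapply(us, function(s) {
    ho <- subjects == s
    if (length(unique(labels[!ho])) != 2L)
      stop("training folds must contain both conditions")
    pred <- .assign1d(projections[!ho], labels[!ho], projections[ho])
    if (is.null(pred)) {
      warning("degenerate training projections (equal condition means) for ",
              "held-out subject '", s, "'; chance assignment used")
      pred <- rep(sort(unique(labels))[1L], sum(ho))
    }
    correct <- sum(pred == labels[ho])
    data.frame(subject = s, correct = correct, total = sum(ho),
               classifiable = subjectClassifiable(correct, sum(ho), rule))
  })
  per <- do.call(rbind, per)
  out <- classificationRate(per$classifiable, rule)
  out$perSubject <- per
  out
}
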