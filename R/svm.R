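## internal: fit e1071 linear SVM and extract the data-space weight vector.
## decision(x) = x %*% w - rho; rows with positive decision belong to
## 'positiveLevel' (determined from the training data, robust to e1071's
## internal label ordering).
.fitSvmRaw <- function(x, labels, cost = 1, ...) {
  y <- factor(as.character(labels))
  if (nlevels(y) != 2L)
    stop("training data must contain exactly two condition labels")
  fit <- tryCatch(
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE, ...),
    error = function(e) stop("SVM solver failed: ", conditionMessage(e),
                             call. = FALSE))
  w <- unname(drop(t(fit$coefs) %*% fit$SV))
  dec <- drop(x %*% w) - fit$rho
  lv <- levels(y)
  mdec <- vapply(lv, function(l) mean(dec[y == l]), 1)
  positive <- lv[which.max(mdec)]
  list(w = w, rho = fit$rho, positiveLevel = positive,
       negativeLevel = setdiff(lv, positive), model = fit)
}

.svmClassify <- function(w, rho, positiveLevel, negativeLevel, x) {
  dec <- drop(x %*% w) - rho
  ifelse(dec > 0, positiveLevel, negativeLevel)
}

#' Fit a single linear SVM discriminant
#'
#' Fits a linear-kernel soft-margin SVM and extracts the discriminant
#' vector as the weighted sum of support vectors,
#' \eqn{d = \sum_i \alpha_i y_i x_i}, normalized to unit length.  With a
#' linear kernel the kernel-sum decision function equals the dot product
#' with the unnormalized discriminant plus the bias, so the discriminant is
#' itself a vector of the data space and linear vector analysis applies.
#'
#' @param x numeric matrix, training trials in rows (typically whitened;
#'   the data are never rescaled internally).
#' @param labels two-level condition labels.
#' @param cost soft-margin box constraint C (default 1).
#' @param ... further arguments to [e1071::svm()] (e.g. a tighter solver
#'   \code{tolerance} for hard-margin studies).
#' @return a \linkS4class{Discriminant} (no folds).
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
#' d <- fitLinearDiscriminant(x, c("a", "a", "b", "b"), cost = 1e6)
#' d@direction          # along the first coordinate
#' @export
fitLinearDiscriminant <- function(x, labels, cost = 1, ...) {
  f <- .fitSvmRaw(x, labels, cost, ...)
  nrm <- sqrt(sum(f$w^2))
  if (nrm <= 0) stop("SVM returned a zero discriminant")
  new("Discriminant", direction = f$w / nrm, bias = -f$rho, normFactor = nrm,
      positiveLevel = f$positiveLevel, negativeLevel = f$negativeLevel,
      folds = data.frame(), foldDirections = matrix(0, length(f$w), 0L),
      rate = NA_real_, significant = NA, effectSize = NA_real_)
}

#' Decision values of a discriminant
#'
#' \code{normFactor * (x . direction) + bias}: identical to the linear
#' kernel-sum decision function of the underlying SVM.
#'
#' @param d a \linkS4class{Discriminant}.
#' @param x numeric matrix of trials in rows.
#' @return numeric decision values; positive values are assigned to
#'   \code{d@positiveLevel}.
#' @export
discriminantDecision <- function(d, x) {
  drop(x %*% d@direction) * d@normFactor + d@bias
}

#' Leave-one-subject-out SVM discriminant
#'
#' For each subject in turn, a linear SVM is fitted on all other subjects'
#' trials and the held-out subject's trials are classified with that fold's
#' discriminant and bias; the subject is classifiable when the correct
#' count passes the trial-level binomial rule.  The overall discriminant is
#' the mean of the sign-aligned fold directions (aligned to the first fold
#' by non-negative dot product), renormalized to unit length; the overall
#' bias is the mean of the aligned fold biases and serves reporting only.
#' The classification rate is the fraction of classifiable subjects, with
#' the subject-level binomial significance flag.
#'
#' @param x a whitened \linkS4class{KinematicExperiment} (>= 3 subjects,
#'   both conditions per subject), or a numeric matrix if \code{labels} and
#'   \code{subjects} are given.
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @param cost SVM box constraint C.
#' @param labels,subjects per-trial metadata when \code{x} is a matrix.
#' @return a \linkS4class{Discriminant} with per-fold bookkeeping.
#' @export
losoDiscriminant <- function(x, rule = classifiabilityRule(), cost = 1,
                             labels = NULL, subjects = NULL) {
  if (is(x, "KinematicExperiment")) {
    cd <- trialInfo(x)
    labels <- as.character(cd$condition)
    subjects <- as.character(cd$subject)
    M <- trialMatrix(x)
  } else {
    M <- x
    labels <- as.character(labels)
    subjects <- as.character(subjects)
  }
  us <- unique(subjects)
  if (length(us) < 3L) stop("need at least 3 subjects for LOSO")

  # The linear kernel depends on the rows only through their inner products,
  # which any orthonormal change of basis preserves, and the weight vector
  # is a combination of support vectors, hence lies in the row space.  When
  # there are more variables than trials, fit in row-space coordinates and
  # map the directions back: identical results, much cheaper kernels.
  V0 <- NULL
  if (ncol(M) > nrow(M)) {
    sv <- svd(M)
    r <- .rankTol(sv$d)
    V0 <- sv$v[, seq_len(r), drop = FALSE]
    M <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  }
  p <- ncol(M)
  dirs <- matrix(NA_real_, p, length(us))
  biases <- numeric(length(us))
  folds <- vector("list", length(us))
  for (i in seq_along(us)) {
    s <- us[i]
    tr <- subjects != s
    f <- tryCatch(.fitSvmRaw(M[tr, , drop = FALSE], labels[tr], cost),
                  error = function(e)
                    stop("fold holding out subject '", s, "': ",
                         conditionMessage(e), call. = FALSE))
    pred <- .svmClassify(f$w, f$rho, f$positiveLevel, f$negativeLevel,
                         M[!tr, , drop = FALSE])
    correct <- sum(pred == labels[!tr])
    total <- sum(!tr)
    nrm <- sqrt(sum(f$w^2))
    dirs[, i] <- f$w / nrm
    biases[i] <- -f$rho / nrm
    folds[[i]] <- data.frame(subject = s, correct = correct, total = total,
                             classifiable = subjectClassifiable(correct, total,
                                                                rule),
                             positiveLevel = f$positiveLevel)
  }
  folds <- do.call(rbind, folds)

  # sign-align all folds to the first fold before averaging
  for (i in seq_along(us)[-1L]) {
    if (sum(dirs[, i] * dirs[, 1L]) < 0) {
      dirs[, i] <- -dirs[, i]
      biases[i] <- -biases[i]
      tmp <- folds$positiveLevel[i]   # orientation flip swaps the sides
      folds$positiveLevel[i] <- setdiff(unique(labels), tmp)
    }
  }
  mdir <- rowMeans(dirs)
  mnrm <- sqrt(sum(mdir^2))
  if (mnrm <= 0) stop("fold directions cancel; no mean discriminant")
  mdir <- mdir / mnrm
  folds$cosineToMean <- drop(crossprod(dirs, mdir))
  cr <- classificationRate(folds$classifiable, rule)

  proj <- drop(M %*% mdir)
  if (!is.null(V0)) {               # map back to the full variable space
    mdir <- drop(V0 %*% mdir)
    dirs <- V0 %*% dirs
  }
  eff <- tryCatch(cohensD(proj, labels), error = function(e) NA_real_)
  new("Discriminant", direction = mdir, bias = mean(biases), normFactor = 1,
      positiveLevel = folds$positiveLevel[1L],
      negativeLevel = setdiff(unique(labels), folds$positiveLevel[1L]),
      folds = folds, foldDirections = dirs, rate = cr$rate,
      significant = cr$significant, effectSize = eff)
}

#' Project data onto the orthogonal complement of a direction
#'
#' Replaces every trial row x by x - (x . v) v, removing the component along
#' the unit vector v.
#'
#' @param x a \linkS4class{KinematicExperiment} or numeric matrix (trials in
#'   rows).
#' @param direction unit vector (|v| = 1 within 1e-10).
#' @return object of the same class with all rows orthogonal to
#'   \code{direction}.
#' @export
deflate <- function(x, direction) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-10)
    stop("'direction' must be a unit vector")
  if (is(x, "KinematicExperiment")) {
    M <- trialMatrix(x)
    M <- M - drop(M %*% direction) %o% direction
    SummarizedExperiment::assay(x) <- t(M)
    x
  } else {
    x - drop(x %*% direction) %o% direction
  }
}

#' Explained-variance fractions of basis vectors
#'
#' Fraction of the matrix's total sum of squares captured along each unit
#' vector: the mean squared projection of all trials, relative to the total.
#' Over any full orthonormal basis the fractions sum to one.
#'
#' @param vectors numeric matrix of unit vectors in columns (or an
#'   \linkS4class{OrthonormalBasis}).
#' @param x a whitened \linkS4class{KinematicExperiment} or numeric matrix.
#' @return numeric vector of fractions.
#' @export
explainedVariance <- function(vectors, x) {
  if (is(vectors, "OrthonormalBasis")) vectors <- vectors@vectors
  M <- if (is(x, "KinematicExperiment")) trialMatrix(x) else x
  total <- sum(M^2)
  if (total <= 0) stop("degenerate matrix: zero total variance")
  colSums((M %*% vectors)^2) / total
}

#' PCA basis of the orthogonal complement
#'
#' PCA of the deflated residual matrix.  The residual holds the part of the
#' movement with no classifiable condition information; its PCA basis,
#' joined with the SVM basis, forms a full orthonormal basis of the data
#' space occupied by the trials.
#'
#' @param x deflated \linkS4class{KinematicExperiment} or matrix (all rows
#'   orthogonal to the accepted SVM vectors).
#' @param totalX the original whitened data used for the variance fractions
#'   (defaults to \code{x}, i.e. fractions of the residual itself).
#' @return an \linkS4class{OrthonormalBasis} of kind \code{"complement"}
#'   (empty when the residual is zero).
#' @export
complementPca <- function(x, totalX = NULL) {
  M <- if (is(x, "KinematicExperiment")) trialMatrix(x) else x
  Mtot <- if (is.null(totalX)) M
          else if (is(totalX, "KinematicExperiment")) trialMatrix(totalX)
          else totalX
  pc <- .pcaCore(M)
  if (ncol(pc$vectors) == 0L)
    return(OrthonormalBasis(vectors = matrix(0, ncol(M), 0L),
                            kind = "complement"))
  OrthonormalBasis(vectors = pc$vectors, scores = pc$scores,
                   varianceFraction = explainedVariance(pc$vectors, Mtot),
                   kind = "complement")
}

#' Iterative SVM decomposition of the data space
#'
#' Repeats: fit a leave-one-subject-out linear-SVM discriminant on the
#' current data; if its classification rate is significant (at least the
#' subject-level binomial threshold -- 8 of 11 in paper-compat mode), accept
#' the mean discriminant as the next SVM base vector (after a Gram-Schmidt
#' purge against the previously accepted vectors), remove that direction
#' from the data (deflation) and iterate; otherwise stop.  The accepted
#' vectors span the SVM space -- the subspace holding all classifiable
#' aspects of the movement; the final orthogonal complement is summarized
#' by PCA.  Every vector of both bases carries its explained-variance
#' fraction relative to the input matrix; the iteration log records the
#' final rejected rate as well.
#'
#' @param x a whitened \linkS4class{KinematicExperiment}.
#' @param rule a \linkS4class{ClassifiabilityRule} (default paper-compat,
#'   alpha 0.05).
#' @param cost SVM box constraint C (default 1; recorded, since the
#'   dimensionality of the SVM space depends on it).
#' @param maxIter cap on accepted iterations (default the matrix rank).
#' @param scoreComplement logical; also LOSO-score each complement PCA
#'   vector with the shared 1-D midpoint rule (costly; default FALSE).
#' @return a \linkS4class{DecompositionResult}.
#' @examples
#' sim <- generateSynthetic(syntheticConfig(subjects = 5, markers = 2,
#'                                          trialsPerCondition = 6,
#'                                          timepoints = 31, seed = 7))
#' ke <- whiten(assembleMatrix(sim$trials))
#' dec <- svmDecompose(ke, classifiabilityRule("exact"), maxIter = 2)
#' dec
#' @export
svmDecompose <- function(x, rule = classifiabilityRule(), cost = 1,
                         maxIter = NULL, scoreComplement = FALSE) {
  stopifnot(is(x, "KinematicExperiment"))
  if (!isWhitened(x)) stop("matrix must be whitened first (see whiten())")
  M0 <- trialMatrix(x)
  cd <- trialInfo(x)
  labels <- as.character(cd$condition)
  subjects <- as.character(cd$subject)
  rk <- .rankTol(svd(M0, nu = 0L, nv = 0L)$d)
  if (is.null(maxIter)) maxIter <- rk
  p <- ncol(M0)

  M <- M0
  accepted <- matrix(0, p, 0L)
  discs <- list()
  log <- list()
  termination <- "rate-drop"
  iter <- 0L
  repeat {
    if (iter >= maxIter || ncol(accepted) >= rk) {
      termination <- if (ncol(accepted) >= rk) "rank-exhausted" else "max-iter"
      break
    }
    if (sum(M^2) <= 1e-12 * sum(M0^2)) { termination <- "rank-exhausted"; break }
    iter <- iter + 1L
    d <- losoDiscriminant(M, rule = rule, cost = cost, labels = labels,
                          subjects = subjects)
    cr <- classificationRate(d@folds$classifiable, rule)
    accept <- cr$significant
    log[[iter]] <- data.frame(iteration = iter, rate = cr$rate,
                              nClassifiable = cr$nClassifiable,
                              nSubjects = cr$nSubjects,
                              significant = cr$significant,
                              accepted = accept)
    discs[[iter]] <- d
    if (!accept) break
    v <- d@direction
    if (ncol(accepted) > 0L) {         # numerical drift guard
      v <- v - accepted %*% crossprod(accepted, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-10) { termination <- "rank-exhausted"; break }
      v <- drop(v) / nv
    }
    accepted <- cbind(accepted, v)
    M <- deflate(M, v)
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(iteration = integer(0), rate = numeric(0),
               nClassifiable = integer(0), nSubjects = integer(0),
               significant = logical(0), accepted = logical(0))

  nAcc <- ncol(accepted)
  svmB <- OrthonormalBasis(
    vectors = accepted,
    varianceFraction = if (nAcc) explainedVariance(accepted, M0) else numeric(0),
    rates = if (nAcc) log$rate[log$accepted] else numeric(0),
    significant = if (nAcc) rep(TRUE, nAcc) else logical(0),
    effectSize = if (nAcc)
      vapply(discs[seq_len(nAcc)], function(d) d@effectSize, 1) else numeric(0),
    kind = "svm")
  compB <- complementPca(M, totalX = M0)
  if (scoreComplement && length(compB) > 0L) {
    pr <- t(M0 %*% compB@vectors)
    sc <- apply(pr, 1L, function(prj)
      losoProjectRate(prj, labels, subjects, rule)[c("rate", "significant")])
    compB@rates <- vapply(sc, function(z) z$rate, 1)
    compB@significant <- vapply(sc, function(z) z$significant, TRUE)
  }
  new("DecompositionResult", svmBasis = svmB, complementBasis = compB,
      discriminants = discs, iterationLog = log, rule = rule, cost = cost,
      termination = termination)
}
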