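## --- small ICA engines on pre-whitened data -------------------------------
## Z: n x m with identity second moment. Both return the m x m rotation W
## such that sources S = Z %*% t(W).

.icaInfomax <- function(Z, maxIter = 500L, tol = 1e-7, lrate = NULL) {
  n <- nrow(Z); m <- ncol(Z)
  if (is.null(lrate)) lrate <- 0.01 / log(m^2 + 1) + 0.005
  # random orthonormal start (caller controls the RNG state)
  W <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  I <- diag(m)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    U <- Z %*% t(W)
    # sub/super-Gaussian switching by the sign of the excess kurtosis
    kurt <- colMeans(U^4) / colMeans(U^2)^2 - 3
    k <- ifelse(kurt >= 0, 1, -1)
    G <- I - (crossprod(tanh(U), U) * k + crossprod(U)) / n
    dW <- lrate * G %*% W
    W <- W + dW
    delta <- sqrt(sum(dW^2)) / sqrt(sum(W^2))
    if (!all(is.finite(W))) stop("infomax ICA diverged; try a smaller learning rate")
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
    if (iter %% 50L == 0L) lrate <- lrate * 0.9
  }
  list(W = W, iterations = iter, converged = converged)
}

.icaFastDeflation <- function(Z, maxIter = 500L, tol = 1e-8) {
  n <- nrow(Z); m <- ncol(Z)
  W <- matrix(0, m, m)
  iterTot <- 0L; converged <- TRUE
  for (j in seq_len(m)) {
    w <- rnorm(m); w <- w / sqrt(sum(w^2))
    for (it in seq_len(maxIter)) {
      iterTot <- iterTot + 1L
      u <- drop(Z %*% w)
      g <- tanh(u); gp <- 1 - g^2
      w1 <- drop(crossprod(Z, g)) / n - mean(gp) * w
      if (j > 1L) {
        prev <- W[seq_len(j - 1L), , drop = FALSE]
        w1 <- w1 - drop(crossprod(prev, prev %*% w1))
      }
      w1 <- w1 / sqrt(sum(w1^2))
      conv <- abs(abs(sum(w1 * w)) - 1) < tol
      w <- w1
      if (conv) break
    }
    if (!conv) converged <- FALSE
    W[j, ] <- w
  }
  list(W = W, iterations = iterTot, converged = converged)
}

#' ICA of the data within the SVM space
#'
#' Expresses every trial by its coordinates in the SVM space (projections
#' onto the orthonormal SVM basis), runs ICA on that trials x m coordinate
#' matrix, and maps each recovered base vector back to data space.  The
#' number of ICA base vectors equals the SVM-space dimension; they span the
#' SVM space but are in general not orthogonal.  Vectors are ordered by
#' decreasing leave-one-subject-out classification rate of their source
#' coordinates, so the ICA discriminant -- when one exists -- is the first
#' vector.
#'
#' The default algorithm is a batch extended-infomax (natural-gradient
#' update with kurtosis-based sub/super-Gaussian switching); a
#' deflationary fastICA-style alternative with the logcosh contrast is
#' available.  Both operate on second-moment-whitened coordinates and are
#' deterministic given \code{seed}.  The condition effect makes the
#' classifying source bimodal (sub-Gaussian), which is why the extended
#' update matters.
#'
#' @param x a whitened \linkS4class{KinematicExperiment}.
#' @param basis the SVM space: an \linkS4class{OrthonormalBasis}, a
#'   \linkS4class{DecompositionResult} (its SVM basis is used), or a
#'   variables x m matrix with orthonormal columns.
#' @param seed integer seed for the random initialization (recorded).
#' @param algorithm \code{"infomax"} (default) or \code{"fastica"}.
#' @param rule \linkS4class{ClassifiabilityRule} for scoring and selection.
#' @param maxIter,tol convergence controls.
#' @return an \linkS4class{IcaResult}.
#' @export
icaInSubspace <- function(x, basis, seed = 1L,
                          algorithm = c("infomax", "fastica"),
                          rule = classifiabilityRule(), maxIter = 500L,
                          tol = NULL) {
  algorithm <- match.arg(algorithm)
  E <- if (is(basis, "DecompositionResult")) basis@svmBasis@vectors
       else if (is(basis, "OrthonormalBasis")) basis@vectors
       else as.matrix(basis)
  m <- ncol(E)
  if (m == 0L) stop("empty SVM space: no subspace to run ICA in")
  M <- trialMatrix(x)
  cd <- trialInfo(x)
  labels <- as.character(cd$condition)
  subjects <- as.character(cd$subject)
  n <- nrow(M)
  if (n < 10L * m)
    warning("only ", n, " trials for a ", m,
            "-dimensional ICA; estimates may be unstable")
  Y <- M %*% E                       # SVM-space coordinates (mean ~ 0)

  if (m == 1L) {
    sdy <- sqrt(mean(Y^2))
    if (sdy <= 0) stop("degenerate SVM-space coordinates")
    Ut <- matrix(1 / sdy, 1L, 1L)
    res <- list(iterations = 0L, converged = TRUE)
  } else {
    C <- crossprod(Y) / n
    eg <- eigen(C, symmetric = TRUE)
    if (min(eg$values) <= 1e-12 * max(eg$values))
      stop("SVM-space coordinates are numerically rank deficient")
    Q <- diag(1 / sqrt(eg$values), m) %*% t(eg$vectors)
    Z <- Y %*% t(Q)
    oldSeed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    res <- switch(algorithm,
      infomax = .icaInfomax(Z, maxIter = maxIter,
                            tol = if (is.null(tol)) 1e-7 else tol),
      fastica = .icaFastDeflation(Z, maxIter = maxIter,
                                  tol = if (is.null(tol)) 1e-8 else tol))
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv)
    if (!res$converged)
      warning("ICA did not converge within ", res$iterations, " iterations")
    Ut <- res$W %*% Q                # sources S = Y %*% t(Ut)
  }
  A <- solve(Ut)                     # Y = S %*% t(A); base vectors = cols of A
  S <- Y %*% t(Ut)

  sc <- lapply(seq_len(m), function(j)
    losoProjectRate(S[, j], labels, subjects, rule))
  rates <- vapply(sc, function(z) z$rate, 1)
  sig <- vapply(sc, function(z) z$significant, TRUE)
  eff <- vapply(seq_len(m), function(j)
    tryCatch(cohensD(S[, j], labels), error = function(e) NA_real_), 1)
  ord <- order(-rates, -ifelse(is.na(eff), -Inf, eff))

  Ut <- Ut[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  rates <- rates[ord]; sig <- sig[ord]; eff <- eff[ord]
  V <- E %*% A
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  new("IcaResult", vectors = V, svmVectors = E, mixing = A, unmixing = Ut,
      rates = rates, significant = sig, effectSize = eff,
      discriminantIndex = if (isTRUE(sig[1L])) 1L else integer(0),
      seed = as.integer(seed), algorithm = algorithm,
      converged = res$converged, iterations = as.integer(res$iterations))
}

#' Select the classifying ICA discriminant
#'
#' Re-scores every ICA base vector by the shared leave-one-subject-out 1-D
#' midpoint rule applied to its source coordinates and selects the vector
#' with the highest significant classification rate (ties broken by the
#' larger effect size).  Absence of a significant vector is a valid
#' outcome, reported as an empty index.
#'
#' @param ica an \linkS4class{IcaResult}.
#' @param x the whitened \linkS4class{KinematicExperiment} the ICA was
#'   computed on.
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @return list: \code{index} (integer, possibly length 0), \code{rate},
#'   \code{effectSize}, and the per-vector \code{rates}, \code{significant},
#'   \code{effectSizes}.
#' @export
selectIcaDiscriminant <- function(ica, x, rule = classifiabilityRule()) {
  cd <- trialInfo(x)
  labels <- as.character(cd$condition)
  subjects <- as.character(cd$subject)
  S <- icaSources(ica, x)
  m <- ncol(S)
  sc <- lapply(seq_len(m), function(j)
    losoProjectRate(S[, j], labels, subjects, rule))
  rates <- vapply(sc, function(z) z$rate, 1)
  sig <- vapply(sc, function(z) z$significant, TRUE)
  eff <- vapply(seq_len(m), function(j)
    tryCatch(cohensD(S[, j], labels), error = function(e) NA_real_), 1)
  cand <- which(sig)
  idx <- if (length(cand) == 0L) integer(0) else
    cand[order(-rates[cand], -ifelse(is.na(eff[cand]), -Inf, eff[cand]))][1L]
  list(index = idx,
       rate = if (length(idx)) rates[idx] else NA_real_,
       effectSize = if (length(idx)) eff[idx] else NA_real_,
       rates = rates, significant = sig, effectSizes = eff)
}

#' Source coordinates of the trials under an ICA result
#'
#' @param ica an \linkS4class{IcaResult}.
#' @param x the whitened \linkS4class{KinematicExperiment}.
#' @return trials x m matrix of source coordinates
#'   (\code{(M E) \%*\% t(unmixing)}).
#' @export
icaSources <- function(ica, x) {
  M <- if (is(x, "KinematicExperiment")) trialMatrix(x) else x
  (M %*% ica@svmVectors) %*% t(ica@unmixing)
}
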