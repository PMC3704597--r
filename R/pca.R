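## numerical rank via relative singular-value tolerance
.rankTol <- function(d, tol = 1e-10) {
  if (length(d) == 0L || max(d) <= 0) 0L else sum(d > tol * max(d))
}

## PCA of a trials x variables matrix already centered by construction
## (per-subject whitening makes every column mean exactly zero).
## Returns vectors (p x r), eigenvalue-scale scores d^2/N, and fractions.
.pcaCore <- function(X, maxVectors = NULL) {
  sv <- svd(X)
  r <- .rankTol(sv$d)
  if (r == 0L) return(list(vectors = matrix(0, ncol(X), 0L),
                           scores = numeric(0), fractions = numeric(0)))
  keep <- seq_len(if (is.null(maxVectors)) r else min(r, maxVectors))
  total <- sum(sv$d^2)
  list(vectors = sv$v[, keep, drop = FALSE],
       scores = sv$d[keep]^2 / nrow(X),
       fractions = sv$d[keep]^2 / total)
}

#' PCA basis of the whitened matrix
#'
#' Singular value decomposition of the whitened trial-by-variable matrix;
#' the right singular vectors up to the numerical rank form the PCA base,
#' with eigenvalues (singular values squared over the number of trials) as
#' variance scores, sorted descending.
#'
#' @param x a whitened \linkS4class{KinematicExperiment}.
#' @param maxVectors optional cap on the number of vectors returned.
#' @return an \linkS4class{OrthonormalBasis} of kind \code{"pca"}.
#' @export
pcaBasis <- function(x, maxVectors = NULL) {
  stopifnot(is(x, "KinematicExperiment"))
  if (!isWhitened(x)) stop("matrix must be whitened first (see whiten())")
  if (ncol(x) < 2L) stop("need at least 2 trials")
  pc <- .pcaCore(trialMatrix(x), maxVectors)
  if (ncol(pc$vectors) == 0L) stop("degenerate data: matrix has rank 0")
  OrthonormalBasis(vectors = pc$vectors, scores = pc$scores,
                   varianceFraction = pc$fractions, kind = "pca")
}

#' Leave-one-subject-out classification rates of PCA vectors
#'
#' For each held-out subject, the PCA is recomputed on the remaining
#' subjects' (whitened) trials; the held-out subject's trials -- whitened by
#' its own statistics -- are projected onto the fold's vector of the given
#' ordinal index, assigned by the midpoint rule trained on the remaining
#' subjects' projections, and counted against the trial-level binomial
#' test.  Fold vectors are matched to the full-data vectors by ordinal
#' position and sign-aligned by dot product; a warning is issued when a
#' fold-to-full |cosine| drops below 0.7 (ordinal instability).
#'
#' @param x a whitened \linkS4class{KinematicExperiment} with >= 3 subjects,
#'   both conditions per subject.
#' @param vectors integer vector of ordinal PCA indices to score.
#' @param rule a \linkS4class{ClassifiabilityRule}.
#' @param fullBasis optional precomputed [pcaBasis()] of \code{x}.
#' @return data.frame with one row per scored vector: \code{index},
#'   \code{rate}, \code{significant}, \code{nClassifiable},
#'   \code{minFoldCosine}.
#' @export
losoRates <- function(x, vectors = NULL, rule = classifiabilityRule(),
                      fullBasis = NULL) {
  stopifnot(is(x, "KinematicExperiment"))
  if (!isWhitened(x)) stop("matrix must be whitened first")
  M <- trialMatrix(x)
  cd <- trialInfo(x)
  subj <- as.character(cd$subject)
  cond <- as.character(cd$condition)
  us <- unique(subj)
  if (length(us) < 3L) stop("need at least 3 subjects for LOSO scoring")
  if (is.null(fullBasis)) fullBasis <- pcaBasis(x)
  if (is.null(vectors)) vectors <- seq_len(length(fullBasis))
  kmax <- max(vectors)

  folds <- lapply(us, function(s) {
    tr <- subj != s
    if (length(unique(cond[tr])) != 2L)
      stop("subject '", s, "': remaining training data lacks a condition")
    pc <- .pcaCore(M[tr, , drop = FALSE], maxVectors = kmax)
    if (ncol(pc$vectors) < kmax)
      stop("fold holding out subject '", s, "' has rank ", ncol(pc$vectors),
           " < requested vector index ", kmax)
    list(subject = s, heldOut = !tr, V = pc$vectors)
  })

  res <- lapply(vectors, function(k) {
    vfull <- fullBasis@vectors[, k]
    cosines <- numeric(length(folds))
    flags <- logical(length(folds))
    for (i in seq_along(folds)) {
      f <- folds[[i]]
      v <- f$V[, k]
      cs <- sum(v * vfull)
      if (cs < 0) { v <- -v; cs <- -cs }
      cosines[i] <- cs
      proj <- drop(M %*% v)
      pred <- .assign1d(proj[!f$heldOut], cond[!f$heldOut], proj[f$heldOut])
      if (is.null(pred)) {
        warning("degenerate training projections for PCA vector ", k,
                ", fold '", f$subject, "'")
        pred <- rep(sort(unique(cond))[1L], sum(f$heldOut))
      }
      correct <- sum(pred == cond[f$heldOut])
      flags[i] <- subjectClassifiable(correct, sum(f$heldOut), rule)
    }
    if (min(cosines) < 0.7)
      warning("PCA vector ", k, ": fold-to-full |cosine| ",
              signif(min(cosines), 3L), " < 0.7; ordinal matching unstable")
    cr <- classificationRate(flags, rule)
    data.frame(index = k, rate = cr$rate, significant = cr$significant,
               nClassifiable = cr$nClassifiable,
               minFoldCosine = min(cosines))
  })
  do.call(rbind, res)
}

#' Partition a scored PCA basis into classifying and non-classifying spaces
#'
#' @param basis a PCA \linkS4class{OrthonormalBasis}.
#' @param rates data.frame from [losoRates()] covering the tested vectors.
#' @return list with \linkS4class{OrthonormalBasis} elements
#'   \code{classifying} and \code{nonClassifying} (order preserved;
#'   together they partition the tested set).
#' @export
classifyingPcaSpace <- function(basis, rates) {
  stopifnot(is(basis, "OrthonormalBasis"))
  idx <- rates$index
  scored <- basis[idx]
  scored@rates <- rates$rate
  scored@significant <- rates$significant
  sig <- which(rates$significant)
  list(classifying = scored[sig],
       nonClassifying = scored[setdiff(seq_along(idx), sig)])
}
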