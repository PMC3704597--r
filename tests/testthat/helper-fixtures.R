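# Shared fixture builders.  All data are generated in code; the "small"
# configuration keeps LOSO SVM rounds fast while preserving the study
# structure (balanced subjects x conditions x trials).

smallConfig <- function(seed = 1, subjects = 5, markers = 2,
                        trialsPerCondition = 8, timepoints = 31, ...) {
  syntheticConfig(subjects = subjects, markers = markers,
                  trialsPerCondition = trialsPerCondition,
                  timepoints = timepoints, seed = seed, ...)
}

# the scale used for the Monte-Carlo suites: study-sized cohort, reduced
# marker count (4 markers -> 1212 variables)
mcConfig <- function(seed, ...) {
  syntheticConfig(subjects = 11, markers = 4, trialsPerCondition = 20,
                  timepoints = 101, seed = seed, ...)
}

nullConfig <- function(seed) {
  syntheticConfig(subjects = 8, markers = 2, trialsPerCondition = 10,
                  timepoints = 51, effects = NULL, seed = seed)
}

whitenedSim <- function(config) {
  sim <- generateSynthetic(config)
  list(ke = whiten(assembleMatrix(sim$trials)), truth = sim$truth,
       trials = sim$trials)
}

# hand-built tiny experiment: explicit values, 1 "marker", 1 "axis"
toyExperiment <- function(values, subjects, conditions, whitened = FALSE) {
  kinematicExperiment(values, subjects = subjects, conditions = conditions,
                      whitened = whitened)
}

# brute-force nearest points between the convex hulls of two 2-D point
# sets: dense scan over convex weights of all point pairs/edges followed by
# a box-constrained quadratic refinement.  Independent of the SVM solver.
hardMarginOracle <- function(A, B, gridN = 201L) {
  bestD <- Inf; best <- NULL
  combA <- utils::combn(seq_len(nrow(A)), min(2L, nrow(A)),
                        simplify = FALSE)
  combB <- utils::combn(seq_len(nrow(B)), min(2L, nrow(B)),
                        simplify = FALSE)
  lam <- seq(0, 1, length.out = gridN)
  for (ia in combA) for (ib in combB) {
    PA <- A[ia, , drop = FALSE]; PB <- B[ib, , drop = FALSE]
    UA <- if (nrow(PA) == 1L) PA[rep(1L, gridN), , drop = FALSE]
          else outer(1 - lam, PA[1L, ]) + outer(lam, PA[2L, ])
    UB <- if (nrow(PB) == 1L) PB[rep(1L, gridN), , drop = FALSE]
          else outer(1 - lam, PB[1L, ]) + outer(lam, PB[2L, ])
    D <- outer(rowSums(UA^2), rowSums(UB^2), "+") - 2 * UA %*% t(UB)
    ij <- arrayInd(which.min(D), dim(D))
    # quadratic refinement of (s, t) around the grid optimum
    f <- function(st) {
      u <- if (nrow(PA) == 1L) PA[1L, ] else (1 - st[1L]) * PA[1L, ] + st[1L] * PA[2L, ]
      v <- if (nrow(PB) == 1L) PB[1L, ] else (1 - st[2L]) * PB[1L, ] + st[2L] * PB[2L, ]
      sum((u - v)^2)
    }
    op <- stats::optim(c(lam[ij[1L]], lam[ij[2L]]), f, method = "L-BFGS-B",
                       lower = 0, upper = 1,
                       control = list(factr = 1e3))
    if (op$value < bestD) {
      bestD <- op$value
      st <- op$par
      u <- if (nrow(PA) == 1L) PA[1L, ] else (1 - st[1L]) * PA[1L, ] + st[1L] * PA[2L, ]
      v <- if (nrow(PB) == 1L) PB[1L, ] else (1 - st[2L]) * PB[1L, ] + st[2L] * PB[2L, ]
      best <- list(u = u, v = v)
    }
  }
  w <- best$u - best$v
  list(direction = w / sqrt(sum(w^2)), midpoint = (best$u + best$v) / 2,
       margin = sqrt(bestD))
}
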