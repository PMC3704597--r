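test_that("the linear discriminant reproduces hard-margin geometry", {
  # symmetric 1-D pair: midpoint of the margin at zero
  d1 <- fitLinearDiscriminant(matrix(c(-1, 1), 2, 1), c("a", "b"),
                              cost = 1e6)
  expect_equal(abs(d1@direction), 1, tolerance = 1e-10)
  expect_lt(abs(discriminantDecision(d1, matrix(0, 1, 1))), 1e-6)
  pred1 <- ifelse(discriminantDecision(d1, matrix(c(-1, 1), 2, 1)) > 0,
                  d1@positiveLevel, d1@negativeLevel)
  expect_identical(pred1, c("a", "b"))

  # separating plane of the 2-D block toy lies at first coordinate = 1
  x <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  d2 <- fitLinearDiscriminant(x, c("a", "a", "b", "b"), cost = 1e6)
  expect_equal(abs(d2@direction[1]), 1, tolerance = 1e-6)
  expect_lt(abs(d2@direction[2]), 1e-6)
  expect_lt(max(abs(discriminantDecision(d2, rbind(c(1, 0), c(1, 1))))), 1e-6)
  pred <- ifelse(discriminantDecision(d2, x) > 0, d2@positiveLevel,
                 d2@negativeLevel)
  expect_identical(pred, c("a", "a", "b", "b"))

  expect_error(fitLinearDiscriminant(x, rep("a", 4)), "two condition")
})

test_that("kernel-sum decision values equal the data-space dot product", {
  set.seed(10)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("a", "b"), each = 20)
  x[y == "b", 1] <- x[y == "b", 1] + 1.5
  d <- fitLinearDiscriminant(x, y, cost = 1)
  xn <- matrix(rnorm(15 * 6), 15, 6)

  # oracle 1: explicit kernel sum over support vectors, Eq. 3 form
  fit <- e1071::svm(x, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  kern <- drop(xn %*% t(fit$SV) %*% fit$coefs) - fit$rho
  ours <- discriminantDecision(d, xn)
  expect_lt(max(abs(abs(ours) - abs(kern))), 1e-8)

  # oracle 2: libsvm's own decision values on the training fit
  dv <- drop(attr(predict(fit, xn, decision.values = TRUE),
                  "decision.values"))
  expect_lt(max(abs(abs(ours) - abs(dv))), 1e-8)
})

test_that("hard-margin fits agree with a nearest-point hull oracle", {
  sets <- list(
    list(A = rbind(c(0, 0), c(0, 1)), B = rbind(c(2, 0), c(2, 1))),
    list(A = rbind(c(0, 0), c(1, 1)), B = rbind(c(3, 0), c(4, 1))),
    list(A = rbind(c(-1, 0), c(0, 1.5)), B = rbind(c(2, -1), c(2.5, 2))))
  for (s in sets) {
    or <- hardMarginOracle(s$A, s$B)
    x <- rbind(s$A, s$B)
    y <- rep(c("a", "b"), c(nrow(s$A), nrow(s$B)))
    d <- fitLinearDiscriminant(x, y, cost = 1e8, tolerance = 1e-10)
    expect_lt(abs(abs(sum(d@direction * or$direction)) - 1), 1e-6)
    # decision boundary passes through the midpoint of the closest pair
    expect_lt(abs(discriminantDecision(d, matrix(or$midpoint, 1))) /
                d@normFactor, 1e-6)
  }
})

test_that("deflation projects exactly onto the orthogonal complement", {
  set.seed(11)
  v <- rnorm(20); v <- v / sqrt(sum(v^2))
  u <- rnorm(20); u <- u - sum(u * v) * v         # orthogonal row
  X <- rbind(u, 3 * v, rnorm(20))
  D <- deflate(X, v)
  expect_lt(max(abs(D[1, ] - u)), 1e-12)
  expect_lt(max(abs(D[2, ])), 1e-12)
  expect_lt(max(abs(D %*% v)), 1e-10)
  expect_lt(max(abs(deflate(D, v) - D)), 1e-12)   # projector idempotence
  expect_error(deflate(X, 2 * v), "unit")
})

test_that("explained variance fractions satisfy Parseval's identity", {
  set.seed(12)
  X <- matrix(rnorm(30 * 6), 30, 6)
  E <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  fr <- explainedVariance(E, X)
  expect_equal(sum(fr), 1, tolerance = 1e-8)

  e1 <- diag(6)[, 1]
  expect_equal(explainedVariance(diag(6), matrix(e1, 1, 6)),
               c(1, 0, 0, 0, 0, 0))
  # two-variable toy with axis variances 4 and 1
  toy <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  expect_equal(explainedVariance(diag(2), toy), c(0.8, 0.2))
  expect_error(explainedVariance(diag(2), matrix(0, 3, 2)), "degenerate")
})

test_that("LOSO discriminants recover a strong planted effect", {
  sim <- whitenedSim(smallConfig(seed = 13))
  d <- losoDiscriminant(sim$ke, rule = classifiabilityRule("exact"))
  expect_equal(d@rate, 1)
  expect_true(d@significant)
  expect_true(all(d@folds$classifiable))
  # fold discriminants point almost in the same direction
  G <- crossprod(d@foldDirections)
  expect_gte(min(G), 0.8)
  # and their projections are mutually correlated: they separate the same
  # dichotomous data
  P <- trialMatrix(sim$ke) %*% d@foldDirections
  for (j in 2:ncol(P)) {
    ct <- cor.test(P[, 1], P[, j])
    expect_gt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.05)
  }
  # strong effect: large effect size, unit direction
  expect_gt(d@effectSize, 2)
  expect_equal(sqrt(sum(d@direction^2)), 1, tolerance = 1e-10)
})

test_that("shuffled labels are rarely significant under the exact rule", {
  cfg <- syntheticConfig(subjects = 6, markers = 1, trialsPerCondition = 6,
                         timepoints = 31, effects = NULL, seed = 1)
  sim <- whitenedSim(cfg)
  M <- trialMatrix(sim$ke)
  cd <- trialInfo(sim$ke)
  sig <- 0
  for (seed in 1:30) {
    set.seed(seed)
    lab <- unlist(lapply(split(as.character(cd$condition), cd$subject),
                         sample), use.names = FALSE)
    d <- losoDiscriminant(M, rule = classifiabilityRule("exact"),
                          labels = lab, subjects = as.character(cd$subject))
    sig <- sig + d@significant
  }
  expect_lte(sig, 3)
})

test_that("the iterative decomposition terminates and accounts for variance", {
  sim <- whitenedSim(smallConfig(seed = 14))
  dec <- svmDecompose(sim$ke, rule = classifiabilityRule("exact"))
  log <- iterationLog(dec)
  k <- length(svmBasis(dec))
  expect_gte(k, 1L)
  # every accepted vector classified at a significant rate; the final
  # logged iteration is the rejected one
  expect_true(all(basisSignificant(svmBasis(dec))))
  if (dec@termination == "rate-drop")
    expect_false(log$significant[nrow(log)])
  # joint basis orthonormal, variance conserved
  J <- jointBasis(dec)
  expect_lt(max(abs(crossprod(J) - diag(ncol(J)))), 1e-8)
  expect_equal(sum(varianceFractions(svmBasis(dec))) +
                 sum(varianceFractions(complementBasis(dec))), 1,
               tolerance = 1e-6)
  # at most rank(M') accepted steps
  expect_lte(k + length(complementBasis(dec)),
             min(dim(trialMatrix(sim$ke))))
  # planted direction captured by the SVM space
  expect_gte(truthAlignment(dec, sim$truth)$scores, 0.9)
  # maxIter caps the accepted vectors
  dec1 <- svmDecompose(sim$ke, rule = classifiabilityRule("exact"),
                       maxIter = 0)
  expect_identical(length(svmBasis(dec1)), 0L)
  expect_identical(dec1@termination, "max-iter")
})

test_that("the complement carries no classifiable condition information", {
  nseeds <- 8; clean <- 0
  for (seed in seq_len(nseeds)) {
    sim <- whitenedSim(smallConfig(seed = 100 + seed))
    dec <- svmDecompose(sim$ke, rule = classifiabilityRule("exact"),
                        scoreComplement = TRUE)
    sig <- basisSignificant(complementBasis(dec))
    clean <- clean + !any(sig)
  }
  expect_gte(clean, ceiling(0.9 * nseeds) - 1)   # allow one stray seed
})
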