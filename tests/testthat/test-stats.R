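test_that("exact binomial thresholds match the enumerated tail sums", {
  expect_identical(binomialThreshold(5), 5L)     # tail 1/32 = 0.03125
  expect_true(is.na(binomialThreshold(4)))       # minimal tail 1/16 > 0.05
  expect_identical(binomialThreshold(40), 26L)
  expect_identical(binomialThreshold(11), 9L)
  expect_error(binomialThreshold(0), "n >= 1")
  expect_error(binomialThreshold(10, alpha = 1.5), "alpha")
})

test_that("exact thresholds are monotone and respect the alpha level", {
  # exhaustive check over n <= 64: P(X >= k) <= alpha at the threshold and
  # > alpha one below; thresholds never decrease with n
  prev <- 0L
  for (n in 1:64) {
    k <- binomialThreshold(n)
    if (is.na(k)) next
    expect_lte(pbinom(k - 1, n, 0.5, lower.tail = FALSE), 0.05)
    if (k > 1)
      expect_gt(pbinom(k - 2, n, 0.5, lower.tail = FALSE), 0.05)
    expect_gte(k, prev)
    prev <- k
  }
})

test_that("paper-compat mode pins the printed 25/40 and 8/11 thresholds", {
  paper <- classifiabilityRule("paper")
  exact <- classifiabilityRule("exact")
  expect_true(subjectClassifiable(25, 40, paper))
  expect_false(subjectClassifiable(24, 40, paper))
  expect_false(subjectClassifiable(25, 40, exact))
  expect_true(subjectClassifiable(26, 40, exact))
  expect_true(subjectClassifiable(20, 20, paper))  # perfect classification

  r <- classificationRate(rep(c(TRUE, FALSE), c(8, 3)), paper)
  expect_equal(r$rate, 8 / 11, tolerance = 1e-12)
  expect_true(r$significant)
  expect_false(classificationRate(rep(c(TRUE, FALSE), c(8, 3)),
                                  exact)$significant)
  expect_true(classificationRate(rep(c(TRUE, FALSE), c(9, 2)),
                                 exact)$significant)
  expect_false(classificationRate(rep(FALSE, 11), paper)$significant)
  # away from the pinned n the two modes agree
  expect_identical(trialThreshold(paper, 20), trialThreshold(exact, 20))
})

test_that("Cohen's d uses the pooled-SD formula and is scale invariant", {
  d <- cohensD(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))
  expect_equal(d, 2)
  expect_equal(cohensD(c(5, 5, 5, 5) + c(1, 2, 3, 4), rep(c("a", "b"), 2)),
               cohensD(-3 * (c(5, 5, 5, 5) + c(1, 2, 3, 4)),
                       rep(c("a", "b"), 2)), tolerance = 1e-12)
  expect_equal(cohensD(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0)
  expect_error(cohensD(c(1, 1, 1, 1), c("a", "a", "b", "b")), "pooled")
})

test_that("the normality gate distinguishes normal from uniform samples", {
  set.seed(77)
  norm500 <- rnorm(500)
  unif500 <- runif(500)
  expect_true(unname(normalityGate(norm500)))
  expect_false(unname(normalityGate(unif500)))
  g <- normalityGate(c(norm500, unif500),
                     rep(c("n", "u"), each = 500))
  expect_true(g[["n"]]); expect_false(g[["u"]])
  expect_error(normalityGate(rnorm(3)), "at least 5")
})

test_that("the shared 1-D LOSO rule scores separation and nulls correctly", {
  subjects <- rep(sprintf("s%d", 1:6), each = 10)
  labels <- rep(rep(c("a", "b"), each = 5), 6)
  # perfectly separated projections
  proj <- ifelse(labels == "a", 1, -1) + rnorm(60, sd = 0.01)
  r <- losoProjectRate(proj, labels, subjects, classifiabilityRule("exact"))
  expect_equal(r$rate, 1)
  expect_true(r$significant)

  # orientation invariance: flipping the projection flips nothing
  r2 <- losoProjectRate(-proj, labels, subjects, classifiabilityRule("exact"))
  expect_equal(r2$rate, 1)
  # affine transforms preserve midpoint decisions, hence the rate
  r3 <- losoProjectRate(3.7 * proj + 11, labels, subjects,
                        classifiabilityRule("exact"))
  expect_identical(r3$perSubject$correct, r$perSubject$correct)

  # label-independent projections are non-significant in >= 90% of seeds
  sig <- 0
  for (seed in 1:50) {
    set.seed(seed)
    sig <- sig + losoProjectRate(rnorm(60), labels, subjects,
                                 classifiabilityRule("exact"))$significant
  }
  expect_lte(sig, 5)
})
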