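test_that("the full joint basis reconstructs the preprocessed movement", {
  sim <- whitenedSim(smallConfig(seed = 19))
  raw <- trialMatrix(assembleMatrix(generateSynthetic(smallConfig(seed = 19))$trials))
  dec <- svmDecompose(sim$ke, rule = classifiabilityRule("exact"))
  full <- reconstructMovement(sim$ke, jointBasis(dec))
  expect_lt(max(abs(trialMatrix(full) - raw)), 1e-6)
  expect_false(isWhitened(full))
})

test_that("an empty vector set reconstructs each subject's mean movement", {
  sim <- whitenedSim(smallConfig(seed = 20, subjects = 4))
  rec <- reconstructMovement(sim$ke, matrix(0, nrow(sim$ke), 0L))
  M <- trialMatrix(rec)
  st <- subjectStats(sim$ke)
  subj <- as.character(trialInfo(sim$ke)$subject)
  for (s in unique(subj))
    expect_lt(max(abs(sweep(M[subj == s, , drop = FALSE], 2,
                            st$mean[, s]))), 1e-10)
})

test_that("reconstruction is additive over orthogonal subspace splits", {
  sim <- whitenedSim(smallConfig(seed = 21))
  dec <- svmDecompose(sim$ke, rule = classifiabilityRule("exact"))
  full <- trialMatrix(reconstructMovement(sim$ke, jointBasis(dec)))
  svmPart <- trialMatrix(reconstructMovement(sim$ke, svmBasis(dec)))
  compPart <- trialMatrix(reconstructMovement(sim$ke, complementBasis(dec)))
  meanPart <- trialMatrix(reconstructMovement(sim$ke,
                                              matrix(0, nrow(sim$ke), 0L)))
  expect_lt(max(abs(svmPart + compPart - meanPart - full)), 1e-8)
  # non-orthogonal vector sets are rejected
  V <- jointBasis(dec)[, 1:2]
  V[, 2] <- (V[, 1] + V[, 2]) / sqrt(2)
  expect_error(reconstructMovement(sim$ke, V), "orthogonal")
})

test_that("condition averages match hand arithmetic and have zero SD when exact", {
  vals <- rbind(c(1, 10), c(3, 14), c(5, 20), c(7, 28))
  ke <- kinematicExperiment(vals, subjects = rep("s1", 4),
                            conditions = c("a", "a", "b", "b"))
  avg <- conditionAverage(ke)
  expect_equal(unname(avg$mean["a", ]), c(2, 12))
  expect_equal(unname(avg$mean["b", ]), c(6, 24))
  expect_equal(unname(avg$sd["a", ]), c(sd(c(1, 3)), sd(c(10, 14))))

  same <- kinematicExperiment(rbind(c(1, 2), c(1, 2), c(3, 4), c(3, 4)),
                              subjects = rep("s1", 4),
                              conditions = c("a", "a", "b", "b"))
  expect_true(all(conditionAverage(same)$sd == 0))
})

test_that("frame export amplifies condition gaps linearly", {
  sim <- whitenedSim(smallConfig(seed = 22, subjects = 4))
  rec <- reconstructMovement(sim$ke, pcaBasis(sim$ke))
  avg <- conditionAverage(rec)
  f1 <- exportFrames(avg, plane = "sagittal", magnification = 1)
  f5 <- exportFrames(avg, plane = "sagittal", magnification = 5)
  expect_identical(length(unique(f1$time_index)),
                   as.integer(avg$layout@timepoints))
  # magnification 1 leaves coordinates at the condition means
  i <- f1$time_index == 10 & f1$marker == 2
  lay <- avg$layout
  expect_equal(f1$coord2[i & f1$condition == avg$condition[1]],
               unname(avg$mean[1, variableIndex(lay, 2, 3, 10)]),
               tolerance = 1e-12)
  # gap scales exactly fivefold
  gap1 <- f1$coord2[i & f1$condition == avg$condition[1]] -
          f1$coord2[i & f1$condition == avg$condition[2]]
  gap5 <- f5$coord2[i & f5$condition == avg$condition[1]] -
          f5$coord2[i & f5$condition == avg$condition[2]]
  expect_equal(gap5, 5 * gap1, tolerance = 1e-10)
  expect_error(exportFrames(avg, plane = "transverse"), "arg")

  # CSV writing round-trips
  fn <- tempfile(fileext = ".csv")
  exportFrames(avg, "frontal", file = fn)
  back <- read.csv(fn)
  expect_identical(names(back),
                   c("time_index", "condition", "marker", "coord1", "coord2"))
  expect_identical(nrow(back), nrow(f1))
})

test_that("the complement reconstruction shows no condition difference", {
  sim <- whitenedSim(smallConfig(seed = 23))
  dec <- svmDecompose(sim$ke, rule = classifiabilityRule("exact"))
  cd <- trialInfo(sim$ke)
  # LOSO rate of the data projected on the complement's leading vectors
  M <- trialMatrix(sim$ke)
  V <- basisVectors(complementBasis(dec))[, 1:5]
  for (j in 1:5) {
    r <- losoProjectRate(drop(M %*% V[, j]), cd$condition, cd$subject,
                         classifiabilityRule("exact"))
    expect_false(r$significant)
  }
  # and the waveform bands of the two conditions overlap at the effect site
  rec <- reconstructMovement(sim$ke, complementBasis(dec))
  wf <- extractWaveform(rec, marker = 2, axis = 3, byCondition = TRUE)
  gap <- abs(wf$mean[1, ] - wf$mean[2, ])
  band <- wf$sd[1, ] + wf$sd[2, ]
  expect_true(all(gap <= pmax(band, 1e-12)))
})
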