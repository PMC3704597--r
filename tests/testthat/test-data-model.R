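test_that("variable index map reproduces the canonical column positions", {
  lay <- KinematicLayout()
  expect_identical(variableIndex(lay, 3, 3, 39), 847L)
  expect_identical(variableIndex(lay, 1, 1, 1), 1L)
  expect_identical(variableIndex(lay, 13, 3, 101), 3939L)
  expect_identical(nVariables(lay), 3939L)
  expect_error(variableIndex(lay, 14, 1, 1), "marker")
  expect_error(variableIndex(lay, 1, 4, 1), "axis")
  expect_error(variableIndex(lay, 1, 1, 102), "time")
  expect_error(variableInfo(lay, 3940), "column")
})

test_that("index map and its inverse are a bijection", {
  lay <- KinematicLayout(markers = 3, axes = 3, timepoints = 7)
  cols <- variableIndex(lay,
                        marker = rep(1:3, each = 21),
                        axis = rep(rep(1:3, each = 7), 3),
                        time = rep(1:7, 9))
  expect_identical(sort(cols), seq_len(nVariables(lay)))
  inv <- variableInfo(lay, cols)
  expect_identical(variableIndex(lay, inv$marker, inv$axis, inv$time), cols)
  # spot check against the full default layout
  full <- KinematicLayout()
  inv847 <- variableInfo(full, 847)
  expect_identical(unlist(inv847, use.names = FALSE), c(3L, 3L, 39L))
})

makeTrial <- function(subject, condition, trial, tp = 101, mk = 1, value = 0) {
  TrialRecord(subject, condition, trial,
              positions = array(value, dim = c(tp, mk, 3)))
}

test_that("assembly lays trials out row-wise with the documented layout", {
  # minimal single-trial layout: 1 marker x 3 axes x 101 points -> 303 columns
  ke <- assembleMatrix(list(makeTrial("s1", "a", 1),
                            makeTrial("s1", "b", 1)))
  expect_identical(dim(trialMatrix(ke)), c(2L, 303L))

  # a sentinel planted at (marker 2, axis y, time 5) must surface at
  # column 409, found by brute-force scan rather than the index map
  pos <- array(0, dim = c(101, 2, 3))
  pos[5, 2, 2] <- 42
  tr <- list(TrialRecord("s1", "a", 1, positions = pos),
             TrialRecord("s1", "b", 1, positions = array(0, dim = c(101, 2, 3))))
  row <- trialMatrix(assembleMatrix(tr))[1L, ]
  expect_identical(which(row == 42), 409L)

  # errors carry the offending key / empty input is rejected
  bad <- list(makeTrial("s1", "a", 1), makeTrial("s2", "b", 1, tp = 50))
  expect_error(assembleMatrix(bad), "subject=s2")
  expect_error(assembleMatrix(list()), "empty")
})

test_that("per-subject whitening matches the hand-computed sample-SD form", {
  # subject s1 has column values 1 and 3: mean 2, sample SD sqrt(2)
  vals <- rbind(c(1, 5), c(3, 9), c(0, 1), c(4, 3))
  ke <- toyExperiment(vals, subjects = c("s1", "s1", "s2", "s2"),
                      conditions = c("a", "b", "a", "b"))
  w <- whiten(ke)
  W <- trialMatrix(w)
  expect_equal(W[1:2, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  st <- subjectStats(w)
  expect_equal(unname(st$mean[1, "s1"]), 2)
  expect_equal(unname(st$sd[1, "s1"]), sqrt(2))
  # every subject block: mean 0 +- 1e-10, SD 1 +- 1e-8
  for (s in c("s1", "s2")) {
    blk <- W[c("s1", "s1", "s2", "s2") == s, ]
    expect_lt(max(abs(colMeans(blk))), 1e-10)
    expect_lt(max(abs(apply(blk, 2, sd) - 1)), 1e-8)
  }
  expect_error(whiten(w), "already whitened")
})

test_that("degenerate zero-variance variables error by default, zero on request", {
  vals <- rbind(c(1, 7), c(3, 7), c(0, 1), c(4, 3))   # col 2 constant for s1
  ke <- toyExperiment(vals, subjects = c("s1", "s1", "s2", "s2"),
                      conditions = c("a", "b", "a", "b"))
  expect_error(whiten(ke), "degenerate")
  w <- whiten(ke, degenerate = "zero")
  expect_identical(subjectStats(w)$degenerate, 2L)
  expect_equal(trialMatrix(w)[1:2, 2], c(0, 0))
})

test_that("whitening round-trips and is idempotent on standardized blocks", {
  sim <- whitenedSim(smallConfig(seed = 4))
  raw <- unwhiten(sim$ke)
  back <- trialMatrix(whiten(raw))
  expect_lt(max(abs(back - trialMatrix(sim$ke))), 1e-10)

  # de-whitening reproduces the assembled raw matrix
  trialsRaw <- trialMatrix(assembleMatrix(generateSynthetic(smallConfig(seed = 4))$trials))
  expect_lt(max(abs(trialMatrix(raw) - trialsRaw)), 1e-10)

  # re-whitening an already zero-mean unit-SD data set leaves it unchanged
  cd <- trialInfo(sim$ke)
  ke2 <- toyExperiment(trialMatrix(sim$ke), subjects = cd$subject,
                       conditions = cd$condition)
  expect_lt(max(abs(trialMatrix(whiten(ke2)) - trialMatrix(sim$ke))), 1e-10)
})

test_that("waveform extraction returns the documented contiguous blocks", {
  lay <- KinematicLayout()
  cols <- variableIndex(lay, 3, 3, seq_len(101))
  expect_identical(range(cols), c(809L, 909L))
  expect_identical(cols[39], 847L)
  expect_identical(range(variableIndex(lay, 1, 1, seq_len(101))), c(1L, 101L))

  # a ramp written into columns 405..505 comes back via (marker 2, axis 2)
  lay2 <- KinematicLayout(markers = 2)
  vals <- matrix(0, 2, nVariables(lay2))
  vals[1, 405:505] <- seq_len(101)
  ke <- kinematicExperiment(vals, subjects = c("s1", "s1"),
                            conditions = c("a", "b"), layout = lay2)
  wf <- extractWaveform(ke, marker = 2, axis = 2)
  expect_identical(dim(wf), c(2L, 101L))
  expect_equal(wf[1, ], as.numeric(seq_len(101)))
  expect_equal(wf[2, ], rep(0, 101))
  expect_error(extractWaveform(ke, marker = 3, axis = 1), "marker")

  byc <- extractWaveform(ke, 2, 2, byCondition = TRUE)
  expect_identical(byc$condition, c("a", "b"))
  expect_equal(byc$mean["a", ], as.numeric(seq_len(101)))
})
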