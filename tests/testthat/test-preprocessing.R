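test_that("stance detection follows the threshold-crossing definition", {
  expect_identical(unname(detectStance(c(0, 5, 20, 600, 400, 10, 0))),
                   c(3L, 5L))
  expect_error(detectStance(rep(0, 50)), "threshold")
  expect_warning(st <- detectStance(c(0, 100, 200, 0, 0, 300, 250, 0)),
                 "multiple")
  expect_identical(unname(st), c(2L, 3L))

  # half-sine footstrike vs an exhaustive frame-by-frame scan
  f <- 800 * sin(pi * seq(0, 1, length.out = 60))
  f <- c(rep(0, 10), f, rep(0, 10))
  st <- detectStance(f, 15)
  above <- which(f >= 15)
  expect_identical(unname(st), c(min(above), max(above)))
})

test_that("zero-phase Butterworth filtering matches its designed response", {
  fs <- 240
  t <- seq(0, 2, by = 1 / fs)
  # unit DC gain
  expect_lt(max(abs(lowpassFilter(rep(3.2, 400)) - 3.2)), 1e-9)

  # magnitude-response oracle: squared |H| of the per-pass design,
  # evaluated directly from the transfer-function coefficients
  bf <- signal::butter(2, 12 / (fs / 2), "low")
  gain <- function(fHz) {
    z <- exp(-1i * 2 * pi * fHz / fs * (seq_along(bf$b) - 1))
    h <- sum(bf$b * z) / sum(bf$a * z)
    Mod(h)^2                     # forward + backward pass
  }
  interior <- 150:330            # exclude edge effects
  for (fHz in c(1, 50)) {
    x <- sin(2 * pi * fHz * t)
    y <- lowpassFilter(x, cutoff = 12, order = 4, sampleRate = fs)
    amp <- max(abs(y[interior]))
    expect_equal(amp, gain(fHz), tolerance = 0.05)
    if (fHz == 1) expect_equal(amp, 1, tolerance = 0.01)   # passband
  }

  expect_error(lowpassFilter(t, cutoff = 130, sampleRate = fs), "Nyquist")
  expect_error(lowpassFilter(1:5, order = 4), "short")
  expect_error(lowpassFilter(t, order = 3), "even")
})

test_that("time normalization is endpoint-exact and line-exact", {
  seg <- cbind(seq(2, 8, length.out = 57), seq(-1, 5, length.out = 57))
  out <- timeNormalize(seg)
  expect_identical(nrow(out), 101L)
  # a line resampled at equidistant points is the same line
  expect_lt(max(abs(out[, 1] - seq(2, 8, length.out = 101))), 1e-9)

  x <- sin(seq(0, 3, length.out = 101))
  expect_lt(max(abs(timeNormalize(x) - x)), 1e-9)   # already 101 samples
  expect_error(timeNormalize(matrix(1, 1, 2)), "2 frames")
})

test_that("pelvis centering and height scaling behave geometrically", {
  set.seed(42)
  pos <- array(rnorm(101 * 3 * 3, sd = 0.2) + 0.8, dim = c(101, 3, 3))
  tr <- TrialRecord("s1", "a", 1, positions = pos)
  cen <- centerAndScale(tr, pelvisMarkers = 1:2, height = 1.8)

  # pelvis centroid at zero in both horizontal axes, every frame
  for (a in 1:2)
    expect_lt(max(abs(rowMeans(cen@positions[, 1:2, a]))), 1e-10)
  # floor at zero
  expect_equal(min(cen@positions[, , 3]), 0)
  # doubling height halves the output
  cen2 <- centerAndScale(tr, pelvisMarkers = 1:2, height = 3.6)
  expect_equal(cen2@positions, cen@positions / 2, tolerance = 1e-12)
  # rigid horizontal translation is invisible after per-frame centering
  shifted <- pos
  shifted[, , 1] <- shifted[, , 1] + 0.37
  shifted[, , 2] <- shifted[, , 2] - 1.12
  cen3 <- centerAndScale(TrialRecord("s1", "a", 1, positions = shifted),
                         pelvisMarkers = 1:2, height = 1.8)
  expect_lt(max(abs(cen3@positions - cen@positions)), 1e-10)
  expect_error(centerAndScale(tr, 1:2, height = 0), "height")
})

test_that("filtering plus resampling preserves band-limited signals", {
  # a < 6 Hz signal filtered at 12 Hz and resampled to 101 points must
  # match the analytic signal at the normalized time instants
  fs <- 240
  t <- seq(0, 0.6, by = 1 / fs)
  x <- 0.3 * sin(2 * pi * 2.5 * t) + 0.1 * cos(2 * pi * 5 * t + 0.4)
  y <- timeNormalize(lowpassFilter(x, sampleRate = fs))
  tn <- seq(min(t), max(t), length.out = 101)
  ref <- 0.3 * sin(2 * pi * 2.5 * tn) + 0.1 * cos(2 * pi * 5 * tn + 0.4)
  expect_lt(sqrt(mean((y - ref)^2)) / sqrt(mean(ref^2)), 0.02)
})

test_that("the raw-trial preprocessing chain recovers the planted movement", {
  # raw-mode synthetic trial: frame-rate trajectories + half-sine force
  sim <- generateSynthetic(smallConfig(seed = 6, trialNoiseSd = 0,
                                       subjectEffectSd = 0, timepoints = 101),
                           rawMode = TRUE)
  raw <- sim$trials[[1L]]
  expect_gt(length(raw@force), 0)
  out <- preprocessTrial(raw, height = 1, pelvisMarkers = 1)
  expect_identical(dim(out@positions), c(101L, 2L, 3L))

  # the same trial generated directly at 101 normalized points, centered
  # the same way, is the reference (base waveforms are ~2 Hz, far below
  # the 12 Hz cutoff; residual error stems from the resampling round trip)
  ref <- generateSynthetic(smallConfig(seed = 6, trialNoiseSd = 0,
                                       subjectEffectSd = 0, timepoints = 101))
  refc <- centerAndScale(ref$trials[[1L]], pelvisMarkers = 1, height = 1)
  err <- out@positions[, 2, ] - refc@positions[, 2, ]
  rms <- sqrt(mean(err^2)) / stats::sd(refc@positions[, 2, ])
  expect_lt(rms, 0.02)
})
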