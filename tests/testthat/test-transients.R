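test_that("normalization pins the reference frame at 1 and dff at norm - 1", {
  ts <- TraceSet(0:4, matrix(7, 5, 2))
  nt <- normalizeTrace(ts)
  expect_equal(normValues(nt), matrix(1, 5, 2, dimnames = dimnames(normValues(nt))))
  expect_equal(dffValues(nt), normValues(nt) - 1)

  F <- matrix(c(100, 150, 120, 100, 90), 5, 1)
  nt2 <- normalizeTrace(TraceSet(0:4, F))
  expect_equal(unname(normValues(nt2)[2, 1]), 1.5)
  expect_equal(unname(dffValues(nt2)[2, 1]), 0.5)
  expect_equal(unname(normValues(nt2)[1, ]), 1)
})

test_that("cells with non-positive reference intensity are excluded with a reason", {
  F <- cbind(good = c(10, 11, 12), bad = c(0, 5, 6))
  expect_warning(nt <- normalizeTrace(TraceSet(0:2, F)), "non-positive")
  expect_equal(cellIds(nt), "good")
  expect_named(excludedCells(nt), "bad")
})

test_that("the first derivative is the raw finite difference", {
  dff <- matrix(c(0, 0.5, 0.2), 3, 1)
  expect_equal(as.numeric(firstDerivative(dff)), c(0.5, -0.3))
  expect_equal(as.numeric(firstDerivative(matrix(1, 4, 1))), rep(0, 3))
  ramp <- matrix(0.25 * (0:9), 10, 1)
  expect_equal(as.numeric(firstDerivative(ramp)), rep(0.25, 9))
})

test_that("the threshold is quiet mean + k x population SD", {
  d <- matrix(c(-0.05, 0.05, -0.05, 0.05, 0), 5, 1,
              dimnames = list(NULL, "c1"))
  thr <- estimateThreshold(d, kSd = 2, quietFrames = 0:4)
  expect_equal(unname(thr["c1"]), 2 * sqrt(0.01 / 5), tolerance = 1e-12)
  expect_equal(unname(thr["c1"]), 0.0894, tolerance = 1e-3)

  zero <- matrix(0, 6, 1, dimnames = list(NULL, "c1"))
  expect_equal(unname(estimateThreshold(zero, quietFrames = 0:5)["c1"]), 0)

  expect_error(estimateThreshold(d, quietFrames = 0:2),
               "insufficient quiet frames")
})

test_that("zero quiet SD with signal elsewhere degrades to the mean with a warning", {
  d <- matrix(c(rep(0, 6), 1, 0, 0, 0), 10, 1, dimnames = list(NULL, "c1"))
  expect_warning(thr <- estimateThreshold(d, quietFrames = 0:5),
                 "zero quiet SD")
  expect_equal(unname(thr["c1"]), 0)
})

test_that("automatic quiet-region search converges to the explicit truth set", {
  set.seed(5)
  n <- 60
  dff <- c(rnorm(30, 0, 0.01), 0.8 * exp(-(0:29) / 2)) + rnorm(n, 0, 0.01)
  nt <- ntFromDff(matrix(dff, n, 1, dimnames = list(NULL, "c1")))
  d <- firstDerivative(nt)
  auto <- estimateThreshold(d, kSd = 2)
  quiet <- attr(auto, "quietFrames")$c1
  expect_false(29 %in% quiet)  # the spike's rise frame is excluded
  explicit <- estimateThreshold(d, kSd = 2, quietFrames = quiet)
  expect_equal(unname(auto["c1"]), unname(explicit["c1"]))
})

test_that("a hand-traced toy transient yields the documented onset, peak and amplitude", {
  dff <- matrix(c(0, 0, 0, 0.6, 1.0, 0.5, 0.2, 0, 0, 0), 10, 1,
                dimnames = list(NULL, "c1"))
  nt <- ntFromDff(dff)
  ev <- detectEvents(nt, threshold = 0.1, localBaselineWindow = 3)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_frame, 3L)
  expect_equal(ev$peak_frame, 4L)
  expect_equal(ev$amplitude, 1.0)
})

test_that("flat and noiseless traces produce no events at any positive k", {
  ts <- TraceSet(0:99, matrix(50, 100, 3))
  nt <- normalizeTrace(ts)
  d <- firstDerivative(nt)
  for (k in c(0.5, 1, 2, 4)) {
    thr <- stats::setNames(rep(0, 3), cellIds(nt))  # mean 0, sd 0
    expect_equal(nrow(detectEvents(nt, d, thr)), 0L)
  }
})

test_that("detected dff peak matches the true amplitude on clean simulations", {
  sim <- simulateSpiking(nCells = 1, epochRates = c(baseline = 1, ttx = 0),
                         noiseSd = 0, seed = 8)
  nt <- normalizeTrace(sim$traces)
  for (i in seq_len(nrow(sim$truth))) {
    fr <- sim$truth$frame[i]
    # dff at the rise frame = A * exp(-(t_frame - t0)/tau) plus decay tails
    # of earlier spikes; isolated spikes (no neighbour within 30 frames,
    # tail < 2e-7 of amplitude) must match the forward model
    prev <- sim$truth$frame[sim$truth$frame < fr]
    if (length(prev) == 0 || fr - max(prev) > 30) {
      got <- unname(dffValues(nt)[fr + 1, 1])
      expect_lt(abs(got - sim$truth$amplitude[i] *
                      exp(-(fr - sim$truth$time_s[i]) / 2)), 1e-6)
    }
  }
})

test_that("event counts rise monotonically with the simulated spike rate", {
  mean_counts <- vapply(c(0.5, 1, 2, 4), function(rate) {
    sim <- simulateSpiking(nCells = 10, seed = 41,
                           epochRates = c(baseline = rate, ttx = 0))
    r <- detectTransients(sim$traces, sim$plan)
    nrow(r$events) / 10
  }, numeric(1))
  expect_true(all(diff(mean_counts) > 0))
})

test_that("activity summaries count the 4-min window and assess abolition", {
  plan <- fluo4Plan()
  ev <- data.frame(cell_id = "c1", onset_frame = c(10L, 100L, 230L),
                   peak_frame = c(11L, 101L, 231L), amplitude = 0.5,
                   duration = 1L, threshold = 0.1)
  s <- summarizeActivity(ev, plan, dt = 1)
  expect_equal(s$spikes_per_4min, 3L)
  expect_true(s$abolished_ttx)

  ev2 <- rbind(ev, data.frame(cell_id = "c1", onset_frame = 300L,
                              peak_frame = 301L, amplitude = 0.4,
                              duration = 1L, threshold = 0.1))
  expect_false(summarizeActivity(ev2, plan, dt = 1)$abolished_ttx)
  expect_error(summarizeActivity(ev, plan, dt = 1, window = 500),
               "longer than")
})

test_that("amplitude binning yields exact proportions with overflow bins", {
  h <- binAmplitudes(c(0.2, 0.2, 0.8), c(0, 0.5, 1.0))
  expect_equal(h$proportion[h$bin == "[0,0.5)"], 2 / 3)
  expect_equal(h$proportion[h$bin == "[0.5,1)"], 1 / 3)
  expect_equal(sum(h$proportion), 1)

  single <- binAmplitudes(0.3, c(0, 0.5, 1.0))
  expect_equal(single$proportion[single$bin == "[0,0.5)"], 1)

  over <- binAmplitudes(c(0.2, 1.7, -0.1), c(0, 0.5, 1.0))
  expect_equal(over$proportion[over$bin == "overflow"], 1 / 3)
  expect_equal(over$proportion[over$bin == "underflow"], 1 / 3)
  expect_equal(sum(over$proportion), 1)

  expect_error(binAmplitudes(0.5, c(1, 0.5)), "strictly increasing")
})

test_that("per-condition proportions are computed within each condition", {
  h <- binAmplitudes(c(0.1, 0.6, 0.1, 0.1), c(0, 0.5, 1.0),
                     condition = c("young", "young", "old", "old"))
  for (g in c("young", "old"))
    expect_equal(sum(h$proportion[h$condition == g]), 1)
})

test_that("the intensity-statistic reading of the event criterion is available", {
  sim <- simulateSpiking(nCells = 5, seed = 13)
  r <- detectTransients(sim$traces, sim$plan, statistic = "intensity")
  expect_true(nrow(r$events) > 0)
  expect_true(all(c("events", "summary", "thresholds") %in% names(r)))
})

test_that("the vectorized detector agrees exactly with the brute-force oracle", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    nc <- sample(1:3, 1)
    dff <- matrix(rnorm(n * nc, 0, 0.05), n, nc)
    spikes <- sample(0:3, 1)
    for (s in seq_len(spikes)) {
      c <- sample(nc, 1); f <- sample(2:(n - 1), 1)
      dff[f:n, c] <- dff[f:n, c] + runif(1, 0.2, 1) * exp(-(0:(n - f)) / 2)
    }
    colnames(dff) <- paste0("cell_", seq_len(nc))
    nt <- ntFromDff(dff)
    d <- firstDerivative(nt)
    thr <- stats::setNames(runif(nc, 0.02, 0.2), colnames(dff))
    ms <- sample(1:3, 1)
    got <- detectEvents(nt, d, thr, minSeparation = ms)
    want <- bruteForceEvents(dffValues(nt), d, thr, minSeparation = ms)
    expect_equal(got, want)
  }
})
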