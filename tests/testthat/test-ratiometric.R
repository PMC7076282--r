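mkParams <- function(ids, kd = 225, sf = 2, rmin = 0.5, rmax = 5) {
  n <- length(ids)
  new("CalibrationParams", kd = stats::setNames(rep(kd, n), ids),
      sf = stats::setNames(rep(sf, n), ids),
      rmin = stats::setNames(rep(rmin, n), ids),
      rmax = stats::setNames(rep(rmax, n), ids),
      valid = stats::setNames(rep(TRUE, n), ids))
}

test_that("the 340/380 ratio is elementwise division with flagged bad frames", {
  rt <- RatioTraceSet(0:2 * 5, matrix(2, 3, 1), matrix(4, 3, 1))
  expect_equal(unname(computeRatio(rt)[, 1]), rep(0.5, 3))
  eq <- RatioTraceSet(0:2 * 5, matrix(7, 3, 2), matrix(7, 3, 2))
  expect_true(all(computeRatio(eq) == 1))
  suppressWarnings({
    bad <- RatioTraceSet(0:2 * 5, matrix(2, 3, 1),
                         matrix(c(4, 0, 4), 3, 1))
    expect_warning(R <- computeRatio(bad), "non-positive F380")
  })
  expect_true(is.na(R[2, 1]))
  expect_equal(attr(R, "flaggedFrames")[["cell_1"]], 1)
})

test_that("ratios from a zero-noise simulation match the forward model exactly", {
  sim <- simulateSOCE(nCells = 2, noiseSd = 0, seed = 4)
  R <- computeRatio(sim$traces)
  c <- sim$truth$conc[, 1]
  expected <- ifelse(is.infinite(c), 5, (c * 5 + 450 * 0.5) / (c + 450))
  expect_equal(unname(R[, 1]), expected, tolerance = 1e-12)
})

test_that("calibration recovers the true constants from clean recordings", {
  sim <- simulateSOCE(nCells = 5, noiseSd = 0, seed = 6)
  R <- computeRatio(sim$traces)
  cal <- estimateCalibration(R, sim$traces, sim$plan)
  expect_true(all(calibValid(cal)))
  expect_lt(max(abs(calibRmax(cal) - 5) / 5), 1e-9)
  expect_lt(max(abs(calibRmin(cal) - 0.5) / 0.5), 1e-9)
  expect_lt(max(abs(calibSf(cal) - 2) / 2), 1e-9)
  expect_equal(unname(calibKd(cal)), rep(225, 5))
})

test_that("calibration tolerates channel noise at SNR 50 within 5%", {
  # F380 bound-form intensity 100 a.u.; SNR 50 -> noise SD 2 a.u.
  sim <- simulateSOCE(nCells = 25, noiseSd = 2, seed = 9)
  R <- computeRatio(sim$traces)
  cal <- estimateCalibration(R, sim$traces, sim$plan)
  expect_true(all(calibValid(cal)))
  expect_true(all(abs(calibRmax(cal) - 5) / 5 < 0.05))
  expect_true(all(abs(calibRmin(cal) - 0.5) / 0.5 < 0.05))
  expect_true(all(abs(calibSf(cal) - 2) / 2 < 0.05))
})

test_that("a missing calibration epoch is a hard error", {
  sim <- simulateSOCE(nCells = 1, noiseSd = 0, seed = 1)
  plan <- epochPlan(c("basal", "tg", "caadd", "iono"),
                    c(0, 12, 96, 156), c(12, 96, 156, 180))
  R <- computeRatio(sim$traces)
  expect_error(estimateCalibration(R, sim$traces, plan),
               "epoch labelled 'egta'")
})

test_that("the Grynkiewicz conversion reproduces hand-computed values", {
  p <- mkParams("cell_1")
  expect_equal(unname(traceValues(grynkiewicz(
    matrix(0.5, 1, 1, dimnames = list(NULL, "cell_1")), p))[1, 1]), 0)
  expect_equal(unname(traceValues(grynkiewicz(
    matrix(1, 1, 1, dimnames = list(NULL, "cell_1")), p))[1, 1]), 56.25)
  # rmin = 0, sf = 1, R = rmax/2 -> conc = kd
  p0 <- mkParams("cell_1", sf = 1, rmin = 0, rmax = 5)
  expect_equal(unname(traceValues(grynkiewicz(
    matrix(2.5, 1, 1, dimnames = list(NULL, "cell_1")), p0))[1, 1]), 225)
})

test_that("the conversion is strictly increasing in R between Rmin and Rmax", {
  p <- mkParams("cell_1")
  r <- seq(0.51, 4.99, length.out = 200)
  conc <- traceValues(grynkiewicz(
    matrix(r, length(r), 1, dimnames = list(NULL, "cell_1")), p))[, 1]
  expect_true(all(diff(conc) > 0))
})

test_that("saturated and sub-Rmin frames are flagged, not silently converted", {
  p <- mkParams("cell_1")
  R <- matrix(c(0.2, 5, 6, 1), 4, 1, dimnames = list(NULL, "cell_1"))
  ct <- grynkiewicz(R, p)
  expect_equal(concFlags(ct)[, 1],
               c("below_rmin", "saturated_high", "saturated_high", "ok"))
  expect_equal(unname(traceValues(ct)[1, 1]), 0)
  expect_true(all(is.na(traceValues(ct)[2:3, 1])))
})

test_that("SOCE quantification recovers the programmed epoch amplitudes", {
  # constant concentration: basal equals it, both deltas 0
  flat <- new("CalciumConcTrace", times = 0:203 * 5,
              conc = matrix(26, 204, 1, dimnames = list(NULL, "c1")),
              flags = matrix("ok", 204, 1, dimnames = list(NULL, "c1")))
  s <- quantifySOCE(flat, socePlan())
  expect_equal(s$basal_nM, 26)
  expect_equal(s$store_release_delta_nM, 0)
  expect_equal(s$soce_delta_nM, 0)

  sim <- simulateSOCE(nCells = 3, noiseSd = 0, seed = 10)
  ana <- analyzeSOCE(sim$traces, sim$plan)
  expect_lt(max(abs(ana$summary$basal_nM - 50)), 1e-6)
  expect_lt(max(abs(ana$summary$store_release_delta_nM - 120)), 1e-6)
  expect_lt(max(abs(ana$summary$soce_delta_nM - 200)), 1e-6)
})

test_that("noisy SOCE recordings recover the deltas within 5% at the population level", {
  # per-cell estimates at SNR 50 carry peak-statistic noise of up to ~10%;
  # the population mean over 25 cells (how the study reports these
  # quantities) recovers the programmed values within 5%
  sim <- simulateSOCE(nCells = 25, noiseSd = 2, seed = 12)
  ana <- analyzeSOCE(sim$traces, sim$plan)
  s <- ana$summary
  expect_lt(abs(mean(s$basal_nM) - 50) / 50, 0.05)
  expect_lt(abs(mean(s$store_release_delta_nM) - 120) / 120, 0.05)
  expect_lt(abs(mean(s$soce_delta_nM) - 200) / 200, 0.05)
  expect_true(all(abs(s$basal_nM - 50) / 50 < 0.15))
  expect_true(all(abs(s$store_release_delta_nM - 120) / 120 < 0.15))
  expect_true(all(abs(s$soce_delta_nM - 200) / 200 < 0.15))
})

test_that("adding a constant shifts basal but leaves the deltas unchanged", {
  sim <- simulateSOCE(nCells = 2, noiseSd = 0, seed = 3)
  ana <- analyzeSOCE(sim$traces, sim$plan)
  ct <- ana$conc
  shifted <- new("CalciumConcTrace", times = ct@times,
                 conc = traceValues(ct) + 30, flags = concFlags(ct))
  a <- quantifySOCE(ct, sim$plan)
  b <- quantifySOCE(shifted, sim$plan)
  expect_equal(b$basal_nM, a$basal_nM + 30)
  expect_equal(b$store_release_delta_nM, a$store_release_delta_nM)
  expect_equal(b$soce_delta_nM, a$soce_delta_nM)
})

test_that("robust and plain epoch peaks are both available and ordered", {
  sim <- simulateSOCE(nCells = 5, noiseSd = 2, seed = 14)
  ana <- analyzeSOCE(sim$traces, sim$plan)
  plain <- quantifySOCE(ana$conc, sim$plan, robust = FALSE)
  rob <- quantifySOCE(ana$conc, sim$plan, robust = TRUE)
  # a median of the top-k frames can never exceed the plain maximum
  expect_true(all(rob$store_release_delta_nM <=
                  plain$store_release_delta_nM + 1e-12))
  expect_true(all(rob$soce_delta_nM <= plain$soce_delta_nM + 1e-12))
})

test_that("cells whose required epochs are entirely flagged are excluded with a reason", {
  conc <- matrix(50, 204, 1, dimnames = list(NULL, "c1"))
  flags <- matrix("ok", 204, 1, dimnames = list(NULL, "c1"))
  flags[epochFrames(socePlan(), "basal"), 1] <- "missing"
  ct <- new("CalciumConcTrace", times = 0:203 * 5, conc = conc, flags = flags)
  s <- quantifySOCE(ct, socePlan())
  expect_true(is.na(s$basal_nM))
  expect_match(s$flags, "excluded:all_frames_flagged_in_basal")
})
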