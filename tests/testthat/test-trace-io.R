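writeToy <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("wide trace tables are read with preserved cell order and uniform dt", {
  path <- writeToy(c("time_s\troiA\troiB", "0\t10\t20", "1\t11\t21",
                     "2\t12\t22"))
  ts <- readTraceTable(path)
  expect_s4_class(ts, "TraceSet")
  expect_equal(nFrames(ts), 3L)
  expect_equal(nCells(ts), 2L)
  expect_equal(frameInterval(ts), 1)
  expect_equal(cellIds(ts), c("roiA", "roiB"))
  expect_equal(traceValues(ts)[, "roiB"], c(20, 21, 22))
})

test_that("non-uniform sampling and non-numeric cells are hard errors with coordinates", {
  bad <- writeToy(c("time_s\troi1", "0\t1", "1\t2", "2.5\t3"))
  expect_error(readTraceTable(bad), "non-uniform sampling")
  nn <- writeToy(c("time_s\troi1\troi2", "0\t1\tx", "1\t2\t3"))
  expect_error(readTraceTable(nn), "row 1, column 'roi2'")
})

test_that("a 600-frame, 30-ROI recording at 1 s round-trips losslessly", {
  set.seed(11)
  F <- matrix(runif(600 * 30, 50, 200), 600, 30)
  ts <- TraceSet(0:599, F)
  expect_equal(nFrames(ts), 600L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraceTable(ts, path)
  back <- readTraceTable(path)
  expect_identical(traceValues(back), traceValues(ts))
  expect_identical(traceTimes(back), traceTimes(ts))
})

test_that("ratio tables require matching channels and flag non-positive F380", {
  a <- writeToy(c("time_s\tc1", paste(0:9 * 5, 1:10, sep = "\t")))
  b <- writeToy(c("time_s\tc1", paste(0:8 * 5, 1:9, sep = "\t")))
  expect_error(readRatioTable(a, b), "shape mismatch")
  bz <- writeToy(c("time_s\tc1", paste(0:9 * 5, c(0, 2:10), sep = "\t")))
  expect_warning(rt <- readRatioTable(a, bz), "non-positive F380")
  expect_equal(unname(traceMeta(rt)$f380_nonpositive["c1"]), 1L)
  expect_equal(nCells(rt), 1L)   # flagged, not dropped
})

test_that("a 204-frame two-channel recording reads as a RatioTraceSet", {
  t <- 0:203 * 5
  p340 <- writeToy(c("time_s\tc1\tc2", paste(t, 2, 3, sep = "\t")))
  p380 <- writeToy(c("time_s\tc1\tc2", paste(t, 4, 5, sep = "\t")))
  rt <- readRatioTable(p340, p380)
  expect_equal(nFrames(rt), 204L)
  expect_equal(frameInterval(rt), 5)
})

test_that("the long-format ratio reader reconstructs the grid", {
  df <- expand.grid(time_s = 0:3 * 5, cell_id = c("a", "b"),
                    stringsAsFactors = FALSE)
  df$f340 <- seq_len(nrow(df))
  df$f380 <- df$f340 + 10
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- readRatioTable(path)
  expect_equal(nCells(rt), 2L)
  expect_equal(unname(f340(rt)[2, "a"]),
               df$f340[df$time_s == 5 & df$cell_id == "a"])
})

test_that("result tables round-trip at full precision, including empty tables", {
  df <- data.frame(cell_id = c("a", "b"),
                   amplitude = c(1 / 3, exp(1) * 1e-7),
                   onset_frame = c(3L, 5L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeResultTable(df, path, kind = "events")
  back <- readResultTable(path)
  expect_identical(back$amplitude, df$amplitude)
  expect_identical(attr(back, "kind"), "events")

  empty <- df[0, ]
  writeResultTable(empty, path, kind = "events")
  expect_equal(nrow(readResultTable(path)), 0L)
  expect_equal(names(readResultTable(path)), names(df))
})

test_that("histogram proportions still sum to 1 after a write/read cycle", {
  h <- binAmplitudes(c(0.2, 0.2, 0.8, 1.4), c(0, 0.5, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeResultTable(h, path, kind = "amplitude_histogram")
  back <- readResultTable(path)
  expect_equal(sum(back$proportion), 1)
})
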