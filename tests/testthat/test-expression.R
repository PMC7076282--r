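test_that("relative expression follows the 2^-dCt law", {
  ct <- data.frame(gene = c("GAPDH", "TUBB3"), sample = "NSC",
                   replicate = 1L, ct = c(20, 20))
  r <- relativeExpression(ct)
  expect_equal(r$delta_ct, 0)
  expect_equal(r$rel_expr, 1)

  ct2 <- data.frame(gene = c("GAPDH", "SYN"), sample = "s",
                    replicate = 1L, ct = c(20, 25))
  r2 <- relativeExpression(ct2)
  expect_equal(r2$delta_ct, 5)
  expect_equal(r2$rel_expr, 2^-5)
  expect_identical(r2$rel_expr, 0.03125)
})

test_that("each added cycle of dCt exactly halves relative expression", {
  grid <- -3:10
  ct <- do.call(rbind, lapply(grid, function(d)
    data.frame(gene = c("GAPDH", paste0("g", d)), sample = paste0("s", d),
               replicate = 1L, ct = c(20, 20 + d))))
  r <- relativeExpression(ct)
  r <- r[order(r$delta_ct), ]
  expect_identical(r$rel_expr, 2^-sort(grid))
  expect_equal(r$rel_expr[-1] / r$rel_expr[-length(grid)],
               rep(0.5, length(grid) - 1))
  expect_equal(log2(r$rel_expr), -r$delta_ct)
  expect_true(all(r$rel_expr > 0))
})

test_that("replicates aggregate by mean and noisy triplicates are flagged", {
  ct <- data.frame(gene = rep(c("GAPDH", "g1"), each = 3),
                   sample = "s", replicate = rep(1:3, 2),
                   ct = c(20, 20.1, 19.9, 25.2, 25.0, 24.7))
  r <- relativeExpression(ct)
  expect_equal(r$delta_ct, mean(c(25.2, 25, 24.7)) - 20)
  expect_equal(r$flag, "")

  noisy <- data.frame(gene = rep(c("GAPDH", "g1"), each = 3),
                      sample = "s", replicate = rep(1:3, 2),
                      ct = c(20, 20, 20, 24, 25.5, 26))
  expect_warning(rn <- relativeExpression(noisy), "replicate SD")
  expect_equal(rn$flag, "high_replicate_sd")
})

test_that("a sample without the reference gene is an error", {
  ct <- data.frame(gene = "g1", sample = "s", replicate = 1L, ct = 25)
  expect_error(relativeExpression(ct), "reference gene 'GAPDH' missing")
})

test_that("DE classification uses inclusive log2FC and strict p/FDR cutoffs", {
  de <- data.frame(gene = paste0("g", 1:6),
                   log2fc = c(2.0, 1.5, 2.0, 1.49, -1.5, -2.0),
                   p = c(0.01, 0.01, 0.01, 0.01, 0.04, 0.06),
                   fdr = c(0.01, 0.01, 0.2, 0.01, 0.049, 0.01))
  lab <- classifyDE(de)$label
  expect_equal(lab, c("up", "up", "ns", "ns", "down", "ns"))
})

test_that("classification partitions genes and is monotone in the p cutoff", {
  set.seed(3)
  de <- data.frame(gene = paste0("g", 1:500),
                   log2fc = rnorm(500, 0, 2), p = runif(500),
                   fdr = runif(500))
  lab <- classifyDE(de)$label
  expect_true(all(lab %in% c("up", "down", "ns")))
  expect_equal(length(lab), 500L)
  called <- function(pMax) sum(classifyDE(de, pMax = pMax)$label != "ns")
  ps <- c(0.01, 0.05, 0.2, 1)
  expect_true(all(diff(vapply(ps, called, numeric(1))) >= 0))
})

test_that("overlap counts match brute-force set algebra and conserve totals", {
  a <- c(g1 = "up", g2 = "up", g3 = "ns")
  b <- c(g1 = "ns", g2 = "up", g3 = "up")
  ov <- overlapCounts(a, b)
  expect_equal(unname(ov[c("up_common", "up_only_a", "up_only_b")]),
               c(1L, 1L, 1L))
  expect_equal(sum(ov[c("down_common", "down_only_a", "down_only_b")]), 0L)

  identical_ov <- overlapCounts(a, a)
  expect_equal(unname(identical_ov[c("up_only_a", "up_only_b")]), c(0L, 0L))

  set.seed(8)
  genes <- paste0("g", 1:1000)
  la <- stats::setNames(sample(c("up", "down", "ns"), 1000, TRUE), genes)
  lb <- stats::setNames(sample(c("up", "down", "ns"), 1000, TRUE), genes)
  ov2 <- overlapCounts(la, lb)
  upA <- names(la)[la == "up"]; upB <- names(lb)[lb == "up"]
  dnA <- names(la)[la == "down"]; dnB <- names(lb)[lb == "down"]
  expect_equal(unname(ov2["up_common"]), length(intersect(upA, upB)))
  expect_equal(unname(ov2["up_only_a"]), length(setdiff(upA, upB)))
  expect_equal(unname(ov2["down_only_b"]), length(setdiff(dnB, dnA)))
  expect_equal(unname(ov2["up_common"] + ov2["up_only_a"]), length(upA))

  expect_error(overlapCounts(c(g1 = "up", g1 = "ns"), a), "duplicated")
  expect_error(overlapCounts(a, b[1:2]), "same gene universe")
})

test_that("panel z-scores are population z-scores per column", {
  lfc <- matrix(c(1, 2, 3), 3, 1,
                dimnames = list(c("STIM1", "ORAI1", "ITPR1"), "c1"))
  z <- panelZscoreMatrix(lfc, panel = rownames(lfc))
  expect_equal(unname(z[, 1]), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(z[, 1]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  # every column of a scored matrix has mean 0 and population SD 1
  set.seed(2)
  m <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:3)))
  z2 <- panelZscoreMatrix(m, panel = rownames(m))
  for (j in 1:3) {
    expect_lt(abs(mean(z2[, j])), 1e-12)
    expect_lt(abs(sqrt(mean((z2[, j] - mean(z2[, j]))^2)) - 1), 1e-12)
  }
})

test_that("constant columns, missing panel genes and clipping are handled explicitly", {
  lfc <- matrix(5, 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  expect_warning(z <- panelZscoreMatrix(lfc, panel = rownames(lfc)),
                 "zero SD")
  expect_true(all(z == 0))

  # both the missing-gene and the zero-SD warnings fire here
  w <- capture_warnings(
    panelZscoreMatrix(lfc, panel = c(rownames(lfc), "ABSENT")))
  expect_match(w, "absent from the matrix", all = FALSE)
  expect_match(w, "zero SD", all = FALSE)

  m <- matrix(c(-10, 0, 10), 3, 1, dimnames = list(paste0("g", 1:3), "c1"))
  zc <- panelZscoreMatrix(m, panel = rownames(m), clip = 1)
  expect_true(all(abs(zc) <= 1))
})

test_that("the bundled calcium panel holds 109 unique genes", {
  panel <- calciumPanelGenes()
  expect_length(panel, 109L)
  expect_false(anyDuplicated(panel) > 0)
  expect_true(all(c("STIM1", "ORAI1", "ITPR1", "ATP2A2") %in% panel))
})

test_that("marker positivity reproduces the study's truncated two-decimal arithmetic", {
  expect_identical(markerPositivePercentage(91, 283), 32.15)
  expect_identical(markerPositivePercentage(0, 10), 0)
  expect_identical(markerPositivePercentage(10, 10), 100)
  expect_error(markerPositivePercentage(5, 0), "positive integer")
  expect_error(markerPositivePercentage(11, 10), "cannot exceed")
})
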