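#' Relative expression by the delta-Ct method (2^-dCt)
#'
#' For every (gene, sample), technical-replicate Ct values are aggregated
#' (mean by default), the reference gene's aggregated Ct in the same sample
#' is subtracted (dCt = Ct_gene - Ct_ref), and relative expression is
#' 2^-dCt. Each +1 cycle of dCt halves the relative expression. Gene/sample
#' pairs whose replicate SD exceeds \code{replicateSdWarn} cycles are flagged
#' \code{high_replicate_sd}.
#'
#' @param ct long-format data frame with columns \code{gene, sample,
#'   replicate, ct} (cycles; finite, typically 0-40).
#' @param referenceGene endogenous control gene (default \code{"GAPDH"});
#'   must be measured in every sample.
#' @param aggregate replicate aggregation, \code{"mean"} (convention) or
#'   \code{"median"}.
#' @param replicateSdWarn replicate-SD warning level, cycles.
#' @return data frame: \code{gene, sample, n_replicates, delta_ct, rel_expr,
#'   flag} (reference gene rows excluded).
#' @examples
#' ct <- data.frame(gene = c("GAPDH", "STIM1"), sample = "NSC",
#'                  replicate = 1, ct = c(20, 25))
#' relativeExpression(ct)$rel_expr   # 2^-5 = 0.03125
#' @export
relativeExpression <- function(ct, referenceGene = "GAPDH",
                               aggregate = c("mean", "median"),
                               replicateSdWarn = 0.5) {
  aggregate <- match.arg(aggregate)
  need <- c("gene", "sample", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns gene, sample, ct (and optionally replicate)",
         call. = FALSE)
  if (!all(is.finite(ct$ct))) stop("all Ct values must be finite",
                                   call. = FALSE)
  agg <- if (aggregate == "mean") mean else stats::median
  out <- list()
  for (s in unique(ct$sample)) {
    sub <- ct[ct$sample == s, , drop = FALSE]
    refCt <- sub$ct[sub$gene == referenceGene]
    if (!length(refCt))
      stop(sprintf("reference gene '%s' missing for sample '%s'",
                   referenceGene, s), call. = FALSE)
    ref <- agg(refCt)
    for (g in setdiff(unique(sub$gene), referenceGene)) {
      x <- sub$ct[sub$gene == g]
      dct <- agg(x) - ref
      flag <- if (length(x) > 1L && stats::sd(x) > replicateSdWarn)
        "high_replicate_sd" else ""
      out <- c(out, list(data.frame(
        gene = g, sample = s, n_replicates = length(x), delta_ct = dct,
        rel_expr = 2^(-dct), flag = flag, stringsAsFactors = FALSE)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$flag == "high_replicate_sd"))
    warning(sprintf("replicate SD > %g cycles for %d gene/sample pair(s)",
                    replicateSdWarn, sum(res$flag == "high_replicate_sd")),
            call. = FALSE)
  res
}

#' Classify genes from a differential-expression table
#'
#' Applies the study's thresholds: a gene is \code{up} if its log2 fold
#' change is at least \code{upLfc} (boundary inclusive: "+1.5 and greater")
#' with p-value and FDR strictly below their cutoffs; \code{down} if the
#' log2FC is at most \code{downLfc} under the same significance conditions;
#' otherwise \code{ns}. Every gene receives exactly one label.
#'
#' @param de data frame with columns \code{gene, log2fc, p, fdr}.
#' @param upLfc,downLfc inclusive log2FC bounds (defaults +1.5 / -1.5).
#' @param pMax,fdrMax strict significance cutoffs (defaults 0.05).
#' @return the input with a \code{label} column (\code{up/down/ns}) appended.
#' @examples
#' classifyDE(data.frame(gene = "g", log2fc = 1.5, p = 0.01, fdr = 0.01))
#' @export
classifyDE <- function(de, upLfc = 1.5, downLfc = -1.5, pMax = 0.05,
                       fdrMax = 0.05) {
  need <- c("gene", "log2fc", "p", "fdr")
  if (!all(need %in% names(de)))
    stop("DE table needs columns gene, log2fc, p, fdr", call. = FALSE)
  if (any(de$p < 0 | de$p > 1 | de$fdr < 0 | de$fdr > 1, na.rm = TRUE))
    stop("p and fdr must be in [0, 1]", call. = FALSE)
  sig <- de$p < pMax & de$fdr < fdrMax
  de$label <- ifelse(sig & de$log2fc >= upLfc, "up",
                     ifelse(sig & de$log2fc <= downLfc, "down", "ns"))
  de
}

#' Overlap counts of up/down gene sets between two contrasts
#'
#' Set-algebra counts of the genes called up (resp. down) in two contrasts
#' over the same gene universe: common, only in A, only in B.
#'
#' @param labelsA,labelsB outputs of [classifyDE()] (data frames with
#'   \code{gene} and \code{label}), or named character vectors of labels.
#' @return named integer vector: \code{up_common, up_only_a, up_only_b,
#'   down_common, down_only_a, down_only_b}.
#' @export
overlapCounts <- function(labelsA, labelsB) {
  asNamed <- function(x, which) {
    if (is.data.frame(x)) x <- stats::setNames(x$label, x$gene)
    if (anyDuplicated(names(x)))
      stop(sprintf("duplicated gene ids in contrast %s", which),
           call. = FALSE)
    x
  }
  a <- asNamed(labelsA, "A")
  b <- asNamed(labelsB, "B")
  if (!setequal(names(a), names(b)))
    stop("contrasts must share the same gene universe", call. = FALSE)
  cnt <- function(la, lb, lab) {
    sa <- names(la)[la == lab]
    sb <- names(lb)[lb == lab]
    c(common = length(intersect(sa, sb)),
      only_a = length(setdiff(sa, sb)),
      only_b = length(setdiff(sb, sa)))
  }
  up <- cnt(a, b, "up")
  dn <- cnt(a, b, "down")
  c(up_common = up[["common"]], up_only_a = up[["only_a"]],
    up_only_b = up[["only_b"]], down_common = dn[["common"]],
    down_only_a = dn[["only_a"]], down_only_b = dn[["only_b"]])
}

#' Column z-score matrix for a gene-panel heatmap
#'
#' Restricts a genes x contrasts log2FC matrix to a gene panel and z-scores
#' every column over the panel genes: z = (x - column mean) / column SD,
#' population (divide-by-n) SD. Panel genes absent from the matrix are
#' reported with a warning, never silently dropped. A zero-SD column becomes
#' zeros with a warning. An optional symmetric clip (e.g. \code{clip = 1} for
#' a -1..+1 display range) is applied after scoring; clipping is a display
#' choice, off by default.
#'
#' @param lfc numeric matrix, rownames = genes, one column per contrast.
#' @param panel character vector of panel gene ids (default: the bundled
#'   109-gene neuronal calcium-signalling panel, [calciumPanelGenes()]).
#' @param clip optional positive number: clamp z to \code{[-clip, clip]}.
#' @return numeric matrix (panel genes found) x contrasts of z-scores, with
#'   missing panel genes in attribute \code{"missingGenes"}.
#' @export
panelZscoreMatrix <- function(lfc, panel = calciumPanelGenes(), clip = NULL) {
  lfc <- as.matrix(lfc)
  if (is.null(rownames(lfc))) stop("lfc must have gene rownames",
                                   call. = FALSE)
  missing <- setdiff(panel, rownames(lfc))
  if (length(missing))
    warning(sprintf("%d panel gene(s) absent from the matrix: %s",
                    length(missing),
                    paste(utils::head(missing, 10), collapse = ", ")),
            call. = FALSE)
  found <- intersect(panel, rownames(lfc))
  if (!length(found)) stop("no panel genes found in the matrix",
                           call. = FALSE)
  x <- lfc[found, , drop = FALSE]
  z <- x
  for (j in seq_len(ncol(x))) {
    s <- popSd(x[, j])
    if (is.na(s) || s == 0) {
      warning(sprintf("column %s has zero SD; z-scores set to 0",
                      colnames(x)[j] %||% j), call. = FALSE)
      z[, j] <- 0
    } else {
      z[, j] <- (x[, j] - mean(x[, j])) / s
    }
  }
  if (!is.null(clip)) {
    assertScalar(clip, "clip", lower = 1e-12)
    z <- pmin(pmax(z, -clip), clip)
  }
  attr(z, "missingGenes") <- missing
  z
}

#' Marker-positive cell percentage
#'
#' Percentage of positively stained cells among all counted cells, truncated
#' (not rounded) to two decimals, matching the study's reporting convention
#' for count-based percentages (e.g. 91 of 283 Ki-67-positive cells =
#' 32.15\%).
#'
#' @param positive number of positive cells (0 <= positive <= total).
#' @param total total number of cells counted (> 0).
#' @return percentage, two-decimal precision.
#' @examples
#' markerPositivePercentage(91, 283)   # 32.15
#' @export
markerPositivePercentage <- function(positive, total) {
  total <- assertCount(total, "total")
  positive <- assertCount(positive, "positive", positive = FALSE)
  if (positive > total) stop("'positive' cannot exceed 'total'",
                             call. = FALSE)
  floor(100 * positive / total * 100 + 1e-9) / 100
}

#' The bundled neuronal calcium-signalling gene panel
#'
#' A 109-gene panel of neuronal calcium-signalling genes (voltage-gated
#' channel subunits, SOCE machinery, IP3 and ryanodine receptors, SERCA and
#' plasma-membrane pumps, exchangers, buffers, calmodulins and CaM kinases,
#' calcium-regulated effectors) used for the differential-expression heatmap.
#' The membership ships as an editable one-gene-per-line text fixture and is
#' a replaceable convention, not a canonical list: pass your own file to use
#' a different panel.
#'
#' @param file path to a one-gene-per-line text file (\code{#} comments
#'   allowed); default the bundled panel.
#' @return character vector of gene symbols.
#' @export
calciumPanelGenes <- function(file = NULL) {
  file <- file %||% system.file("extdata", "calcium_panel_109.txt",
                                package = "neurocal", mustWork = TRUE)
  x <- readLines(file)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
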