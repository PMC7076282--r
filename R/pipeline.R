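#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate (both imaging modalities) -> transient detection ->
#' SOCE quantification -> qPCR relative expression -> DE threshold filtering,
#' writing every result as a schema-tagged table plus a manifest
#' (configuration echo, seed, package version, output checksums). A fixed
#' seed makes every artifact byte-identical across runs. On a hard error,
#' a \code{_FAILED} marker naming the error is left in the output directory
#' so partial outputs are never mistaken for results.
#'
#' The configuration is a YAML file or an equivalent named list with optional
#' sections \code{spiking}, \code{soce}, \code{detect}, \code{qpcr},
#' \code{de} (unknown top-level keys are rejected):
#' \itemize{
#'   \item \code{spiking}: arguments of [simulateSpiking()] (snake_case keys
#'     \code{n_cells, noise_sd, ...}).
#'   \item \code{soce}: arguments of [simulateSOCE()].
#'   \item \code{detect}: \code{k_sd}, \code{window_s},
#'     \code{abolition_fraction}.
#'   \item \code{qpcr}: \code{ct_table} path (default: bundled synthetic
#'     example), \code{reference_gene}.
#'   \item \code{de}: \code{table_a}, \code{table_b} paths (defaults:
#'     bundled synthetic examples), thresholds.
#' }
#'
#' @param config YAML path or named list; NULL for all defaults.
#' @param outDir output directory (created; default a fresh temporary one).
#' @param seed integer master seed (overrides the config's).
#' @return invisibly, a list with the written file paths and the in-memory
#'   results (\code{events}, \code{activity}, \code{soce}, \code{qpcr},
#'   \code{de_labels}, \code{overlap}, \code{zscore}).
#' @export
runPipeline <- function(config = NULL, outDir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config)
         else config %||% list()
  known <- c("seed", "outdir", "spiking", "soce", "detect", "qpcr", "de")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  seed <- seed %||% cfg$seed %||% 1L
  outDir <- outDir %||% cfg$outdir %||% tempfile("neurocal_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(outDir, "_FAILED")
  if (file.exists(marker)) unlink(marker)
  paths <- character(0)
  res <- list()
  tryCatch({
    ## spontaneous-transient arm
    sp <- cfg$spiking %||% list()
    sim <- simulateSpiking(
      nCells = sp$n_cells %||% 30, dt = sp$dt %||% 1,
      epochRates = unlist(sp$epoch_rates %||% list(baseline = 3, ttx = 0)),
      amplitudeMedian = sp$amplitude_median %||% 0.5,
      amplitudeSdLog = sp$amplitude_sdlog %||% 0.5,
      decayTau = sp$decay_tau %||% 2, noiseSd = sp$noise_sd %||% 0.02,
      seed = seed)
    paths["traces"] <- file.path(outDir, "fluo4_traces.tsv")
    writeTraceTable(sim$traces, paths["traces"])
    paths["truth"] <- file.path(outDir, "fluo4_truth.tsv")
    writeResultTable(sim$truth, paths["truth"], kind = "spike_truth")
    paths["plan"] <- file.path(outDir, "fluo4_plan.yaml")
    writeEpochPlan(sim$plan, paths["plan"], dt = sp$dt %||% 1)

    det <- cfg$detect %||% list()
    da <- detectTransients(sim$traces, sim$plan, kSd = det$k_sd %||% 2,
                           window = det$window_s %||% 240,
                           abolitionFraction = det$abolition_fraction %||% 0)
    paths["events"] <- file.path(outDir, "events.tsv")
    writeResultTable(da$events, paths["events"], kind = "events")
    paths["activity"] <- file.path(outDir, "activity_summary.tsv")
    writeResultTable(da$summary, paths["activity"], kind = "activity_summary")
    res$events <- da$events
    res$activity <- da$summary

    ## SOCE arm
    so <- cfg$soce %||% list()
    soceSim <- simulateSOCE(
      nCells = so$n_cells %||% 25, dt = so$dt %||% 5,
      basalCa = so$basal_ca %||% 50,
      storeReleaseDelta = so$store_release_delta %||% 120,
      soceDelta = so$soce_delta %||% 200, kd = so$kd %||% 225,
      sf = so$sf %||% 2, rmin = so$rmin %||% 0.5, rmax = so$rmax %||% 5,
      noiseSd = so$noise_sd %||% 0, seed = seed)
    ana <- analyzeSOCE(soceSim$traces, soceSim$plan, kd = so$kd %||% 225)
    paths["soce"] <- file.path(outDir, "soce_summary.tsv")
    writeResultTable(ana$summary, paths["soce"], kind = "soce_summary")
    concDf <- cbind(time_s = traceTimes(ana$conc),
                    as.data.frame(traceValues(ana$conc)))
    paths["conc"] <- file.path(outDir, "calcium_conc_nM.tsv")
    writeResultTable(concDf, paths["conc"], kind = "conc_trace")
    res$soce <- ana$summary

    ## expression arm
    qp <- cfg$qpcr %||% list()
    ctPath <- qp$ct_table %||% system.file("extdata",
                                           "example_ct_synthetic.tsv",
                                           package = "neurocal",
                                           mustWork = TRUE)
    rel <- relativeExpression(readResultTable(ctPath),
                              referenceGene = qp$reference_gene %||% "GAPDH")
    paths["qpcr"] <- file.path(outDir, "relative_expression.tsv")
    writeResultTable(rel, paths["qpcr"], kind = "relative_expression")
    res$qpcr <- rel

    de <- cfg$de %||% list()
    pa <- de$table_a %||% system.file("extdata",
                                      "example_de_45div_synthetic.tsv",
                                      package = "neurocal", mustWork = TRUE)
    pb <- de$table_b %||% system.file("extdata",
                                      "example_de_60div_synthetic.tsv",
                                      package = "neurocal", mustWork = TRUE)
    la <- classifyDE(readResultTable(pa), upLfc = de$up_lfc %||% 1.5,
                     downLfc = de$down_lfc %||% -1.5,
                     pMax = de$p_max %||% 0.05, fdrMax = de$fdr_max %||% 0.05)
    lb <- classifyDE(readResultTable(pb), upLfc = de$up_lfc %||% 1.5,
                     downLfc = de$down_lfc %||% -1.5,
                     pMax = de$p_max %||% 0.05, fdrMax = de$fdr_max %||% 0.05)
    ov <- overlapCounts(la, lb)
    paths["de_a"] <- file.path(outDir, "de_labels_a.tsv")
    writeResultTable(la, paths["de_a"], kind = "de_labels")
    paths["de_b"] <- file.path(outDir, "de_labels_b.tsv")
    writeResultTable(lb, paths["de_b"], kind = "de_labels")
    paths["overlap"] <- file.path(outDir, "de_overlap.tsv")
    writeResultTable(data.frame(set = names(ov), count = as.integer(ov)),
                     paths["overlap"], kind = "de_overlap")
    res$de_labels <- list(a = la, b = lb)
    res$overlap <- ov

    lfc <- cbind(a = stats::setNames(la$log2fc, la$gene),
                 b = stats::setNames(lb$log2fc, lb$gene))
    z <- suppressWarnings(panelZscoreMatrix(lfc))
    paths["zscore"] <- file.path(outDir, "panel_zscores.tsv")
    writeResultTable(cbind(gene = rownames(z),
                           as.data.frame(z, stringsAsFactors = FALSE)),
                     paths["zscore"], kind = "panel_zscores")
    res$zscore <- z

    ## manifest
    manifest <- list(
      package = "neurocal",
      version = as.character(utils::packageVersion("neurocal")),
      seed = seed,
      config = cfg,
      outputs = lapply(stats::setNames(as.list(paths), names(paths)),
                       function(p) list(file = basename(p),
                                        md5 = unname(tools::md5sum(p)))))
    paths["manifest"] <- file.path(outDir, "manifest.yaml")
    yaml::write_yaml(manifest, paths["manifest"])
  }, error = function(e) {
    writeLines(conditionMessage(e), marker)
    stop(e)
  })
  invisible(c(list(paths = paths, outDir = outDir), res))
}
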