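## Orchestration: configuration, deterministic end-to-end runs, the
## cohort baseline table, and a consolidated machine-readable report.

#' Published cohort baseline summaries and peptidome counts
#'
#' `cohortBaseline()` returns the published per-group means, SDs and
#' sample sizes of the 48-participant cohort's demographics, complete
#' blood counts and physical-function scores (inputs for
#' [baselineTable()]; published p-values are not stored -- they are
#' recomputed). `proteomeCounts()` returns the published peptide and
#' protein counts of the detected EV peptidome and its annotated and
#' differential subsets.
#'
#' @return data.frame read from the package's `extdata`.
#' @export
cohortBaseline <- function() {
    utils::read.delim(system.file("extdata", "cohort_baseline.tsv",
                                  package = "evlongevity"),
                      stringsAsFactors = FALSE)
}

#' @rdname cohortBaseline
#' @export
proteomeCounts <- function() {
    utils::read.delim(system.file("extdata", "ev_proteome_counts.tsv",
                                  package = "evlongevity"),
                      stringsAsFactors = FALSE)
}

#' Percentage share of a peptidome subset
#'
#' @param nSubset,nTotal Peptide counts.
#' @return `100 * nSubset / nTotal`.
#' @export
peptideShare <- function(nSubset, nTotal) {
    if (nTotal <= 0) stop("total peptide count must be positive")
    100 * nSubset / nTotal
}

#' Group-comparison table from per-group summary statistics
#'
#' One [tTestSummary()] per row of a baseline table (variable, group
#' means, SDs, ns), flagged significant at `p < alpha`. Because the
#' inputs are typically rounded published summaries, recomputed
#' p-values match published ones only to rounding accuracy.
#'
#' @param baseline data.frame with columns `variable`, `mean_short`,
#'   `sd_short`, `n_short`, `mean_long`, `sd_long`, `n_long`.
#' @param alpha Significance level (default 0.05).
#' @param pooled Pooled-variance t (default) or Welch.
#' @return The table with `t`, `df`, `p` and `significant` appended.
#' @export
baselineTable <- function(baseline = cohortBaseline(), alpha = 0.05,
                          pooled = TRUE) {
    need <- c("variable", "mean_short", "sd_short", "n_short",
              "mean_long", "sd_long", "n_long")
    if (!all(need %in% colnames(baseline)))
        stop("baseline table needs columns: ", paste(need, collapse = ", "))
    res <- lapply(seq_len(nrow(baseline)), function(i) {
        r <- baseline[i, ]
        tTestSummary(r$mean_long, r$sd_long, r$n_long,
                     r$mean_short, r$sd_short, r$n_short, pooled = pooled)
    })
    baseline$t <- vapply(res, `[[`, numeric(1), "statistic")
    baseline$df <- vapply(res, `[[`, numeric(1), "df")
    baseline$p <- vapply(res, `[[`, numeric(1), "p_value")
    baseline$significant <- baseline$p < alpha
    baseline
}

#' Pipeline configuration
#'
#' All thresholds and stage settings in one place; every source of
#' randomness flows from the single root `seed`.
#'
#' @param seed Root integer seed.
#' @param qLevel BH FDR level for the differential tracks (default
#'   0.01).
#' @param markerAlpha Raw significance level for marker tests and
#'   correlations (default 0.05).
#' @param modes Encoding modes to fit.
#' @param cv A [cvControl()] list (its seed is derived from the root
#'   seed).
#' @param synthetic A [syntheticConfig()] for cohort simulation, or
#'   `NULL` with `inputDir` to read a bundle from disk.
#' @param inputDir Directory with a cohort bundle ([readCohort()]
#'   layout); used when `synthetic` is `NULL`.
#' @param baseline Optional baseline summary table for
#'   [baselineTable()].
#' @return List of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, qLevel = 0.01, markerAlpha = 0.05,
                           modes = c("complete_continuous",
                                     "missing_binary", "all_zero_imputed"),
                           cv = cvControl(), synthetic = NULL,
                           inputDir = NULL, baseline = NULL) {
    if (any(c(qLevel, markerAlpha) <= 0) || any(c(qLevel, markerAlpha) >= 1))
        stop("significance levels must lie in (0, 1)")
    if (is.null(synthetic) && is.null(inputDir))
        synthetic <- syntheticConfig(seed = .deriveSeed(seed, 11L))
    structure(list(seed = as.integer(seed), qLevel = qLevel,
                   markerAlpha = markerAlpha, modes = modes, cv = cv,
                   synthetic = synthetic, inputDir = inputDir,
                   baseline = baseline),
              class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> volumetric normalization -> missingness
#' stratification -> dual-track differential -> rollup -> predictive
#' models for every requested encoding -> peptide-to-region mapping ->
#' marker comparisons and correlations -> consolidated report. Every
#' stage's table is written to `outDir`, the run is a pure function of
#' (config, seed), and `report.json` records seeds and per-stage record
#' counts.
#'
#' @param config A [pipelineConfig()].
#' @param outDir Output directory.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile()) {
    if (!inherits(config, "PipelineConfig"))
        stop("use pipelineConfig()")
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
        stop("stage 'setup' failed: cannot create ", outDir)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    cohort <- stage("ingest", {
        if (!is.null(config$inputDir)) readCohort(config$inputDir)
        else generateCohort(config$synthetic)
    })
    pe <- stage("normalize", toVolumetric(cohort$experiment))
    writePeptideTable(pe, file.path(outDir, "volumetric.tsv"),
                      file.path(outDir, "samples.tsv"))

    diff <- stage("differential", differentialAnalysis(pe, config$qLevel))
    utils::write.table(diff$profile, file.path(outDir, "missingness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    combined <- rbind(diff$quantitative[, 1:7], diff$missingness[, 1:7])
    protMap <- stats::setNames(
        SummarizedExperiment::rowData(pe)$protein, rownames(pe))
    combined$protein <- unname(protMap[combined$peptide_id])
    utils::write.table(combined, file.path(outDir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rollup <- stage("rollup", rollupCounts(combined, protMap))
    utils::write.table(rollup, file.path(outDir, "rollup.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    split <- stage("split", splitCohort(pe, seed = .deriveSeed(config$seed,
                                                               21L)))
    cvCfg <- config$cv
    cvCfg$seed <- .deriveSeed(config$seed, 22L)
    models <- list()
    for (mode in config$modes) {
        fitRes <- stage(paste0("predict:", mode),
                        runEncodingModel(pe, split, mode, cvCfg))
        models[[mode]] <- fitRes
        jsonlite::write_json(
            list(mode = mode, cv_config = cvCfg,
                 selected_peptides = as.list(fitRes$selected),
                 weights = as.list(fitRes$model@weights),
                 cv_auc = fitRes$cv_auc, holdout_auc = fitRes$holdout_auc,
                 holdout_scores = as.list(fitRes$scores)),
            file.path(outDir, paste0("model_", mode, ".json")),
            auto_unbox = TRUE, digits = NA)
    }

    rd <- as.data.frame(SummarizedExperiment::rowData(pe))
    hits <- data.frame(peptide_id = rownames(pe), protein = rd$protein,
                       sequence = rd$sequence, stringsAsFactors = FALSE)
    dirMap <- stats::setNames(combined$direction, combined$peptide_id)
    hits$direction <- unname(dirMap[hits$peptide_id])
    hits <- hits[!is.na(hits$direction) & hits$direction != "none", ]
    mapped <- stage("pepmap", mapPeptides(hits, cohort$proteins,
                                          cohort$regions))
    utils::write.table(mapped, file.path(outDir, "pepmap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    regionSummary <- stage("pepmap", summarizeRegions(mapped))
    utils::write.table(regionSummary, file.path(outDir,
                                                "region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    markerTests <- stage("markers",
                         compareMarkers(cohort$markers, pe,
                                        alpha = config$markerAlpha))
    utils::write.table(markerTests, file.path(outDir, "marker_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    markerCor <- stage("markers",
                       correlateMarkersPeptides(cohort$markers, pe, diff,
                                                alpha = config$markerAlpha))
    utils::write.table(markerCor$correlations,
                       file.path(outDir, "marker_peptide_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(markerCor$counts,
                       file.path(outDir, "marker_correlation_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    baseline <- if (!is.null(config$baseline))
        stage("baseline", baselineTable(config$baseline))
    if (!is.null(baseline))
        utils::write.table(baseline, file.path(outDir, "baseline.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

    report <- list(
        seed = config$seed, q_level = config$qLevel,
        marker_alpha = config$markerAlpha,
        n_samples = ncol(pe), n_peptides = nrow(pe),
        n_proteins = length(unique(protMap)),
        n_complete = length(diff$strata$complete),
        n_incomplete = length(diff$strata$incomplete),
        n_rejected_quantitative = sum(diff$quantitative$reject),
        n_rejected_missingness = sum(diff$missingness$reject),
        rollup = rollup,
        split_composition = as.data.frame(split$composition),
        models = lapply(models, function(m)
            list(cv_auc = m$cv_auc, holdout_auc = m$holdout_auc,
                 n_selected = length(m$selected))),
        n_significant_marker_cells = sum(markerTests$significant),
        n_mapped_rows = nrow(mapped))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(cohort = cohort, experiment = pe, differential = diff,
                   rollup = rollup, split = split, models = models,
                   mapped = mapped, region_summary = regionSummary,
                   marker_tests = markerTests, marker_cor = markerCor,
                   baseline = baseline, report = report, out_dir = outDir))
}
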