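## Dual-track differential analysis. Fully observed peptides are
## compared on their quantitative values (Wilcoxon rank-sum); partially
## observed peptides on their per-group missing rates (Pearson
## chi-squared on the 2x2 missing/observed x group table). BH FDR is
## controlled at `qLevel` separately within each track, mirroring the
## design's two separate FDR statements; joint adjustment is available
## behind `family = "joint"` on the combined runner.

.direction <- function(rejected, higher) {
    ifelse(!rejected, "none",
           ifelse(higher > 0, "higher_in_long",
                  ifelse(higher < 0, "lower_in_long", "none")))
}

#' Quantitative differential track (fully observed peptides)
#'
#' One two-sided [rankSumTest()] per peptide comparing long- versus
#' short-lived samples, BH-adjusted across exactly this family.
#' Direction for rejected peptides is the sign of
#' (long median - short median).
#'
#' @param pe A [PeptideExperiment-class].
#' @param completeIds Peptides with no missing values (the
#'   [stratifyPeptides()] `complete` set); a missing value among them
#'   is an error, enforcing the stratification contract.
#' @param qLevel BH FDR level (default 0.01).
#' @return data.frame: peptide_id, track, statistic, p, q, reject,
#'   direction, median_long, median_short.
#' @export
quantTrack <- function(pe, completeIds, qLevel = 0.01) {
    q <- quantities(pe)[completeIds, , drop = FALSE]
    if (anyNA(q))
        stop("stratification contract violated: quantitative track ",
             "received peptides with missing values")
    long <- sampleGroups(pe) == "long_lived"
    stat <- p <- medL <- medS <- numeric(nrow(q))
    for (i in seq_len(nrow(q))) {
        tr <- rankSumTest(q[i, long], q[i, !long])
        stat[i] <- tr$statistic; p[i] <- tr$p_value
        medL[i] <- stats::median(q[i, long])
        medS[i] <- stats::median(q[i, !long])
    }
    adj <- bhAdjust(p, qLevel)
    data.frame(peptide_id = completeIds, track = "quantitative",
               statistic = stat, p = p, q = adj$q_values,
               reject = adj$reject,
               direction = .direction(adj$reject, sign(medL - medS)),
               median_long = medL, median_short = medS,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Missingness differential track (partially observed peptides)
#'
#' One [chi2TwoByTwo()] per peptide on the missing/observed x group
#' table, BH-adjusted across this family only. A lower missing rate in
#' the long-lived group means higher abundance there, so direction is
#' `higher_in_long` when `missing_rate_long < missing_rate_short`.
#' Peptides with a degenerate table (observed everywhere or missing
#' everywhere within the analysed samples) are excluded and reported in
#' the `"excluded"` attribute rather than patched with pseudo-counts.
#'
#' @param pe A [PeptideExperiment-class].
#' @param incompleteIds Peptides with at least one missing value.
#' @param qLevel BH FDR level (default 0.01).
#' @return data.frame as in [quantTrack()] but with evidence columns
#'   missing_rate_long / missing_rate_short; excluded peptides in
#'   `attr(, "excluded")`.
#' @export
missingTrack <- function(pe, incompleteIds, qLevel = 0.01) {
    mm <- missingMask(pe)[incompleteIds, , drop = FALSE]
    if (any(rowSums(mm) == 0))
        stop("stratification contract violated: missingness track ",
             "received fully observed peptides")
    long <- sampleGroups(pe) == "long_lived"
    nL <- sum(long); nS <- sum(!long)
    missL <- rowSums(mm[, long, drop = FALSE])
    missS <- rowSums(mm[, !long, drop = FALSE])
    degenerate <- (missL + missS == 0) | (missL + missS == nL + nS)
    excluded <- data.frame(
        peptide_id = incompleteIds[degenerate],
        reason = ifelse(missL[degenerate] + missS[degenerate] == 0,
                        "observed in every sample", "missing in every sample"),
        stringsAsFactors = FALSE)
    keep <- which(!degenerate)
    stat <- p <- numeric(length(keep))
    for (j in seq_along(keep)) {
        i <- keep[j]
        tr <- chi2TwoByTwo(missL[i], missS[i], nL - missL[i], nS - missS[i])
        stat[j] <- tr$statistic; p[j] <- tr$p_value
    }
    adj <- bhAdjust(p, qLevel)
    rateL <- missL[keep] / nL; rateS <- missS[keep] / nS
    out <- data.frame(peptide_id = incompleteIds[keep], track = "missingness",
                      statistic = stat, p = p, q = adj$q_values,
                      reject = adj$reject,
                      direction = .direction(adj$reject, sign(rateS - rateL)),
                      missing_rate_long = rateL, missing_rate_short = rateS,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "excluded") <- excluded
    if (nrow(excluded))
        message(nrow(excluded),
                " peptide(s) excluded from the missingness track ",
                "(degenerate 2x2 table)")
    out
}

#' Run both differential tracks
#'
#' Stratifies the peptidome and runs [quantTrack()] and
#' [missingTrack()]. With `family = "separate"` (default) BH is applied
#' within each track; `family = "joint"` adjusts both tracks' p-values
#' as one family.
#'
#' @param pe A [PeptideExperiment-class].
#' @param qLevel BH FDR level.
#' @param family `"separate"` or `"joint"` BH families.
#' @return List with `quantitative`, `missingness` (data.frames),
#'   `profile` and `strata`.
#' @export
differentialAnalysis <- function(pe, qLevel = 0.01,
                                 family = c("separate", "joint")) {
    family <- match.arg(family)
    profile <- missingnessProfile(pe)
    strata <- stratifyPeptides(profile)
    qt <- quantTrack(pe, strata$complete, qLevel)
    mt <- missingTrack(pe, strata$incomplete, qLevel)
    if (family == "joint") {
        adj <- bhAdjust(c(qt$p, mt$p), qLevel)
        nq <- nrow(qt)
        qt$q <- adj$q_values[seq_len(nq)]
        qt$reject <- adj$reject[seq_len(nq)]
        qt$direction <- .direction(qt$reject,
                                   sign(qt$median_long - qt$median_short))
        mt$q <- adj$q_values[-seq_len(nq)]
        mt$reject <- adj$reject[-seq_len(nq)]
        mt$direction <- .direction(mt$reject,
                                   sign(mt$missing_rate_short -
                                        mt$missing_rate_long))
    }
    list(quantitative = qt, missingness = mt, profile = profile,
         strata = strata)
}

#' Roll rejected peptides up to category and distinct-protein counts
#'
#' Counts rejected peptides and their distinct parent proteins in the
#' four categories: quantitative higher/lower abundance in long-lived,
#' and missingness-track higher abundance (lower missing rate) / lower
#' abundance (higher missing rate) in long-lived. A protein
#' contributing to several categories is counted once per category.
#'
#' @param results data.frame combining both tracks (rbind of the track
#'   outputs, evidence columns optional).
#' @param proteinMap Named character vector, peptide id -> protein
#'   symbol; every rejected peptide must be mapped.
#' @return data.frame: track, direction, n_peptides,
#'   n_distinct_proteins.
#' @export
rollupCounts <- function(results, proteinMap) {
    hits <- results[results$reject, c("peptide_id", "track", "direction")]
    if (nrow(hits) && any(!hits$peptide_id %in% names(proteinMap)))
        stop("unmapped rejected peptide(s): ",
             paste(setdiff(hits$peptide_id, names(proteinMap))[1:5],
                   collapse = ", "))
    grid <- expand.grid(track = c("quantitative", "missingness"),
                        direction = c("higher_in_long", "lower_in_long"),
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$track, decreasing = TRUE), ]
    cnt <- function(tr, dir) {
        ids <- hits$peptide_id[hits$track == tr & hits$direction == dir]
        c(n_peptides = length(ids),
          n_distinct_proteins = length(unique(proteinMap[ids])))
    }
    counts <- t(mapply(cnt, grid$track, grid$direction))
    out <- cbind(grid, as.data.frame(counts))
    rownames(out) <- NULL
    out
}
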