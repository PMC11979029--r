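## EV surface-marker statistics: per-marker, per-size-class group
## comparisons (Mann-Whitney at raw p < 0.05, as in the flow-cytometry
## analysis -- no multiplicity adjustment by default, unlike the
## FDR-controlled proteomic tracks) and Spearman screening of marker
## percentages against longevity-associated peptide abundances.

#' Compare marker percentages between survival groups
#'
#' One two-sided [rankSumTest()] per (marker, size class), flagged
#' significant at raw `p < alpha` (default 0.05); direction from group
#' medians. `adjust = TRUE` optionally applies BH across the grid.
#' Marker cells with all-missing percentages are skipped with a
#' message.
#'
#' @param markers Long marker table: sample_id, marker, size_class,
#'   percentage.
#' @param annotation data.frame with sample_id and group, or a
#'   [PeptideExperiment-class].
#' @param alpha Raw significance level.
#' @param adjust Apply BH across all (marker, size class) tests.
#' @return data.frame: marker, size_class, statistic, p, median_long,
#'   median_short, direction, significant.
#' @export
compareMarkers <- function(markers, annotation, alpha = 0.05,
                           adjust = FALSE) {
    if (is(annotation, "PeptideExperiment"))
        annotation <- data.frame(sample_id = colnames(annotation),
                                 group = sampleGroups(annotation),
                                 stringsAsFactors = FALSE)
    grp <- stats::setNames(as.character(annotation$group),
                           annotation$sample_id)
    if (any(!markers$sample_id %in% names(grp)))
        stop("marker table contains unannotated samples")
    cells <- unique(markers[, c("marker", "size_class")])
    cells <- cells[order(cells$marker, cells$size_class), ]
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
        sub <- markers[markers$marker == cells$marker[i] &
                       markers$size_class == cells$size_class[i], ]
        ok <- is.finite(sub$percentage)
        if (!any(ok)) {
            message("skipping all-missing marker cell: ", cells$marker[i],
                    "/", cells$size_class[i])
            next
        }
        sub <- sub[ok, ]
        long <- grp[sub$sample_id] == "long_lived"
        tr <- rankSumTest(sub$percentage[long], sub$percentage[!long])
        medL <- stats::median(sub$percentage[long])
        medS <- stats::median(sub$percentage[!long])
        rows[[i]] <- data.frame(
            marker = cells$marker[i], size_class = cells$size_class[i],
            statistic = tr$statistic, p = tr$p_value,
            median_long = medL, median_short = medS,
            direction = if (medL > medS) "higher_in_long"
                        else if (medL < medS) "lower_in_long" else "none",
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no testable marker cells")
    out$significant <- if (adjust) bhAdjust(out$p, alpha)$reject
                       else out$p < alpha
    rownames(out) <- NULL
    out
}

#' Correlate marker percentages with longevity-associated peptides
#'
#' [spearmanCorr()] of each (marker, size class) percentage against the
#' quantitative expression of each longevity-associated peptide
#' (rejected on either differential track), over pairwise-complete
#' samples; pairs with fewer than `minPairs` observations are skipped.
#' A correlation is counted as significant-positive when `p < alpha`
#' and `rho > 0`.
#'
#' @param markers Long marker table.
#' @param pe Volumetric [PeptideExperiment-class].
#' @param differential Combined differential results (rbind of the two
#'   tracks, or a [differentialAnalysis()] result).
#' @param alpha Raw significance level (default 0.05).
#' @param minPairs Minimum pairwise-complete observations (default 3).
#' @return List: `correlations` (marker, size_class, peptide_id, track,
#'   rho, p, n, significant_positive) and `counts`
#'   (significant-positive peptides per marker cell, with per-track
#'   breakdown).
#' @export
correlateMarkersPeptides <- function(markers, pe, differential,
                                     alpha = 0.05, minPairs = 3L) {
    if (is.list(differential) && !is.data.frame(differential) &&
        all(c("quantitative", "missingness") %in% names(differential))) {
        keep <- c("peptide_id", "track", "reject")
        differential <- rbind(differential$quantitative[, keep],
                              differential$missingness[, keep])
    }
    assoc <- differential[differential$reject, c("peptide_id", "track")]
    q <- quantities(pe)
    cells <- unique(markers[, c("marker", "size_class")])
    cells <- cells[order(cells$marker, cells$size_class), ]
    rows <- list(); ri <- 0L
    for (i in seq_len(nrow(cells))) {
        sub <- markers[markers$marker == cells$marker[i] &
                       markers$size_class == cells$size_class[i], ]
        pct <- stats::setNames(sub$percentage, sub$sample_id)
        for (j in seq_len(nrow(assoc))) {
            pep <- assoc$peptide_id[j]
            x <- pct[colnames(q)]
            y <- q[pep, ]
            ok <- is.finite(x) & is.finite(y)
            if (sum(ok) < minPairs) next
            if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
            sc <- spearmanCorr(x[ok], y[ok])
            ri <- ri + 1L
            rows[[ri]] <- data.frame(
                marker = cells$marker[i], size_class = cells$size_class[i],
                peptide_id = pep, track = assoc$track[j],
                rho = sc$rho, p = sc$p_value, n = sc$n,
                significant_positive = sc$p_value < alpha & sc$rho > 0,
                stringsAsFactors = FALSE)
        }
    }
    cor <- if (ri) do.call(rbind, rows)
           else data.frame(marker = character(), size_class = character(),
                           peptide_id = character(), track = character(),
                           rho = numeric(), p = numeric(), n = integer(),
                           significant_positive = logical())
    rownames(cor) <- NULL
    counts <- merge(cells, .sigCounts(cor), by = c("marker", "size_class"),
                    all.x = TRUE)
    counts[is.na(counts)] <- 0L
    counts <- counts[order(counts$marker, counts$size_class), ]
    rownames(counts) <- NULL
    list(correlations = cor, counts = counts)
}

.sigCounts <- function(cor) {
    if (nrow(cor) == 0L)
        return(data.frame(marker = character(), size_class = character(),
                          n_significant_positive = integer(),
                          n_quantitative = integer(),
                          n_missingness = integer()))
    sig <- cor[cor$significant_positive, ]
    tot <- stats::aggregate(list(n_significant_positive = sig$peptide_id),
                            by = sig[, c("marker", "size_class")],
                            FUN = length)
    byTrack <- function(tr, nm) {
        s <- sig[sig$track == tr, ]
        if (nrow(s) == 0L)
            return(stats::setNames(
                data.frame(marker = character(), size_class = character(),
                           n = integer()), c("marker", "size_class", nm)))
        stats::setNames(
            stats::aggregate(list(n = s$peptide_id),
                             by = s[, c("marker", "size_class")],
                             FUN = length),
            c("marker", "size_class", nm))
    }
    out <- merge(tot, byTrack("quantitative", "n_quantitative"),
                 by = c("marker", "size_class"), all = TRUE)
    out <- merge(out, byTrack("missingness", "n_missingness"),
                 by = c("marker", "size_class"), all = TRUE)
    out[is.na(out)] <- 0L
    out
}
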