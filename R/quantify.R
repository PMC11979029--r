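#' @describeIn toVolumetric Divide each sample's per-ug quantities by
#'   that sample's `volume_for_20ug` (ul yielding 20 ug EV protein) and
#'   multiply by 2, accounting for the twofold urea dilution of the
#'   plasma-derived EVs. Missing entries stay missing. Converting an
#'   already-volumetric table is an error (idempotence guard).
#' @export
setMethod("toVolumetric", "PeptideExperiment", function(x) {
    if (quantBasis(x) == "volumetric")
        stop("table is already on the volumetric basis")
    vol <- SummarizedExperiment::colData(x)$volume_for_20ug
    if (is.null(vol))
        stop("colData(x)$volume_for_20ug is required for the conversion")
    if (any(!is.finite(vol)) || any(vol <= 0))
        stop("volume_for_20ug must be positive")
    q <- quantities(x)
    SummarizedExperiment::assay(x, "quant") <-
        sweep(q, 2L, vol, "/") * 2
    S4Vectors::metadata(x)$basis <- "volumetric"
    validObject(x)
    x
})

#' Scalar volumetric conversion
#'
#' `value / volume_for_20ug * 2`: converts a per-ug peptide quantity to
#' a per-ul-plasma quantity given the ul of plasma-equivalent that
#' yielded 20 ug of EV protein (the factor 2 undoes the twofold urea
#' dilution).
#'
#' @param value Non-negative per-ug quantity (NA passes through).
#' @param volumeFor20ug Positive volume in ul.
#' @return The per-ul quantity.
#' @examples
#' volumetricValue(10, 5)  # 4
#' @export
volumetricValue <- function(value, volumeFor20ug) {
    if (any(!is.finite(volumeFor20ug)) || any(volumeFor20ug <= 0))
        stop("volumeFor20ug must be positive")
    if (any(value < 0, na.rm = TRUE))
        stop("quantities must be non-negative")
    value / volumeFor20ug * 2
}

#' Per-peptide, per-group missingness profile
#'
#' Missing rate = missing count / group size, computed separately for
#' the long-lived and short-lived groups.
#'
#' @param pe A [PeptideExperiment-class]; every sample must carry a
#'   group label.
#' @return data.frame with one row per peptide: observed/missing counts
#'   and missing rates per group.
#' @export
missingnessProfile <- function(pe) {
    g <- sampleGroups(pe)
    if (anyNA(g)) stop("every sample must be annotated with a group")
    mm <- missingMask(pe)
    long <- g == "long_lived"
    nL <- sum(long); nS <- sum(!long)
    if (nL == 0L || nS == 0L) stop("both groups must be non-empty")
    missL <- rowSums(mm[, long, drop = FALSE])
    missS <- rowSums(mm[, !long, drop = FALSE])
    data.frame(peptide_id = rownames(pe),
               n_missing_long = missL, n_observed_long = nL - missL,
               n_missing_short = missS, n_observed_short = nS - missS,
               missing_rate_long = missL / nL,
               missing_rate_short = missS / nS,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratify peptides by missingness status
#'
#' Peptides with missing rate > 0% in either group are excluded from
#' quantitative expression analysis and handled on the missingness
#' track instead; the two sets partition the peptidome.
#'
#' @param profile A [missingnessProfile()] result.
#' @return List with character vectors `complete` (missing rate exactly
#'   0 in both groups) and `incomplete` (all others).
#' @export
stratifyPeptides <- function(profile) {
    complete <- profile$missing_rate_long == 0 &
        profile$missing_rate_short == 0
    list(complete = profile$peptide_id[complete],
         incomplete = profile$peptide_id[!complete])
}
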