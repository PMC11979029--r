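#' PeptideExperiment: sample-annotated peptide quantity matrix
#'
#' The pipeline's central container: a [SummarizedExperiment] whose
#' single `"quant"` assay holds the peptide x sample quantity matrix of
#' a label-free quantification run, with `NA` marking peptides not
#' detected in a sample. Undetected is not the same as zero: an
#' observed quantity of exactly 0 stays observed. `colData` carries the
#' sample annotation (group label, per-sample `volume_for_20ug` in ul,
#' optional demographics); `rowData` carries per-peptide annotation
#' (parent protein symbol, peptide sequence, modification flag). The
#' quantity basis (`"gravimetric"` per-ug or `"volumetric"` per-ul) is
#' tracked in `metadata(x)$basis`.
#'
#' @slot . Inherits all slots from [SummarizedExperiment].
#'
#' @seealso [PeptideExperiment()] (constructor), [toVolumetric()],
#'   [missingnessProfile()], [stratifyPeptides()].
#' @aliases PeptideExperiment-class
#' @exportClass PeptideExperiment
setClass("PeptideExperiment", contains = "SummarizedExperiment")

.GROUP_LEVELS <- c("short_lived", "long_lived")

setValidity("PeptideExperiment", function(object) {
    msg <- character()
    if (!("quant" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'quant' is required")
    basis <- S4Vectors::metadata(object)$basis
    if (is.null(basis) || !basis %in% c("gravimetric", "volumetric"))
        msg <- c(msg, "metadata(x)$basis must be 'gravimetric' or 'volumetric'")
    cd <- SummarizedExperiment::colData(object)
    if (!("group" %in% colnames(cd))) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else {
        g <- cd$group
        if (!is.factor(g) || !identical(levels(g), .GROUP_LEVELS))
            msg <- c(msg, sprintf("'group' must be a factor with levels %s",
                                  paste(.GROUP_LEVELS, collapse = ", ")))
    }
    if ("volume_for_20ug" %in% colnames(cd)) {
        v <- cd$volume_for_20ug
        if (any(!is.finite(v)) || any(v <= 0))
            msg <- c(msg, "volume_for_20ug must be positive and finite")
    }
    if ("quant" %in% SummarizedExperiment::assayNames(object)) {
        q <- SummarizedExperiment::assay(object, "quant")
        if (any(q < 0, na.rm = TRUE))
            msg <- c(msg, "observed quantities must be non-negative")
        if (is.null(rownames(q)) || is.null(colnames(q)))
            msg <- c(msg, "quant matrix must have peptide rownames and sample colnames")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PeptideExperiment
#'
#' @param quant Numeric peptide x sample matrix; `NA` = not detected.
#'   Rownames are peptide ids (`SYMBOL__<n>[ox]` convention), colnames
#'   are sample ids.
#' @param sampleData `data.frame` (or DataFrame) of per-sample
#'   annotation, one row per column of `quant`, containing at least
#'   `group` (`"long_lived"` / `"short_lived"`); usually also
#'   `volume_for_20ug` (ul of plasma-equivalent that yielded 20 ug EV
#'   protein) and demographics.
#' @param peptideData Optional `data.frame` of per-peptide annotation
#'   (e.g. `protein`, `sequence`, `modified`), one row per row of
#'   `quant`.
#' @param basis `"gravimetric"` (default) or `"volumetric"`.
#' @return A [PeptideExperiment-class] object.
#' @examples
#' q <- matrix(c(1, 2, NA, 4, 5, 6), nrow = 3,
#'             dimnames = list(paste0("P1__", 1:3), c("s1", "s2")))
#' ann <- data.frame(group = c("long_lived", "short_lived"),
#'                   volume_for_20ug = c(5, 5), row.names = c("s1", "s2"))
#' pe <- PeptideExperiment(q, ann)
#' missingMask(pe)["P1__3", ]
#' @export
PeptideExperiment <- function(quant, sampleData, peptideData = NULL,
                              basis = "gravimetric") {
    quant <- as.matrix(quant)
    storage.mode(quant) <- "double"
    sampleData <- as.data.frame(sampleData)
    if (nrow(sampleData) != ncol(quant))
        stop("sampleData must have one row per sample column of 'quant'")
    if (is.null(rownames(sampleData)) ||
        identical(rownames(sampleData), as.character(seq_len(nrow(sampleData))))) {
        if ("sample_id" %in% colnames(sampleData))
            rownames(sampleData) <- sampleData$sample_id
        else
            rownames(sampleData) <- colnames(quant)
    }
    sampleData <- sampleData[colnames(quant), , drop = FALSE]
    sampleData$group <- factor(as.character(sampleData$group),
                               levels = .GROUP_LEVELS)
    if (anyNA(sampleData$group))
        stop("every sample must be annotated as 'long_lived' or 'short_lived'")
    rd <- if (is.null(peptideData)) {
        S4Vectors::DataFrame(row.names = rownames(quant))
    } else {
        peptideData <- as.data.frame(peptideData)
        if (nrow(peptideData) != nrow(quant))
            stop("peptideData must have one row per peptide row of 'quant'")
        rownames(peptideData) <- rownames(quant)
        S4Vectors::DataFrame(peptideData)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(quant = quant),
        colData = S4Vectors::DataFrame(sampleData),
        rowData = rd)
    S4Vectors::metadata(se)$basis <- basis
    new("PeptideExperiment", se)
}

#' @rdname quantBasis
#' @export
setMethod("quantBasis", "PeptideExperiment", function(x)
    S4Vectors::metadata(x)$basis)

#' @rdname missingMask
#' @export
setMethod("missingMask", "PeptideExperiment", function(x)
    is.na(SummarizedExperiment::assay(x, "quant")))

#' @rdname quantities
#' @export
setMethod("quantities", "PeptideExperiment", function(x)
    SummarizedExperiment::assay(x, "quant"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "PeptideExperiment", function(x)
    SummarizedExperiment::colData(x)$group)

setMethod("show", "PeptideExperiment", function(object) {
    g <- table(sampleGroups(object))
    cat("PeptideExperiment:", nrow(object), "peptides x", ncol(object),
        "samples\n")
    cat("  basis:", quantBasis(object), "\n")
    cat("  groups:", paste(sprintf("%s=%d", names(g), g), collapse = ", "),
        "\n")
    mm <- missingMask(object)
    cat(sprintf("  missing entries: %.1f%%; fully observed peptides: %d\n",
                100 * mean(mm), sum(rowSums(mm) == 0)))
})
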