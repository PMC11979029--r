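## Plain-text readers and writers for every pipeline interface file.
## Quantities are written with 17 significant digits so numeric tables
## round-trip losslessly through write/read.

.fmtNum <- function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- ""
    out
}

#' Write a peptide table and its sample annotation to TSV
#'
#' `peptides.tsv` is wide: one row per sample, first column
#' `sample_id`, one column per peptide id, empty cell = missing.
#' `samples.tsv` holds the sample annotation.
#'
#' @param pe A [PeptideExperiment-class].
#' @param peptidesFile,samplesFile Output paths.
#' @return Invisibly, the two paths.
#' @export
writePeptideTable <- function(pe, peptidesFile, samplesFile) {
    q <- t(quantities(pe))  # samples x peptides
    df <- data.frame(sample_id = rownames(q),
                     apply(q, 2, .fmtNum),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, peptidesFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ann <- as.data.frame(SummarizedExperiment::colData(pe))
    ann <- cbind(sample_id = rownames(ann),
                 ann[setdiff(colnames(ann), "sample_id")])
    utils::write.table(ann, samplesFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(peptidesFile, samplesFile))
}

#' Read a peptide table written by [writePeptideTable()]
#'
#' @param peptidesFile,samplesFile Input paths.
#' @param peptideInfoFile Optional `peptide_info.tsv` path restoring
#'   per-peptide annotation (protein, sequence, modification flag).
#' @param basis Quantity basis of the stored table.
#' @return A [PeptideExperiment-class].
#' @export
readPeptideTable <- function(peptidesFile, samplesFile,
                             peptideInfoFile = NULL,
                             basis = "gravimetric") {
    wide <- utils::read.delim(peptidesFile, check.names = FALSE,
                              na.strings = "", stringsAsFactors = FALSE)
    if (colnames(wide)[1L] != "sample_id")
        stop("malformed peptide table: first column must be sample_id; got '",
             colnames(wide)[1L], "' in ", peptidesFile)
    quant <- t(as.matrix(wide[, -1L, drop = FALSE]))
    colnames(quant) <- wide$sample_id
    ann <- utils::read.delim(samplesFile, stringsAsFactors = FALSE)
    rownames(ann) <- ann$sample_id
    info <- NULL
    if (!is.null(peptideInfoFile)) {
        info <- utils::read.delim(peptideInfoFile, stringsAsFactors = FALSE)
        rownames(info) <- info$peptide_id
        info <- info[rownames(quant),
                     setdiff(colnames(info), "peptide_id"), drop = FALSE]
    }
    PeptideExperiment(quant, ann, peptideData = info, basis = basis)
}

#' Read/write a long-format surface-marker table
#'
#' Columns: `sample_id`, `marker`, `size_class` (LEV/MEV/SEV),
#' `percentage` in \[0, 100\].
#'
#' @param markers Marker data.frame.
#' @param file Path.
#' @return `readMarkerTable` returns the data.frame.
#' @export
writeMarkerTable <- function(markers, file) {
    out <- markers
    out$percentage <- .fmtNum(out$percentage)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeMarkerTable
#' @export
readMarkerTable <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("sample_id", "marker", "size_class", "percentage")
    if (!all(need %in% colnames(df)))
        stop("marker table must have columns ",
             paste(need, collapse = ", "), ": ", file)
    df$percentage <- as.numeric(df$percentage)
    if (any(df$percentage < 0 | df$percentage > 100, na.rm = TRUE))
        stop("marker percentages must lie in [0, 100]: ", file)
    df
}

#' Read/write a region annotation set as JSON
#'
#' The file declares its coordinate convention explicitly
#' (`"1-based inclusive"`) to avoid BED-style half-open confusion.
#' Regions (chains, fragments, anaphylatoxins) may nest.
#'
#' @param regions Named list, one entry per protein symbol:
#'   `list(length =, regions = data.frame(name, kind, start, end))`.
#' @param file Path.
#' @return `readRegionSet` returns the named list.
#' @export
writeRegionSet <- function(regions, file) {
    payload <- list(coordinates = "1-based inclusive",
                    proteins = lapply(regions, function(p)
                        list(length = p$length, regions = p$regions)))
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(file)
}

#' @rdname writeRegionSet
#' @export
readRegionSet <- function(file) {
    payload <- jsonlite::read_json(file, simplifyVector = TRUE,
                                   simplifyDataFrame = TRUE)
    if (!identical(payload$coordinates, "1-based inclusive"))
        stop("region file must declare coordinates '1-based inclusive': ",
             file)
    out <- lapply(payload$proteins, function(p) {
        rg <- as.data.frame(p$regions)
        rg$start <- as.integer(rg$start); rg$end <- as.integer(rg$end)
        len <- as.integer(p$length)
        if (any(rg$start < 1L) || any(rg$end > len) || any(rg$start > rg$end))
            stop("region coordinates must satisfy 1 <= start <= end <= length")
        list(length = len, regions = rg)
    })
    out
}

#' Write a full synthetic cohort bundle to a directory
#'
#' Emits `peptides.tsv`, `samples.tsv`, `peptide_info.tsv`,
#' `markers.tsv`, `truth.json`, `proteins.fasta` and `regions.json` in
#' the formats consumed by the pipeline readers; the bundle round-trips
#' losslessly through [readCohort()].
#'
#' @param cohort A [generateCohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    pe <- cohort$experiment
    writePeptideTable(pe, file.path(dir, "peptides.tsv"),
                      file.path(dir, "samples.tsv"))
    info <- as.data.frame(SummarizedExperiment::rowData(pe))
    info <- cbind(peptide_id = rownames(info), info)
    utils::write.table(info, file.path(dir, "peptide_info.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeMarkerTable(cohort$markers, file.path(dir, "markers.tsv"))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    Biostrings::writeXStringSet(cohort$proteins,
                                file.path(dir, "proteins.fasta"))
    writeRegionSet(cohort$regions, file.path(dir, "regions.json"))
    invisible(dir)
}

#' Read a cohort bundle written by [writeCohort()]
#'
#' @param dir Directory containing the bundle.
#' @param basis Quantity basis of the stored peptide table.
#' @return List with `experiment`, `markers`, `truth`, `proteins`,
#'   `regions`.
#' @export
readCohort <- function(dir, basis = "gravimetric") {
    pe <- readPeptideTable(file.path(dir, "peptides.tsv"),
                           file.path(dir, "samples.tsv"),
                           file.path(dir, "peptide_info.tsv"),
                           basis = basis)
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    if (length(truth$marker_links))
        truth$marker_links <- lapply(truth$marker_links, unlist)
    list(experiment = pe,
         markers = readMarkerTable(file.path(dir, "markers.tsv")),
         truth = truth,
         proteins = Biostrings::readAAStringSet(
             file.path(dir, "proteins.fasta")),
         regions = readRegionSet(file.path(dir, "regions.json")))
}
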