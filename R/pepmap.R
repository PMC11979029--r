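## Mapping peptides onto protein sequence coordinates and region
## annotations (chains, fragments, anaphylatoxins). Coordinates are
## 1-based inclusive throughout, the protein sequence-feature
## convention. The ordinal in a `SYMBOL__N` id is an opaque identifier,
## not a residue position: localization is by exact sequence match
## only.

#' Parse a peptide identifier
#'
#' Ids follow `SYMBOL__<integer>[ox]`, the `ox` suffix marking the
#' oxidized variant. The ordinal is opaque (not a residue position).
#' Symbol comparison downstream is case-insensitive (ids such as
#' `C4A__136` and `C4a__136` denote the same peptide) but the raw form
#' is preserved.
#'
#' @param raw Non-empty id string.
#' @return List with `raw`, `protein_symbol`, `ordinal`, `modified`.
#' @examples
#' parsePeptideId("APOB__264ox")
#' @export
parsePeptideId <- function(raw) {
    if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
        stop("peptide id must be a non-empty string")
    m <- regmatches(raw,
                    regexec("^([A-Za-z0-9]+)__([0-9]+)(ox)?$", raw))[[1L]]
    if (length(m) == 0L)
        stop("malformed peptide id: '", raw, "'")
    ordinal <- as.integer(m[3L])
    if (ordinal < 1L) stop("peptide ordinal must be >= 1: '", raw, "'")
    list(raw = raw, protein_symbol = m[2L], ordinal = ordinal,
         modified = m[4L] == "ox")
}

#' Case-insensitive peptide id equality
#' @param a,b Id strings.
#' @return Logical.
#' @export
samePeptideId <- function(a, b) tolower(a) == tolower(b)

.checkAA <- function(s, what) {
    if (!grepl(sprintf("^[%s]+$", paste(.AA, collapse = "")), s))
        stop(what, " contains characters outside the 20-letter ",
             "amino-acid alphabet")
}

#' Locate a peptide in a protein sequence
#'
#' All exact-match positions as 1-based inclusive intervals, including
#' overlapping occurrences; an empty result means the peptide is
#' absent.
#'
#' @param peptideSeq Amino-acid string, shorter than the protein.
#' @param proteinSeq Amino-acid string (or
#'   [Biostrings::AAString]-coercible).
#' @return data.frame with columns `start`, `end`.
#' @examples
#' locatePeptide("AB", "ABZAB")  # intervals (1,2) and (4,5)
#' @export
locatePeptide <- function(peptideSeq, proteinSeq) {
    proteinSeq <- as.character(proteinSeq)
    .checkAA(peptideSeq, "peptide sequence")
    .checkAA(proteinSeq, "protein sequence")
    if (nchar(peptideSeq) >= nchar(proteinSeq))
        stop("peptide must be shorter than the protein")
    hits <- Biostrings::matchPattern(peptideSeq,
                                     Biostrings::AAString(proteinSeq))
    data.frame(start = BiocGenerics::start(hits),
               end = BiocGenerics::end(hits))
}

#' Attach region labels to a located peptide interval
#'
#' Every region of the protein overlapping the interval by at least one
#' residue is reported with its overlap fraction (overlapping residues
#' / peptide length); nested regions (an anaphylatoxin inside a chain)
#' are all reported, and full containment is flagged.
#'
#' @param protein Protein symbol present in `regions`.
#' @param start,end 1-based inclusive peptide interval.
#' @param regions A region annotation set ([readRegionSet()] format).
#' @return data.frame: region, kind, region_start, region_end,
#'   overlap_fraction, contained.
#' @export
annotateRegion <- function(protein, start, end, regions) {
    if (!protein %in% names(regions))
        stop("unknown protein in region set: ", protein)
    rg <- regions[[protein]]$regions
    pep <- IRanges::IRanges(start = start, end = end)
    reg <- IRanges::IRanges(start = rg$start, end = rg$end)
    ov <- IRanges::width(IRanges::pintersect(
        rep(pep, length(reg)), reg, resolve.empty = "start.x"))
    keep <- ov >= 1L
    data.frame(region = rg$name[keep], kind = rg$kind[keep],
               region_start = rg$start[keep], region_end = rg$end[keep],
               overlap_fraction = ov[keep] / IRanges::width(pep),
               contained = ov[keep] == IRanges::width(pep),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Map a set of peptides onto protein sequences and regions
#'
#' Locates each peptide by exact sequence match in its parent protein
#' and attaches region labels. Peptides matching at several sites have
#' every site reported, flagged by `match_index`; downstream summaries
#' use the first match unless `allMatches = TRUE`.
#'
#' @param hits data.frame with columns `peptide_id`, `protein`,
#'   `sequence` and optionally `direction`.
#' @param proteins Named character vector or
#'   [Biostrings::AAStringSet] of protein sequences.
#' @param regions Region annotation set.
#' @return data.frame, one row per (peptide, match site, overlapping
#'   region): peptide_id, protein, direction, match_index, start, end,
#'   region, kind, overlap_fraction, contained. Peptides absent from
#'   their protein get a single row with NA coordinates.
#' @export
mapPeptides <- function(hits, proteins, regions) {
    seqs <- stats::setNames(as.character(proteins), names(proteins))
    rows <- vector("list", nrow(hits))
    for (i in seq_len(nrow(hits))) {
        pid <- hits$peptide_id[i]; prot <- hits$protein[i]
        dir <- if ("direction" %in% colnames(hits)) hits$direction[i]
               else NA_character_
        if (!prot %in% names(seqs))
            stop("no sequence for protein ", prot)
        loc <- locatePeptide(hits$sequence[i], seqs[[prot]])
        if (nrow(loc) == 0L) {
            rows[[i]] <- data.frame(peptide_id = pid, protein = prot,
                                    direction = dir, match_index = NA_integer_,
                                    start = NA_integer_, end = NA_integer_,
                                    region = NA_character_,
                                    kind = NA_character_,
                                    overlap_fraction = NA_real_,
                                    contained = NA, stringsAsFactors = FALSE)
            next
        }
        sub <- vector("list", nrow(loc))
        for (j in seq_len(nrow(loc))) {
            ann <- annotateRegion(prot, loc$start[j], loc$end[j], regions)
            sub[[j]] <- cbind(
                data.frame(peptide_id = pid, protein = prot, direction = dir,
                           match_index = j, start = loc$start[j],
                           end = loc$end[j], stringsAsFactors = FALSE),
                ann)
        }
        rows[[i]] <- do.call(rbind, sub)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-region, per-direction peptide counts
#'
#' Counts differential peptides by (protein, region, direction), the
#' summary behind statements like "all low-abundant C4 peptides lie in
#' the beta chain". A peptide overlapping k regions contributes to each
#' of the k rows; only the first match site is used unless
#' `allMatches = TRUE`. Every peptide must carry a direction.
#'
#' @param mapped A [mapPeptides()] result with directions.
#' @param allMatches Count all match sites instead of the first.
#' @return data.frame: protein, region, kind, direction, n_peptides,
#'   ordered for reproducibility.
#' @export
summarizeRegions <- function(mapped, allMatches = FALSE) {
    m <- mapped[!is.na(mapped$start), , drop = FALSE]
    if (nrow(m) == 0L)
        return(data.frame(protein = character(), region = character(),
                          kind = character(), direction = character(),
                          n_peptides = integer()))
    if (any(is.na(m$direction)))
        stop("every mapped peptide needs a direction")
    if (!allMatches) m <- m[m$match_index == 1L, , drop = FALSE]
    key <- unique(m[, c("peptide_id", "protein", "region", "kind",
                        "direction")])
    agg <- stats::aggregate(list(n_peptides = key$peptide_id),
                            by = key[, c("protein", "region", "kind",
                                         "direction")],
                            FUN = length)
    agg <- agg[order(agg$protein, agg$region, agg$direction), ]
    rownames(agg) <- NULL
    agg
}
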