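#' @import methods
NULL

#' Quantity basis of a peptide table
#'
#' LFQ peptide quantities come off the instrument on a gravimetric
#' (per-ug EV protein) basis; [toVolumetric()] converts them to a
#' per-ul-plasma basis. The basis is tracked so the conversion can only
#' be applied once.
#'
#' @param x A [PeptideExperiment-class] object.
#' @return A character scalar, `"gravimetric"` or `"volumetric"`.
#' @export
setGeneric("quantBasis", function(x) standardGeneric("quantBasis"))

#' Missingness mask of a peptide table
#'
#' @param x A [PeptideExperiment-class] object.
#' @return A logical peptide x sample matrix, `TRUE` where the peptide
#'   was not detected in the sample.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Peptide quantity matrix
#'
#' @param x A [PeptideExperiment-class] object.
#' @return The numeric peptide x sample quantity matrix with `NA` for
#'   undetected entries. An observed value of exactly 0 is kept as
#'   observed-zero, distinct from missing.
#' @export
setGeneric("quantities", function(x) standardGeneric("quantities"))

#' Sample group labels
#'
#' @param x A [PeptideExperiment-class] object.
#' @return Factor of length `ncol(x)` with levels
#'   `c("short_lived", "long_lived")`.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Convert peptide quantities to a volumetric basis
#'
#' @param x A [PeptideExperiment-class] object on the gravimetric basis.
#' @return The object with each sample's quantities divided by that
#'   sample's `volume_for_20ug` and multiplied by 2, and the basis flag
#'   set to `"volumetric"`.
#' @export
setGeneric("toVolumetric", function(x) standardGeneric("toVolumetric"))
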