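#' @import methods
NULL

#' Sequence identifier of an object
#'
#' @param x An object carrying a sequence identifier.
#' @return A character scalar.
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' Motif hits of a tandem array
#'
#' @param x A [MotifArray-class] object.
#' @return A data.frame with one row per motif hit.
#' @export
setGeneric("motifHits", function(x) standardGeneric("motifHits"))

#' Summed bit score of a tandem array
#'
#' @param x A [MotifArray-class] object.
#' @return A numeric scalar, the sum of all hit scores.
#' @export
setGeneric("sumScore", function(x) standardGeneric("sumScore"))

#' Motif composition string
#'
#' Renders the ordered motif types of an array as a dash-separated string,
#' e.g. `"P1-L1-S1-E1-E2-DYW"`.
#'
#' @param x A [MotifArray-class] object.
#' @return A character scalar.
#' @export
setGeneric("motifString", function(x) standardGeneric("motifString"))

#' Text rendering of a degenerate nucleotide pattern
#'
#' @param x A [DegeneratePattern-class] object.
#' @return A character scalar in the bracket dialect, e.g. `"UUG[CU]CGC"`.
#' @export
setGeneric("patternText", function(x) standardGeneric("patternText"))

#' Per-position nucleotide sets of a pattern
#'
#' @param x A [DegeneratePattern-class] object.
#' @return A list of character vectors, one per position.
#' @export
setGeneric("patternPositions", function(x) standardGeneric("patternPositions"))

#' Gene names of a plastid gene set
#'
#' @param x A [PlastidGeneSet-class] object.
#' @return Character vector of gene names (one per record, duplicates from
#'   the inverted repeat included).
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' Gene table of a plastid gene set
#'
#' @param x A [PlastidGeneSet-class] object.
#' @return A data.frame with columns `record_id`, `gene_name`, `ir_duplicate`.
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' Feature annotations of a plastid gene set
#'
#' @param x A [PlastidGeneSet-class] object.
#' @return A data.frame with columns `record_id`, `type`, `start`, `end`
#'   (1-based inclusive, gene-local coordinates).
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' RNA sequences of a plastid gene set
#'
#' @param x A [PlastidGeneSet-class] object.
#' @return An [Biostrings::RNAStringSet] named by record id.
#' @export
setGeneric("geneSequences", function(x) standardGeneric("geneSequences"))
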