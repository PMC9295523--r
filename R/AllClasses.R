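#' @include AllGenerics.R
#' @import methods
NULL

## Catalog of PPR motif types, in canonical order. "E+" labels a truncated
## DYW region carrying at least the PG box; SMR is handled as an auxiliary
## domain on annotations, not a motif type.
.MOTIF_CATALOG <- c("P", "P1", "L1", "S1", "P2", "L2", "S2", "SS",
                    "E1", "E2", "DYW", "E+")

.PLS_MOTIFS <- c("P1", "L1", "S1", "P2", "L2", "S2", "SS")
.CODE_MOTIFS <- c("P", "P1", "P2", "S1", "S2", "SS")

#' Catalog of PPR motif types
#'
#' The twelve motif/domain labels recognised by the pipeline, in canonical
#' order: the canonical P motif, the PLS-triad variants (P1, L1, S1, P2, L2,
#' S2), the short SS motif, the E1/E2 extension motifs, the DYW deaminase
#' domain and the truncated E+ domain.
#'
#' @return Character vector of motif type labels.
#' @examples
#' motifCatalog()
#' @export
motifCatalog <- function() .MOTIF_CATALOG

.AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' MotifArray: a resolved tandem array of PPR motif hits
#'
#' Holds the ordered, non-overlapping motif hits on one protein sequence
#' together with their summed bit score. Arrays are normally produced by
#' [resolveOverlaps()] from a filtered hit table; the validity method
#' enforces sortedness, non-overlap and catalog membership.
#'
#' @slot seqId character scalar, the protein/ORF identifier.
#' @slot hits data.frame with columns `motif_type`, `aa_start`, `aa_end`
#'   (1-based inclusive protein coordinates), `score` (bits) and
#'   `source_profile`.
#' @slot sumScore numeric scalar, the sum of all hit scores.
#'
#' @seealso [resolveOverlaps()], [validateArray()], [classifyArray()]
#' @exportClass MotifArray
setClass("MotifArray",
         representation(seqId = "character",
                        hits = "data.frame",
                        sumScore = "numeric"))

setValidity("MotifArray", function(object) {
  h <- object@hits
  msgs <- character()
  if (length(object@seqId) != 1L || is.na(object@seqId))
    msgs <- c(msgs, "seqId must be a single string")
  need <- c("motif_type", "aa_start", "aa_end", "score", "source_profile")
  if (!all(need %in% names(h)))
    return(paste("hits must have columns:", paste(need, collapse = ", ")))
  if (nrow(h) > 0L) {
    if (!all(h$motif_type %in% .MOTIF_CATALOG))
      msgs <- c(msgs, "unknown motif_type in hits")
    if (any(h$aa_start > h$aa_end))
      msgs <- c(msgs, "aa_start must be <= aa_end")
    if (is.unsorted(h$aa_start))
      msgs <- c(msgs, "hits must be sorted by aa_start")
    if (nrow(h) > 1L && any(h$aa_start[-1L] <= h$aa_end[-nrow(h)]))
      msgs <- c(msgs, "hits must not overlap")
    if (any(!is.finite(h$score)))
      msgs <- c(msgs, "scores must be finite")
  }
  if (!isTRUE(all.equal(object@sumScore, sum(h$score), tolerance = 1e-8)))
    msgs <- c(msgs, "sumScore must equal the sum of hit scores")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MotifArray
#'
#' @param seqId Protein identifier.
#' @param hits data.frame of motif hits (columns `motif_type`, `aa_start`,
#'   `aa_end`, `score`, optional `source_profile`). Rows are sorted by
#'   `aa_start`; overlapping rows are an error (use [resolveOverlaps()] to
#'   resolve a raw hit list first).
#' @return A [MotifArray-class] object.
#' @examples
#' MotifArray("seq1", data.frame(motif_type = c("P", "P"),
#'                               aa_start = c(1, 36), aa_end = c(35, 70),
#'                               score = c(20, 18)))
#' @export
MotifArray <- function(seqId, hits = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(motif_type = character(), aa_start = integer(),
                       aa_end = integer(), score = numeric(),
                       source_profile = character(),
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(hits$source_profile)) hits$source_profile <- ""
    hits <- hits[order(hits$aa_start, hits$aa_end),
                 c("motif_type", "aa_start", "aa_end", "score",
                   "source_profile")]
    hits$aa_start <- as.integer(hits$aa_start)
    hits$aa_end <- as.integer(hits$aa_end)
    rownames(hits) <- NULL
  }
  new("MotifArray", seqId = as.character(seqId), hits = hits,
      sumScore = sum(hits$score))
}

#' @describeIn MotifArray Sequence identifier.
#' @param x,object A `MotifArray`.
#' @export
setMethod("seqId", "MotifArray", function(x) x@seqId)

#' @describeIn MotifArray The hit table (data.frame).
#' @export
setMethod("motifHits", "MotifArray", function(x) x@hits)

#' @describeIn MotifArray Summed bit score.
#' @export
setMethod("sumScore", "MotifArray", function(x) x@sumScore)

#' @describeIn MotifArray Number of motif hits.
#' @export
setMethod("length", "MotifArray", function(x) nrow(x@hits))

#' @describeIn MotifArray Dash-separated motif composition string.
#' @export
setMethod("motifString", "MotifArray",
          function(x) paste(x@hits$motif_type, collapse = "-"))

setMethod("show", "MotifArray", function(object) {
  cat("MotifArray for", object@seqId, "\n")
  cat(" ", length(object), "motifs, sum score",
      format(object@sumScore, digits = 6), "bits\n")
  if (length(object) > 0L)
    cat("  array:", motifString(object), "\n")
})

#' RegionPwm: position weight matrix for a conserved DYW-domain region
#'
#' A per-position amino-acid probability matrix for one of the three
#' conserved regions of the DYW deaminase domain (PG box, active site,
#' C-terminal), with its background model. Built by [buildPwm()] and
#' consumed by [scanPwm()] / [gradeDyw()].
#'
#' @slot region character scalar: `"PG_box"`, `"active_site"` or
#'   `"C_terminal"` (other labels allowed for user-supplied regions).
#' @slot width integer scalar, number of columns.
#' @slot matrix 20 x width numeric matrix of probabilities, rows named by
#'   amino acid; every column sums to 1 and all entries are positive.
#' @slot background length-20 probability vector over amino acids.
#' @slot offsetHint integer scalar, expected start residue of the region
#'   within the full domain (a soft prior: ordering is enforced, offsets are
#'   not).
#'
#' @exportClass RegionPwm
setClass("RegionPwm",
         representation(region = "character", width = "integer",
                        matrix = "matrix", background = "numeric",
                        offsetHint = "integer"))

setValidity("RegionPwm", function(object) {
  m <- object@matrix
  msgs <- character()
  if (nrow(m) != 20L || !identical(rownames(m), .AMINO_ACIDS))
    msgs <- c(msgs, "matrix must have 20 rows named by amino acid")
  if (ncol(m) != object@width)
    msgs <- c(msgs, "width must match ncol(matrix)")
  if (any(m <= 0))
    msgs <- c(msgs, "all probabilities must be > 0 (apply a pseudocount)")
  if (any(abs(colSums(m) - 1) > 1e-9))
    msgs <- c(msgs, "every column must sum to 1")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-9 || any(object@background <= 0))
    msgs <- c(msgs, "background must be a positive length-20 probability vector")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RegionPwm", function(object) {
  cat("RegionPwm:", object@region, "| width", object@width,
      "| offset hint", object@offsetHint, "\n")
})

#' DegeneratePattern: per-position nucleotide sets compiled from the PPR code
#'
#' Represents a predicted RNA binding site as an ordered list of nucleotide
#' sets, one per code-bearing motif. Rendered in the bracket dialect
#' (singleton set as a bare letter, larger sets as a bracket group, e.g.
#' `"UUG[CU]CGC"`). Patterns compiled from the code table list each group
#' in A<C<G<U order; parsed patterns preserve the printed group order, so
#' `patternText(parsePattern(s))` reproduces `s` verbatim.
#'
#' @slot positions list of character vectors, each a duplicate-free
#'   non-empty subset of A, C, G, U.
#'
#' @seealso [buildPattern()], [parsePattern()], [searchTargets()]
#' @exportClass DegeneratePattern
setClass("DegeneratePattern", representation(positions = "list"))

setValidity("DegeneratePattern", function(object) {
  ok <- vapply(object@positions, function(p) {
    length(p) >= 1L && all(p %in% c("A", "C", "G", "U")) &&
      anyDuplicated(p) == 0L
  }, logical(1))
  if (length(object@positions) == 0L)
    return("pattern must have at least one position")
  if (!all(ok))
    return("each position must be a duplicate-free subset of ACGU")
  TRUE
})

#' @describeIn DegeneratePattern Number of positions.
#' @param x,object A `DegeneratePattern`.
#' @export
setMethod("length", "DegeneratePattern", function(x) length(x@positions))

#' @describeIn DegeneratePattern The per-position nucleotide sets.
#' @export
setMethod("patternPositions", "DegeneratePattern", function(x) x@positions)

#' @describeIn DegeneratePattern Bracket-dialect text rendering.
#' @export
setMethod("patternText", "DegeneratePattern", function(x) {
  paste(vapply(x@positions, function(p) {
    if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
})

setMethod("show", "DegeneratePattern", function(object) {
  cat("DegeneratePattern (", length(object), " nt): ",
      patternText(object), "\n", sep = "")
})

#' PlastidGeneSet: annotated plastid gene regions on the RNA sense strand
#'
#' The search substrate for RNA target prediction: one record per annotated
#' gene copy, each with its sense-strand RNA sequence and gene-local feature
#' annotations (CDS, intron, exon, tRNA, rRNA). Genes duplicated in the
#' inverted-repeat (IR) regions appear as two records sharing a `gene_name`,
#' the second flagged `ir_duplicate`; [searchTargets()] reports hits on such
#' genes once, IR-flagged.
#'
#' @slot genes data.frame with columns `record_id`, `gene_name`,
#'   `ir_duplicate` (logical).
#' @slot sequences [Biostrings::RNAStringSet] named by `record_id`.
#' @slot features data.frame with columns `record_id`, `type` (one of CDS,
#'   intron, exon, tRNA, rRNA), `start`, `end` (1-based inclusive on the
#'   record's RNA sequence).
#'
#' @seealso [plastidGeneSet()], [readPlastidGenes()], [searchTargets()]
#' @exportClass PlastidGeneSet
setClass("PlastidGeneSet",
         representation(genes = "data.frame", sequences = "ANY",
                        features = "data.frame"))

.FEATURE_TYPES <- c("CDS", "intron", "exon", "tRNA", "rRNA")

setValidity("PlastidGeneSet", function(object) {
  g <- object@genes
  f <- object@features
  msgs <- character()
  if (!all(c("record_id", "gene_name", "ir_duplicate") %in% names(g)))
    return("genes must have columns record_id, gene_name, ir_duplicate")
  if (!all(c("record_id", "type", "start", "end") %in% names(f)))
    return("features must have columns record_id, type, start, end")
  if (!methods::is(object@sequences, "RNAStringSet"))
    msgs <- c(msgs, "sequences must be an RNAStringSet")
  else {
    if (!identical(names(object@sequences), g$record_id))
      msgs <- c(msgs, "sequence names must equal genes$record_id, in order")
    if (nrow(f) > 0L) {
      if (!all(f$type %in% .FEATURE_TYPES))
        msgs <- c(msgs, "unknown feature type")
      if (!all(f$record_id %in% g$record_id))
        msgs <- c(msgs, "feature record_id not in gene table")
      lens <- stats::setNames(Biostrings::width(object@sequences),
                                  names(object@sequences))
      if (any(f$start < 1L) || any(f$end > lens[f$record_id]) ||
          any(f$start > f$end))
        msgs <- c(msgs, "features must lie within sequence bounds")
    }
  }
  if (anyDuplicated(g$record_id))
    msgs <- c(msgs, "record_id must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PlastidGeneSet
#'
#' @param genes data.frame with columns `record_id`, `gene_name` and
#'   optionally `ir_duplicate` (defaults to duplicated gene names: the
#'   second and later copies of a name are flagged).
#' @param sequences Named [Biostrings::RNAStringSet] (or DNA/character,
#'   coerced to RNA) in the same order as `genes`.
#' @param features data.frame with columns `record_id`, `type`, `start`,
#'   `end`; if missing, each record gets a single `exon` feature covering
#'   its full length.
#' @return A [PlastidGeneSet-class] object.
#' @export
plastidGeneSet <- function(genes, sequences, features = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::RNAStringSet(
    chartr("Tt", "Uu", sequences))
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::RNAStringSet(sequences)
  if (is.null(names(sequences)) || !all(nzchar(names(sequences))))
    names(sequences) <- genes$record_id
  if (is.null(genes$ir_duplicate))
    genes$ir_duplicate <- duplicated(genes$gene_name)
  if (is.null(features)) {
    features <- data.frame(record_id = genes$record_id,
                           type = rep("exon", nrow(genes)),
                           start = rep(1L, nrow(genes)),
                           end = as.integer(Biostrings::width(sequences)),
                           stringsAsFactors = FALSE)
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  rownames(genes) <- rownames(features) <- NULL
  new("PlastidGeneSet", genes = genes, sequences = sequences,
      features = features)
}

#' @describeIn PlastidGeneSet Number of gene records (IR copies counted).
#' @export
setMethod("length", "PlastidGeneSet", function(x) nrow(x@genes))

#' @describeIn PlastidGeneSet Gene names, one per record.
#' @export
setMethod("geneNames", "PlastidGeneSet", function(x) x@genes$gene_name)

#' @describeIn PlastidGeneSet The gene table.
#' @export
setMethod("geneTable", "PlastidGeneSet", function(x) x@genes)

#' @describeIn PlastidGeneSet The feature table.
#' @export
setMethod("geneFeatures", "PlastidGeneSet", function(x) x@features)

#' @describeIn PlastidGeneSet The RNA sequences.
#' @export
setMethod("geneSequences", "PlastidGeneSet", function(x) x@sequences)

setMethod("show", "PlastidGeneSet", function(object) {
  n <- nrow(object@genes)
  nir <- sum(object@genes$ir_duplicate)
  cat("PlastidGeneSet:", n, "gene records (", nir, "IR duplicates ),",
      sum(Biostrings::width(object@sequences)), "nt total\n")
  tt <- table(object@features$type)
  cat("  features:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
})
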