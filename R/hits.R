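#' @importFrom utils read.delim write.table
NULL

## Map assorted producer motif labels onto the catalog enum.
.normalizeMotifName <- function(x) {
  x <- sub("^PPR[_-]?", "", x, ignore.case = FALSE)
  up <- toupper(x)
  canon <- stats::setNames(.MOTIF_CATALOG, toupper(.MOTIF_CATALOG))
  out <- canon[up]
  out[up %in% c("EPLUS", "E_PLUS")] <- "E+"
  unname(out)
}

#' Read a per-motif hit table
#'
#' Ingests tabular motif-hit output in either a plain header-bearing TSV
#' dialect or the HMMER `domtblout` dialect (auto-detected from the leading
#' `#` comment block). Motif names are normalized to the catalog
#' ([motifCatalog()]); rows with unknown motif names are skipped with a
#' warning. An `evalue` column is carried through when present.
#'
#' @param path Path to the hit table.
#' @param columns Optional named character vector remapping input column
#'   names onto `seq_id`, `motif_type`, `aa_start`, `aa_end`, `score`
#'   (and optionally `source_profile`, `evalue`) for the plain dialect.
#' @return data.frame of hits with columns `seq_id`, `motif_type`,
#'   `aa_start`, `aa_end`, `score`, `source_profile` and, when present,
#'   `evalue`.
#' @export
readHitTable <- function(path, columns = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#") || grepl("^\\S+\\s+-\\s", first)) {
    return(.readDomtblout(path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  if (!is.null(columns)) {
    for (want in names(columns)) {
      if (!columns[[want]] %in% names(tab))
        stop("hit table is missing mapped column '", columns[[want]], "'")
      names(tab)[names(tab) == columns[[want]]] <- want
    }
  }
  need <- c("seq_id", "motif_type", "aa_start", "aa_end", "score")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("hit table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(tab$source_profile)) tab$source_profile <- ""
  .finishHits(tab)
}

.readDomtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(.finishHits(data.frame(seq_id = character(),
                                  motif_type = character(),
                                  aa_start = integer(), aa_end = integer(),
                                  score = numeric(), source_profile = character(),
                                  stringsAsFactors = FALSE)))
  fields <- strsplit(trimws(lines), "\\s+")
  short <- vapply(fields, length, integer(1)) < 22L
  if (any(short)) stop("malformed domtblout row (fewer than 22 fields)")
  # domtblout: 1 target, 4 qname(profile), 13 i-Evalue, 14 dom score,
  # 18-19 ali coords
  tab <- data.frame(
    seq_id = vapply(fields, `[`, "", 1L),
    motif_type = vapply(fields, `[`, "", 4L),
    aa_start = as.integer(vapply(fields, `[`, "", 18L)),
    aa_end = as.integer(vapply(fields, `[`, "", 19L)),
    score = as.numeric(vapply(fields, `[`, "", 14L)),
    evalue = as.numeric(vapply(fields, `[`, "", 13L)),
    stringsAsFactors = FALSE)
  tab$source_profile <- tab$motif_type
  .finishHits(tab)
}

.finishHits <- function(tab) {
  tab$motif_type <- as.character(tab$motif_type)
  norm <- .normalizeMotifName(tab$motif_type)
  bad <- is.na(norm)
  if (any(bad)) {
    warning(sum(bad), " hit row(s) with unknown motif name skipped: ",
            paste(unique(tab$motif_type[bad]), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
    norm <- norm[!bad]
  }
  tab$motif_type <- norm
  tab$aa_start <- as.integer(tab$aa_start)
  tab$aa_end <- as.integer(tab$aa_end)
  tab$score <- as.numeric(tab$score)
  keep <- c("seq_id", "motif_type", "aa_start", "aa_end", "score",
            "source_profile", intersect("evalue", names(tab)))
  rownames(tab) <- NULL
  tab[, keep, drop = FALSE]
}

#' Filter motif hits by the per-type score cutoffs
#'
#' Retains a hit iff its score strictly exceeds the cutoff for its motif
#' type: `> ss_min` for SS motifs (default 10), `> dyw_min` for DYW
#' domains (default 30), `> 0` for every other type. When the table carries
#' an `evalue` column, hits with `evalue > evalue_max` are additionally
#' removed; tables without E-values are governed by the score rules alone.
#' The operation is idempotent.
#'
#' @param hits Hit data.frame (see [readHitTable()]).
#' @param ss_min,dyw_min,other_min Strict score cutoffs in bits.
#' @param evalue_max Maximum E-value, applied only if an `evalue` column
#'   exists (default 1e-10).
#' @return The retained rows of `hits`.
#' @examples
#' h <- data.frame(seq_id = "s", motif_type = c("SS", "SS", "DYW", "P", "P"),
#'                 aa_start = 1:5, aa_end = 1:5,
#'                 score = c(10, 10.01, 30, 0.5, -1))
#' filterHits(h)$score
#' @export
filterHits <- function(hits, ss_min = 10, dyw_min = 30, other_min = 0,
                       evalue_max = 1e-10) {
  if (nrow(hits) == 0L) return(hits)
  cut <- rep(other_min, nrow(hits))
  cut[hits$motif_type == "SS"] <- ss_min
  cut[hits$motif_type == "DYW"] <- dyw_min
  keep <- hits$score > cut
  if ("evalue" %in% names(hits))
    keep <- keep & (is.na(hits$evalue) | hits$evalue <= evalue_max)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping motif hits into a tandem array
#'
#' Greedy selection by descending score; ties broken by leftmost
#' `aa_start`, then catalog order ([motifCatalog()]). A hit is kept iff it
#' does not overlap any already-kept hit. The result is sorted by position
#' and carries the summed score. Greedy resolution is deterministic and
#' `O(n log n)`; an exact maximum-weight interval scheduler serves as a
#' test oracle on small instances.
#'
#' @param hits Hit data.frame for a single sequence.
#' @param seq_id Sequence id (defaults to the one in `hits`).
#' @return A [MotifArray-class] object.
#' @export
resolveOverlaps <- function(hits, seq_id = NULL) {
  if (is.null(seq_id))
    seq_id <- if (nrow(hits)) hits$seq_id[1L] else ""
  if (nrow(hits) == 0L) return(MotifArray(seq_id))
  stopifnot(all(hits$seq_id == seq_id))
  cat_rank <- match(hits$motif_type, .MOTIF_CATALOG)
  ord <- order(-hits$score, hits$aa_start, cat_rank)
  hits <- hits[ord, , drop = FALSE]
  kept_start <- integer(0)
  kept_end <- integer(0)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$aa_start[i]; e <- hits$aa_end[i]
    if (!any(s <= kept_end & e >= kept_start)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, s)
      kept_end <- c(kept_end, e)
    }
  }
  MotifArray(seq_id, hits[keep, , drop = FALSE])
}

#' Write resolved arrays to a TSV
#'
#' @param arrays List of [MotifArray-class] objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeArrayTable <- function(arrays, path) {
  tab <- do.call(rbind, lapply(arrays, function(a)
    data.frame(seq_id = seqId(a), motif_count = length(a),
               motif_string = motifString(a), sum_score = sumScore(a),
               stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
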