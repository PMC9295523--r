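#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet GENETIC_CODE AAStringSet
NULL

## Normalize a transcript to an uppercase DNA (T) alphabet character string,
## validating characters. Errors name the first offending position.
.normalizeTranscript <- function(sequence, id = "transcript") {
  s <- toupper(as.character(sequence))
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L) stop("empty sequence for ", id)
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% iupac)
  if (length(bad))
    stop("non-nucleotide character '", chars[bad[1]], "' at position ",
         bad[1], " in ", id)
  s
}

## Translate an in-frame DNA string to amino acids; ambiguity codes give 'X'.
.translateFrame <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## ORF segments within one translated frame. Returns rows with codon-level
## coordinates (1-based codon indices into the frame) and completeness.
.frameSegments <- function(aa, min_aa) {
  n <- nchar(aa)
  if (n == 0L) return(NULL)
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  stops <- stops[stops > 0L]
  bounds <- c(0L, stops, n + 1L)
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    from <- bounds[k] + 1L
    to <- bounds[k + 1L] - 1L
    if (to < from) next
    seg <- substr(aa, from, to)
    up_stop <- bounds[k] > 0L
    down_stop <- bounds[k + 1L] <= n
    if (up_stop) {
      mpos <- regexpr("M", seg, fixed = TRUE)
      if (mpos < 0L) next  # stop-bounded segment without a start codon
      from <- from + as.integer(mpos) - 1L
      seg <- substr(aa, from, to)
      completeness <- if (down_stop) "complete" else "3'partial"
    } else {
      completeness <- if (down_stop) "5'partial" else "internal"
    }
    if (nchar(seg) < min_aa) next
    out[[length(out) + 1L]] <-
      data.frame(codon_start = from, codon_end = to, aa_sequence = seg,
                 completeness = completeness, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Extract candidate ORFs from a transcript
#'
#' Scans all six reading frames for open reading frames, defined as the
#' longest stop-to-stop intervals per frame, trimmed to the first ATG when an
#' upstream stop exists. Segments open at the 5' end (no upstream stop) are
#' reported as `5'partial` without trimming; segments lacking a downstream
#' stop are `3'partial`; a frame with no stop at all yields an `internal`
#' segment. Stop-bounded segments without a start codon are not reported.
#'
#' @param sequence Transcript nucleotide sequence (character,
#'   [Biostrings::DNAString] or RNAString). Case and T/U alphabet are
#'   normalized; IUPAC ambiguity codes are accepted and translate to `X`.
#' @param transcript_id Identifier used to derive ORF ids.
#' @param min_aa Minimum ORF length in amino acid residues (default 31).
#' @return data.frame with one row per retained ORF: `orf_id`,
#'   `transcript_id`, `strand` (+/-), `frame` (0..2 on the scanned strand),
#'   `nt_start`, `nt_end` (0-based half-open, forward-strand coordinates),
#'   `aa_sequence`, `length_aa`, `completeness`.
#' @details Coordinates always refer to the forward strand of the input
#'   transcript; for minus-strand ORFs, reverse-complementing
#'   `[nt_start, nt_end)` and translating reproduces `aa_sequence`.
#' @examples
#' tx <- paste0("CCC", "ATG", strrep("GCT", 30), "TAA", "GG")
#' extractOrfs(tx, "tx1", min_aa = 31)
#' @export
extractOrfs <- function(sequence, transcript_id = "transcript",
                        min_aa = 31L) {
  stopifnot(min_aa >= 1L)
  s <- .normalizeTranscript(sequence, transcript_id)
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rows <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") s else rc
    for (frame in 0:2) {
      sub <- substr(src, frame + 1L, L)
      aa <- .translateFrame(sub)
      segs <- .frameSegments(aa, min_aa)
      if (is.null(segs)) next
      # codon k occupies [frame + 3(k-1), frame + 3k) on the scanned strand
      scan_start <- frame + 3L * (segs$codon_start - 1L)
      scan_end <- frame + 3L * segs$codon_end
      if (strand == "+") {
        segs$nt_start <- scan_start
        segs$nt_end <- scan_end
      } else {
        segs$nt_start <- L - scan_end
        segs$nt_end <- L - scan_start
      }
      segs$strand <- strand
      segs$frame <- frame
      rows[[length(rows) + 1L]] <- segs
    }
  }
  if (!length(rows)) {
    return(data.frame(orf_id = character(), transcript_id = character(),
                      strand = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa_sequence = character(), length_aa = integer(),
                      completeness = character(), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  orfs <- orfs[order(orfs$nt_start, orfs$nt_end, orfs$strand, orfs$frame), ]
  data.frame(orf_id = sprintf("%s.p%d", transcript_id, seq_len(nrow(orfs))),
             transcript_id = transcript_id,
             strand = orfs$strand, frame = orfs$frame,
             nt_start = orfs$nt_start, nt_end = orfs$nt_end,
             aa_sequence = orfs$aa_sequence,
             length_aa = nchar(orfs$aa_sequence),
             completeness = orfs$completeness,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract ORFs from a FASTA file of transcripts
#'
#' @param fasta Path to a (multi-)FASTA of transcript nucleotide sequences.
#' @param min_aa Minimum ORF length in amino acids.
#' @return Combined ORF data.frame (see [extractOrfs()]).
#' @export
extractOrfsFasta <- function(fasta, min_aa = 31L) {
  txs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(txs))
  do.call(rbind, lapply(seq_along(txs), function(i)
    extractOrfs(as.character(txs[[i]]), ids[i], min_aa = min_aa)))
}

#' Join split ORFs showing structural continuity of their motif arrays
#'
#' Two ORFs from the same transcript are joined when they lie on the same
#' strand, are adjacent in coordinate order with a gap of at most
#' `max_gap_nt`, and their concatenated motif arrays still form a valid
#' tandem array (non-overlapping, with the junction inter-motif gap within
#' `max_intermotif_gap` residues). The joined peptide inserts
#' `ceiling(gap_nt / 3)` `X` spacer residues. Joined products are
#' hypothetical reconstructions: they carry `hypothetical = TRUE` and are
#' excluded from final reported sets by the pipeline.
#'
#' @param orfs data.frame of ORFs from one transcript (as from
#'   [extractOrfs()]).
#' @param arrays Named list of [MotifArray-class] objects, one per
#'   `orf_id` (members without an array are never joined).
#' @param max_gap_nt Maximum nucleotide gap between member ORFs (default 90,
#'   about one PPR motif).
#' @param max_intermotif_gap Maximum residue gap between the flanking motifs
#'   across the junction (default 50).
#' @return data.frame with one row per join: `join_id`, `transcript_id`,
#'   `members` (comma-separated orf ids), `strand`, `aa_sequence`,
#'   `x_count`, `motif_count`, `hypothetical`, plus a `refused` attribute
#'   listing candidate pairs rejected with a reason code
#'   (`overlap`, `strand`, `gap`, `array_discontinuity`, `no_array`).
#' @export
joinOrfs <- function(orfs, arrays, max_gap_nt = 90L,
                     max_intermotif_gap = 50L) {
  stopifnot(length(unique(orfs$transcript_id)) <= 1L)
  joins <- list()
  refused <- list()
  if (nrow(orfs) >= 2L) {
    orfs <- orfs[order(orfs$nt_start, orfs$nt_end), ]
    used <- logical(nrow(orfs))
    for (i in seq_len(nrow(orfs) - 1L)) {
      j <- i + 1L
      a <- orfs[i, ]; b <- orfs[j, ]
      pair <- paste(a$orf_id, b$orf_id, sep = "+")
      refuse <- function(code) refused[[length(refused) + 1L]] <<-
        data.frame(pair = pair, reason = code, stringsAsFactors = FALSE)
      if (used[i]) next  # no transitive chains beyond pairs
      if (a$strand != b$strand) { refuse("strand"); next }
      gap <- b$nt_start - a$nt_end
      if (gap < 0L) { refuse("overlap"); next }
      if (gap > max_gap_nt) { refuse("gap"); next }
      arr_a <- arrays[[a$orf_id]]; arr_b <- arrays[[b$orf_id]]
      if (is.null(arr_a) || is.null(arr_b) ||
          length(arr_a) == 0L || length(arr_b) == 0L) {
        refuse("no_array"); next
      }
      x_count <- as.integer(ceiling(gap / 3))
      offset <- a$length_aa + x_count
      hb <- motifHits(arr_b)
      hb$aa_start <- hb$aa_start + offset
      hb$aa_end <- hb$aa_end + offset
      combined <- rbind(motifHits(arr_a), hb)
      junction_gap <- hb$aa_start[1L] - max(motifHits(arr_a)$aa_end) - 1L
      if (junction_gap > max_intermotif_gap) {
        refuse("array_discontinuity"); next
      }
      used[i] <- used[j] <- TRUE
      joins[[length(joins) + 1L]] <- data.frame(
        join_id = paste0(a$orf_id, "+", b$orf_id),
        transcript_id = a$transcript_id,
        members = paste(a$orf_id, b$orf_id, sep = ","),
        strand = a$strand,
        aa_sequence = paste0(a$aa_sequence, strrep("X", x_count),
                             b$aa_sequence),
        x_count = x_count,
        motif_count = nrow(combined),
        hypothetical = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(joins)) do.call(rbind, joins) else
    data.frame(join_id = character(), transcript_id = character(),
               members = character(), strand = character(),
               aa_sequence = character(), x_count = integer(),
               motif_count = integer(), hypothetical = logical(),
               stringsAsFactors = FALSE)
  attr(out, "refused") <- if (length(refused)) do.call(rbind, refused) else
    data.frame(pair = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Write ORF peptides to FASTA
#'
#' Headers carry `orf_id|transcript|strand|frame|start-end|completeness`
#' with 1-based inclusive coordinates, the user-facing convention.
#'
#' @param orfs ORF data.frame from [extractOrfs()].
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
writeOrfFasta <- function(orfs, path) {
  aa <- Biostrings::AAStringSet(orfs$aa_sequence)
  names(aa) <- sprintf("%s|%s|%s|%d|%d-%d|%s", orfs$orf_id,
                       orfs$transcript_id, orfs$strand, orfs$frame,
                       orfs$nt_start + 1L, orfs$nt_end, orfs$completeness)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
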