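#' @importFrom Biostrings RNAStringSet readDNAStringSet
NULL

.NT_ORDER <- c("A", "C", "G", "U")

#' The packaged PPR code table
#'
#' Loads the packaged mapping from the amino acids at a motif's 5th and
#' last positions to the nucleotide set that motif prefers (the PPR code).
#' Pairs absent from the table are treated as uninformative and default to
#' the full set ACGU via [codeLookup()]. The table is an editable TSV
#' resource under `inst/extdata/ppr_code.tsv`.
#'
#' @param path Optional path to an alternative code TSV (columns `aa5`,
#'   `aalast`, `nucleotides`).
#' @return data.frame with columns `aa5`, `aalast`, `nucleotides` (a
#'   string over ACGU in A<C<G<U order).
#' @export
pprCodeTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ppr_code.tsv", package = "pprscout",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("aa5", "aalast", "nucleotides") %in% names(tab)))
  tab
}

#' Look up the PPR code for a residue pair
#'
#' @param aa5,aalast Amino acids at the motif's 5th and last positions
#'   (single letters; `NA` or unknown residues are uninformative).
#' @param table Code table from [pprCodeTable()].
#' @return Character vector of preferred nucleotides in A<C<G<U order;
#'   the full set `c("A","C","G","U")` for unknown pairs.
#' @examples
#' codeLookup("T", "D")
#' codeLookup("W", "W")  # unknown pair -> full set
#' @export
codeLookup <- function(aa5, aalast, table = pprCodeTable()) {
  if (is.na(aa5) || is.na(aalast)) return(.NT_ORDER)
  row <- which(table$aa5 == aa5 & table$aalast == aalast)
  if (length(row) == 0L) return(.NT_ORDER)
  sort(strsplit(table$nucleotides[row[1L]], "")[[1]])
}

#' Extract PPR-code residues from a motif array
#'
#' For each code-bearing motif (by default the P- and S-type motifs: P, P1,
#' P2, S1, S2, SS — L-type and E/DYW motifs carry no code), reads the
#' residues at the motif's 5th and last positions. Motifs shorter than 5
#' residues yield an unknown pair (`NA`, `NA`).
#'
#' @param array A [MotifArray-class] object.
#' @param aa_sequence The protein sequence the array lies on.
#' @param code_bearing Motif types contributing pattern positions.
#' @return data.frame with columns `motif_index`, `motif_type`, `aa5`,
#'   `aalast`, in array order.
#' @export
extractCodeResidues <- function(array, aa_sequence,
                                code_bearing = c("P", "P1", "P2", "S1",
                                                 "S2", "SS")) {
  h <- motifHits(array)
  n <- nchar(aa_sequence)
  if (nrow(h) > 0L && max(h$aa_end) > n)
    stop("motif ", which.max(h$aa_end), " of ", seqId(array),
         " extends beyond the sequence (", max(h$aa_end), " > ", n, ")")
  idx <- which(h$motif_type %in% code_bearing)
  rows <- lapply(idx, function(i) {
    len <- h$aa_end[i] - h$aa_start[i] + 1L
    if (len < 5L) {
      a5 <- al <- NA_character_
    } else {
      a5 <- substr(aa_sequence, h$aa_start[i] + 4L, h$aa_start[i] + 4L)
      al <- substr(aa_sequence, h$aa_end[i], h$aa_end[i])
    }
    data.frame(motif_index = i, motif_type = h$motif_type[i],
               aa5 = a5, aalast = al, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(motif_index = integer(), motif_type = character(),
               aa5 = character(), aalast = character(),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Build a degenerate pattern from nucleotide sets
#'
#' Positions map motif `i` to nucleotide `i`, 5' to 3', with no terminal
#' offset. Rendering follows the bracket dialect: singleton sets as bare
#' letters, larger sets bracketed in A<C<G<U order, the full set as
#' `"[ACGU]"`.
#'
#' @param code_sets List of character vectors (each a non-empty subset of
#'   ACGU).
#' @return A [DegeneratePattern-class] object.
#' @examples
#' patternText(buildPattern(list("U", "U", "G", c("C", "U"),
#'                               "C", "G", "C")))
#' @export
buildPattern <- function(code_sets) {
  stopifnot(length(code_sets) >= 1L)
  positions <- lapply(code_sets, function(p) sort(unique(as.character(p))))
  new("DegeneratePattern", positions = positions)
}

#' Parse a bracket-dialect pattern string
#'
#' Inverse of [patternText()]: `parsePattern(patternText(p))` equals `p`.
#'
#' @param text Pattern string, e.g. `"UUG[CU]CGC"`.
#' @return A [DegeneratePattern-class] object.
#' @export
parsePattern <- function(text) {
  text <- chartr("Tt", "Uu", toupper(text))
  chars <- strsplit(text, "")[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- i + 1L
      while (close <= length(chars) && chars[close] != "]") close <- close + 1L
      if (close > length(chars)) stop("unclosed bracket group in pattern")
      if (close == i + 1L) stop("empty bracket group in pattern")
      grp <- chars[(i + 1L):(close - 1L)]
      positions[[length(positions) + 1L]] <- unique(grp)
      i <- close + 1L
    } else {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    }
  }
  # printed group order is preserved verbatim (sets, not sequences)
  new("DegeneratePattern", positions = positions)
}

#' Compile a PPR protein's binding pattern from its array
#'
#' Convenience wrapper: extracts the code residues, looks each pair up in
#' the code table, and assembles the degenerate pattern.
#'
#' @inheritParams extractCodeResidues
#' @param code_table Code table from [pprCodeTable()].
#' @return A [DegeneratePattern-class] object, or `NULL` when no
#'   code-bearing motifs exist.
#' @export
pprPattern <- function(array, aa_sequence, code_table = pprCodeTable(),
                       code_bearing = c("P", "P1", "P2", "S1", "S2",
                                        "SS")) {
  pairs <- extractCodeResidues(array, aa_sequence,
                               code_bearing = code_bearing)
  if (nrow(pairs) == 0L) return(NULL)
  sets <- lapply(seq_len(nrow(pairs)), function(i)
    codeLookup(pairs$aa5[i], pairs$aalast[i], table = code_table))
  buildPattern(sets)
}

## Convert a pattern to a PCRE fragment over the U alphabet.
.patternRegex <- function(pattern) {
  paste(vapply(patternPositions(pattern), function(p) {
    if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
}

## Feature type at a position of one gene record; 'exon' wins over the
## generic gene span, first matching feature otherwise.
.featureAt <- function(features, record_id, pos) {
  f <- features[features$record_id == record_id &
                  features$start <= pos & features$end >= pos, , drop = FALSE]
  if (nrow(f) == 0L) return(NA_character_)
  f$type[1L]
}

#' Search a plastid gene set for pattern matches
#'
#' Reports every ungapped window of each gene's sense-strand RNA that
#' satisfies all position sets of the pattern, including overlapping
#' windows. Genes duplicated in the inverted repeats are searched once
#' (their copies are identical by construction) and the hits flagged
#' `ir_flagged`. Each hit is annotated with the feature context at the
#' match midpoint. Output is ordered by `(gene_name, match_start)`.
#'
#' @param pattern A [DegeneratePattern-class] object (or pattern string).
#' @param genes A [PlastidGeneSet-class] object.
#' @param ppr_id Identifier of the querying protein, carried through.
#' @return data.frame with columns `ppr_id`, `gene_name`,
#'   `feature_context`, `match_start` (1-based), `matched_sequence`,
#'   `ir_flagged`.
#' @export
searchTargets <- function(pattern, genes, ppr_id = "query") {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  empty <- data.frame(ppr_id = character(), gene_name = character(),
                      feature_context = character(), match_start = integer(),
                      matched_sequence = character(), ir_flagged = logical(),
                      stringsAsFactors = FALSE)
  gt <- geneTable(genes)
  if (nrow(gt) == 0L) return(empty)
  rx <- paste0("(?=", .patternRegex(pattern), ")")
  w <- length(pattern)
  dup_names <- unique(c(gt$gene_name[gt$ir_duplicate],
                        gt$gene_name[duplicated(gt$gene_name)]))
  primary <- gt[!duplicated(gt$gene_name), , drop = FALSE]
  seqs <- geneSequences(genes)
  feats <- geneFeatures(genes)
  rows <- lapply(seq_len(nrow(primary)), function(i) {
    rid <- primary$record_id[i]
    s <- as.character(seqs[[match(rid, names(seqs))]])
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0L])
    if (!length(starts)) return(NULL)
    mid <- starts + (w - 1L) %/% 2L
    data.frame(ppr_id = ppr_id, gene_name = primary$gene_name[i],
               feature_context = vapply(mid, function(p)
                 .featureAt(feats, rid, p), character(1)),
               match_start = starts,
               matched_sequence = substring(s, starts, starts + w - 1L),
               ir_flagged = primary$gene_name[i] %in% dup_names,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  out <- out[order(out$gene_name, out$match_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag promiscuous proteins
#'
#' A protein is flagged when its number of distinct targets (gene,
#' position pairs) strictly exceeds `threshold`; flagged proteins are
#' excluded from the headline target report.
#'
#' @param hits_by_ppr Named list of target-hit data.frames
#'   (from [searchTargets()]), or one combined data.frame with `ppr_id`.
#' @param threshold Maximum acceptable target count (default 60).
#' @return Character vector of flagged `ppr_id`s.
#' @export
flagPromiscuous <- function(hits_by_ppr, threshold = 60L) {
  if (is.data.frame(hits_by_ppr))
    hits_by_ppr <- split(hits_by_ppr, hits_by_ppr$ppr_id)
  counts <- vapply(hits_by_ppr, nrow, integer(1))
  names(counts)[counts > threshold]
}

#' Classify a plastid target gene by name convention
#'
#' Maps plastid gene names onto functional categories by their standard
#' nomenclature prefixes: photosystem/cytochrome/ATP-synthase/NADH-
#' dehydrogenase/RuBisCO genes (`psa`, `psb`, `pet`, `atp`, `ndh`, `rbc`)
#' are photosynthesis-related; `rps`/`rpl` are ribosomal proteins; `trn`
#' transfer RNAs; `rrn` ribosomal RNAs; `rpo` subunits of the
#' plastid-encoded polymerase (PEP); `ycf` hypothetical reading frames of
#' unknown function.
#'
#' @param gene_name Character vector of gene names.
#' @return Character vector of categories: `photosynthesis`,
#'   `ribosomal_protein`, `tRNA`, `rRNA`, `PEP`, `unknown_function` or
#'   `other`.
#' @examples
#' classifyTargetGene(c("psbA", "rps12", "trnK-UUU", "ycf1"))
#' @export
classifyTargetGene <- function(gene_name) {
  g <- tolower(gene_name)
  out <- rep("other", length(g))
  out[grepl("^(psa|psb|pet|atp|ndh|rbc)", g)] <- "photosynthesis"
  out[grepl("^(rps|rpl)", g)] <- "ribosomal_protein"
  out[grepl("^trn", g)] <- "tRNA"
  out[grepl("^rrn", g)] <- "rRNA"
  out[grepl("^rpo", g)] <- "PEP"
  out[grepl("^ycf", g)] <- "unknown_function"
  out
}

#' Summarize target genes by functional category
#'
#' Deduplicates gene names and counts them per category of
#' [classifyTargetGene()].
#'
#' @param gene_names Character vector (duplicates allowed; IR copies count
#'   once since they share a name).
#' @return Named integer vector of category counts.
#' @export
summarizeTargetCategories <- function(gene_names) {
  genes <- unique(gene_names)
  tab <- table(classifyTargetGene(genes))
  stats::setNames(as.integer(tab), names(tab))
}

#' The packaged AaPPR hypothetical-target table
#'
#' The curated table of degenerate binding patterns and candidate plastid
#' RNA targets for the twelve chloroplastic AaPPR proteins of
#' *Agave angustifolia* (see
#' `inst/extdata/aappr_target_table.tsv`): per row a protein, its compiled
#' pattern, a target gene, the feature context, the IR-duplication flag and
#' the matched RNA sequence.
#'
#' @return data.frame with columns `ppr_id`, `pattern`, `gene`, `context`,
#'   `ir_duplicate`, `target_sequence`.
#' @export
aapprTargetTable <- function() {
  path <- system.file("extdata", "aappr_target_table.tsv",
                      package = "pprscout", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Does a sequence satisfy a degenerate pattern?
#'
#' @param pattern A [DegeneratePattern-class] or pattern string.
#' @param sequence RNA string of exactly the pattern length (T accepted).
#' @return Logical scalar.
#' @export
patternMatches <- function(pattern, sequence) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  s <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  if (length(s) != length(pattern)) return(FALSE)
  all(mapply(function(set, ch) ch %in% set, patternPositions(pattern), s))
}

#' Read an annotated plastid gene set from FASTA + GFF3
#'
#' Extracts each annotated gene span from the genome on its sense strand,
#' transcribes it to the RNA alphabet, and maps child features (CDS, exon,
#' intron, tRNA, rRNA) into gene-local 1-based coordinates. Genes whose
#' name occurs more than once (the inverted-repeat duplicates) are flagged
#' `ir_duplicate` from the second copy on. When the annotation has gene
#' features without explicit introns, gaps between a gene's exons/CDS are
#' filled in as introns.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff Path to the GFF3 annotation (feature types gene, CDS, exon,
#'   intron, tRNA, rRNA; 1-based inclusive).
#' @return A [PlastidGeneSet-class] object.
#' @export
readPlastidGenes <- function(fasta, gff) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- rtracklayer::import(gff)
  gname <- function(x) {
    nm <- S4Vectors::mcols(x)$Name
    if (is.null(nm)) nm <- S4Vectors::mcols(x)$ID
    as.character(nm)
  }
  genes <- ann[tolower(as.character(ann$type)) == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", gff)
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
  genes <- genes[ord]
  nms <- gname(genes)
  record_id <- make.unique(nms, sep = "#")
  child_types <- c("CDS", "exon", "intron", "tRNA", "rRNA")
  feats <- ann[as.character(ann$type) %in% child_types]
  gene_rows <- list()
  seq_list <- character(length(genes))
  feat_rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    chr <- as.character(GenomicRanges::seqnames(g))
    gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
    strand <- as.character(GenomicRanges::strand(g))
    dna <- Biostrings::subseq(genome[[chr]], gs, ge)
    if (strand == "-") dna <- Biostrings::reverseComplement(dna)
    seq_list[i] <- chartr("T", "U", as.character(dna))
    ov <- feats[as.character(GenomicRanges::seqnames(feats)) == chr &
                  GenomicRanges::start(feats) >= gs &
                  GenomicRanges::end(feats) <= ge]
    if (length(ov)) {
      if (strand == "-") {
        loc_start <- ge - GenomicRanges::end(ov) + 1L
        loc_end <- ge - GenomicRanges::start(ov) + 1L
      } else {
        loc_start <- GenomicRanges::start(ov) - gs + 1L
        loc_end <- GenomicRanges::end(ov) - gs + 1L
      }
      ftab <- data.frame(record_id = record_id[i],
                         type = as.character(ov$type),
                         start = loc_start, end = loc_end,
                         stringsAsFactors = FALSE)
      ftab <- ftab[order(ftab$start), , drop = FALSE]
      # fill unannotated gaps between blocks as introns
      if (!"intron" %in% ftab$type && nrow(ftab) > 1L) {
        gaps <- which(ftab$start[-1L] > ftab$end[-nrow(ftab)] + 1L)
        for (k in gaps) {
          ftab <- rbind(ftab, data.frame(
            record_id = record_id[i], type = "intron",
            start = ftab$end[k] + 1L, end = ftab$start[k + 1L] - 1L,
            stringsAsFactors = FALSE))
        }
        ftab <- ftab[order(ftab$start), , drop = FALSE]
      }
      feat_rows[[length(feat_rows) + 1L]] <- ftab
    }
    gene_rows[[i]] <- data.frame(record_id = record_id[i],
                                 gene_name = nms[i],
                                 ir_duplicate = duplicated(nms)[i],
                                 stringsAsFactors = FALSE)
  }
  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else NULL
  plastidGeneSet(do.call(rbind, gene_rows),
                 Biostrings::RNAStringSet(stats::setNames(
                   seq_list, record_id)),
                 features)
}
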