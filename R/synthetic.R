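#' @importFrom stats rnorm runif
NULL

## Evaluate expr under a derived seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.subSeed <- function(seed, k) (as.integer(seed) %% 199999999L) * 10L + k

## 35-residue scaffold for generated PPR motifs; positions 5 and 35 carry
## the planted code residues in code-bearing motifs.
.MOTIF_SCAFFOLD <- "VTYNTLIDGLCKAGRVDEALELFREMVERGIVPDV"

## Default class mix: the observed subfamily/class composition of the
## 1581-sequence Agave cohort (758 P, 344 E2, 227 PLS, 176 DYW, 63 E+,
## 13 E1), expressed as exact fractions so proportions sum to 1.
.DEFAULT_CLASS_MIX <- c(P = 758, E2 = 344, PLS = 227, DYW = 176,
                        `E+` = 63, E1 = 13) / 1581

#' Specification for the synthetic-data generators
#'
#' Collects every tunable of the synthetic cohort, genome and qPCR
#' generators with the study-condition defaults: the class mix of the
#' observed 1581-sequence cohort, 35-residue motifs, the four inverted-
#' repeat gene duplicates (rps12, rrn23, ycf2, trnI-GAU), and four tissues
#' (GL, GM, AL, AM) with leaf-dominant albino overexpression.
#'
#' @param seed Mandatory integer seed; every generator derives its own
#'   stream from it.
#' @param n_sequences Cohort size (default 200).
#' @param class_mix Named proportions over P, PLS, E1, E2, E+, DYW
#'   (must sum to 1).
#' @param motif_length Motif length in residues (default 35).
#' @param score_noise_sd SD of Gaussian noise added to hit scores
#'   (default 1 bit; 0 gives noise-free tables).
#' @param genome list: `n_genes`, `intron_probability`, `ir_gene_names`,
#'   `planted_sites` (sites planted per pattern).
#' @param qpcr list: `fold_changes` (named per-tissue fold relative to the
#'   GL calibrator), `ct_noise_sd` (cycles), `replicates`,
#'   `reference_genes`.
#' @return list of class `synthetic_spec`.
#' @export
syntheticSpec <- function(seed,
                          n_sequences = 200L,
                          class_mix = .DEFAULT_CLASS_MIX,
                          motif_length = 35L,
                          score_noise_sd = 1,
                          genome = list(),
                          qpcr = list()) {
  if (missing(seed)) stop("a seed is mandatory")
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1")
  stopifnot(all(names(class_mix) %in% c("P", "PLS", "E1", "E2", "E+",
                                        "DYW")))
  genome <- utils::modifyList(list(
    n_genes = 30L, intron_probability = 0.3,
    ir_gene_names = c("rps12", "rrn23", "ycf2", "trnI-GAU"),
    planted_sites = 1L), genome)
  qpcr <- utils::modifyList(list(
    fold_changes = c(GL = 1, GM = 0.6, AL = 4, AM = 1.8),
    ct_noise_sd = 0.2, replicates = 3L,
    reference_genes = c("actin", "tubulin", "18S")), qpcr)
  structure(list(seed = as.integer(seed),
                 n_sequences = as.integer(n_sequences),
                 class_mix = class_mix,
                 motif_length = as.integer(motif_length),
                 score_noise_sd = score_noise_sd,
                 genome = genome, qpcr = qpcr),
            class = "synthetic_spec")
}

.BASE_SCORES <- c(P = 15, P1 = 15, L1 = 15, S1 = 15, P2 = 15, L2 = 15,
                  S2 = 15, SS = 18, E1 = 12, E2 = 12, DYW = 45, `E+` = 12)

## Consensus (argmax) string of a RegionPwm.
.pwmConsensus <- function(pwm) {
  paste(rownames(pwm@matrix)[apply(pwm@matrix, 2, which.max)],
        collapse = "")
}

## Full or truncated DYW domain text from the packaged region consensi,
## at the canonical offsets (PG 1, active 68, C-terminal 112).
.dywDomainText <- function(pwms, truncated = FALSE) {
  pg <- .pwmConsensus(pwms$PG_box)
  if (truncated) return(pg)
  act <- .pwmConsensus(pwms$active_site)
  ct <- .pwmConsensus(pwms$C_terminal)
  linker1 <- strrep("G", 68L - nchar(pg) - 1L)
  linker2 <- strrep("G", 112L - 68L - nchar(act))
  paste0(pg, linker1, act, linker2, ct)
}

#' Generate a synthetic PPR cohort with ground truth
#'
#' Builds `n_sequences` proteins by concatenating motif scaffold blocks
#' according to a class drawn from `class_mix`: P-subfamily proteins carry
#' 3-12 canonical P motifs; PLS-subfamily proteins carry 2-4 P1-L1-S1
#' triads plus the class-defining C-terminus (E1, E1+E2, a truncated DYW
#' domain with PG box for E+, or a full DYW domain). Code-bearing motifs
#' get a code pair planted at their 5th and last residues, drawn from the
#' packaged code table. The hit table reports exact motif coordinates with
#' `score = base + N(0, score_noise_sd)`. Regeneration under the same spec
#' is byte-identical.
#'
#' @param spec A [syntheticSpec()] object.
#' @return list with `proteins` ([Biostrings::AAStringSet]), `hits`
#'   (data.frame in [readHitTable()] layout), `truth` (one row per
#'   sequence: planted class/subfamily, motif string, DYW grade, counts),
#'   and `code_pairs` (named list of per-motif code-pair data.frames).
#' @export
genPprCohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pwms <- dywRegionPwms()
  code <- pprCodeTable()
  .withSeed(.subSeed(spec$seed, 1L), {
    classes <- sample(names(spec$class_mix), spec$n_sequences,
                      replace = TRUE, prob = spec$class_mix)
    seqs <- character(spec$n_sequences)
    ids <- sprintf("synthPPR%04d", seq_len(spec$n_sequences))
    hit_rows <- list()
    truth_rows <- list()
    code_pairs <- list()
    for (i in seq_len(spec$n_sequences)) {
      cls <- classes[i]
      motifs <- switch(cls,
        P = rep("P", sample(3:12, 1L)),
        PLS = rep(c("P1", "L1", "S1"), sample(2:4, 1L)),
        E1 = c(rep(c("P1", "L1", "S1"), sample(2:4, 1L)), "E1"),
        E2 = c(rep(c("P1", "L1", "S1"), sample(2:4, 1L)), "E1", "E2"),
        `E+` = c(rep(c("P1", "L1", "S1"), sample(2:4, 1L)), "E1", "E2"),
        DYW = c(rep(c("P1", "L1", "S1"), sample(2:4, 1L)), "E1", "E2",
                "DYW"))
      dyw_status <- switch(cls, DYW = "full", `E+` = "truncated_with_PG",
                           "absent")
      leader <- "MAS"
      pos <- nchar(leader) + 1L
      blocks <- character()
      rows <- list()
      pair_rows <- list()
      for (m in motifs) {
        if (m == "DYW") {
          block <- .dywDomainText(pwms, truncated = FALSE)
        } else {
          block <- .MOTIF_SCAFFOLD
          if (m %in% .CODE_MOTIFS) {
            k <- sample(nrow(code), 1L)
            substr(block, 5L, 5L) <- code$aa5[k]
            substr(block, nchar(block), nchar(block)) <- code$aalast[k]
            pair_rows[[length(pair_rows) + 1L]] <- data.frame(
              motif_type = m, aa5 = code$aa5[k], aalast = code$aalast[k],
              nucleotides = code$nucleotides[k], stringsAsFactors = FALSE)
          }
        }
        aa_start <- pos
        aa_end <- pos + nchar(block) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = ids[i], motif_type = m, aa_start = aa_start,
          aa_end = aa_end,
          score = .BASE_SCORES[[m]] + stats::rnorm(1L, 0,
                                                   spec$score_noise_sd),
          source_profile = paste0("synth_", m), stringsAsFactors = FALSE)
        blocks <- c(blocks, block)
        pos <- aa_end + 1L
      }
      tail_block <- if (cls == "E+") .dywDomainText(pwms, truncated = TRUE)
      else ""
      seqs[i] <- paste0(leader, paste(blocks, collapse = ""), tail_block)
      hit_rows[[i]] <- do.call(rbind, rows)
      code_pairs[[ids[i]]] <- if (length(pair_rows))
        do.call(rbind, pair_rows) else NULL
      truth_rows[[i]] <- data.frame(
        seq_id = ids[i], class = cls,
        subfamily = if (cls == "P") "P" else "PLS",
        ppr_class = if (cls == "P") "none" else cls,
        motif_string = paste(motifs, collapse = "-"),
        n_motifs = length(motifs), dyw_status = dyw_status,
        length_aa = nchar(seqs[i]), stringsAsFactors = FALSE)
    }
    proteins <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    list(proteins = proteins, hits = do.call(rbind, hit_rows),
         truth = do.call(rbind, truth_rows), code_pairs = code_pairs)
  })
}

.PLASTID_GENE_POOL <- c(
  "psbA", "psbB", "psbC", "psbD", "psaA", "psaB", "petA", "petB", "petN",
  "atpA", "atpB", "atpE", "atpF", "ndhA", "ndhB", "ndhG", "rbcL", "rpoA",
  "rpoB", "rpoC1", "rpoC2", "rps2", "rps4", "rps7", "rps8", "rps11",
  "rps12", "rps14", "rps16", "rpl2", "rpl14", "rpl16", "rpl20", "rpl33",
  "rrn16", "rrn23", "rrn5", "trnK-UUU", "trnI-GAU", "trnL-UAA", "matK",
  "ycf1", "ycf2", "ycf3", "clpP", "ccsA", "cemA", "accD", "infA", "psbE")

#' Generate a toy annotated plastid genome with planted target sites
#'
#' Builds `n_genes` gene records drawn from the standard plastid gene
#' nomenclature (always including the IR gene names), each a uniform-
#' composition RNA of 300-1500 nt: protein genes carry CDS features (split
#' by an intron with probability `intron_probability`), tRNA/rRNA genes
#' carry exon (and intron) features. For each supplied pattern,
#' `planted_sites` windows are overwritten with a draw from the pattern's
#' position sets and recorded in the truth table with their feature
#' context. IR genes are then duplicated verbatim, with `ir_duplicate`
#' flagged on the second copy.
#'
#' @param spec A [syntheticSpec()] object.
#' @param patterns Named list of [DegeneratePattern-class] objects (or
#'   pattern strings), the proteins whose sites to plant; may be empty.
#' @return list with `genes` (a [PlastidGeneSet-class]) and `truth`
#'   (data.frame: `ppr_id`, `gene_name`, `position`, `site`,
#'   `feature_context`, `ir_duplicate`).
#' @export
genPlastidGenome <- function(spec, patterns = list()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- spec$genome
  patterns <- lapply(patterns, function(p)
    if (is.character(p)) parsePattern(p) else p)
  .withSeed(.subSeed(spec$seed, 2L), {
    nm <- unique(c(g$ir_gene_names, .PLASTID_GENE_POOL))[seq_len(g$n_genes)]
    gene_rows <- list()
    feat_rows <- list()
    seqs <- character(length(nm))
    for (i in seq_along(nm)) {
      L <- sample(300:1500, 1L)
      seqs[i] <- paste(sample(.NT_ORDER, L, replace = TRUE),
                       collapse = "")
      is_trn <- startsWith(nm[i], "trn")
      is_rrn <- startsWith(nm[i], "rrn")
      block_type <- if (is_trn || is_rrn) "exon" else "CDS"
      if (stats::runif(1L) < g$intron_probability && L >= 300L) {
        a <- sample(80:(L %/% 3), 1L)
        b <- sample((a + 40L):(2L * L %/% 3), 1L)
        feat <- data.frame(record_id = nm[i],
                           type = c(block_type, "intron", block_type),
                           start = c(1L, a + 1L, b + 1L),
                           end = c(a, b, L), stringsAsFactors = FALSE)
      } else {
        feat <- data.frame(record_id = nm[i], type = block_type,
                           start = 1L, end = L, stringsAsFactors = FALSE)
      }
      gene_rows[[i]] <- data.frame(record_id = nm[i], gene_name = nm[i],
                                   ir_duplicate = FALSE,
                                   stringsAsFactors = FALSE)
      feat_rows[[i]] <- feat
    }
    genes <- do.call(rbind, gene_rows)
    features <- do.call(rbind, feat_rows)
    truth <- list()
    used <- lapply(seq_along(nm), function(i) integer(0))  # occupied nt
    for (pid in names(patterns)) {
      pat <- patterns[[pid]]
      w <- length(pat)
      for (s in seq_len(g$planted_sites)) {
        # rejection-sample a window that does not overlap a prior plant,
        # so every truth record is guaranteed to survive verbatim
        placed <- FALSE
        for (try in 1:100) {
          gi <- sample(length(nm), 1L)
          L <- nchar(seqs[gi])
          if (L < w) next
          at <- sample(L - w + 1L, 1L)
          if (!any(at:(at + w - 1L) %in% used[[gi]])) { placed <- TRUE; break }
        }
        if (!placed) next
        used[[gi]] <- c(used[[gi]], at:(at + w - 1L))
        site <- paste(vapply(patternPositions(pat),
                             function(p) if (length(p) == 1L) p
                             else sample(p, 1L), character(1)),
                      collapse = "")
        substr(seqs[gi], at, at + w - 1L) <- site
        mid <- at + (w - 1L) %/% 2L
        ftab <- features[features$record_id == nm[gi], , drop = FALSE]
        ctx <- ftab$type[ftab$start <= mid & ftab$end >= mid][1L]
        truth[[length(truth) + 1L]] <- data.frame(
          ppr_id = pid, gene_name = nm[gi], position = at, site = site,
          feature_context = ctx,
          ir_duplicate = nm[gi] %in% g$ir_gene_names,
          stringsAsFactors = FALSE)
      }
    }
    # duplicate the IR genes verbatim (after planting, so copies agree)
    for (ir in intersect(g$ir_gene_names, nm)) {
      i <- match(ir, nm)
      rid <- paste0(ir, "#IR")
      genes <- rbind(genes, data.frame(record_id = rid, gene_name = ir,
                                       ir_duplicate = TRUE,
                                       stringsAsFactors = FALSE))
      f <- feat_rows[[i]]
      f$record_id <- rid
      features <- rbind(features, f)
      seqs <- c(seqs, seqs[i])
    }
    gs <- plastidGeneSet(genes,
                         Biostrings::RNAStringSet(stats::setNames(
                           seqs, genes$record_id)),
                         features)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(ppr_id = character(), gene_name = character(),
                 position = integer(), site = character(),
                 feature_context = character(), ir_duplicate = logical(),
                 stringsAsFactors = FALSE)
    list(genes = gs, truth = truth)
  })
}

#' Write a synthetic genome as FASTA + GFF3
#'
#' Concatenates the gene records (alternating strands) into a single
#' chromosome with 50-nt spacers and writes the genome FASTA plus a GFF3
#' with gene and child features, round-trippable through
#' [readPlastidGenes()].
#'
#' @param genome Result of [genPlastidGenome()] (or a
#'   [PlastidGeneSet-class]).
#' @param dir Output directory.
#' @param seed Seed for the spacer composition.
#' @return Named character vector with the `fasta` and `gff` paths.
#' @export
writeSyntheticGenome <- function(genome, dir, seed = 1L) {
  gs <- if (methods::is(genome, "PlastidGeneSet")) genome else genome$genes
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- geneTable(gs)
  seqs <- geneSequences(gs)
  feats <- geneFeatures(gs)
  .withSeed(seed, {
    chrom <- character()
    offset <- 0L
    granges <- list()
    for (i in seq_len(nrow(gt))) {
      spacer <- paste(sample(c("A", "C", "G", "T"), 50L, replace = TRUE),
                      collapse = "")
      rna <- as.character(seqs[[i]])
      dna <- chartr("U", "T", rna)
      strand <- if (i %% 2L == 0L) "-" else "+"
      if (strand == "-")
        dna <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(dna)))
      gs_start <- offset + 51L
      gs_end <- gs_start + nchar(dna) - 1L
      chrom <- c(chrom, spacer, dna)
      offset <- gs_end
      L <- nchar(dna)
      f <- feats[feats$record_id == gt$record_id[i], , drop = FALSE]
      if (strand == "+") {
        fs <- gs_start + f$start - 1L; fe <- gs_start + f$end - 1L
      } else {
        fs <- gs_end - f$end + 1L; fe <- gs_end - f$start + 1L
      }
      granges[[length(granges) + 1L]] <- data.frame(
        start = c(gs_start, fs), end = c(gs_end, fe),
        type = c("gene", f$type), strand = strand,
        name = gt$gene_name[i], stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, granges)
    gr <- GenomicRanges::GRanges("synth_plastome",
                                 IRanges::IRanges(tab$start, tab$end),
                                 strand = tab$strand)
    gr$type <- tab$type
    gr$Name <- tab$name
    gr$ID <- make.unique(paste(tab$name, tab$type, sep = "."))
    fasta <- file.path(dir, "synth_plastome.fa")
    gff <- file.path(dir, "synth_plastome.gff3")
    genome_seq <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
    names(genome_seq) <- "synth_plastome"
    Biostrings::writeXStringSet(genome_seq, fasta)
    rtracklayer::export(gr, gff, format = "gff3")
    c(fasta = fasta, gff = gff)
  })
}

#' Generate a qPCR Ct table from planted fold changes
#'
#' Target Cts follow `ct = base - log2(fold) + N(0, ct_noise_sd)` per
#' tissue and replicate; reference genes are constant across tissues (up
#' to the same noise). With zero noise, [ddct()] returns exactly the
#' planted folds, and the GL calibrator is always 1.
#'
#' @param spec A [syntheticSpec()] object.
#' @param target_genes Character vector of target gene names.
#' @return list with `ct` (data.frame: gene, tissue, replicate, ct) and
#'   `truth` (data.frame: gene, tissue, fold).
#' @export
genCtTable <- function(spec, target_genes = c("AaPPR1", "AaPPR2")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  q <- spec$qpcr
  tissues <- names(q$fold_changes)
  .withSeed(.subSeed(spec$seed, 3L), {
    rows <- list()
    truth <- list()
    ref_base <- stats::setNames(
      20 + seq_along(q$reference_genes), q$reference_genes)
    for (gene in target_genes) {
      base <- 26
      for (tt in tissues) {
        fold <- q$fold_changes[[tt]]
        for (r in seq_len(q$replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = gene, tissue = tt, replicate = r,
            ct = base - log2(fold) + stats::rnorm(1L, 0, q$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          gene = gene, tissue = tt, fold = fold, stringsAsFactors = FALSE)
      }
    }
    for (ref in q$reference_genes) {
      for (tt in tissues) {
        for (r in seq_len(q$replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = ref, tissue = tt, replicate = r,
            ct = ref_base[[ref]] + stats::rnorm(1L, 0, q$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(ct = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Generate ortholog, predictor and differential-expression tables
#'
#' Plants per-sequence memberships at the study rates: 282/1581 of
#' sequences get a chloroplast localization (half via predictor consensus,
#' half via a "chloroplastic" subject-title keyword) and 222/1581 are
#' differentially expressed. Best-hit identities are drawn Uniform(50, 95)
#' for kept sequences; a `drop_identity` fraction (default 0) instead gets
#' identities below 50 to exercise the ortholog filter.
#'
#' @param spec A [syntheticSpec()] object.
#' @param seq_ids Sequence identifiers to annotate.
#' @param chloroplast_rate,de_rate Planting rates (defaults 282/1581 and
#'   222/1581).
#' @param drop_identity Fraction of sequences given sub-threshold best-hit
#'   identity.
#' @return list with `ortholog_hits`, `predictor_rows`, `de_table` and
#'   `truth` (data.frame: seq_id, chloroplast, de_significant,
#'   low_identity).
#' @export
genAnnotationTables <- function(spec, seq_ids,
                                chloroplast_rate = 282 / 1581,
                                de_rate = 222 / 1581,
                                drop_identity = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- length(seq_ids)
  .withSeed(.subSeed(spec$seed, 4L), {
    chloro <- stats::runif(n) < chloroplast_rate
    de <- stats::runif(n) < de_rate
    lowid <- stats::runif(n) < drop_identity
    via_pred <- chloro & (stats::runif(n) < 0.5)
    species <- sample(c("Asparagus officinalis", "Elaeis guineensis",
                        "Phoenix dactylifera", "Dendrobium catenatum"),
                      n, replace = TRUE,
                      prob = c(0.45, 0.3, 0.15, 0.1))
    title <- ifelse(chloro & !via_pred,
                    "pentatricopeptide repeat-containing protein, chloroplastic",
                    "pentatricopeptide repeat-containing protein")
    hits <- data.frame(
      query_id = seq_ids,
      subject_id = sprintf("XP_%07d", sample(1e6, n)),
      subject_title = title,
      identity_pct = ifelse(lowid, stats::runif(n, 30, 49.9),
                            stats::runif(n, 50, 95)),
      bitscore = stats::runif(n, 200, 900),
      evalue = 10^stats::runif(n, -180, -20),
      subject_species = species, stringsAsFactors = FALSE)
    pred_rows <- list()
    for (i in which(via_pred)) {
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        query_id = seq_ids[i],
        predictor = c("predotar", "targetp"),
        compartment = "plastid", stringsAsFactors = FALSE)
    }
    predictor_rows <- if (length(pred_rows)) do.call(rbind, pred_rows)
    else data.frame(query_id = character(), predictor = character(),
                    compartment = character(), stringsAsFactors = FALSE)
    de_table <- data.frame(seq_id = seq_ids[de], comparison = "GL_vs_AL",
                           log2fc = round(stats::runif(sum(de), 1, 4), 2),
                           significant = TRUE, stringsAsFactors = FALSE)
    list(ortholog_hits = hits, predictor_rows = predictor_rows,
         de_table = de_table,
         truth = data.frame(seq_id = seq_ids, chloroplast = chloro,
                            de_significant = de, low_identity = lowid,
                            stringsAsFactors = FALSE))
  })
}
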