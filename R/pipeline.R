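#' Pipeline configuration
#'
#' Collects every stage threshold with its study default: minimum ORF
#' length 31 aa, SS/DYW score cutoffs 10/30 bits, array sum-score cutoff
#' 40 bits, ortholog identity cutoff 50%, PWM scan p-value cutoff 1e-5,
#' promiscuity threshold 60 targets, ORF join gap 90 nt, inter-motif gap
#' 50 aa. The configuration is serialized into every run manifest.
#'
#' @param min_aa,ss_min,dyw_min,sum_score_min,identity_min,fimo_p,
#'   promiscuity,max_join_gap,max_intermotif_gap Stage thresholds.
#' @param calibrator Calibrator tissue for qPCR (default GL).
#' @param reference_genes qPCR reference genes.
#' @param stages Stage toggles: subset of `classify`, `localize`,
#'   `targets`, `qpcr`. Disabling a stage a later stage depends on is a
#'   dependency error at run time.
#' @param seed Seed forwarded to synthetic generation.
#' @return list of class `ppr_pipeline_config`.
#' @export
pipelineConfig <- function(min_aa = 31L, ss_min = 10, dyw_min = 30,
                           sum_score_min = 40, identity_min = 50,
                           fimo_p = 1e-5, promiscuity = 60L,
                           max_join_gap = 90L, max_intermotif_gap = 50L,
                           calibrator = "GL",
                           reference_genes = c("actin", "tubulin", "18S"),
                           stages = c("classify", "localize", "targets",
                                      "qpcr"),
                           seed = 1L) {
  stopifnot(all(stages %in% c("classify", "localize", "targets", "qpcr")))
  cfg <- list(min_aa = min_aa, ss_min = ss_min, dyw_min = dyw_min,
              sum_score_min = sum_score_min, identity_min = identity_min,
              fimo_p = fimo_p, promiscuity = promiscuity,
              max_join_gap = max_join_gap,
              max_intermotif_gap = max_intermotif_gap,
              calibrator = calibrator, reference_genes = reference_genes,
              stages = stages, seed = seed)
  stopifnot(all(vapply(cfg[1:9], function(x) is.numeric(x) && x > 0,
                       logical(1))))
  structure(cfg, class = "ppr_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipelineConfig()] defaults.
#' @return A `ppr_pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
  overrides <- yaml::read_yaml(path)
  do.call(pipelineConfig, overrides)
}

## Grade DYW completeness for every protein in an AAStringSet, scanning
## the C-terminal tail (last `tail_aa` residues).
.cohortDywStatus <- function(proteins, pwms = dywRegionPwms(),
                             p_cutoff = 1e-5, tail_aa = 200L) {
  vapply(seq_along(proteins), function(i) {
    s <- as.character(proteins[[i]])
    n <- nchar(s)
    gradeDyw(substr(s, max(1L, n - tail_aa + 1L), n), pwms = pwms,
             p_cutoff = p_cutoff)
  }, character(1)) |>
    stats::setNames(names(proteins))
}

#' Run the full discovery pipeline on a synthetic cohort
#'
#' Executes every stage in order on generated data with known ground
#' truth: cohort generation, hit filtering, overlap resolution,
#' DYW grading, validation/classification, ortholog and localization
#' filtering, validation-set selection, PPR-code pattern compilation,
#' plastid genome generation with planted sites, target search with
#' promiscuity flagging, and qPCR quantification. Returns every
#' intermediate table plus a funnel report in which
#' `retained + discarded = input` at every stage, and a JSON-serializable
#' manifest of thresholds and seeds.
#'
#' @param spec A [syntheticSpec()] object.
#' @param config A [pipelineConfig()] object.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV/JSON (timestamp-free, so reruns are byte-identical).
#' @return list with `cohort`, `arrays`, `dyw_status`, `annotations`,
#'   `funnel`, `best_hits`, `localization`, `selected`, `patterns`,
#'   `genome`, `targets`, `promiscuous`, `qpcr`, `manifest`.
#' @export
runPipeline <- function(spec, config = pipelineConfig(seed = spec$seed),
                        out_dir = NULL) {
  on <- function(stage) stage %in% config$stages
  deps <- list(localize = "classify", targets = c("classify", "localize"),
               qpcr = c("classify", "localize"))
  for (stage in intersect(names(deps), config$stages)) {
    missing <- setdiff(deps[[stage]], config$stages)
    if (length(missing))
      stop("stage '", stage, "' requires disabled stage(s): ",
           paste(missing, collapse = ", "))
  }
  cohort <- genPprCohort(spec)
  if (!on("classify")) {
    return(list(cohort = cohort,
                manifest = list(config = unclass(config),
                                seed = spec$seed,
                                counts = list(input = spec$n_sequences))))
  }
  hits <- filterHits(cohort$hits, ss_min = config$ss_min,
                     dyw_min = config$dyw_min)
  arrays <- lapply(split(hits, hits$seq_id), resolveOverlaps)
  pwms <- dywRegionPwms()
  dyw_status <- .cohortDywStatus(cohort$proteins, pwms,
                                 p_cutoff = config$fimo_p)
  annotations <- annotateCohort(arrays, dyw_status = dyw_status,
                                sum_score_min = config$sum_score_min,
                                max_intermotif_gap =
                                  config$max_intermotif_gap)
  if (!on("localize")) {
    funnel <- summarizeFunnel(annotations)
    return(list(cohort = cohort, arrays = arrays,
                dyw_status = dyw_status, annotations = annotations,
                funnel = funnel,
                manifest = list(config = unclass(config),
                                seed = spec$seed,
                                counts = list(
                                  input = nrow(annotations),
                                  retained = sum(annotations$fate ==
                                                   "retained")))))
  }
  ann <- genAnnotationTables(spec, annotations$seq_id)
  best <- selectBestHits(ann$ortholog_hits,
                         min_identity = config$identity_min)
  dropped_ids <- setdiff(annotations$seq_id, best$query_id)
  annotations$fate[annotations$seq_id %in% dropped_ids &
                     annotations$fate == "retained"] <- "discarded"
  annotations$discard_reason[annotations$seq_id %in% dropped_ids &
                               annotations$discard_reason == "none"] <-
    "low_identity_ortholog"
  annotations$subfamily[annotations$fate == "discarded"] <- "none"
  annotations$ppr_class[annotations$fate == "discarded"] <- "none"
  loc <- inferLocalization(ann$predictor_rows, best)
  lengths_aa <- stats::setNames(
    Biostrings::width(cohort$proteins), names(cohort$proteins))
  funnel <- summarizeFunnel(annotations, lengths_aa = lengths_aa)
  # synthetic proteins are single complete ORFs by construction
  completeness <- data.frame(seq_id = annotations$seq_id,
                             complete = annotations$fate == "retained",
                             stringsAsFactors = FALSE)
  selected <- selectForValidation(completeness, loc, ann$de_table)
  retained <- annotations$seq_id[annotations$fate == "retained"]
  patterns <- list()
  genome <- NULL
  promiscuous <- character()
  empty_hits <- data.frame(ppr_id = character(), gene_name = character(),
                           feature_context = character(),
                           match_start = integer(),
                           matched_sequence = character(),
                           ir_flagged = logical(), stringsAsFactors = FALSE)
  target_hits <- headline <- empty_hits
  if (on("targets")) {
    code_table <- pprCodeTable()
    for (sid in intersect(selected, retained)) {
      p <- pprPattern(arrays[[sid]],
                      as.character(cohort$proteins[[sid]]),
                      code_table = code_table)
      if (!is.null(p)) patterns[[sid]] <- p
    }
    genome <- genPlastidGenome(spec, patterns = patterns)
    target_hits <- do.call(rbind, c(lapply(names(patterns), function(pid)
      searchTargets(patterns[[pid]], genome$genes, ppr_id = pid)),
      list(empty_hits)))
    promiscuous <- flagPromiscuous(split(target_hits,
                                         target_hits$ppr_id),
                                   threshold = config$promiscuity)
    headline <- target_hits[!target_hits$ppr_id %in% promiscuous, ,
                            drop = FALSE]
  }
  ctgen <- if (on("qpcr"))
    genCtTable(spec, target_genes = utils::head(selected, 2L))
  else list(ct = data.frame())
  qpcr <- if (nrow(ctgen$ct)) {
    tg <- unique(ctgen$truth$gene)
    do.call(rbind, lapply(tg, function(g) {
      out <- ddct(ctgen$ct, g, references = spec$qpcr$reference_genes,
                  calibrator = config$calibrator)
      out$gene <- g
      out
    }))
  } else NULL
  manifest <- list(config = unclass(config), seed = spec$seed,
                   n_sequences = spec$n_sequences,
                   counts = list(
                     input = nrow(annotations),
                     retained = sum(annotations$fate == "retained"),
                     discarded = sum(annotations$fate == "discarded"),
                     selected_for_validation = length(selected),
                     patterns = length(patterns),
                     target_hits = nrow(target_hits),
                     promiscuous = length(promiscuous)))
  result <- list(cohort = cohort, arrays = arrays,
                 dyw_status = dyw_status, annotations = annotations,
                 funnel = funnel, best_hits = best, localization = loc,
                 selected = selected, patterns = patterns,
                 genome = genome, targets = headline,
                 all_targets = target_hits, promiscuous = promiscuous,
                 qpcr = qpcr, manifest = manifest)
  if (!is.null(out_dir)) .writePipelineOutputs(result, out_dir)
  result
}

.writePipelineOutputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tab, name) if (!is.null(tab) && nrow(tab))
    utils::write.table(tab, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(result$annotations, "annotations.tsv")
  w(result$targets, "targets.tsv")
  w(result$qpcr, "relative_expression.tsv")
  w(result$funnel$by_class, "funnel_by_class.tsv")
  pat <- data.frame(ppr_id = names(result$patterns),
                    pattern = vapply(result$patterns, patternText, ""),
                    stringsAsFactors = FALSE)
  w(pat, "patterns.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Format a target report in the curated-table dialect
#'
#' One row per hit with the pattern, gene, feature context, the matched
#' sequence in 5'-...-3' notation and an asterisk on IR-duplicated genes.
#'
#' @param target_hits data.frame from [searchTargets()].
#' @param patterns Named list of patterns by `ppr_id`.
#' @return data.frame with display columns.
#' @export
formatTargetReport <- function(target_hits, patterns) {
  if (nrow(target_hits) == 0L)
    return(data.frame(ppr_id = character(), pattern = character(),
                      gene = character(), context = character(),
                      target = character(), stringsAsFactors = FALSE))
  data.frame(
    ppr_id = target_hits$ppr_id,
    pattern = vapply(target_hits$ppr_id, function(p)
      if (p %in% names(patterns)) patternText(patterns[[p]]) else "",
      character(1)),
    gene = paste0(target_hits$gene_name,
                  ifelse(target_hits$ir_flagged, "*", "")),
    context = target_hits$feature_context,
    target = sprintf("5'-%s-3'", target_hits$matched_sequence),
    stringsAsFactors = FALSE, row.names = NULL)
}
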