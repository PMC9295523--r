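.DISCARD_REASONS <- c("single_motif", "low_sum_score", "no_classic_array",
                      "standalone_DYW_no_PGbox", "E+_no_PGbox",
                      "low_identity_ortholog", "joined_hypothetical", "none")

#' Validate a tandem array against the retention filters
#'
#' A resolved array survives iff it has more than one motif (a single motif
#' is discarded unless it is a DYW domain, whose fate is decided by the
#' PG-box rule downstream), its summed score strictly exceeds
#' `sum_score_min`, and no two adjacent motifs are separated by more than
#' `max_intermotif_gap` residues (the "classic array" continuity rule).
#'
#' @param array A [MotifArray-class] object.
#' @param sum_score_min Strict sum-score cutoff (default 40 bits).
#' @param max_intermotif_gap Maximum residue gap between adjacent motifs
#'   (default 50).
#' @param dyw_status DYW-domain grade for the sequence (`"absent"`,
#'   `"truncated_with_PG"` or `"full"`), used to adjudicate single-DYW
#'   arrays and E+-type arrays lacking a PG box.
#' @return list with `ok` (logical) and `reason` (one of the discard-reason
#'   codes, `"none"` when retained).
#' @examples
#' arr <- MotifArray("s", data.frame(motif_type = "P", aa_start = 1,
#'                                   aa_end = 35, score = 55))
#' validateArray(arr)
#' @export
validateArray <- function(array, sum_score_min = 40,
                          max_intermotif_gap = 50L,
                          dyw_status = c("absent", "truncated_with_PG",
                                         "full")) {
  dyw_status <- match.arg(dyw_status)
  h <- motifHits(array)
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (nrow(h) == 0L) return(fail("single_motif"))
  if (nrow(h) == 1L) {
    if (h$motif_type != "DYW") return(fail("single_motif"))
    # standalone DYW survives only with at least a PG box
    if (dyw_status == "absent") return(fail("standalone_DYW_no_PGbox"))
    return(list(ok = TRUE, reason = "none"))
  }
  if (sumScore(array) <= sum_score_min) return(fail("low_sum_score"))
  gaps <- h$aa_start[-1L] - h$aa_end[-nrow(h)] - 1L
  if (any(gaps > max_intermotif_gap)) return(fail("no_classic_array"))
  if ("E+" %in% h$motif_type && dyw_status == "absent")
    return(fail("E+_no_PGbox"))
  list(ok = TRUE, reason = "none")
}

#' Classify a valid array into subfamily and class
#'
#' Subfamily P holds arrays composed only of canonical P motifs (an
#' auxiliary SMR domain is allowed and recorded, not a motif); any
#' PLS-triad variant, SS, E or DYW motif — or a graded DYW/E+ domain —
#' places the sequence in the PLS subfamily. Within PLS, class follows the
#' C-terminal composition: `DYW` when the graded domain is full, `E+` when
#' it is truncated but keeps the PG box (with at least one N-terminal PPR
#' motif), `E2` when E2 motifs are present without a DYW domain, `E1` when
#' E1 is present without E2, and `PLS` otherwise. Classification is a pure
#' function of the array and the DYW grade.
#'
#' @param array A [MotifArray-class] object (assumed validated).
#' @param dyw_status `"absent"`, `"truncated_with_PG"` or `"full"`.
#' @param aux_domains Character vector of auxiliary domain labels (e.g.
#'   `"SMR"`).
#' @param fate,discard_reason Fate bookkeeping carried into the annotation.
#' @return One-row data.frame: `seq_id`, `subfamily` (P/PLS/none),
#'   `ppr_class` (none/PLS/E1/E2/E+/DYW), `motif_count`, `motif_string`,
#'   `sum_score`, `aux_domains`, `fate`, `discard_reason`.
#' @examples
#' arr <- MotifArray("s", data.frame(
#'   motif_type = c("P1", "L1", "S1", "E1", "E2"),
#'   aa_start = c(1, 36, 71, 103, 137), aa_end = c(35, 70, 102, 136, 170),
#'   score = rep(15, 5)))
#' classifyArray(arr, dyw_status = "absent")
#' @export
classifyArray <- function(array,
                          dyw_status = c("absent", "truncated_with_PG",
                                         "full"),
                          aux_domains = character(),
                          fate = "retained", discard_reason = "none") {
  dyw_status <- match.arg(dyw_status)
  types <- motifHits(array)$motif_type
  n <- length(types)
  pure_p <- n > 0L && all(types == "P")
  is_pls <- any(types %in% c(.PLS_MOTIFS, "E1", "E2", "DYW", "E+")) ||
    dyw_status != "absent"
  if (pure_p && is_pls && dyw_status != "absent")
    message("pure-P array ", seqId(array),
            " carries a graded DYW/E+ domain; classified PLS")
  subfamily <- if (fate == "discarded") "none"
  else if (is_pls) "PLS"
  else if (pure_p) "P"
  else "none"
  ppr_class <- "none"
  if (subfamily == "PLS") {
    has_nterm_ppr <- any(types %in% c("P", .PLS_MOTIFS))
    ppr_class <-
      if (dyw_status == "full") "DYW"
      else if (dyw_status == "truncated_with_PG" &&
               (has_nterm_ppr || "E+" %in% types)) "E+"
      else if ("E2" %in% types) "E2"
      else if ("E1" %in% types) "E1"
      else "PLS"
  }
  data.frame(seq_id = seqId(array), subfamily = subfamily,
             ppr_class = ppr_class, motif_count = n,
             motif_string = motifString(array), sum_score = sumScore(array),
             aux_domains = paste(aux_domains, collapse = ","),
             fate = fate, discard_reason = discard_reason,
             stringsAsFactors = FALSE)
}

#' Annotate a cohort of arrays: validate, grade and classify
#'
#' Applies [validateArray()] and [classifyArray()] to each array.
#' Discarded sequences get `subfamily = "none"`, `ppr_class = "none"` and
#' their discard reason; reasons partition the discards and every input
#' appears exactly once.
#'
#' @param arrays Named list of [MotifArray-class] objects.
#' @param dyw_status Named character vector of DYW grades per seq_id
#'   (missing ids default to `"absent"`).
#' @param aux_domains Named list of auxiliary-domain character vectors.
#' @param sum_score_min,max_intermotif_gap Filter thresholds, see
#'   [validateArray()].
#' @return data.frame with one row per array (see [classifyArray()]).
#' @export
annotateCohort <- function(arrays, dyw_status = NULL, aux_domains = NULL,
                           sum_score_min = 40, max_intermotif_gap = 50L) {
  rows <- lapply(arrays, function(a) {
    ds <- if (!is.null(dyw_status) && seqId(a) %in% names(dyw_status))
      dyw_status[[seqId(a)]] else "absent"
    aux <- if (!is.null(aux_domains) && seqId(a) %in% names(aux_domains))
      aux_domains[[seqId(a)]] else character()
    v <- validateArray(a, sum_score_min = sum_score_min,
                       max_intermotif_gap = max_intermotif_gap,
                       dyw_status = ds)
    if (v$ok)
      classifyArray(a, dyw_status = ds, aux_domains = aux)
    else
      classifyArray(a, dyw_status = ds, aux_domains = aux,
                    fate = "discarded", discard_reason = v$reason)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    seq_id = character(), subfamily = character(),
    ppr_class = character(), motif_count = integer(),
    motif_string = character(), sum_score = numeric(),
    aux_domains = character(), fate = character(),
    discard_reason = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Summarize the classification funnel
#'
#' Emits counts and percentages by subfamily and class over retained
#' sequences, a motif-count histogram by subfamily and a length histogram
#' when lengths are supplied. Percentages sum to 100 over retained
#' sequences.
#'
#' @param annotations Annotation data.frame from [annotateCohort()].
#' @param lengths_aa Optional named integer vector of protein lengths.
#' @return list with `by_class` (subfamily/class counts and percentages),
#'   `fates` (retained/discarded counts by reason), `motif_histogram`, and
#'   optionally `length_summary`.
#' @export
summarizeFunnel <- function(annotations, lengths_aa = NULL) {
  if (nrow(annotations) == 0L) {
    return(list(by_class = data.frame(subfamily = character(),
                                      ppr_class = character(),
                                      n = integer(), pct = numeric()),
                fates = data.frame(fate = character(), reason = character(),
                                   n = integer()),
                motif_histogram = data.frame(subfamily = character(),
                                             motif_count = integer(),
                                             n = integer())))
  }
  kept <- annotations[annotations$fate == "retained", , drop = FALSE]
  by_class <- as.data.frame(table(subfamily = kept$subfamily,
                                  ppr_class = kept$ppr_class),
                            stringsAsFactors = FALSE)
  names(by_class)[3] <- "n"
  by_class <- by_class[by_class$n > 0L, , drop = FALSE]
  by_class$pct <- 100 * by_class$n / max(1L, nrow(kept))
  by_class <- by_class[order(-by_class$n), ]
  fates <- as.data.frame(table(fate = annotations$fate,
                               reason = annotations$discard_reason),
                         stringsAsFactors = FALSE)
  names(fates)[3] <- "n"
  fates <- fates[fates$n > 0L, , drop = FALSE]
  hist <- as.data.frame(table(subfamily = kept$subfamily,
                              motif_count = kept$motif_count),
                        stringsAsFactors = FALSE)
  names(hist)[3] <- "n"
  hist <- hist[hist$n > 0L, , drop = FALSE]
  hist$motif_count <- as.integer(hist$motif_count)
  out <- list(by_class = by_class, fates = fates, motif_histogram = hist)
  if (!is.null(lengths_aa)) {
    ids <- intersect(kept$seq_id, names(lengths_aa))
    ll <- as.numeric(lengths_aa[ids])
    out$length_summary <- data.frame(n = length(ll), min = min(ll),
                                     mean = mean(ll), max = max(ll))
  }
  rownames(out$by_class) <- rownames(out$fates) <-
    rownames(out$motif_histogram) <- NULL
  out
}
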