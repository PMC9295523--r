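#' Select best ortholog hits and apply the identity filter
#'
#' Per query, the hit with the highest bitscore wins (ties broken by lowest
#' E-value, then lexicographic subject id). Queries whose best hit falls
#' below `min_identity` percent identity are dropped — the filter is
#' non-strict, so exactly 50.0% identity is retained at the default.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`,
#'   `subject_title`, `identity_pct`, `bitscore`, `evalue` and optionally
#'   `subject_species` (BLAST outfmt-6 style).
#' @param min_identity Minimum percent identity of the best hit
#'   (default 50).
#' @return data.frame of best hits, one row per retained query, ordered by
#'   `query_id`.
#' @export
selectBestHits <- function(hits, min_identity = 50) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  out <- best[best$identity_pct >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.normalizeCompartment <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("other", length(x))
  out[x %in% c("chloroplast", "plastid", "chloroplastic", "c", "ctp", "p")] <-
    "chloroplast"
  out[x %in% c("mitochondrion", "mitochondria", "mitochondrial", "m",
               "mtp")] <- "mitochondrion"
  out[x %in% c("", "none", "unknown", "-", "_", "na")] <- "unknown"
  out
}

#' Infer subcellular localization with a keyword fallback
#'
#' For each query with a best ortholog hit: when both targeting-signal
#' predictors agree on a compartment, that consensus is called with
#' `basis = "predictor"`; a single confident predictor (the other absent or
#' uninformative) also counts as consensus. When predictors are absent or
#' discordant, the ortholog's subject title is scanned case-insensitively
#' for the keyword `chloroplast` (matching `chloroplastic` too) and a hit
#' is called with `basis = "keyword"`. Otherwise the call is `unknown`
#' with `basis = "none"`.
#'
#' @param predictor_rows data.frame with columns `query_id`, `predictor`,
#'   `compartment` (may be empty or NULL).
#' @param best_hits Best-hit data.frame from [selectBestHits()].
#' @return data.frame with columns `query_id`, `call`
#'   (chloroplast/mitochondrion/other/unknown), `basis`
#'   (predictor/keyword/none), one row per query in `best_hits`.
#' @export
inferLocalization <- function(predictor_rows, best_hits) {
  if (is.null(predictor_rows))
    predictor_rows <- data.frame(query_id = character(),
                                 predictor = character(),
                                 compartment = character(),
                                 stringsAsFactors = FALSE)
  calls <- lapply(seq_len(nrow(best_hits)), function(i) {
    q <- best_hits$query_id[i]
    pr <- predictor_rows[predictor_rows$query_id == q, , drop = FALSE]
    comp <- .normalizeCompartment(pr$compartment)
    comp <- comp[comp != "unknown"]
    if (length(comp) > 0L && length(unique(comp)) == 1L) {
      return(data.frame(query_id = q, call = comp[1L],
                        basis = "predictor", stringsAsFactors = FALSE))
    }
    title <- best_hits$subject_title[i]
    if (!is.na(title) && grepl("chloroplast", title, ignore.case = TRUE)) {
      return(data.frame(query_id = q, call = "chloroplast",
                        basis = "keyword", stringsAsFactors = FALSE))
    }
    data.frame(query_id = q, call = "unknown", basis = "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(calls, list(
    data.frame(query_id = character(), call = character(),
               basis = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Tally best-hit species
#'
#' Side report of how many queries hit each subject species; no threshold
#' is applied.
#'
#' @param best_hits Best-hit data.frame with a `subject_species` column.
#' @return data.frame with columns `species`, `n`, `pct`, sorted by
#'   descending count.
#' @export
speciesTally <- function(best_hits) {
  if (nrow(best_hits) == 0L || is.null(best_hits$subject_species))
    return(data.frame(species = character(), n = integer(),
                      pct = numeric()))
  tt <- sort(table(best_hits$subject_species), decreasing = TRUE)
  data.frame(species = names(tt), n = as.integer(tt),
             pct = 100 * as.integer(tt) / nrow(best_hits),
             stringsAsFactors = FALSE, row.names = NULL)
}
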