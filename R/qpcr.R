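.TISSUES <- c("GL", "GM", "AL", "AM")

#' Read a qPCR Ct table
#'
#' @param path CSV with columns `gene`, `tissue`, `replicate`, `ct`.
#' @return data.frame of Ct records; Ct values outside (0, 45) cycles are
#'   rejected.
#' @export
readCtTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "tissue", "replicate", "ct")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("Ct table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0 | tab$ct >= 45))
    stop("Ct values must lie in (0, 45) cycles")
  tab
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged at the Ct level. For each tissue,
#' `dCt = mean Ct(target) - mean over reference genes of mean Ct(ref)`;
#' `ddCt = dCt(tissue) - dCt(calibrator)`; relative expression is
#' `2^(-ddCt)`. The calibrator tissue therefore maps to exactly 1. With
#' several reference genes, per-gene mean Cts are averaged arithmetically
#' (equivalent to a geometric mean of the linear reference quantities).
#' Adding a constant to every Ct leaves the result unchanged.
#'
#' @param records Ct data.frame (see [readCtTable()]).
#' @param target Target gene name.
#' @param references Character vector of reference gene names.
#' @param calibrator Calibrator tissue (default `"GL"`).
#' @return data.frame with columns `tissue`, `d_ct`, `dd_ct`, `rel_expr`,
#'   `sem_ct` (standard error of the target mean Ct, for plotting).
#' @examples
#' ct <- expand.grid(gene = c("tgt", "ref"), tissue = c("GL", "AL"),
#'                   replicate = 1:3, stringsAsFactors = FALSE)
#' ct$ct <- ifelse(ct$gene == "ref", 20, ifelse(ct$tissue == "AL", 23, 25))
#' ddct(ct, "tgt", "ref", calibrator = "GL")
#' @export
ddct <- function(records, target, references, calibrator = "GL") {
  tissues <- unique(records$tissue)
  if (!calibrator %in% tissues)
    stop("calibrator tissue '", calibrator, "' has no Ct records")
  meanCt <- function(gene, tissue) {
    x <- records$ct[records$gene == gene & records$tissue == tissue]
    if (length(x) == 0L)
      stop("no Ct measurements for gene '", gene, "' in tissue '", tissue,
           "'")
    mean(x)
  }
  d_ct <- vapply(tissues, function(tt) {
    ref_mean <- mean(vapply(references, meanCt, numeric(1), tissue = tt))
    meanCt(target, tt) - ref_mean
  }, numeric(1))
  sem <- vapply(tissues, function(tt) {
    x <- records$ct[records$gene == target & records$tissue == tt]
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  }, numeric(1))
  dd_ct <- d_ct - d_ct[[calibrator]]
  data.frame(tissue = tissues, d_ct = unname(d_ct), dd_ct = unname(dd_ct),
             rel_expr = unname(2^(-dd_ct)), sem_ct = unname(sem),
             stringsAsFactors = FALSE)
}

#' Amplification efficiency from a standard-curve slope
#'
#' For a dilution series, `efficiency = (10^(-1/slope) - 1) * 100` percent;
#' a perfectly doubling reaction has slope `-1/log10(2) ~ -3.32` and 100%
#' efficiency. Primer pairs are acceptable between 90 and 110%.
#'
#' @param slope Slope of Ct versus log10 dilution (must be negative).
#' @param primer_pair Label carried into the result.
#' @return data.frame with `primer_pair`, `slope`, `efficiency_pct`,
#'   `in_range` (90-110%).
#' @examples
#' efficiencyFromSlope(-1 / log10(2))
#' @export
efficiencyFromSlope <- function(slope, primer_pair = "primer") {
  if (!is.finite(slope) || slope >= 0)
    stop("standard-curve slope must be negative, got ", slope)
  eff <- (10^(-1 / slope) - 1) * 100
  data.frame(primer_pair = primer_pair, slope = slope,
             efficiency_pct = eff,
             in_range = eff >= 90 & eff <= 110,
             stringsAsFactors = FALSE)
}

#' Select sequences for qPCR validation
#'
#' Intersects the three selection criteria: a complete ORF structure
#' (start and stop codon), an inferred chloroplast localization, and
#' detected differential expression.
#'
#' @param annotations Annotation data.frame with `seq_id` and a
#'   `complete` logical column (or an ORF `completeness` column, where
#'   `"complete"` qualifies).
#' @param localization_calls data.frame from [inferLocalization()].
#' @param de_table data.frame with `seq_id` and logical `significant`
#'   (any significant comparison qualifies); may be empty.
#' @return Sorted character vector of selected seq_ids.
#' @export
selectForValidation <- function(annotations, localization_calls, de_table) {
  complete_ids <- if ("complete" %in% names(annotations))
    annotations$seq_id[annotations$complete]
  else annotations$seq_id[annotations$completeness == "complete"]
  chloro_ids <- localization_calls$query_id[
    localization_calls$call == "chloroplast"]
  de_ids <- if (is.null(de_table) || nrow(de_table) == 0L) character()
  else unique(de_table$seq_id[de_table$significant])
  sort(intersect(intersect(complete_ids, chloro_ids), de_ids))
}
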