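#' Build a position weight matrix from an aligned block
#'
#' Column probabilities are `(count + pseudocount) / (n + 20 * pseudocount)`.
#' Columns containing gap characters (`-` or `.`) are dropped with a
#' warning. At least two equal-length sequences are required.
#'
#' @param aligned_block Character vector of equal-length amino-acid strings.
#' @param region Region label (e.g. `"PG_box"`).
#' @param pseudocount Additive pseudocount (default 0.1; must be > 0 so all
#'   probabilities are positive).
#' @param background Length-20 background probability vector (default
#'   uniform 1/20).
#' @param offset_hint Expected start residue of the region within the full
#'   domain (default 1).
#' @return A [RegionPwm-class] object.
#' @examples
#' buildPwm(c("AC", "AA"), region = "demo", pseudocount = 0.01)
#' @export
buildPwm <- function(aligned_block, region = "region", pseudocount = 0.1,
                     background = rep(1 / 20, 20), offset_hint = 1L) {
  stopifnot(length(aligned_block) >= 2L, pseudocount > 0)
  lens <- nchar(aligned_block)
  if (length(unique(lens)) != 1L)
    stop("aligned block sequences must all have equal length")
  chars <- do.call(rbind, strsplit(toupper(aligned_block), ""))
  gapped <- apply(chars, 2, function(col) any(col %in% c("-", ".")))
  if (any(gapped)) {
    warning("dropping ", sum(gapped), " gapped column(s) from the block")
    chars <- chars[, !gapped, drop = FALSE]
  }
  n <- nrow(chars)
  w <- ncol(chars)
  if (w == 0L) stop("no ungapped columns left in the block")
  mat <- vapply(seq_len(w), function(j) {
    counts <- table(factor(chars[, j], levels = .AMINO_ACIDS))
    (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
  }, numeric(20))
  mat <- matrix(mat, nrow = 20, ncol = w,
                dimnames = list(.AMINO_ACIDS, NULL))
  new("RegionPwm", region = region, width = as.integer(w), matrix = mat,
      background = background, offsetHint = as.integer(offset_hint))
}

## Session-scoped cache of score models: the null-distribution DP depends
## only on the PWM, so it is computed once per matrix.
.pwmModelCache <- new.env(parent = emptyenv())

## Integer-scaled log-odds scores and the exact null score distribution.
## Scores are log2(p/bg) rounded to `scale` units per bit; the distribution
## of a random background window's total integer score is computed by
## column-wise convolution. Returns the per-cell integer scores, the
## column-wise minima (for shifting) and the tail probability vector:
## tail[k] = P(shifted score >= k - 1).
.pwmScoreModel <- function(pwm, scale = 1000L) {
  ## compact content fingerprint (position-weighted sums) keyed per matrix
  key <- paste(pwm@region, pwm@width, scale,
               format(sum(pwm@matrix * seq_along(pwm@matrix)), digits = 17),
               format(sum(pwm@background * 1:20), digits = 17), sep = "|")
  cached <- .pwmModelCache[[key]]
  if (!is.null(cached)) return(cached)
  int_scores <- round(scale * log2(pwm@matrix / pwm@background))
  mode(int_scores) <- "integer"
  mins <- apply(int_scores, 2, min)
  shifted <- sweep(int_scores, 2, mins)
  maxs <- apply(shifted, 2, max)
  dist <- 1
  for (j in seq_len(ncol(shifted))) {
    new <- numeric(length(dist) + maxs[j])
    for (a in seq_len(20L)) {
      sh <- shifted[a, j]
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * pwm@background[a]
    }
    dist <- new
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  model <- list(int_scores = int_scores, shift = sum(mins), tail = tail)
  .pwmModelCache[[key]] <- model
  model
}

#' Scan a sequence with a region PWM, FIMO-style
#'
#' Every window of the PWM's width is scored as the sum of per-position
#' log2 likelihood ratios against the background. P-values are exact tail
#' probabilities of the integer-scaled score (1000 units per bit) under the
#' background model, computed by dynamic programming over the score
#' distribution; windows with `p <= p_cutoff` are returned sorted by
#' position. Non-standard residues score as the background (a neutral
#' zero contribution).
#'
#' @param pwm A [RegionPwm-class] object.
#' @param sequence Amino-acid string; sequences shorter than the PWM width
#'   yield an empty result.
#' @param p_cutoff P-value threshold (default 1e-5).
#' @param seq_id Identifier carried into the output.
#' @return data.frame with columns `seq_id`, `region`, `aa_start`
#'   (1-based), `score_bits`, `p_value`.
#' @export
scanPwm <- function(pwm, sequence, p_cutoff = 1e-5, seq_id = "seq") {
  empty <- data.frame(seq_id = character(), region = character(),
                      aa_start = integer(), score_bits = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  n <- nchar(sequence)
  w <- pwm@width
  if (n < w) return(empty)
  model <- .pwmScoreModel(pwm)
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, .AMINO_ACIDS)  # NA -> non-standard, neutral score 0
  if (anyNA(idx))
    message(sum(is.na(idx)), " non-standard residue(s) scored as background")
  starts <- seq_len(n - w + 1L)
  scores <- vapply(starts, function(s) {
    ai <- idx[s:(s + w - 1L)]
    ok <- !is.na(ai)
    sum(model$int_scores[cbind(ai[ok], which(ok))])
  }, numeric(1))
  shifted <- as.integer(scores) - model$shift + 1L
  shifted <- pmax(pmin(shifted, length(model$tail)), 1L)
  pvals <- model$tail[shifted]
  keep <- which(pvals <= p_cutoff)
  data.frame(seq_id = rep(seq_id, length(keep)),
             region = rep(pwm@region, length(keep)),
             aa_start = starts[keep], score_bits = scores[keep] / 1000,
             p_value = pvals[keep], stringsAsFactors = FALSE)
}

#' Grade the completeness of a DYW domain
#'
#' Scans a candidate C-terminal sequence with the three region PWMs
#' (PG box, active site, C-terminal). The grade is `"full"` when all three
#' regions hit at `p <= p_cutoff` with their best hits in consistent order
#' (PG box before active site before C-terminal), `"truncated_with_PG"`
#' when the PG box hits but the full ordered triple does not, and
#' `"absent"` otherwise. The grade is monotone: appending missing regions
#' never downgrades it.
#'
#' @param cterm_sequence Amino-acid string (the sequence C-terminus).
#' @param pwms List of three [RegionPwm-class] objects named `PG_box`,
#'   `active_site`, `C_terminal` (e.g. from [dywRegionPwms()]).
#' @param p_cutoff P-value threshold (default 1e-5).
#' @return One of `"full"`, `"truncated_with_PG"`, `"absent"`.
#' @export
gradeDyw <- function(cterm_sequence, pwms = dywRegionPwms(),
                     p_cutoff = 1e-5) {
  need <- c("PG_box", "active_site", "C_terminal")
  stopifnot(all(need %in% names(pwms)))
  best <- lapply(need, function(r) {
    h <- scanPwm(pwms[[r]], cterm_sequence, p_cutoff = p_cutoff)
    if (nrow(h) == 0L) return(NA_integer_)
    h$aa_start[which.max(h$score_bits)]
  })
  names(best) <- need
  pg <- best$PG_box
  if (is.na(pg)) return("absent")
  if (!is.na(best$active_site) && !is.na(best$C_terminal) &&
      pg < best$active_site && best$active_site < best$C_terminal)
    return("full")
  "truncated_with_PG"
}

#' Packaged DYW-region PWMs
#'
#' Builds the three region PWMs from the packaged synthetic alignment
#' blocks (see `inst/extdata/dyw_regions_synthetic.tsv`): constructed
#' stand-in alignments embedding the hallmark residues of the PG box,
#' deaminase active site and DYW C-terminus at widths 24/32/25. Offset
#' hints (1, 68, 112) order the regions within a ~136-residue domain.
#'
#' @param pseudocount Pseudocount forwarded to [buildPwm()].
#' @return Named list of three [RegionPwm-class] objects.
#' @export
dywRegionPwms <- function(pseudocount = 0.1) {
  path <- system.file("extdata", "dyw_regions_synthetic.tsv",
                      package = "pprscout", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  hints <- c(PG_box = 1L, active_site = 68L, C_terminal = 112L)
  out <- lapply(names(hints), function(r)
    buildPwm(tab$sequence[tab$region == r], region = r,
             pseudocount = pseudocount, offset_hint = hints[[r]]))
  stats::setNames(out, names(hints))
}

#' Read / write PWM files
#'
#' The native dialect is a tab-delimited position x residue probability
#' matrix with a `pos` column and 20 residue columns; the MEME minimal-text
#' dialect (`letter-probability matrix` blocks with the protein alphabet)
#' is also readable.
#'
#' @param path File path.
#' @param region Region label for the returned object.
#' @param background,offset_hint See [buildPwm()].
#' @return `readPwm`: a [RegionPwm-class]. `writePwm`: the path, invisibly.
#' @export
readPwm <- function(path, region = "region",
                    background = rep(1 / 20, 20), offset_hint = 1L) {
  lines <- readLines(path)
  if (any(grepl("letter-probability matrix", lines, fixed = TRUE))) {
    alpha_line <- grep("^ALPHABET=", lines, value = TRUE)
    alphabet <- if (length(alpha_line))
      strsplit(sub("^ALPHABET=\\s*", "", alpha_line[1]), "")[[1]]
    else .AMINO_ACIDS
    start <- grep("letter-probability matrix", lines, fixed = TRUE)[1]
    rows <- list()
    for (ln in lines[-seq_len(start)]) {
      if (!grepl("^\\s*[0-9.eE+-]", ln)) break
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(ln),
                                                       "\\s+")[[1]])
    }
    m <- do.call(rbind, rows)  # positions x alphabet
    mat <- matrix(0, 20, nrow(m), dimnames = list(.AMINO_ACIDS, NULL))
    mat[match(alphabet, .AMINO_ACIDS), ] <- t(m)
    mat[mat <= 0] <- 1e-9
    mat <- sweep(mat, 2, colSums(mat), "/")
  } else {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    tab <- tab[order(tab$pos), setdiff(names(tab), "pos"), drop = FALSE]
    mat <- t(as.matrix(tab))[.AMINO_ACIDS, , drop = FALSE]
    dimnames(mat) <- list(.AMINO_ACIDS, NULL)
  }
  new("RegionPwm", region = region, width = ncol(mat), matrix = mat,
      background = background, offsetHint = as.integer(offset_hint))
}

#' @rdname readPwm
#' @param pwm A [RegionPwm-class] to write.
#' @export
writePwm <- function(pwm, path) {
  tab <- data.frame(pos = seq_len(pwm@width), t(pwm@matrix),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
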