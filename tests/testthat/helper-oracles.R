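# Independent oracles: brute-force or closed-form re-derivations of each
# operation's contract, kept deliberately separate from the package's own
# code paths.

# Six-frame ORF scan by explicit codon iteration.
oracle_orf_scan <- function(seq, min_aa) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                       "")[[1]]), collapse = "")
  }
  translate1 <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa) || is.na(aa)) "X" else aa
  }
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3
      if (ncod < 1) next
      aa <- character(ncod)
      for (k in seq_len(ncod)) {
        aa[k] <- translate1(substr(s, frame + 3 * k - 2, frame + 3 * k))
      }
      # walk segments between stops
      seg_start <- 1
      upstream_stop <- FALSE
      k <- 1
      while (k <= ncod + 1) {
        at_end <- k == ncod + 1
        if (at_end || aa[k] == "*") {
          seg_end <- k - 1
          down <- !at_end
          if (seg_end >= seg_start) {
            aas <- paste(aa[seg_start:seg_end], collapse = "")
            keep <- TRUE
            if (upstream_stop) {
              m <- regexpr("M", aas, fixed = TRUE)
              if (m < 0) keep <- FALSE
              else {
                seg_start2 <- seg_start + as.integer(m) - 1
                aas <- paste(aa[seg_start2:seg_end], collapse = "")
                comp <- if (down) "complete" else "3'partial"
              }
            } else {
              seg_start2 <- seg_start
              comp <- if (down) "5'partial" else "internal"
            }
            if (keep && nchar(aas) >= min_aa) {
              cs <- frame + 3 * (seg_start2 - 1)  # 0-based on scanned strand
              ce <- frame + 3 * seg_end
              if (strand == "+") {
                ns <- cs; ne <- ce
              } else {
                ns <- L - ce; ne <- L - cs
              }
              out[[length(out) + 1]] <- data.frame(
                strand = strand, frame = frame, nt_start = ns, nt_end = ne,
                aa_sequence = aas, completeness = comp,
                stringsAsFactors = FALSE)
            }
          }
          seg_start <- k + 1
          upstream_stop <- !at_end
        }
        k <- k + 1
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(strand = character(), frame = integer(),
               nt_start = integer(), nt_end = integer(),
               aa_sequence = character(), completeness = character(),
               stringsAsFactors = FALSE)
}

# Exact maximum-weight non-overlapping subset by bitmask enumeration
# (instances of <= 15 hits).
oracle_exact_intervals <- function(hits) {
  n <- nrow(hits)
  stopifnot(n <= 15)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1) {
      o <- idx[order(hits$aa_start[idx])]
      if (any(hits$aa_start[o][-1] <= hits$aa_end[o][-length(o)])) next
    }
    sc <- sum(hits$score[idx])
    if (sc > best) best <- sc
  }
  best
}

# Greedy selection re-derived with a different mechanism: repeatedly take
# the best remaining hit and delete everything overlapping it.
oracle_greedy_trace <- function(hits) {
  catalog <- motifCatalog()
  remaining <- hits
  chosen <- hits[0, ]
  while (nrow(remaining) > 0) {
    rank <- order(-remaining$score, remaining$aa_start,
                  match(remaining$motif_type, catalog))
    pick <- remaining[rank[1], ]
    chosen <- rbind(chosen, pick)
    ov <- remaining$aa_start <= pick$aa_end &
      remaining$aa_end >= pick$aa_start
    remaining <- remaining[!ov, , drop = FALSE]
  }
  chosen[order(chosen$aa_start), , drop = FALSE]
}

# Sliding-window pattern search by per-position set membership.
oracle_search_windows <- function(position_sets, rna) {
  chars <- strsplit(rna, "")[[1]]
  w <- length(position_sets)
  hits <- integer()
  if (length(chars) >= w) {
    for (s in seq_len(length(chars) - w + 1)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!chars[s + j - 1] %in% position_sets[[j]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}

# Exhaustive PWM tail probabilities for widths <= 3: enumerate every
# window, score with independently rounded integer log-odds, and sum
# background probabilities over the tail.
oracle_pwm_enumeration <- function(pwm, scale = 1000) {
  aas <- rownames(pwm@matrix)
  w <- pwm@width
  stopifnot(w <= 3)
  ints <- round(scale * log2(pwm@matrix / pwm@background))
  grid <- do.call(expand.grid,
                  c(rep(list(seq_along(aas)), w), KEEP.OUT.ATTRS = FALSE))
  score <- numeric(nrow(grid))
  prob <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    score <- score + ints[grid[[j]], j]
    prob <- prob * pwm@background[grid[[j]]]
  }
  list(windows = grid, score = score, prob = prob,
       tail = function(s) sum(prob[score >= s]))
}

# Probability that a uniformly random permutation of a sequence's letters
# matches the pattern: count permutations by recursion over positions with
# memoization on the remaining composition.
oracle_shuffle_match_prob <- function(position_sets, sequence) {
  letters4 <- c("A", "C", "G", "U")
  comp <- vapply(letters4, function(l)
    sum(strsplit(sequence, "")[[1]] == l), integer(1))
  len <- nchar(sequence)
  stopifnot(len == length(position_sets))
  memo <- new.env(parent = emptyenv())
  g <- function(pos, counts) {
    if (pos > len) return(1)
    key <- paste(pos, paste(counts, collapse = ","))
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- 0
    for (l in position_sets[[pos]]) {
      li <- match(l, letters4)
      if (!is.na(li) && counts[li] > 0) {
        c2 <- counts; c2[li] <- c2[li] - 1
        total <- total + counts[li] * g(pos + 1, c2)
      }
    }
    memo[[key]] <- total
    total
  }
  g(1, comp) / factorial(len)
}

# Straight-line spreadsheet-style ddCt recomputation.
oracle_ddct <- function(records, target, references, calibrator) {
  tissues <- unique(records$tissue)
  dct <- sapply(tissues, function(tt) {
    t_mean <- mean(records$ct[records$gene == target &
                                records$tissue == tt])
    r_means <- sapply(references, function(rg)
      mean(records$ct[records$gene == rg & records$tissue == tt]))
    t_mean - mean(r_means)
  })
  2^(-(dct - dct[[calibrator]]))
}

# Group-by max-bitscore best-hit selection via base split/apply.
oracle_best_hits <- function(hits, min_identity) {
  picked <- lapply(split(hits, hits$query_id), function(g) {
    g <- g[order(-g$bitscore, g$evalue, g$subject_id), , drop = FALSE]
    g[1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out <- out[out$identity_pct >= min_identity, , drop = FALSE]
  out[order(out$query_id), , drop = FALSE]
}

# Convenience: grade DYW over the C-terminal tail of each cohort protein.
grade_cohort <- function(proteins, tail_aa = 200, p_cutoff = 1e-5) {
  vapply(names(proteins), function(id) {
    s <- as.character(proteins[[id]])
    n <- nchar(s)
    gradeDyw(substr(s, max(1, n - tail_aa + 1), n), p_cutoff = p_cutoff)
  }, character(1))
}
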