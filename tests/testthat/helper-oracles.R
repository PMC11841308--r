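# Independent oracles used by the tests. These deliberately re-derive
# results with the most literal method available (full-matrix DP, word
# enumeration, column expansion, all-pairs overlap) so they share no code
# with the implementation they check.

# Plain-R Gotoh local alignment, score only. Gap of length L costs
# go + (L - 1) * ge.
sw_score_oracle <- function(q, t, match = 2, mismatch = -4, go = 4, ge = 2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  FF <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
      FF[i, j] <- max(H[i - 1, j] - go, FF[i - 1, j] - ge)
      s <- if (qc[i - 1] == tc[j - 1] && qc[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force PWM p-values: enumerate all 4^w words, score with the same
# discretized matrix, weight by the background. Returns function(int_score).
enum_pvalue_oracle <- function(ppm, bg, granularity = 1e-3, pseudocount = 0.01) {
  sm <- promcons::log_odds(ppm, bg, pseudocount)
  I <- matrix(as.integer(round(sm / granularity)), nrow = nrow(sm))
  w <- nrow(I)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(words, 1, function(ww) sum(I[cbind(seq_len(w), ww)]))
  probs <- apply(words, 1, function(ww) prod(bg[ww]))
  function(int_score) sum(probs[scores >= int_score])
}

# CIGAR projection by explicit column expansion: build the full list of
# (q, t) column pairs and look the query position up.
project_oracle <- function(q_start, t_start, cigar, q_pos) {
  runs <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  qc <- q_start; tc <- t_start
  for (r in runs) {
    len <- as.integer(sub("[MID]$", "", r))
    op <- sub("^\\d+", "", r)
    for (k in seq_len(len)) {
      if (op == "M") {
        if (qc == q_pos) return(tc)
        qc <- qc + 1L; tc <- tc + 1L
      } else if (op == "I") {
        if (qc == q_pos) return(tc)
        qc <- qc + 1L
      } else {
        tc <- tc + 1L
      }
    }
  }
  NA_integer_
}

# Naive per-position interval stabbing over query intervals, deduplicated
# per gene.
coverage_oracle <- function(alignments, up, down) {
  len <- up + down
  counts <- integer(len)
  for (g in unique(alignments$query_gene)) {
    a <- alignments[alignments$query_gene == g, ]
    covered <- logical(len)
    for (i in seq_len(nrow(a))) {
      span <- seq.int(a$q_start[i] + 1L, min(a$q_end[i], len))
      covered[span] <- TRUE
    }
    counts <- counts + covered
  }
  counts
}

# All-pairs variant/site overlap with the documented rules.
variant_overlap_oracle <- function(variants, sites) {
  hits <- 0L
  for (i in seq_len(nrow(variants))) {
    v_start <- variants$pos[i]
    v_end <- variants$pos[i] + max(nchar(variants$ref[i]) - 1L, 0L)
    for (j in seq_len(nrow(sites))) {
      if (variants$contig[i] != sites$genomic_contig[j]) next
      s1 <- sites$genomic_start[j] + 1L; e1 <- sites$genomic_end[j]
      if (v_start <= e1 && v_end >= s1) hits <- hits + 1L
    }
  }
  hits
}

random_dna_str <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
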