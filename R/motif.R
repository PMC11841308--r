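#' Estimate a 0-order Markov background from promoter sequences
#'
#' Letter frequencies of A, C, G, T over all promoter sequences with a +1
#' pseudocount per letter; `N` is excluded from the counts.
#'
#' @param promoters promoter tibble (with a `seq` column) or a character
#'   vector of sequences.
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @export
estimate_background <- function(promoters) {
  seqs <- if (is.data.frame(promoters)) promoters$seq else promoters
  all <- paste(seqs, collapse = "")
  chars <- strsplit(all, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = c("A", "C", "G", "T"))) + 1
  p <- as.numeric(counts) / sum(counts)
  setNames(p, c("A", "C", "G", "T"))
}

#' Log-odds score matrix for a motif
#'
#' `score[i, b] = log2((ppm[i, b] * (1 - 4 * pseudocount) + pseudocount) /
#' background[b])`.
#'
#' @param ppm width x 4 probability matrix (columns A, C, G, T).
#' @param background named background vector ([estimate_background()]).
#' @param pseudocount probability mass redistributed uniformly (default 0.01).
#'   With `pseudocount = 0`, zero probabilities give -Inf log-odds, which are
#'   capped at -30 bits so the analytic distribution stays finite.
#' @return width x 4 matrix of log2-odds scores.
#' @export
log_odds <- function(ppm, background, pseudocount = 0.01) {
  bg <- background[c("A", "C", "G", "T")]
  adj <- ppm * (1 - 4 * pseudocount) + pseudocount
  sm <- log2(sweep(adj, 2, bg, "/"))
  sm[sm < -30] <- -30
  dimnames(sm) <- list(NULL, c("A", "C", "G", "T"))
  sm
}

#' Analytic score distribution of a PWM under the background
#'
#' Scores are discretized to `granularity` and the exact distribution of the
#' window score under the 0-order background is computed by positional
#' convolution; p-values are upper-tail masses `P(score' >= score)`.
#'
#' @param score_matrix width x 4 log-odds matrix ([log_odds()]).
#' @param background named background vector.
#' @param granularity score discretization step (> 0).
#' @return object of class `promcons_score_dist` holding the integer score
#'   matrix and the tail distribution; see [score_pvalue()].
#' @export
score_distribution <- function(score_matrix, background, granularity = 1e-3) {
  if (granularity <= 0) stop("granularity must be > 0", call. = FALSE)
  bg <- as.numeric(background[c("A", "C", "G", "T")])
  I <- matrix(as.integer(round(score_matrix / granularity)),
              nrow = nrow(score_matrix), ncol = 4L)
  dist <- 1
  off <- 0L
  for (i in seq_len(nrow(I))) {
    row <- I[i, ]
    rmin <- min(row)
    nd <- numeric(length(dist) + max(row) - rmin)
    for (b in 1:4) {
      sh <- row[b] - rmin
      idx <- seq.int(1L + sh, length.out = length(dist))
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    off <- off + rmin
    dist <- nd
  }
  tail <- rev(cumsum(rev(dist)))
  structure(
    list(int_matrix = I, offset = off, tail = tail, granularity = granularity),
    class = "promcons_score_dist"
  )
}

#' Upper-tail p-value of an integer window score
#'
#' @param dist a `promcons_score_dist` from [score_distribution()].
#' @param int_score integer (discretized) window score(s).
#' @return numeric p-value(s) in (0, 1].
#' @export
score_pvalue <- function(dist, int_score) {
  k <- int_score - dist$offset + 1L
  p <- numeric(length(k))
  p[k <= 0L] <- 1
  inside <- k >= 1L & k <= length(dist$tail)
  p[inside] <- dist$tail[k[inside]]
  # above the maximum attainable score: impossible, mass 0
  p
}

# Encode an ACGTN sequence as integers 1..4 with NA for N.
encode_seq <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

# Integer window scores of matrix I (w x 4) along an encoded sequence.
# Windows containing N (NA codes) return NA.
window_scores <- function(code, I) {
  w <- nrow(I)
  n <- length(code) - w + 1L
  if (n < 1L) return(integer(0))
  S <- integer(n)
  bad <- logical(n)
  for (i in seq_len(w)) {
    b <- code[seq.int(i, length.out = n)]
    na <- is.na(b)
    bad <- bad | na
    b[na] <- 1L
    S <- S + I[i, b]
  }
  S[bad] <- NA_integer_
  S
}

#' Scan promoters with a motif library
#'
#' Both strands of every promoter are scanned; a site is emitted iff its
#' analytic p-value is at or below `alpha`. Minus-strand scores and p-values
#' are those of the reverse complement of the window under the plus-strand
#' matrix, so results are invariant to which strand the promoter was read
#' from. Windows containing `N` are skipped. Sites are sorted by start, then
#' strand (`+` first).
#'
#' @param promoters promoter tibble.
#' @param motifs motif tibble ([read_meme_motifs()]).
#' @param background named background vector; estimated from `promoters` when
#'   `NULL`.
#' @param alpha p-value threshold (default 1e-4, the conventional scanning
#'   default).
#' @param pseudocount,granularity see [log_odds()] / [score_distribution()].
#' @return site tibble: `gene_id`, `motif_id`, `tf_family`, `start` (0-based
#'   local), `strand` (relative to promoter orientation), `matched_seq`
#'   (motif-strand letters), `score` (log2-odds, discretized), `p_value`.
#' @export
scan_promoters <- function(promoters, motifs, background = NULL, alpha = 1e-4,
                           pseudocount = 0.01, granularity = 1e-3) {
  if (is.null(background)) background <- estimate_background(promoters)
  prep <- purrr::pmap(motifs[, c("motif_id", "tf_family", "ppm")],
                      function(motif_id, tf_family, ppm) {
    sm <- log_odds(ppm, background, pseudocount)
    dist <- score_distribution(sm, background, granularity)
    I <- dist$int_matrix
    Irc <- I[rev(seq_len(nrow(I))), 4:1, drop = FALSE]
    list(motif_id = motif_id, tf_family = tf_family, dist = dist,
         I = I, Irc = Irc, w = nrow(I))
  })
  res <- list()
  for (pi in seq_len(nrow(promoters))) {
    seq <- promoters$seq[pi]
    code <- encode_seq(seq)
    for (m in prep) {
      if (length(code) < m$w) next
      for (strand in c("+", "-")) {
        S <- window_scores(code, if (strand == "+") m$I else m$Irc)
        ok <- which(!is.na(S))
        if (length(ok) == 0L) next
        p <- score_pvalue(m$dist, S[ok])
        hit <- ok[p <= alpha]
        if (length(hit) == 0L) next
        word <- substring(seq, hit, hit + m$w - 1L)
        if (strand == "-") word <- revcomp(word)
        res[[length(res) + 1L]] <- tibble(
          gene_id = promoters$gene_id[pi], motif_id = m$motif_id,
          tf_family = m$tf_family, start = hit - 1L, strand = strand,
          matched_seq = word,
          score = S[hit] * m$dist$granularity,
          p_value = p[match(hit, ok)]
        )
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(gene_id = character(), motif_id = character(),
                  tf_family = character(), start = integer(), strand = character(),
                  matched_seq = character(), score = numeric(), p_value = numeric()))
  }
  dplyr::arrange(out, .data$gene_id, .data$motif_id, .data$start, .data$strand)
}
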