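#' Select ortholog pairs for promoter comparison
#'
#' Keeps one-to-one and one-to-many pairs whose protein identity strictly
#' exceeds `min_protein_id`; when GOC / WGA scores are present each must meet
#' its threshold. For one-to-many relations the target with the highest
#' protein identity is chosen per query gene and species, ties broken
#' lexicographically by target gene.
#'
#' @param pairs ortholog tibble ([read_ortholog_table()]).
#' @param min_protein_id exclusive lower bound on protein percent identity.
#' @param min_goc,min_wga inclusive thresholds applied to non-missing scores.
#' @return tibble with one selected pair per (query gene, species).
#' @export
select_pairs <- function(pairs, min_protein_id = 25, min_goc = 50, min_wga = 50) {
  kept <- pairs |>
    dplyr::filter(.data$homology_type %in% c("one2one", "one2many"),
                  .data$protein_pct_id > min_protein_id,
                  is.na(.data$goc) | .data$goc >= min_goc,
                  is.na(.data$wga) | .data$wga >= min_wga)
  kept |>
    dplyr::arrange(.data$query_gene, .data$species,
                   dplyr::desc(.data$protein_pct_id), .data$target_gene) |>
    dplyr::distinct(.data$query_gene, .data$species, .keep_all = TRUE)
}

#' Exact affine-gap local alignment of two promoter sequences
#'
#' Smith-Waterman with Gotoh affine gaps; a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. The primary alignment is the optimum;
#' secondary alignments are obtained by masking already-aligned query columns
#' and re-running until the score drops below `min_score` or `max_secondary`
#' is reached. Traceback tie-breaks are fixed (M over D over I; first maximum
#' in row-major order) so CIGARs are reproducible. `N` scores as a mismatch
#' against everything, including `N`.
#'
#' @param query_seq,target_seq sequences over `ACGTN`.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (penalties negative).
#' @param min_score minimum reported alignment score.
#' @param max_secondary maximum number of secondary alignments.
#' @return tibble with `q_start`, `q_end`, `t_start`, `t_end` (0-based
#'   half-open local coordinates), `cigar` (M/I/D; I consumes query, D
#'   consumes target), `n_matches`, `identity` (matches / alignment columns),
#'   `score`, `rank`.
#' @export
local_align <- function(query_seq, target_seq,
                        scoring = list(match = 2, mismatch = -4,
                                       gap_open = -4, gap_extend = -2),
                        min_score = 40, max_secondary = 5) {
  empty <- tibble(q_start = integer(), q_end = integer(), t_start = integer(),
                  t_end = integer(), cigar = character(), n_matches = integer(),
                  identity = numeric(), score = integer(), rank = character())
  if (is.na(query_seq) || is.na(target_seq) ||
      nchar(query_seq) == 0L || nchar(target_seq) == 0L) {
    return(empty)
  }
  df <- sw_align_cpp(query_seq, target_seq,
                     as.integer(scoring$match), as.integer(scoring$mismatch),
                     as.integer(scoring$gap_open), as.integer(scoring$gap_extend),
                     as.integer(min_score), as.integer(max_secondary))
  if (nrow(df) == 0L) return(empty)
  tibble(q_start = df$q_start, q_end = df$q_end, t_start = df$t_start,
         t_end = df$t_end, cigar = df$cigar, n_matches = df$n_matches,
         identity = df$n_matches / df$aln_len, score = df$score, rank = df$rank)
}

#' Align promoters of selected ortholog pairs
#'
#' Runs [local_align()] for every (query gene, species) pair and stacks the
#' results.
#'
#' @param query_promoters,target_promoters promoter tibbles; target gene
#'   identifiers must be unique across species.
#' @param pairs tibble with `query_gene`, `target_gene`, `species` (e.g. from
#'   [select_pairs()]).
#' @inheritParams local_align
#' @return alignment tibble with identifying columns `query_gene`,
#'   `target_gene`, `species` prepended.
#' @export
align_orthologs <- function(query_promoters, target_promoters, pairs,
                            scoring = list(match = 2, mismatch = -4,
                                           gap_open = -4, gap_extend = -2),
                            min_score = 40, max_secondary = 5) {
  qs <- setNames(query_promoters$seq, query_promoters$gene_id)
  ts <- setNames(target_promoters$seq, target_promoters$gene_id)
  res <- purrr::pmap(pairs[, c("query_gene", "target_gene", "species")],
                     function(query_gene, target_gene, species) {
    q <- unname(qs[query_gene]); t <- unname(ts[target_gene])
    if (is.na(q) || is.na(t)) return(NULL)  # pair without promoters: skipped
    aln <- local_align(q, t, scoring = scoring, min_score = min_score,
                       max_secondary = max_secondary)
    if (nrow(aln) == 0L) return(NULL)
    dplyr::bind_cols(tibble(query_gene = query_gene, target_gene = target_gene,
                            species = species), aln)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(query_gene = character(), target_gene = character(),
                  species = character(), q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer(), cigar = character(),
                  n_matches = integer(), identity = numeric(), score = integer(),
                  rank = character())
  }
  out
}

#' Call promoter similarity per ortholog pair
#'
#' A (query gene, species) pair is similar iff it has at least one alignment
#' with score at or above `min_score`; `aligned_span` is the length of the
#' union of query intervals over all its alignments.
#'
#' @param alignments alignment tibble from [align_orthologs()].
#' @param pairs the pair tibble that was aligned (pairs without alignments
#'   are reported with `similar = FALSE`).
#' @param min_score score threshold defining a significant alignment.
#' @return tibble with `query_gene`, `species`, `target_gene`, `similar`,
#'   `n_alignments`, `aligned_span`, `best_score`.
#' @export
similarity_calls <- function(alignments, pairs, min_score = 40) {
  if (nrow(alignments) == 0L) {
    return(pairs |>
             dplyr::select("query_gene", "species", "target_gene") |>
             dplyr::mutate(similar = FALSE, n_alignments = 0L,
                           aligned_span = 0L, best_score = NA_integer_))
  }
  agg <- alignments |>
    dplyr::group_by(.data$query_gene, .data$species, .data$target_gene) |>
    dplyr::summarise(
      similar = any(.data$score >= min_score),
      n_alignments = dplyr::n(),
      aligned_span = interval_union_length(.data$q_start, .data$q_end),
      best_score = max(.data$score),
      .groups = "drop"
    )
  pairs |>
    dplyr::select("query_gene", "species", "target_gene") |>
    dplyr::left_join(agg, by = c("query_gene", "species", "target_gene")) |>
    dplyr::mutate(
      similar = !is.na(.data$similar) & .data$similar,
      n_alignments = dplyr::coalesce(.data$n_alignments, 0L),
      aligned_span = dplyr::coalesce(.data$aligned_span, 0L),
      best_score = dplyr::coalesce(.data$best_score, NA_integer_)
    )
}

#' Shuffle orthology assignments into false orthologs
#'
#' Within each species, target genes are permuted by a derangement (no pair
#' keeps its true target), so re-running the alignment measures the rate of
#' spurious promoter similarity. Species with fewer than two pairs are left
#' unshuffled with a warning.
#'
#' @param pairs tibble with `query_gene`, `target_gene`, `species`.
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return `pairs` with `target_gene` permuted within species.
#' @export
shuffle_orthology <- function(pairs, seed) {
  with_seed(seed, {
    parts <- split(seq_len(nrow(pairs)), pairs$species)
    out <- pairs
    for (sp in names(parts)) {
      idx <- parts[[sp]]
      n <- length(idx)
      if (n < 2L) {
        warning("species '", sp, "' has fewer than 2 pairs; left unshuffled",
                call. = FALSE)
        next
      }
      perm <- derangement(n)
      out$target_gene[idx] <- pairs$target_gene[idx][perm]
    }
    out
  })
}

# Uniform random derangement by rejection sampling (expected ~e tries).
derangement <- function(n) {
  if (n == 2L) return(c(2L, 1L))
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Per-position alignment coverage profile
#'
#' For every TSS-relative position, counts how many query genes have at
#' least one alignment whose query interval covers the position (each gene
#' counted at most once per position). Positions are labeled relative to the
#' TSS assuming full `up`/`down` windows.
#'
#' @param alignments alignment tibble (query coordinates are local promoter
#'   coordinates).
#' @param up,down promoter extent used at extraction.
#' @return tibble of class `promcons_coverage` with `position` (-up ..
#'   down-1) and `count`.
#' @export
coverage_profile <- function(alignments, up = 2000L, down = 200L) {
  len <- up + down
  delta <- integer(len + 1L)
  for (g in split(alignments, alignments$query_gene)) {
    # per-gene dedup: union the gene's query intervals first
    o <- order(g$q_start, g$q_end)
    s <- g$q_start[o]; e <- pmin(g$q_end[o], len)
    cur_s <- s[1]; cur_e <- e[1]
    add <- function(a, b) {
      delta[a + 1L] <<- delta[a + 1L] + 1L
      delta[b + 1L] <<- delta[b + 1L] - 1L
    }
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e) { add(cur_s, cur_e); cur_s <- s[i]; cur_e <- e[i] }
      else cur_e <- max(cur_e, e[i])
    }
    add(cur_s, cur_e)
  }
  counts <- cumsum(delta[seq_len(len)])
  out <- tibble(position = seq.int(-up, down - 1L), count = as.integer(counts))
  class(out) <- c("promcons_coverage", class(out))
  out
}
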