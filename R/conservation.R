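#' Project a query position through an alignment
#'
#' Walks the CIGAR: M columns map one-to-one; a position inside an I run
#' (insertion in query) maps to the target position immediately after the
#' preceding aligned column. Positions outside the query interval return
#' `NA`.
#'
#' @param alignment one-row alignment tibble (needs `q_start`, `t_start`,
#'   `q_end`, `cigar`).
#' @param q_pos query local position (0-based).
#' @return target local position (0-based) or `NA`.
#' @export
project_position <- function(alignment, q_pos) {
  if (q_pos < alignment$q_start || q_pos >= alignment$q_end) return(NA_integer_)
  runs <- parse_cigar(alignment$cigar)
  qc <- alignment$q_start
  tc <- alignment$t_start
  for (i in seq_len(nrow(runs))) {
    len <- runs$len[i]
    op <- runs$op[i]
    if (op == "M") {
      if (q_pos < qc + len) return(as.integer(tc + (q_pos - qc)))
      qc <- qc + len; tc <- tc + len
    } else if (op == "I") {
      if (q_pos < qc + len) return(as.integer(tc))
      qc <- qc + len
    } else { # D
      tc <- tc + len
    }
  }
  NA_integer_
}

# Conservation test for one site against one target promoter.
# word: promoter-strand letters of the site; anchor: expected target-local
# start. Returns list(conserved, target_position, offset).
.test_one_site <- function(word, anchor, target_seq, window) {
  if (is.na(anchor) || nchar(target_seq) < nchar(word)) {
    return(list(conserved = FALSE, target_position = NA_integer_,
                offset = NA_integer_))
  }
  occ <- fixed_matches(word, target_seq) - 1L
  occ <- occ[abs(occ - anchor) <= window]
  if (length(occ) == 0L) {
    return(list(conserved = FALSE, target_position = NA_integer_,
                offset = NA_integer_))
  }
  d <- abs(occ - anchor)
  best <- occ[order(d, occ)][1]
  list(conserved = TRUE, target_position = as.integer(best),
       offset = as.integer(best - anchor))
}

#' Test conservation of one site in one ortholog promoter
#'
#' The anchor is the site start projected through the best-scoring alignment
#' covering it; with `anchor_mode = "auto"`, sites not covered by any
#' alignment fall back to the same TSS-relative coordinate in the target
#' (`anchor_mode = "projection"` calls them not conserved). A site is
#' conserved iff its exact matched word occurs on the same strand (relative
#' to promoter orientation) with start within `window` nucleotides of the
#' anchor; the nearest occurrence wins, ties toward the smaller coordinate.
#'
#' @param site one-row site tibble (`start`, `strand`, `matched_seq`).
#' @param query_promoter,target_promoter one-row promoter tibbles.
#' @param alignments alignments of this (query gene, species) pair.
#' @param window maximum distance from the anchor (default 100 nt).
#' @param anchor_mode `"auto"` or `"projection"`.
#' @return tibble with `conserved`, `target_position`, `offset`, `anchored_by`
#'   (`"alignment"` or `"tss_relative"`).
#' @export
test_conservation <- function(site, query_promoter, target_promoter, alignments,
                              window = 100L, anchor_mode = c("auto", "projection")) {
  anchor_mode <- match.arg(anchor_mode)
  covering <- alignments[alignments$q_start <= site$start &
                           site$start < alignments$q_end, , drop = FALSE]
  if (nrow(covering) > 0L) {
    best <- covering[order(-covering$score, covering$q_start), , drop = FALSE][1, ]
    anchor <- project_position(best, site$start)
    anchored_by <- "alignment"
  } else if (anchor_mode == "auto") {
    anchor <- site$start + (target_promoter$up_len - query_promoter$up_len)
    anchored_by <- "tss_relative"
  } else {
    anchor <- NA_integer_
    anchored_by <- "none"
  }
  word <- if (site$strand == "+") site$matched_seq else revcomp(site$matched_seq)
  r <- .test_one_site(word, anchor, target_promoter$seq, window)
  tibble(conserved = r$conserved, target_position = r$target_position,
         offset = r$offset, anchored_by = anchored_by)
}

#' Conservation calls for all sites across all species
#'
#' Applies [test_conservation()] to every site of every query gene against
#' each comparator species for which the gene's promoter was called similar.
#'
#' @param sites site tibble ([scan_promoters()]).
#' @param alignments alignment tibble ([align_orthologs()]).
#' @param query_promoters,target_promoters promoter tibbles.
#' @param similarity similarity tibble ([similarity_calls()]); only pairs
#'   with `similar = TRUE` are tested.
#' @inheritParams test_conservation
#' @return call tibble: site columns plus `species`, `target_gene`,
#'   `conserved`, `target_position`, `offset`, `anchored_by`.
#' @export
conservation_calls <- function(sites, alignments, query_promoters,
                               target_promoters, similarity, window = 100L,
                               anchor_mode = c("auto", "projection")) {
  anchor_mode <- match.arg(anchor_mode)
  sim <- similarity[similarity$similar, , drop = FALSE]
  tp_idx <- setNames(seq_len(nrow(target_promoters)), target_promoters$gene_id)
  qp_idx <- setNames(seq_len(nrow(query_promoters)), query_promoters$gene_id)
  aln_by_pair <- split(alignments, paste(alignments$query_gene, alignments$species))
  sites_by_gene <- split(sites, sites$gene_id)
  res <- list()
  for (i in seq_len(nrow(sim))) {
    g <- sim$query_gene[i]; sp <- sim$species[i]; tg <- sim$target_gene[i]
    ss <- sites_by_gene[[g]]
    if (is.null(ss) || nrow(ss) == 0L) next
    qp <- query_promoters[qp_idx[[g]], ]
    tp <- target_promoters[tp_idx[[tg]], ]
    aln <- aln_by_pair[[paste(g, sp)]]
    if (is.null(aln)) aln <- alignments[0, ]
    calls <- purrr::map(seq_len(nrow(ss)), function(k) {
      test_conservation(ss[k, ], qp, tp, aln, window = window,
                        anchor_mode = anchor_mode)
    })
    res[[length(res) + 1L]] <- dplyr::bind_cols(
      ss, tibble(species = sp, target_gene = tg), dplyr::bind_rows(calls))
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- dplyr::bind_cols(
      sites[0, ], tibble(species = character(), target_gene = character(),
                         conserved = logical(), target_position = integer(),
                         offset = integer(), anchored_by = character()))
  }
  out
}

#' Aggregate conservation calls into unique conserved sites
#'
#' Unique site key = (gene_id, motif_id, start, strand). Sites conserved in
#' no species are dropped; the conservation level is the number of species
#' in which the site is conserved.
#'
#' @param calls call tibble ([conservation_calls()]).
#' @return tibble with one row per unique conserved site: key columns,
#'   `tf_family`, `matched_seq`, `species_conserved` (list-column), `level`.
#' @export
aggregate_conserved <- function(calls) {
  calls |>
    dplyr::group_by(.data$gene_id, .data$motif_id, .data$start, .data$strand) |>
    dplyr::summarise(
      tf_family = .data$tf_family[1],
      matched_seq = .data$matched_seq[1],
      species_conserved = list(sort(unique(.data$species[.data$conserved]))),
      level = length(species_conserved[[1]]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$level >= 1L)
}

#' Flag overlap of conserved sites with upstream genes and ACRs
#'
#' A site is flagged `in_upstream_gene` when its genomic interval intersects
#' the body of any gene other than its own, and `in_acr` when it intersects
#' any ACR interval. Intersection is half-open: abutting intervals do not
#' overlap.
#'
#' @param sites site tibble with genomic coordinates (see
#'   [add_genomic_coords()]); if absent they are added from `promoters`.
#' @param promoters promoter tibble the sites live on.
#' @param gene_models gene model tibble ([read_gff3_genes()]).
#' @param acrs optional ACR tibble ([read_bed()]); when `NULL`, `in_acr` is
#'   `NA`.
#' @return `sites` with `in_upstream_gene` and `in_acr` logical columns.
#' @export
annotate_overlap <- function(sites, promoters, gene_models, acrs = NULL) {
  if (!"genomic_start" %in% names(sites)) {
    sites <- add_genomic_coords(sites, promoters)
  }
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(sites, in_upstream_gene = logical(0), in_acr = logical(0)))
  }
  site_gr <- GenomicRanges::GRanges(
    sites$genomic_contig,
    IRanges::IRanges(sites$genomic_start + 1L, sites$genomic_end))
  gene_gr <- GenomicRanges::GRanges(
    gene_models$contig, IRanges::IRanges(gene_models$start, gene_models$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  other <- sites$gene_id[S4Vectors::queryHits(hits)] !=
    gene_models$gene_id[S4Vectors::subjectHits(hits)]
  in_gene <- logical(nrow(sites))
  in_gene[unique(S4Vectors::queryHits(hits)[other])] <- TRUE
  in_acr <- rep(NA, nrow(sites))
  if (!is.null(acrs) && nrow(acrs) > 0L) {
    acr_gr <- GenomicRanges::GRanges(
      acrs$contig, IRanges::IRanges(acrs$start + 1L, acrs$end))
    ah <- GenomicRanges::findOverlaps(site_gr, acr_gr)
    in_acr <- logical(nrow(sites))
    in_acr[unique(S4Vectors::queryHits(ah))] <- TRUE
  }
  dplyr::mutate(sites, in_upstream_gene = in_gene, in_acr = in_acr)
}

#' TSS-relative positional profile of sites
#'
#' Counts each site at its start position relative to the TSS, optionally
#' stratified by conservation level.
#'
#' @param sites site tibble (scanned or conserved); needs `gene_id`, `start`.
#' @param promoters promoter tibble supplying each gene's `up_len` (so
#'   clipped windows are placed correctly).
#' @param up,down profile extent.
#' @param by_level stratify by the `level` column when present.
#' @return tibble of class `promcons_site_profile` with `position`, `count`
#'   and, when stratified, `level`; stratified counts sum to the
#'   unstratified profile.
#' @export
site_position_profile <- function(sites, promoters, up = 2000L, down = 200L,
                                  by_level = FALSE) {
  positions <- seq.int(-up, down - 1L)
  up_len <- promoters$up_len[match(sites$gene_id, promoters$gene_id)]
  rel <- sites$start - up_len
  if (by_level) {
    if (!"level" %in% names(sites)) stop("no 'level' column to stratify by", call. = FALSE)
    out <- tidyr::expand_grid(position = positions,
                              level = sort(unique(sites$level)))
    tab <- dplyr::count(tibble(position = rel, level = sites$level),
                        .data$position, .data$level, name = "count")
    out <- dplyr::left_join(out, tab, by = c("position", "level")) |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  } else {
    tab <- dplyr::count(tibble(position = rel), .data$position, name = "count")
    out <- tibble(position = positions) |>
      dplyr::left_join(tab, by = "position") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  }
  class(out) <- c("promcons_site_profile", class(out))
  out
}
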