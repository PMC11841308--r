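#' Extract TSS-anchored promoter windows
#'
#' For each gene, the window spans `up` nucleotides upstream through `down`
#' nucleotides downstream of the TSS, read 5'->3' toward the gene (so
#' minus-strand windows are reverse-complemented). Local coordinate 0 is the
#' most-upstream base and local coordinate `up_len` is the TSS base. Windows
#' are clipped at contig boundaries; `up_len`/`down_len` record what was
#' actually available.
#'
#' @param genes tibble of gene models ([read_gff3_genes()]).
#' @param assembly named character vector of contig sequences ([read_fasta()]).
#' @param up,down window extent upstream/downstream of the TSS (nt).
#' @return tibble with columns `gene_id`, `contig`, `strand`, `tss`,
#'   `up_len`, `down_len`, `win_start`, `win_end` (0-based half-open genomic
#'   window) and `seq` (TSS-oriented sequence).
#' @export
extract_promoters <- function(genes, assembly, up = 2000L, down = 200L) {
  missing_contig <- setdiff(unique(genes$contig), names(assembly))
  if (length(missing_contig) > 0L) {
    stop("contig(s) absent from assembly: ", paste(missing_contig, collapse = ", "),
         call. = FALSE)
  }
  clipped <- character(0)
  rows <- purrr::pmap(genes[, c("gene_id", "contig", "strand", "tss")],
                      function(gene_id, contig, strand, tss) {
    L <- nchar(assembly[[contig]])
    if (tss < 1L || tss > L) {
      stop("gene ", gene_id, ": TSS ", tss, " outside contig ", contig,
           " (length ", L, ")", call. = FALSE)
    }
    if (strand == "+") {
      s1 <- max(1L, tss - up); e1 <- min(L, tss + down - 1L)
      up_len <- tss - s1; down_len <- e1 - tss + 1L
      seq <- substr(assembly[[contig]], s1, e1)
    } else {
      s1 <- max(1L, tss - down + 1L); e1 <- min(L, tss + up)
      up_len <- e1 - tss; down_len <- tss - s1 + 1L
      seq <- revcomp(substr(assembly[[contig]], s1, e1))
    }
    if (up_len < up || down_len < down) clipped <<- c(clipped, gene_id)
    tibble(gene_id = gene_id, contig = contig, strand = strand, tss = tss,
           up_len = as.integer(up_len), down_len = as.integer(down_len),
           win_start = s1 - 1L, win_end = e1, seq = seq)
  })
  if (length(clipped) > 0L) {
    warning("promoter window clipped at contig boundary for ", length(clipped),
            " gene(s): ", paste(head(clipped, 5), collapse = ", "),
            if (length(clipped) > 5) ", ...", call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Map a local promoter interval to genomic coordinates
#'
#' @param promoter one-row tibble from [extract_promoters()].
#' @param start,end local interval, 0-based half-open,
#'   `0 <= start < end <= nchar(seq)`.
#' @return named integer-ish list: `contig`, `start`, `end` (0-based
#'   half-open genomic) and `strand`.
#' @export
to_genomic <- function(promoter, start, end) {
  len <- nchar(promoter$seq)
  if (!(start >= 0 && start < end && end <= len)) {
    stop("local interval [", start, ",", end, ") outside promoter window of length ",
         len, call. = FALSE)
  }
  if (promoter$strand == "+") {
    gs <- promoter$win_start + start; ge <- promoter$win_start + end
  } else {
    gs <- promoter$win_end - end; ge <- promoter$win_end - start
  }
  list(contig = promoter$contig, start = as.integer(gs), end = as.integer(ge),
       strand = promoter$strand)
}

#' Map a genomic interval back to local promoter coordinates
#'
#' Inverse of [to_genomic()] on the promoter window.
#'
#' @param promoter one-row tibble from [extract_promoters()].
#' @param gstart,gend genomic interval, 0-based half-open, inside the window.
#' @return integer vector `c(start, end)` in local coordinates.
#' @export
from_genomic <- function(promoter, gstart, gend) {
  if (!(gstart >= promoter$win_start && gend <= promoter$win_end && gstart < gend)) {
    stop("genomic interval outside promoter window", call. = FALSE)
  }
  if (promoter$strand == "+") {
    c(start = as.integer(gstart - promoter$win_start),
      end = as.integer(gend - promoter$win_start))
  } else {
    c(start = as.integer(promoter$win_end - gend),
      end = as.integer(promoter$win_end - gstart))
  }
}

#' Add genomic interval columns to a site table
#'
#' @param sites tibble with `gene_id`, `start` and `matched_seq` (site width
#'   is taken from `matched_seq`).
#' @param promoters promoter tibble the sites were called on.
#' @return `sites` with `genomic_contig`, `genomic_start`, `genomic_end`
#'   (0-based half-open) appended.
#' @export
add_genomic_coords <- function(sites, promoters) {
  idx <- match(sites$gene_id, promoters$gene_id)
  if (anyNA(idx)) {
    stop("site gene(s) absent from promoter set: ",
         paste(unique(sites$gene_id[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  w <- nchar(sites$matched_seq)
  ws <- promoters$win_start[idx]; we <- promoters$win_end[idx]
  st <- promoters$strand[idx]
  gs <- ifelse(st == "+", ws + sites$start, we - (sites$start + w))
  ge <- gs + w
  dplyr::mutate(sites, genomic_contig = promoters$contig[idx],
                genomic_start = as.integer(gs), genomic_end = as.integer(ge))
}

#' Cross-assembly promoter identity filter
#'
#' Aligns each gene's promoter from one assembly against the same gene's
#' promoter from another assembly and keeps genes whose best local alignment
#' has identity (matches / alignment columns) at or above `min_identity`.
#' Genes present in only one assembly are excluded with a message, not an
#' error.
#'
#' @param promoters_v1,promoters_v2 promoter tibbles extracted with the same
#'   `up`/`down` from the two assemblies.
#' @param id_map optional tibble with columns `gene_id_v1`, `gene_id_v2`
#'   mapping identifiers across assemblies; by default identifiers are
#'   assumed shared.
#' @param min_identity identity threshold (default 0.90).
#' @param ... passed to [local_align()].
#' @return tibble with `gene_id_v1`, `gene_id_v2`, `identity`, `kept`.
#' @export
cross_assembly_filter <- function(promoters_v1, promoters_v2, id_map = NULL,
                                  min_identity = 0.90, ...) {
  if (is.null(id_map)) {
    shared <- intersect(promoters_v1$gene_id, promoters_v2$gene_id)
    id_map <- tibble(gene_id_v1 = shared, gene_id_v2 = shared)
  }
  in1 <- id_map$gene_id_v1 %in% promoters_v1$gene_id
  in2 <- id_map$gene_id_v2 %in% promoters_v2$gene_id
  dropped <- id_map[!(in1 & in2), , drop = FALSE]
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " gene(s) missing from one assembly; excluded")
  }
  id_map <- id_map[in1 & in2, , drop = FALSE]
  if (nrow(id_map) == 0L) {
    warning("no genes shared between the two assemblies", call. = FALSE)
    return(tibble(gene_id_v1 = character(), gene_id_v2 = character(),
                  identity = numeric(), kept = logical()))
  }
  s1 <- setNames(promoters_v1$seq, promoters_v1$gene_id)
  s2 <- setNames(promoters_v2$seq, promoters_v2$gene_id)
  ident <- purrr::map2_dbl(id_map$gene_id_v1, id_map$gene_id_v2, function(a, b) {
    aln <- local_align(s1[[a]], s2[[b]], ...)
    if (nrow(aln) == 0L) 0 else aln$identity[1]
  })
  tibble(gene_id_v1 = id_map$gene_id_v1, gene_id_v2 = id_map$gene_id_v2,
         identity = ident, kept = ident >= min_identity)
}

#' Remap sites onto promoters from another assembly
#'
#' A site remaps iff its exact matched word occurs on the same strand within
#' `tolerance` nucleotides of its original local coordinate in the target
#' promoter; the nearest occurrence wins, ties broken toward the smaller
#' coordinate.
#'
#' @param sites tibble with `gene_id`, `start`, `strand`, `matched_seq`.
#' @param target_promoters promoter tibble for the target assembly.
#' @param tolerance maximum allowed coordinate shift (nt).
#' @return `sites` with `remapped` (logical), `target_start` and `offset`
#'   columns appended; unmappable sites have `remapped = FALSE`.
#' @export
remap_sites <- function(sites, target_promoters, tolerance = 20L) {
  tseq <- setNames(target_promoters$seq, target_promoters$gene_id)
  res <- purrr::pmap(sites[, c("gene_id", "start", "strand", "matched_seq")],
                     function(gene_id, start, strand, matched_seq) {
    subj <- tseq[[gene_id]]
    if (is.null(subj)) return(tibble(remapped = FALSE, target_start = NA_integer_,
                                     offset = NA_integer_))
    word <- if (strand == "+") matched_seq else revcomp(matched_seq)
    occ <- fixed_matches(word, subj) - 1L  # 0-based starts
    occ <- occ[abs(occ - start) <= tolerance]
    if (length(occ) == 0L) {
      tibble(remapped = FALSE, target_start = NA_integer_, offset = NA_integer_)
    } else {
      d <- abs(occ - start)
      best <- occ[order(d, occ)][1]
      tibble(remapped = TRUE, target_start = best, offset = best - start)
    }
  })
  dplyr::bind_cols(sites, dplyr::bind_rows(res))
}
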