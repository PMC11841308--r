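#' Run the full conservation pipeline on a scenario bundle or file set
#'
#' Convenience driver composing the stage functions: promoter extraction for
#' the focal and each comparator species, ortholog-pair selection, local
#' alignment, similarity calls, PWM scanning of focal promoters, the
#' conservation test, aggregation into unique sites, and overlap annotation.
#'
#' @param assemblies named list of assemblies (named character vectors); the
#'   focal species must be named `focal`.
#' @param genes named list of gene-model tibbles, matching `assemblies`.
#' @param orthologs ortholog tibble ([read_ortholog_table()]).
#' @param motifs motif tibble ([read_meme_motifs()]).
#' @param acrs optional ACR tibble ([read_bed()]).
#' @param up,down promoter extent.
#' @param alpha scan p-value threshold.
#' @param min_score alignment score defining a significant alignment.
#' @param window conservation-test window (nt).
#' @param anchor_mode see [test_conservation()].
#' @param max_secondary see [local_align()].
#' @return list of class `promcons_run`: `promoters` (focal), `target_promoters`,
#'   `pairs`, `alignments`, `similarity`, `sites`, `calls`, `conserved`
#'   (annotated unique conserved sites), `background`.
#' @export
run_conservation_pipeline <- function(assemblies, genes, orthologs, motifs,
                                      acrs = NULL, up = 2000L, down = 200L,
                                      alpha = 1e-4, min_score = 40,
                                      window = 100L,
                                      anchor_mode = c("auto", "projection"),
                                      max_secondary = 5L) {
  anchor_mode <- match.arg(anchor_mode)
  stopifnot("focal" %in% names(assemblies))
  focal_prom <- extract_promoters(genes$focal, assemblies$focal, up, down)
  target_prom <- dplyr::bind_rows(lapply(
    setdiff(names(assemblies), "focal"),
    function(sp) extract_promoters(genes[[sp]], assemblies[[sp]], up, down)))
  pairs <- select_pairs(orthologs)
  alignments <- align_orthologs(focal_prom, target_prom, pairs,
                                min_score = min_score,
                                max_secondary = max_secondary)
  similarity <- similarity_calls(alignments, pairs, min_score = min_score)
  background <- estimate_background(focal_prom)
  sites <- scan_promoters(focal_prom, motifs, background, alpha = alpha)
  calls <- conservation_calls(sites, alignments, focal_prom, target_prom,
                              similarity, window = window,
                              anchor_mode = anchor_mode)
  conserved <- aggregate_conserved(calls)
  conserved <- annotate_overlap(conserved, focal_prom, genes$focal, acrs)
  structure(list(promoters = focal_prom, target_promoters = target_prom,
                 pairs = pairs, alignments = alignments,
                 similarity = similarity, sites = sites, calls = calls,
                 conserved = conserved, background = background),
            class = "promcons_run")
}

#' @export
print.promcons_run <- function(x, ...) {
  cat("promcons pipeline run\n")
  cat("  focal promoters:     ", nrow(x$promoters), "\n", sep = "")
  cat("  ortholog pairs:      ", nrow(x$pairs), "\n", sep = "")
  cat("  similar promoters:   ", sum(x$similarity$similar), " / ",
      nrow(x$similarity), " pairs\n", sep = "")
  cat("  scanned sites:       ", nrow(x$sites), "\n", sep = "")
  cat("  unique conserved:    ", nrow(x$conserved), "\n", sep = "")
  invisible(x)
}

#' Conserved nucleotide counts inside and outside ACRs
#'
#' Builds the 2x2 inputs for [acr_chi_square()]: the union of positions
#' covered by conserved sites, split by ACR membership, against the total
#' studied promoter length split the same way.
#'
#' @param conserved conserved-site tibble with genomic coordinates.
#' @param promoters focal promoter tibble (the studied windows).
#' @param acrs ACR tibble ([read_bed()]).
#' @return list with the four counts and the chi-square result.
#' @export
acr_association <- function(conserved, promoters, acrs) {
  prom_gr <- GenomicRanges::GRanges(
    promoters$contig, IRanges::IRanges(promoters$win_start + 1L, promoters$win_end))
  acr_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    acrs$contig, IRanges::IRanges(acrs$start + 1L, acrs$end)))
  site_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    conserved$genomic_contig,
    IRanges::IRanges(conserved$genomic_start + 1L, conserved$genomic_end)))
  site_gr <- GenomicRanges::intersect(site_gr, GenomicRanges::reduce(prom_gr))
  acr_in_prom <- GenomicRanges::intersect(acr_gr, GenomicRanges::reduce(prom_gr))
  total_nt <- sum(IRanges::width(GenomicRanges::reduce(prom_gr)))
  acr_nt <- sum(IRanges::width(acr_in_prom))
  cons_nt <- sum(IRanges::width(site_gr))
  cons_in_acr <- sum(IRanges::width(GenomicRanges::intersect(site_gr, acr_in_prom)))
  res <- acr_chi_square(cons_in_acr, cons_nt - cons_in_acr,
                        acr_nt, total_nt - acr_nt)
  c(list(conserved_nt_in_acr = cons_in_acr,
         conserved_nt_out = cons_nt - cons_in_acr,
         total_nt_in_acr = acr_nt, total_nt_out = total_nt - acr_nt), res)
}
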