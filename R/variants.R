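#' Intersect variants with conserved-site genomic intervals
#'
#' A SNV overlaps a site when its position falls inside the site interval;
#' a deletion overlaps when its reference span intersects the site; an
#' insertion overlaps when its anchor base lies inside the site. A variant
#' may hit several sites (one output row per variant-site pair).
#'
#' @param variants variant tibble ([read_vcf()]).
#' @param sites conserved-site tibble with genomic columns
#'   (`genomic_contig`, `genomic_start`, `genomic_end`; 0-based half-open).
#' @return tibble with variant columns, the hit site's key columns and its
#'   genomic interval.
#' @export
intersect_variants <- function(variants, sites) {
  if (nrow(variants) == 0L || nrow(sites) == 0L) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), genotypes = list(), gene_id = character(),
                  motif_id = character(), start = integer(), strand = character(),
                  genomic_start = integer(), genomic_end = integer()))
  }
  ref_len <- nchar(variants$ref)
  # variant reference span, 1-based inclusive (insertions occupy the anchor base)
  v_start <- variants$pos
  v_end <- variants$pos + pmax(ref_len - 1L, 0L)
  v_gr <- GenomicRanges::GRanges(variants$contig, IRanges::IRanges(v_start, v_end))
  s_gr <- GenomicRanges::GRanges(
    sites$genomic_contig,
    IRanges::IRanges(sites$genomic_start + 1L, sites$genomic_end))
  hits <- GenomicRanges::findOverlaps(v_gr, s_gr)
  vi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dplyr::bind_cols(
    variants[vi, , drop = FALSE],
    sites[si, c("gene_id", "motif_id", "start", "strand",
                "genomic_start", "genomic_end"), drop = FALSE]
  )
}

#' Per-group alternate-allele carrier summary
#'
#' For each accession group: the number of genotyped accessions carrying the
#' alternate allele (dosage >= 1) and the number genotyped at all (missing
#' genotypes excluded).
#'
#' @param hits tibble from [intersect_variants()] (or any tibble with a
#'   `genotypes` list-column of named dosages).
#' @param groups accession-group tibble ([read_groups_table()]).
#' @return `hits` expanded to one row per (hit, group) with `group`,
#'   `n_with_alt`, `n_genotyped`.
#' @export
group_allele_summary <- function(hits, groups) {
  grp_of <- setNames(groups$group, groups$accession)
  res <- purrr::map(seq_len(nrow(hits)), function(i) {
    dos <- hits$genotypes[[i]]
    grp <- grp_of[names(dos)]
    keep <- !is.na(grp)
    tab <- tibble(group = grp[keep], dosage = dos[keep]) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n_with_alt = sum(!is.na(.data$dosage) & .data$dosage >= 1L),
                       n_genotyped = sum(!is.na(.data$dosage)),
                       .groups = "drop")
    dplyr::bind_cols(hits[rep(i, nrow(tab)), setdiff(names(hits), "genotypes"),
                          drop = FALSE], tab)
  })
  dplyr::bind_rows(res)
}

#' TF-family co-occurrence network over a gene set
#'
#' Nodes are TF families with at least one conserved site in the gene set;
#' an edge connects two families with weight equal to the number of genes
#' whose promoters carry conserved sites of both. No self-loops; zero-weight
#' pairs are omitted.
#'
#' @param conserved_sites conserved-site tibble ([aggregate_conserved()]).
#' @param gene_set character vector of gene identifiers.
#' @return list of class `promcons_network` with `nodes` (tibble: `tf_family`,
#'   `n_genes`) and `edges` (tibble: `family_a`, `family_b`, `weight`;
#'   `family_a < family_b`).
#' @export
cooccurrence_network <- function(conserved_sites, gene_set) {
  ss <- conserved_sites[conserved_sites$gene_id %in% gene_set, , drop = FALSE]
  fam_sets <- ss |>
    dplyr::distinct(.data$gene_id, .data$tf_family) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(fams = list(sort(unique(.data$tf_family))), .groups = "drop")
  nodes <- ss |>
    dplyr::distinct(.data$gene_id, .data$tf_family) |>
    dplyr::count(.data$tf_family, name = "n_genes") |>
    dplyr::arrange(.data$tf_family)
  pair_counts <- list()
  for (fams in fam_sets$fams) {
    if (length(fams) < 2L) next
    cmb <- utils::combn(fams, 2L)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "\r")
      pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
    }
  }
  if (length(pair_counts) == 0L) {
    edges <- tibble(family_a = character(), family_b = character(),
                    weight = integer())
  } else {
    ab <- strsplit(names(pair_counts), "\r", fixed = TRUE)
    edges <- tibble(family_a = vapply(ab, `[`, "", 1),
                    family_b = vapply(ab, `[`, "", 2),
                    weight = as.integer(unlist(pair_counts))) |>
      dplyr::arrange(.data$family_a, .data$family_b)
  }
  structure(list(nodes = nodes, edges = edges), class = "promcons_network")
}

#' @export
print.promcons_network <- function(x, ...) {
  cat("TF-family co-occurrence network: ", nrow(x$nodes), " families, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Regulatory report for a set of genes
#'
#' Per gene: an ordered site track (TSS-relative position, family, level,
#' overlap flags), a family-by-gene count matrix, the TF-family
#' co-occurrence network and per-family occurrence p-values. Deterministic:
#' regenerating from the same inputs yields byte-identical JSON.
#'
#' @param gene_ids genes to report on; unknown ids are listed under
#'   `not_found`.
#' @param conserved_sites conserved-site tibble with overlap flags
#'   ([annotate_overlap()]) or at least key columns.
#' @param promoters promoter tibble (for TSS-relative positions).
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `matrix.tsv`, `network.tsv` and per-gene `track_<gene>.tsv`.
#' @return list of class `promcons_report` with `tracks` (named list of
#'   tibbles), `matrix` (families x genes count matrix), `network`,
#'   `family_tests`, `not_found`.
#' @export
gene_report <- function(gene_ids, conserved_sites, promoters, out_dir = NULL) {
  gene_ids <- unique(gene_ids)
  known <- gene_ids[gene_ids %in% promoters$gene_id]
  not_found <- setdiff(gene_ids, known)
  ss <- conserved_sites[conserved_sites$gene_id %in% known, , drop = FALSE]
  up_len <- promoters$up_len[match(ss$gene_id, promoters$gene_id)]
  ss <- dplyr::mutate(ss, tss_rel = .data$start - up_len)
  tracks <- lapply(setNames(known, known), function(g) {
    tr <- ss[ss$gene_id == g, , drop = FALSE]
    tr <- tr[order(tr$tss_rel, tr$motif_id), , drop = FALSE]
    cols <- intersect(c("tss_rel", "motif_id", "tf_family", "strand", "level",
                        "in_upstream_gene", "in_acr"), names(tr))
    tr[, cols, drop = FALSE]
  })
  fams <- sort(unique(conserved_sites$tf_family))
  mat <- matrix(0L, nrow = length(fams), ncol = length(known),
                dimnames = list(fams, known))
  if (nrow(ss) > 0L && length(fams) > 0L) {
    tb <- table(factor(ss$tf_family, levels = fams),
                factor(ss$gene_id, levels = known))
    mat[] <- as.integer(tb)
  }
  network <- cooccurrence_network(conserved_sites, known)
  family_tests <- if (nrow(ss) > 0L) {
    family_occurrence_test(ss, conserved_sites)
  } else {
    tibble(tf_family = character(), k = integer(), n = integer(),
           background_rate = numeric(), p_value = numeric(), q_value = numeric())
  }
  rep <- structure(
    list(tracks = tracks, matrix = mat, network = network,
         family_tests = family_tests, not_found = sort(not_found)),
    class = "promcons_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

# Serialize a report: report.json (sorted keys), matrix.tsv, network.tsv,
# per-gene track TSVs.
write_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_obj <- list(
    genes = names(rep$tracks),
    not_found = rep$not_found,
    tracks = lapply(rep$tracks, function(tr) as.data.frame(tr)),
    family_counts = apply(rep$matrix, 2, function(col)
      as.list(setNames(as.integer(col), rownames(rep$matrix))), simplify = FALSE),
    network = list(nodes = as.data.frame(rep$network$nodes),
                   edges = as.data.frame(rep$network$edges)),
    family_tests = as.data.frame(rep$family_tests)
  )
  json <- jsonlite::toJSON(json_obj, digits = NA, pretty = TRUE, na = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  write.table(rep$matrix, file.path(out_dir, "matrix.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(as.data.frame(rep$network$edges), file.path(out_dir, "network.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(rep$tracks)) {
    write.table(as.data.frame(rep$tracks[[g]]),
                file.path(out_dir, paste0("track_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
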