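#' Binned weighted regression of promoter similarity on protein identity
#'
#' Ortholog pairs are grouped into integer percent-identity bins
#' (`round(protein_pct_id)`, 0-100); the proportion of pairs with similar
#' promoters is computed per non-empty bin and regressed on the bin percent
#' by weighted least squares with weights equal to the bin counts, so bins
#' with many genes dominate the fit.
#'
#' @param pairs tibble with `protein_pct_id` (numeric) and `similar`
#'   (logical).
#' @return object of class `promcons_regression`: list with `slope`,
#'   `intercept`, `r_squared`, the per-bin tibble `bins` and the underlying
#'   `lm` fit.
#' @export
binned_weighted_regression <- function(pairs) {
  bins <- pairs |>
    dplyr::mutate(bin = round(.data$protein_pct_id)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     proportion_similar = mean(.data$similar),
                     .groups = "drop")
  if (nrow(bins) < 2L) {
    stop("need at least 2 non-empty identity bins for regression", call. = FALSE)
  }
  fit <- lm(proportion_similar ~ bin, data = bins, weights = bins$n_pairs)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         bins = bins, fit = fit),
    class = "promcons_regression"
  )
}

#' @export
print.promcons_regression <- function(x, ...) {
  cat("Binned weighted regression (", nrow(x$bins), " bins)\n", sep = "")
  cat(sprintf("  proportion_similar = %.4f + %.4f * percent_identity\n",
              x$intercept, x$slope))
  cat(sprintf("  weighted R-squared = %.3f\n", x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname binned_weighted_regression
#' @param x a `promcons_regression` object.
#' @param ... unused.
#' @export
tidy.promcons_regression <- function(x, ...) {
  x$bins
}

#' @rdname binned_weighted_regression
#' @export
glance.promcons_regression <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_bins = nrow(x$bins))
}

# Upper-tail binomial p-value P(X >= k), X ~ Binomial(n, p).
binom_upper_tail <- function(k, n, p) {
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' GO binomial enrichment of a gene subset
#'
#' For each GO term annotated to at least one universe gene, tests whether
#' the term is over-represented in the subset relative to its genome-wide
#' frequency: `p = P(X >= k)` with `X ~ Binomial(n, K/N)` where `k`/`K` are
#' subset/universe genes carrying the term and `n`/`N` the subset/universe
#' sizes. Benjamini-Hochberg q-values are computed across all tested terms.
#'
#' @param subset_genes character vector of genes (must be within the
#'   universe).
#' @param annotations GO tibble ([read_go_table()]).
#' @param universe_genes the gene universe; defaults to all annotated genes.
#' @param alpha q-value threshold for the `significant` flag.
#' @return tibble with `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `q_value`, `significant`, sorted by p-value.
#' @export
binomial_enrichment <- function(subset_genes, annotations,
                                universe_genes = unique(annotations$gene_id),
                                alpha = 0.05) {
  subset_genes <- unique(subset_genes)
  if (length(subset_genes) == 0L) stop("empty gene subset", call. = FALSE)
  extra <- setdiff(subset_genes, universe_genes)
  if (length(extra) > 0L) {
    stop("subset gene(s) outside the universe: ",
         paste(head(extra, 3), collapse = ", "), call. = FALSE)
  }
  ann <- annotations[annotations$gene_id %in% universe_genes, , drop = FALSE]
  N <- length(unique(universe_genes))
  n <- length(subset_genes)
  per_term <- ann |>
    dplyr::distinct(.data$gene_id, .data$go_id, .keep_all = TRUE) |>
    dplyr::group_by(.data$go_id) |>
    dplyr::summarise(term_name = .data$go_name[1],
                     K = dplyr::n_distinct(.data$gene_id),
                     k = sum(unique(.data$gene_id) %in% subset_genes),
                     .groups = "drop")
  out <- per_term |>
    dplyr::mutate(n = n, N = N,
                  p_value = binom_upper_tail(.data$k, n, .data$K / N)) |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH"),
                  significant = .data$q_value <= alpha) |>
    dplyr::rename(term_id = "go_id") |>
    dplyr::select("term_id", "term_name", "k", "n", "K", "N",
                  "p_value", "q_value", "significant") |>
    dplyr::arrange(.data$p_value, .data$term_id)
  out
}

#' TF-family occurrence test for a gene set
#'
#' For each TF family, tests whether genes of the query set carry conserved
#' sites of the family more often than genes genome-wide. The background
#' rate is the fraction of all genes with conserved sites that carry the
#' family; the test is an upper-tail binomial over the query genes with
#' conserved sites, BH-corrected across families.
#'
#' @param gene_set_sites conserved sites of the query gene set
#'   ([aggregate_conserved()] rows restricted to the set).
#' @param genome_sites conserved sites of all genes.
#' @return tibble with `tf_family`, `k`, `n`, `background_rate`, `p_value`,
#'   `q_value`.
#' @export
family_occurrence_test <- function(gene_set_sites, genome_sites) {
  genome_genes <- unique(genome_sites$gene_id)
  set_genes <- unique(gene_set_sites$gene_id)
  n <- length(set_genes)
  if (n == 0L) stop("gene set has no genes with conserved sites", call. = FALSE)
  fams <- sort(unique(genome_sites$tf_family))
  out <- purrr::map(fams, function(fam) {
    bg_genes <- unique(genome_sites$gene_id[genome_sites$tf_family == fam])
    rate <- length(bg_genes) / length(genome_genes)
    k <- length(unique(gene_set_sites$gene_id[gene_set_sites$tf_family == fam]))
    tibble(tf_family = fam, k = k, n = n, background_rate = rate,
           p_value = binom_upper_tail(k, n, rate))
  }) |> dplyr::bind_rows()
  dplyr::mutate(out, q_value = p.adjust(.data$p_value, method = "BH"))
}

#' Chi-square association of conserved nucleotides with ACRs
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table of
#' nucleotide counts: rows conserved / non-conserved, columns inside /
#' outside ACRs. Conserved nucleotides are the union of positions covered by
#' conserved sites within the studied promoters.
#'
#' @param conserved_nt_in_acr,conserved_nt_out conserved nucleotide counts
#'   inside and outside ACRs.
#' @param total_nt_in_acr,total_nt_out total studied promoter nucleotides
#'   inside and outside ACRs.
#' @return list with `chi2`, `p_value`, `table` (2x2 matrix).
#' @export
acr_chi_square <- function(conserved_nt_in_acr, conserved_nt_out,
                           total_nt_in_acr, total_nt_out) {
  counts <- c(conserved_nt_in_acr, conserved_nt_out, total_nt_in_acr, total_nt_out)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (total_nt_in_acr < conserved_nt_in_acr || total_nt_out < conserved_nt_out) {
    stop("totals must be at least the conserved counts", call. = FALSE)
  }
  tab <- matrix(c(conserved_nt_in_acr, conserved_nt_out,
                  total_nt_in_acr - conserved_nt_in_acr,
                  total_nt_out - conserved_nt_out),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("conserved", "non_conserved"),
                                c("in_acr", "out_acr")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: a table marginal is zero", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value), table = tab)
}

#' Kruskal-Wallis test of conserved-site counts across evidence codes
#'
#' Rank test (with tie correction, chi-square approximation) of whether
#' per-family conserved-site counts differ across literature evidence codes
#' (1 = no evidence, 2 = indirect evidence such as co-expression, 3 =
#' interaction described in plants).
#'
#' @param counts_by_group named list: evidence code -> numeric vector of
#'   conserved-site counts.
#' @return list with `H` (tie-corrected statistic), `p_value`, `df`.
#' @export
kruskal_wallis_evidence <- function(counts_by_group) {
  if (length(counts_by_group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(counts_by_group) == 0L)) stop("all groups must be non-empty", call. = FALSE)
  x <- unlist(counts_by_group, use.names = FALSE)
  g <- factor(rep(names(counts_by_group), lengths(counts_by_group)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}
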