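# The standard study scenario (200 genes, 3 species, d_bg 0.15, d_mot 0.01,
# indels 0.01) is expensive to build and align, so it is generated once per
# test run and shared by the tests that need it.

.scenario_cache <- new.env(parent = emptyenv())

std_scenario <- function() {
  if (is.null(.scenario_cache$bundle)) {
    .scenario_cache$bundle <- generate_scenario(scenario_config(seed = 20260923L))
  }
  .scenario_cache$bundle
}

std_run <- function() {
  if (is.null(.scenario_cache$run)) {
    b <- std_scenario()
    .scenario_cache$run <- run_conservation_pipeline(
      b$assemblies, b$genes, b$orthologs, b$motifs, acrs = b$acrs)
  }
  .scenario_cache$run
}

# Small helpers for hand-built fixtures.
toy_promoter <- function(gene_id, seq, up_len = NULL, contig = "c1",
                         strand = "+", win_start = 0L) {
  if (is.null(up_len)) up_len <- nchar(seq)
  tibble::tibble(gene_id = gene_id, contig = contig, strand = strand,
                 tss = NA_integer_, up_len = as.integer(up_len),
                 down_len = nchar(seq) - as.integer(up_len),
                 win_start = as.integer(win_start),
                 win_end = as.integer(win_start + nchar(seq)), seq = seq)
}

consensus_motif <- function(motif_id, consensus, tf_family = "fam", p = 1) {
  letters <- strsplit(consensus, "", fixed = TRUE)[[1]]
  ppm <- matrix((1 - p) / 3, nrow = length(letters), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(letters)) ppm[i, letters[i]] <- p
  tibble::tibble(motif_id = motif_id, tf_family = tf_family,
                 width = length(letters), ppm = list(ppm))
}

uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
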