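small_cfg <- function(...) {
  scenario_config(n_genes = 10L, up = 400L, down = 100L, seed = 3L, ...)
}

test_that("zero mutation yields identical promoters and full conservation", {
  cfg <- small_cfg(d_bg = 0, d_mot = 0, indel_rate = 0)
  b <- generate_scenario(cfg)
  tr <- b$truth$sites
  sel <- tr[tr$selected, ]
  expect_true(all(sel$conserved))
  expect_true(all(tr$conserved))  # with d_bg = 0 nothing mutates anywhere
  # comparator promoters equal the focal ones
  fp <- extract_promoters(b$genes$focal, b$assemblies$focal, 400L, 100L)
  tp <- extract_promoters(b$genes$sp1, b$assemblies$sp1, 400L, 100L)
  expect_equal(tp$seq, fp$seq)
})

test_that("saturating mutation with no selection destroys conservation", {
  cfg <- small_cfg(d_bg = 0.9, d_mot = 0.9, conserved_fraction = 0)
  b <- generate_scenario(cfg)
  expect_true(mean(b$truth$sites$conserved) < 0.01)
})

test_that("the same seed reproduces a byte-identical bundle on disk", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_scenario(small_cfg(), out_dir = d1)
  generate_scenario(small_cfg(), out_dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
  # a different seed changes the bundle
  d3 <- withr::local_tempdir()
  generate_scenario(scenario_config(n_genes = 10L, up = 400L, down = 100L,
                                    seed = 4L), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "focal.fa")),
                         readLines(file.path(d3, "focal.fa"))))
})

test_that("emitted files are mutually consistent and parse cleanly", {
  d <- withr::local_tempdir()
  b <- generate_scenario(small_cfg(), out_dir = d)
  asm <- read_fasta(file.path(d, "focal.fa"))
  genes <- read_gff3_genes(file.path(d, "focal.gff3"))
  expect_equal(sort(genes$gene_id), sort(b$genes$focal$gene_id))
  pr_disk <- extract_promoters(genes, asm, 400L, 100L)
  pr_mem <- extract_promoters(b$genes$focal, b$assemblies$focal, 400L, 100L)
  expect_equal(pr_disk[order(pr_disk$gene_id), ]$seq,
               pr_mem[order(pr_mem$gene_id), ]$seq)
  motifs <- read_meme_motifs(file.path(d, "motifs.meme"))
  expect_equal(motifs$motif_id, b$motifs$motif_id)
  orth <- read_ortholog_table(file.path(d, "orthologs.tsv"))
  expect_equal(nrow(orth), nrow(b$orthologs))
  v <- read_vcf(file.path(d, "variants.vcf"))
  expect_equal(nrow(v), nrow(b$variants))
  expect_equal(v$pos, b$variants$pos)
  expect_equal(unname(v$genotypes[[1]]), unname(b$variants$genotypes[[1]]))
  acr <- read_bed(file.path(d, "acrs.bed"))
  expect_equal(nrow(acr), 10L)
})

test_that("planted words sit in the focal promoters where truth says", {
  b <- generate_scenario(small_cfg())
  fp <- extract_promoters(b$genes$focal, b$assemblies$focal, 400L, 100L)
  seqs <- setNames(fp$seq, fp$gene_id)
  tr <- dplyr::distinct(b$truth$sites, gene_id, start, .keep_all = TRUE)
  for (i in seq_len(nrow(tr))) {
    expected <- if (tr$strand[i] == "+") tr$word[i] else revcomp(tr$word[i])
    expect_equal(substr(seqs[[tr$gene_id[i]]], tr$start[i] + 1L,
                        tr$start[i] + tr$width[i]), expected)
  }
})

test_that("truth-conserved words are present intact in descendant promoters", {
  b <- generate_scenario(small_cfg())
  for (sp in b$config$species) {
    tp <- extract_promoters(b$genes[[sp]], b$assemblies[[sp]], 400L, 100L)
    tr <- b$truth$sites[b$truth$sites$species == sp & b$truth$sites$conserved, ]
    for (i in seq_len(nrow(tr))) {
      expected <- if (tr$strand[i] == "+") tr$word[i] else revcomp(tr$word[i])
      subj <- tp$seq[tp$gene_id == paste0(sp, "_", tr$gene_id[i])]
      expect_equal(substr(subj, tr$target_start[i] + 1L,
                          tr$target_start[i] + tr$width[i]), expected)
    }
  }
})

test_that("recovery metrics follow their stated conventions", {
  truth <- tibble::tibble(gene_id = "g1", species = "sp1", motif_id = "m1",
                          strand = "+", start = 100L, conserved = TRUE)
  calls_exact <- dplyr::mutate(truth, conserved = TRUE)
  m <- recovery_metrics(calls_exact, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  expect_warning(m0 <- recovery_metrics(calls_exact[0, ], truth), "convention")
  expect_equal(m0$precision, 1)
  expect_equal(m0$recall, 0)

  off5 <- dplyr::mutate(truth, start = 105L)
  m5 <- recovery_metrics(off5, truth)
  expect_equal(m5$recall, 0)
  off3 <- dplyr::mutate(truth, start = 103L)
  expect_equal(recovery_metrics(off3, truth)$recall, 1)
})

test_that("alignment coverage decays away from the TSS under rate decay", {
  ok <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- scenario_config(n_genes = 25L, species = "sp1", up = 1000L,
                           down = 100L, d_bg = 0.25,
                           decay_with_distance = TRUE,
                           decay_mult_range = c(0.4, 2.4),
                           mean_sites_per_promoter = 2,
                           seed = 1000L + r)
    b <- generate_scenario(cfg)
    fp <- extract_promoters(b$genes$focal, b$assemblies$focal, 1000L, 100L)
    tp <- extract_promoters(b$genes$sp1, b$assemblies$sp1, 1000L, 100L)
    aln <- align_orthologs(fp, tp, select_pairs(b$orthologs))
    cp <- coverage_profile(aln, up = 1000L, down = 100L)
    near <- mean(cp$count[cp$position >= -100 & cp$position < 0])
    far <- mean(cp$count[cp$position >= -1000 & cp$position < -900])
    if (near > far) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("higher background divergence lowers the similar-promoter rate", {
  rates <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  sim_rate <- vapply(seq_along(rates), function(i) {
    cfg <- scenario_config(n_genes = 15L, species = "sp1", up = 500L,
                           down = 100L, d_bg = rates[i], d_mot = 0.01,
                           mean_sites_per_promoter = 1, seed = 77L)
    b <- generate_scenario(cfg)
    fp <- extract_promoters(b$genes$focal, b$assemblies$focal, 500L, 100L)
    tp <- extract_promoters(b$genes$sp1, b$assemblies$sp1, 500L, 100L)
    pairs <- select_pairs(b$orthologs)
    aln <- align_orthologs(fp, tp, pairs)
    mean(similarity_calls(aln, pairs)$similar)
  }, numeric(1))
  expect_lt(stats::cor(rates, sim_rate, method = "spearman"), 0)
  expect_true(sim_rate[1] >= sim_rate[5])
})

test_that("a motif wider than the promoter window is rejected", {
  wide <- consensus_motif("huge", strrep("ACGT", 40))
  cfg <- scenario_config(n_genes = 2L, up = 100L, down = 20L, motifs = wide,
                         seed = 1L)
  expect_error(generate_scenario(cfg), "wider")
})
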