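test_that("CIGAR projection maps M, I and D runs correctly", {
  aln <- tibble::tibble(q_start = 0L, q_end = 10L, t_start = 5L, t_end = 15L,
                        cigar = "10M", score = 20L)
  expect_equal(project_position(aln, 3L), 8L)
  expect_equal(project_position(aln, 10L), NA_integer_)  # past the interval

  aln2 <- tibble::tibble(q_start = 0L, q_end = 8L, t_start = 0L, t_end = 10L,
                         cigar = "4M2D4M", score = 10L)
  expect_equal(project_position(aln2, 5L), 7L)
  expect_equal(project_position(aln2, 3L), 3L)

  aln3 <- tibble::tibble(q_start = 2L, q_end = 12L, t_start = 0L, t_end = 7L,
                         cigar = "3M3I4M", score = 8L)
  # positions inside the I run map to the column right after the last match
  expect_equal(project_position(aln3, 6L), 3L)
  expect_equal(project_position(aln3, 9L), 4L)
})

test_that("projection agrees with explicit column expansion", {
  run <- std_run()
  a <- head(run$alignments, 40)
  set.seed(4)
  for (i in seq_len(nrow(a))) {
    for (q in sample(seq.int(a$q_start[i], a$q_end[i] - 1L),
                     min(5, a$q_end[i] - a$q_start[i]))) {
      expect_equal(project_position(a[i, ], q),
                   project_oracle(a$q_start[i], a$t_start[i], a$cigar[i], q))
    }
  }
})

test_that("identical promoters conserve every site at offset zero", {
  seq <- paste0(strrep("T", 40), "ACGTACGTGG", strrep("C", 40))
  qp <- toy_promoter("g1", seq)
  tp <- toy_promoter("t1", seq)
  aln <- local_align(seq, seq, min_score = 40)
  site <- tibble::tibble(start = 40L, strand = "+", matched_seq = "ACGTACGTGG")
  r <- test_conservation(site, qp, tp, aln)
  expect_true(r$conserved)
  expect_equal(r$offset, 0L)
  expect_equal(r$anchored_by, "alignment")
})

test_that("an indel-shifted site is found through the alignment projection", {
  set.seed(8)
  word <- "ACGTACGTGG"
  left <- random_dna_str(150)
  right <- random_dna_str(150)
  q <- paste0(left, word, right)
  t <- paste0(left, random_dna_str(60), word, right)  # 60-nt insertion upstream
  qp <- toy_promoter("g1", q); tp <- toy_promoter("t1", t)
  aln <- local_align(q, t, min_score = 40)
  site <- tibble::tibble(start = 150L, strand = "+", matched_seq = word)
  r <- test_conservation(site, qp, tp, aln)
  expect_true(r$conserved)
  expect_equal(r$target_position, 210L)
  expect_true(abs(r$offset) <= 60L)
})

test_that("occurrences beyond the window are not conserved", {
  word <- "ACGTACGTGG"
  q <- paste0(strrep("T", 100), word, strrep("T", 100))
  # target: word only 150 nt downstream of the anchor, no alignment
  t <- paste0(strrep("T", 250), word, strrep("T", 50))
  qp <- toy_promoter("g1", q, up_len = 100L)
  tp <- toy_promoter("t1", t, up_len = 100L)
  site <- tibble::tibble(start = 100L, strand = "+", matched_seq = word)
  r <- test_conservation(site, qp, tp, alignments = local_align(q, t)[0, ],
                         window = 100L)
  expect_false(r$conserved)
  r2 <- test_conservation(site, qp, tp, alignments = local_align(q, t)[0, ],
                          window = 200L)
  expect_true(r2$conserved)
})

test_that("minus-strand sites honor strand through the word convention", {
  word_plus <- "ACGTACGTGG"      # promoter-strand letters
  q <- paste0(strrep("T", 60), word_plus, strrep("C", 60))
  site <- tibble::tibble(start = 60L, strand = "-",
                         matched_seq = revcomp(word_plus))
  qp <- toy_promoter("g1", q)
  # same promoter-strand word present => conserved (same relative strand)
  r <- test_conservation(site, qp, toy_promoter("t1", q),
                         local_align(q, q, min_score = 40))
  expect_true(r$conserved)
  # target carrying only the reverse complement of the word => not conserved
  t2 <- paste0(strrep("T", 60), revcomp(word_plus), strrep("C", 60))
  r2 <- test_conservation(site, qp, toy_promoter("t2", t2),
                          local_align(q, t2, min_score = 40)[0, ])
  expect_false(r2$conserved)
})

test_that("conservation is invariant under joint reverse complementation", {
  set.seed(13)
  b <- generate_scenario(scenario_config(n_genes = 6L, seed = 99L,
                                         up = 500L, down = 100L))
  run <- run_conservation_pipeline(b$assemblies, b$genes, b$orthologs,
                                   b$motifs, up = 500L, down = 100L)
  calls <- run$calls
  # reverse-complement every promoter, recompute alignments and calls
  flip <- function(p) {
    p$seq <- revcomp(p$seq)
    p$up_len2 <- p$down_len; p$down_len <- p$up_len; p$up_len <- p$up_len2
    p$up_len2 <- NULL
    p
  }
  fp <- flip(run$promoters); tp <- flip(run$target_promoters)
  L <- 600L
  sites_f <- run$sites
  w <- nchar(sites_f$matched_seq)
  sites_f$start <- L - (sites_f$start + w)
  sites_f$strand <- ifelse(sites_f$strand == "+", "-", "+")
  aln_f <- align_orthologs(fp, tp, run$pairs)
  calls_f <- conservation_calls(sites_f, aln_f, fp, tp, run$similarity)
  key_orig <- paste(calls$gene_id, calls$species, calls$motif_id, calls$start,
                    calls$strand, calls$conserved)
  wf <- nchar(calls_f$matched_seq)
  key_flip <- paste(calls_f$gene_id, calls_f$species, calls_f$motif_id,
                    L - (calls_f$start + wf),
                    ifelse(calls_f$strand == "+", "-", "+"), calls_f$conserved)
  expect_equal(sum(calls$conserved), sum(calls_f$conserved))
  expect_setequal(key_flip, key_orig)
})

test_that("aggregation deduplicates sites and levels partition the total", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    motif_id = c("m1", "m1", "m1", "m2", "m2"),
    tf_family = "fam", start = c(10L, 10L, 10L, 5L, 5L),
    strand = "+", matched_seq = "ACGT",
    species = c("sp1", "sp2", "sp3", "sp1", "sp2"),
    conserved = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  agg <- aggregate_conserved(calls)
  expect_equal(nrow(agg), 1L)  # g2's site conserved nowhere -> dropped
  expect_equal(agg$level, 2L)
  expect_equal(agg$species_conserved[[1]], c("sp1", "sp3"))

  run <- std_run()
  agg2 <- aggregate_conserved(run$calls)
  expect_true(all(agg2$level >= 1 & agg2$level <= 3))
  expect_equal(lengths(agg2$species_conserved), agg2$level)
  expect_equal(sum(table(agg2$level)), nrow(agg2))
})

test_that("overlap flags use half-open intersection semantics", {
  sites <- tibble::tibble(
    gene_id = c("g1", "g1", "g1"), motif_id = "m", tf_family = "f",
    start = 0L, strand = "+", matched_seq = "ACGTACGTGG",
    genomic_contig = "c1",
    genomic_start = c(100L, 200L, 300L), genomic_end = c(110L, 210L, 310L))
  gene_models <- tibble::tibble(
    gene_id = c("g1", "g0"), contig = "c1", strand = "+",
    start = c(1000L, 301L), end = c(1500L, 400L), tss = c(1000L, 301L))
  acrs <- tibble::tibble(contig = "c1", start = c(90L, 210L), end = c(105L, 220L))
  out <- annotate_overlap(sites, promoters = NULL, gene_models, acrs)
  # site [100,110) overlaps ACR [90,105); site [200,210) abuts ACR [210,220)
  expect_equal(out$in_acr, c(TRUE, FALSE, FALSE))
  # site [300,310) overlaps gene g0 ([301,400] 1-based) by its last bases
  expect_equal(out$in_upstream_gene, c(FALSE, FALSE, TRUE))
})

test_that("site position profiles stratify consistently by level", {
  pr <- dplyr::bind_rows(toy_promoter("g1", strrep("A", 2200), up_len = 2000L),
                         toy_promoter("g2", strrep("A", 2200), up_len = 2000L))
  sites <- tibble::tibble(gene_id = c("g1", "g1", "g2"),
                          start = c(1990L, 0L, 1990L),
                          level = c(1L, 2L, 1L))
  prof <- site_position_profile(sites, pr)
  expect_equal(prof$count[prof$position == -10], 2L)
  expect_equal(prof$count[prof$position == -2000], 1L)
  expect_equal(sum(prof$count), 3L)
  strat <- site_position_profile(sites, pr, by_level = TRUE)
  tot <- tapply(strat$count, strat$position, sum)
  expect_equal(as.integer(tot[as.character(prof$position)]), prof$count)

  empty <- site_position_profile(sites[0, ], pr)
  expect_true(all(empty$count == 0L))
})

test_that("planted sites are recovered on the standard scenario", {
  b <- std_scenario()
  run <- std_run()
  m <- recovery_metrics(run$calls, b$truth$sites)
  expect_gte(m$recall, 0.85)
  expect_gte(m$precision, 0.90)
})
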