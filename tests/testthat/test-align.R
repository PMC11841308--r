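test_that("ortholog pair selection filters and breaks ties as documented", {
  pairs <- tibble::tibble(
    query_gene = c("g1", "g1", "g2", "g3", "g4", "g4", "g5"),
    target_gene = c("t40", "t70", "t25", "tX", "gB", "gA", "tLow"),
    species = "sp1",
    homology_type = c("one2many", "one2many", "one2one", "many2many",
                      "one2many", "one2many", "one2one"),
    protein_pct_id = c(40, 70, 25, 90, 60, 60, 80),
    goc = c(NA, NA, NA, NA, 75, 75, 25),
    wga = c(NA, NA, NA, NA, 80, 80, 90))
  sel <- select_pairs(pairs)
  # one2many: highest protein identity wins
  expect_equal(sel$target_gene[sel$query_gene == "g1"], "t70")
  # strict > 25 excludes the pair at exactly 25
  expect_false("g2" %in% sel$query_gene)
  # many2many homology is not eligible
  expect_false("g3" %in% sel$query_gene)
  # tie broken lexicographically
  expect_equal(sel$target_gene[sel$query_gene == "g4"], "gA")
  # GOC below threshold excluded
  expect_false("g5" %in% sel$query_gene)
})

test_that("self-alignment yields a full-length match at 2 points per base", {
  s <- "ACGTACGTACGTACGTACGTACGT"
  a <- local_align(s, s)
  expect_equal(nrow(a), 1L)
  expect_equal(a$score, 48L)
  expect_equal(a$cigar, "24M")
  expect_equal(a$identity, 1)
})

test_that("a single-base gap costs the opening penalty only", {
  a <- local_align("AAAATTTT", "AAAACTTTT", min_score = 1)
  expect_equal(a$cigar[1], "4M1D4M")
  expect_equal(a$score[1], 12L)  # 8 matches * 2 - 4
  expect_equal(a$n_matches[1], 8L)
})

test_that("masked re-runs recover a second conserved block", {
  set.seed(21)
  block1 <- random_dna_str(30)
  block2 <- random_dna_str(30)
  q <- paste0(block1, random_dna_str(200), block2)
  t <- paste0(block2, random_dna_str(180), block1)
  a <- local_align(q, t, min_score = 40)
  expect_equal(nrow(a), 2L)
  expect_equal(a$rank, c("primary", "secondary"))
  # one alignment covers each planted block (ends may extend by chance matches)
  expect_true(any(a$q_start <= 2 & a$q_end >= 28))
  expect_true(any(a$q_start <= 232 & a$q_end >= 258))
})

test_that("alignment scores equal the brute-force affine-gap oracle", {
  set.seed(99)
  for (k in 1:60) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    q <- random_dna_str(n1)
    t <- if (k %% 3 == 0) {
      # related pair: mutated copy, exercises gappy optima
      s <- q
      for (p in sample(n1, ceiling(n1 / 6))) {
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    } else random_dna_str(n2)
    a <- local_align(q, t, min_score = 1)
    got <- if (nrow(a) == 0L) 0L else a$score[1]
    expect_equal(got, sw_score_oracle(q, t), label = paste("pair", k))
  }
})

test_that("emitted CIGARs are consistent with their intervals and matches", {
  run <- std_run()
  a <- head(run$alignments, 500)
  for (i in seq_len(nrow(a))) {
    spans <- promcons:::cigar_spans(a$cigar[i])
    expect_equal(unname(spans["q"]), a$q_end[i] - a$q_start[i])
    expect_equal(unname(spans["t"]), a$t_end[i] - a$t_start[i])
    expect_true(a$identity[i] >= 0 && a$identity[i] <= 1)
  }
})

test_that("similarity calls apply the score threshold and union spans", {
  aln <- tibble::tibble(
    query_gene = c("g1", "g1", "g2"), species = "sp1",
    target_gene = c("t1", "t1", "t2"),
    q_start = c(0L, 50L, 0L), q_end = c(100L, 150L, 24L),
    score = c(60L, 45L, 30L))
  pairs <- tibble::tibble(query_gene = c("g1", "g2", "g3"),
                          target_gene = c("t1", "t2", "t3"), species = "sp1")
  sc <- similarity_calls(aln, pairs, min_score = 40)
  expect_equal(sc$similar, c(TRUE, FALSE, FALSE))
  expect_equal(sc$aligned_span[sc$query_gene == "g1"], 150L)
  expect_equal(sc$aligned_span[sc$query_gene == "g3"], 0L)
})

test_that("orthology shuffling is a seeded derangement within species", {
  pairs <- tibble::tibble(query_gene = c("g1", "g2"),
                          target_gene = c("t1", "t2"), species = "sp1")
  sh <- shuffle_orthology(pairs, seed = 1L)
  expect_equal(sh$target_gene, c("t2", "t1"))

  big <- tibble::tibble(query_gene = sprintf("g%03d", 1:100),
                        target_gene = sprintf("t%03d", 1:100),
                        species = rep(c("spA", "spB"), each = 50))
  sh1 <- shuffle_orthology(big, seed = 7L)
  sh2 <- shuffle_orthology(big, seed = 7L)
  expect_identical(sh1, sh2)
  expect_true(all(sh1$target_gene != big$target_gene))
  expect_equal(sort(sh1$target_gene[1:50]), sort(big$target_gene[1:50]))

  single <- tibble::tibble(query_gene = "g1", target_gene = "t1",
                           species = "lonely")
  expect_warning(shuffle_orthology(single, seed = 1L), "fewer than 2")
})

test_that("coverage profiles count each gene once per position", {
  aln <- tibble::tibble(
    query_gene = c("g1", "g2", "g2"), species = "sp1", target_gene = "t",
    q_start = c(1990L, 1990L, 2000L), q_end = c(2010L, 2010L, 2005L),
    score = 50L)
  cp <- coverage_profile(aln, up = 2000L, down = 200L)
  expect_equal(nrow(cp), 2200L)
  expect_equal(cp$count[cp$position == -10], 2L)
  expect_equal(cp$count[cp$position == 3], 2L)  # overlap counted once for g2
  expect_equal(cp$count[cp$position == -11], 0L)
  expect_equal(cp$count[cp$position == 9], 2L)
  expect_equal(cp$count[cp$position == 10], 0L)
})

test_that("coverage profiles match naive interval stabbing on real alignments", {
  run <- std_run()
  sub <- run$alignments[run$alignments$species == run$alignments$species[1], ]
  sub <- sub[sub$query_gene %in% head(unique(sub$query_gene), 25), ]
  cp <- coverage_profile(sub, up = 2000L, down = 200L)
  expect_equal(cp$count, coverage_oracle(sub, 2000L, 200L))
})
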