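test_that("binned weighted regression recovers exact and degenerate fits", {
  # two bins exactly on a line -> perfect fit
  pairs <- tibble::tibble(
    protein_pct_id = c(rep(40, 10), rep(80, 10)),
    similar = c(rep(c(TRUE, FALSE), 5), rep(TRUE, 8), FALSE, FALSE))
  # two points define the line exactly; lm warns about the perfect fit
  r <- suppressWarnings(binned_weighted_regression(pairs))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, (0.8 - 0.5) / 40)

  # constant proportions -> zero slope
  flat <- tibble::tibble(protein_pct_id = rep(c(30, 50, 70), each = 10),
                         similar = rep(rep(c(TRUE, FALSE), 5), 3))
  expect_equal(suppressWarnings(binned_weighted_regression(flat))$slope, 0,
               tolerance = 1e-12)

  expect_error(binned_weighted_regression(
    tibble::tibble(protein_pct_id = rep(50, 5), similar = TRUE)), "2 non-empty")
})

test_that("weighted fit matches the closed-form normal equations", {
  # bins 10/50/90 with counts 10/1/10 and chosen proportions
  pairs <- dplyr::bind_rows(
    tibble::tibble(protein_pct_id = rep(10, 10), similar = rep(c(TRUE, FALSE), 5)),
    tibble::tibble(protein_pct_id = 50, similar = TRUE),
    tibble::tibble(protein_pct_id = rep(90, 10),
                   similar = rep(c(TRUE, FALSE), c(9, 1))))
  r <- binned_weighted_regression(pairs)
  x <- c(10, 50, 90); y <- c(0.5, 1, 0.9); w <- c(10, 1, 10)
  sw <- sum(w); xb <- sum(w * x) / sw; yb <- sum(w * y) / sw
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  intercept <- yb - slope * xb
  expect_equal(r$slope, slope, tolerance = 1e-12)
  expect_equal(r$intercept, intercept, tolerance = 1e-12)
  ss_res <- sum(w * (y - (intercept + slope * x))^2)
  ss_tot <- sum(w * (y - yb)^2)
  expect_equal(r$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_equal(nrow(tidy(r)), 3L)
  expect_equal(glance(r)$n_bins, 3L)
})

test_that("binomial enrichment tails are exact", {
  ann <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    go_id = rep(c("GO:0000001", "GO:0000002"), each = 20),
    go_name = "t", level = 2L)
  # half the universe carries term 1; a subset of 10 that all carry it
  subset <- sprintf("g%02d", 1:10)
  res <- binomial_enrichment(subset, ann,
                             universe_genes = sprintf("g%02d", 1:40))
  expect_equal(res$p_value[res$term_id == "GO:0000001"], 0.5^10,
               tolerance = 1e-15)
  # k = 0 -> p = 1
  expect_equal(res$p_value[res$term_id == "GO:0000002"], 1)
  expect_error(binomial_enrichment(character(0), ann), "empty")
  expect_error(binomial_enrichment("not_in_universe", ann), "outside")
})

test_that("binomial tails match direct summation to 1e-12 for n <= 50", {
  set.seed(5)
  for (k in 1:40) {
    n <- sample(1:50, 1)
    p <- stats::runif(1, 0.01, 0.99)
    kk <- sample(0:n, 1)
    direct <- sum(vapply(kk:n, function(i)
      choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
    expect_equal(promcons:::binom_upper_tail(kk, n, p), direct,
                 tolerance = 1e-12)
  }
  # n = 20, K/N = 0.1, k = 5 spelled out
  direct <- sum(vapply(5:20, function(i)
    choose(20, i) * 0.1^i * 0.9^(20 - i), numeric(1)))
  expect_equal(promcons:::binom_upper_tail(5, 20, 0.1), direct,
               tolerance = 1e-15)
})

test_that("BH q-values are monotone and order-invariant", {
  ann <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:60), times = 3),
    go_id = rep(sprintf("GO:%07d", 1:3), each = 60)[sample(180)],
    go_name = "t", level = 2L)
  set.seed(2)
  ann <- ann[sample(nrow(ann)), ]
  subset <- sprintf("g%02d", 1:15)
  r1 <- binomial_enrichment(subset, ann)
  expect_true(all(diff(r1$q_value[order(r1$p_value)]) >= -1e-15))
  expect_true(all(r1$q_value >= r1$p_value - 1e-15))
  r2 <- binomial_enrichment(subset, ann[rev(seq_len(nrow(ann))), ])
  expect_equal(r1[order(r1$term_id), ], r2[order(r2$term_id), ])
})

test_that("null GO enrichment keeps the family-wise false-positive rate low", {
  set.seed(17)
  universe <- sprintf("g%03d", 1:200)
  ann <- dplyr::bind_rows(lapply(1:15, function(ti) {
    hit <- stats::runif(200) < 0.15
    tibble::tibble(gene_id = universe[hit], go_id = sprintf("GO:%07d", ti),
                   go_name = "t", level = 2L)
  }))
  n_sig <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    subset <- sample(universe, 30)
    res <- binomial_enrichment(subset, ann, universe_genes = universe,
                               alpha = 0.05)
    if (any(res$significant)) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig / n_rep, 0.10)
})

test_that("enrichment flags the planted term on the standard scenario", {
  b <- std_scenario()
  run <- std_run()
  # the planted term targets genes with conserved sites of one TF family
  fam <- b$config$go_family
  subset <- unique(run$conserved$gene_id[run$conserved$tf_family == fam])
  res <- binomial_enrichment(intersect(subset, unique(b$go$gene_id)), b$go)
  expect_true("GO:0000001" %in% res$term_id[res$significant])
})

test_that("family occurrence test handles saturated and absent families", {
  genome <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:20), each = 2),
    tf_family = rep(c("everywhere", "rare"), times = 20))
  genome <- genome[!(genome$tf_family == "rare" & genome$gene_id > "g05"), ]
  qset <- genome[genome$gene_id %in% sprintf("g%02d", 1:12), ]
  res <- family_occurrence_test(qset, genome)
  expect_equal(res$p_value[res$tf_family == "everywhere"], 1)  # rate 1, k = n
  rare <- res[res$tf_family == "rare", ]
  direct <- sum(vapply(rare$k:rare$n, function(i)
    choose(rare$n, i) * rare$background_rate^i *
      (1 - rare$background_rate)^(rare$n - i), numeric(1)))
  expect_equal(rare$p_value, direct, tolerance = 1e-12)
})

test_that("the 2x2 chi-square equals its closed form", {
  r0 <- acr_chi_square(50, 50, 100, 100)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)

  r <- acr_chi_square(30, 10, 100, 100)
  # closed form: N (ad - bc)^2 / (r1 r2 c1 c2) on table (30,10 / 70,90)
  expect_equal(r$chi2, 12.5, tolerance = 1e-12)
  r2 <- acr_chi_square(60, 20, 200, 200)
  expect_equal(r2$chi2, 25, tolerance = 1e-12)  # doubling doubles chi2

  expect_error(acr_chi_square(0, 0, 100, 100), "marginal")
  expect_error(acr_chi_square(30, 10, 20, 100), "totals")
})

test_that("Kruskal-Wallis matches rank arithmetic, with and without ties", {
  same <- kruskal_wallis_evidence(list(`1` = c(1, 2), `2` = c(1, 2)))
  expect_equal(same$H, 0)

  r <- kruskal_wallis_evidence(list(`1` = c(1, 2, 3), `2` = c(4, 5, 6),
                                    `3` = c(7, 8, 9)))
  expect_equal(r$H, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)

  # tie correction: group of constants against spread groups
  groups <- list(`1` = c(5, 5, 5), `2` = c(1, 2, 3), `3` = c(7, 8, 9))
  rt <- kruskal_wallis_evidence(groups)
  x <- unlist(groups); rk <- rank(x)
  n <- length(x)
  Rsum <- tapply(rk, rep(1:3, each = 3), sum)
  H0 <- 12 / (n * (n + 1)) * sum(Rsum^2 / 3) - 3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  expect_equal(rt$H, H0 / C, tolerance = 1e-12)

  expect_error(kruskal_wallis_evidence(list(a = 1)), "2 groups")
  expect_error(kruskal_wallis_evidence(list(a = 1, b = numeric(0))), "non-empty")
})
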