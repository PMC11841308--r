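#' Default motif library for synthetic scenarios
#'
#' Eight informative motifs (widths 13-14) built around core boxes of common
#' plant TF families (GCC-box for ERF, DRE for DREB, MYB box, G-box for
#' bHLH, W-box for WRKY, CArG-like box for MADS). Each position puts
#' `p_consensus` on the consensus letter and the remainder uniformly on the
#' other three, the profile of a strong, experimentally supported binding
#' site. The consensus strings are chosen so that no two motifs (nor any
#' motif and a reverse complement) share more than 8 aligned letters at any
#' ungapped offset, which keeps cross-motif and cross-strand scan hits out
#' of planted sites.
#'
#' @param p_consensus consensus-letter probability per position.
#' @return motif tibble as from [read_meme_motifs()].
#' @export
default_motif_library <- function(p_consensus = 0.97) {
  defs <- list(
    c("M_ERF", "ERF", "ATAGCCGCCTTCA"),
    c("M_DREB", "DREB", "TTACCGACATGAG"),
    c("M_MYB", "MYB", "CGGTAACTGACCT"),
    c("M_BHLH", "bHLH", "ATTCACGTGGCTT"),
    c("M_WRKY", "WRKY", "CGTTGACCTAGAT"),
    c("M_C2H2", "C2H2", "AGTGGGCGGAGAT"),
    c("M_MADS", "MADS", "TTCCAAATAAGGCA"),
    c("M_NAC", "NAC", "ACACGCAAGTCCTG")
  )
  rows <- purrr::map(defs, function(d) {
    letters <- strsplit(d[3], "", fixed = TRUE)[[1]]
    ppm <- matrix((1 - p_consensus) / 3, nrow = length(letters), ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_along(letters)) ppm[i, letters[i]] <- p_consensus
    tibble(motif_id = d[1], tf_family = d[2], width = length(letters),
           ppm = list(ppm))
  })
  dplyr::bind_rows(rows)
}

#' Configuration of a synthetic multi-species scenario
#'
#' The defaults define the standard study conditions used throughout the
#' package's tests: 200 focal genes with -2000..+200 promoters, three
#' comparator species on a star phylogeny, a background substitution rate of
#' 0.15 per site, purifying selection on binding sites (0.01 inside
#' conserved sites), indels at 0.01 per site with mean length 2, and an
#' AT-rich promoter base composition.
#'
#' @param n_genes number of focal genes.
#' @param species comparator species names.
#' @param up,down promoter extent around the TSS (nt).
#' @param background base composition (A, C, G, T) of ancestral promoters.
#' @param motifs motif tibble; planted words are sampled from these PPMs.
#' @param mean_sites_per_promoter Poisson mean of planted sites per promoter.
#' @param conserved_fraction probability that a planted site is placed under
#'   purifying selection in a given species.
#' @param d_bg per-base substitution probability outside selected sites.
#' @param d_mot per-base substitution probability inside selected sites.
#' @param indel_rate per-base probability of initiating an indel.
#' @param indel_mean_len mean indel length (geometric).
#' @param decay_with_distance when `TRUE`, the background substitution rate
#'   increases linearly with distance from the TSS between
#'   `decay_mult_range[1] * d_bg` (at the TSS) and
#'   `decay_mult_range[2] * d_bg` (at the upstream end).
#' @param decay_mult_range length-2 multiplier range for the decay profile.
#' @param genes_per_contig genes laid out per contig (TSS stride chosen so a
#'   promoter window overlaps the tail of the upstream gene's body,
#'   emulating sites falling within annotated upstream genes).
#' @param acr_fraction fraction of each promoter covered by its ACR.
#' @param acr_site_bias probability that a promoter's ACR is centred on a
#'   planted selected site rather than placed uniformly.
#' @param n_site_variants,n_background_variants planted variant counts
#'   inside conserved sites / elsewhere in promoters.
#' @param group_sizes named vector of accessions per group.
#' @param site_alt_freqs named vector of per-group alternate-allele carrier
#'   frequencies for in-site variants (group-differentiated, emulating
#'   independently evolved gene pools).
#' @param background_alt_freq carrier frequency for background variants in
#'   every group.
#' @param missing_rate genotype missingness.
#' @param n_go_terms,go_base_rate number of GO terms and the per-gene
#'   annotation rate of the unstructured ("filler") terms.
#' @param go_family,go_target_rate,go_offtarget_rate the planted enriched
#'   term (`GO:0000001`) marks a family-specific regulon: genes carrying
#'   conserved sites of TF family `go_family` are annotated with it at
#'   `go_target_rate`, all other genes at `go_offtarget_rate`. The family
#'   restriction makes the target a proper subset of the genes (at the
#'   default densities nearly every gene carries some conserved site), so
#'   enrichment against the genome-wide rate is detectable.
#' @param seed integer seed; the same seed yields a byte-identical bundle.
#' @return list of class `promcons_scenario_config`.
#' @export
scenario_config <- function(n_genes = 200L,
                            species = c("sp1", "sp2", "sp3"),
                            up = 2000L, down = 200L,
                            background = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32),
                            motifs = default_motif_library(),
                            mean_sites_per_promoter = 6,
                            conserved_fraction = 0.8,
                            d_bg = 0.15, d_mot = 0.01,
                            indel_rate = 0.01, indel_mean_len = 2,
                            decay_with_distance = FALSE,
                            decay_mult_range = c(0.5, 2),
                            genes_per_contig = 10L,
                            acr_fraction = 0.19, acr_site_bias = 0.7,
                            n_site_variants = 20L, n_background_variants = 20L,
                            group_sizes = c(Mesoamerican = 50L, Andean = 75L),
                            site_alt_freqs = c(Mesoamerican = 0.9, Andean = 0.08),
                            background_alt_freq = 0.3,
                            missing_rate = 0.02,
                            n_go_terms = 20L, go_base_rate = 0.12,
                            go_family = "ERF", go_target_rate = 0.4,
                            go_offtarget_rate = 0.02,
                            seed = 42L) {
  stopifnot(d_mot <= d_bg, d_bg <= 1, d_mot >= 0, indel_rate >= 0,
            conserved_fraction >= 0, conserved_fraction <= 1,
            abs(sum(background) - 1) < 1e-6)
  cfg <- as.list(environment())
  class(cfg) <- "promcons_scenario_config"
  cfg
}

# Random DNA of length n from a background composition.
random_dna <- function(n, background) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = background),
        collapse = "")
}

# Sample a word from a PPM (rows = positions, cols = A,C,G,T).
sample_word <- function(ppm) {
  paste(apply(ppm, 1, function(p) sample(c("A", "C", "G", "T"), 1, prob = p)),
        collapse = "")
}

# Per-position substitution-rate profile of a promoter.
rate_profile <- function(cfg) {
  L <- cfg$up + cfg$down
  pos <- seq_len(L) - 1L
  if (cfg$decay_with_distance) {
    dist <- pmax(0L, cfg$up - pos) / cfg$up
    mult <- cfg$decay_mult_range[1] +
      (cfg$decay_mult_range[2] - cfg$decay_mult_range[1]) * dist
    pmin(cfg$d_bg * mult, 0.75)
  } else {
    rep(cfg$d_bg, L)
  }
}

# Evolve one ancestral promoter for one species.
# sites: tibble(start (0-based), width, selected). Returns list(seq,
# intact (no substitution / indel touched the site), new_start).
evolve_promoter <- function(anc, sites, base_rates, cfg) {
  chars <- strsplit(anc, "", fixed = TRUE)[[1]]
  L <- length(chars)
  rates <- base_rates
  protected <- sites[sites$selected, , drop = FALSE]
  for (i in seq_len(nrow(sites))) {
    if (sites$selected[i]) {
      span <- seq.int(sites$start[i] + 1L, length.out = sites$width[i])
      rates[span] <- cfg$d_mot
    }
  }
  sub_hit <- stats::runif(L) < rates
  for (p in which(sub_hit)) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  # candidate indel events in ancestral coordinates (1-based anchor)
  ev_pos <- which(stats::runif(L) < cfg$indel_rate)
  events <- list()
  occupied_until <- 0L
  for (p in ev_pos) {
    len <- 1L + stats::rgeom(1, 1 / cfg$indel_mean_len)
    type <- sample(c("ins", "del"), 1)
    span_end <- if (type == "del") min(p + len - 1L, L) else p
    if (p <= occupied_until) next  # keep events disjoint so shifts compose
    clash <- FALSE
    for (i in seq_len(nrow(protected))) {
      s1 <- protected$start[i] + 1L; e1 <- protected$start[i] + protected$width[i]
      if (type == "del" && p <= e1 && span_end >= s1) { clash <- TRUE; break }
      if (type == "ins" && p > s1 && p <= e1) { clash <- TRUE; break }
    }
    if (clash) next
    events[[length(events) + 1L]] <- list(pos = p, len = len, type = type,
                                          span_end = span_end)
    occupied_until <- span_end
  }
  # apply right-to-left so ancestral coordinates stay valid
  for (ev in rev(events)) {
    if (ev$type == "del") {
      chars <- chars[-seq.int(ev$pos, ev$span_end)]
    } else {
      ins <- sample(c("A", "C", "G", "T"), ev$len, replace = TRUE,
                    prob = cfg$background)
      chars <- append(chars, ins, after = ev$pos - 1L)
    }
  }
  # per-site bookkeeping
  intact <- logical(nrow(sites))
  new_start <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s1 <- sites$start[i] + 1L; e1 <- sites$start[i] + sites$width[i]
    shift <- 0L
    touched <- any(sub_hit[s1:e1])
    for (ev in events) {
      if (ev$type == "del") {
        if (ev$span_end < s1) shift <- shift - (ev$span_end - ev$pos + 1L)
        else if (ev$pos <= e1) touched <- TRUE  # del overlaps site
      } else {
        if (ev$pos <= s1) shift <- shift + ev$len
        else if (ev$pos <= e1) touched <- TRUE  # insertion splits site
      }
    }
    intact[i] <- !touched
    new_start[i] <- sites$start[i] + shift
  }
  # evolved position of the ancestral TSS (ancestral local coordinate up)
  tss_anc <- cfg$up  # 0-based: first downstream base
  tss_shift <- 0L
  for (ev in events) {
    if (ev$type == "del") {
      if (ev$span_end < tss_anc + 1L) tss_shift <- tss_shift -
          (ev$span_end - ev$pos + 1L)
      else if (ev$pos <= tss_anc + 1L) tss_shift <- tss_shift -
          (tss_anc + 1L - ev$pos)  # deletion covers the TSS: clamp to its start
    } else if (ev$pos <= tss_anc + 1L) {
      tss_shift <- tss_shift + ev$len
    }
  }
  list(seq = paste(chars, collapse = ""), intact = intact,
       new_start = new_start, tss_local = tss_anc + tss_shift)
}

# Embed oriented promoter sequences into contigs. Returns list(assembly,
# genes). All genes of a contig share a strand; minus contigs are built as
# the reverse complement of a plus layout. Each block is
# [pad][promoter][gap]; gene bodies extend past the promoter window so the
# next gene's window overlaps the tail of the upstream gene's body. The pad
# absorbs indel drift of the evolved TSS so extraction windows stay inside
# the contig and off neighbouring promoters.
embed_promoters <- function(gene_ids, prom_seqs, tss_locals, cfg,
                            contig_prefix) {
  up <- cfg$up; down <- cfg$down
  pad <- 150L
  body_len <- down + 399L  # gene body = [TSS, TSS + down + 399]
  per <- cfg$genes_per_contig
  n <- length(gene_ids)
  contigs <- split(seq_len(n), ceiling(seq_len(n) / per))
  assembly <- character(0)
  genes <- list()
  for (ci in seq_along(contigs)) {
    idx <- contigs[[ci]]
    k <- length(idx)
    parts <- character(3L * k)
    tss_v <- integer(k)
    offset <- 0L
    for (j in seq_len(k)) {
      parts[3L * j - 2L] <- random_dna(pad, cfg$background)
      parts[3L * j - 1L] <- prom_seqs[idx[j]]
      tss_v[j] <- offset + pad + tss_locals[idx[j]] + 1L
      offset <- offset + pad + nchar(prom_seqs[idx[j]])
      gap <- if (j < k) 100L else 700L
      parts[3L * j] <- random_dna(gap, cfg$background)
      offset <- offset + gap
    }
    cseq <- paste(parts, collapse = "")
    clen <- nchar(cseq)
    cname <- sprintf("%s_c%02d", contig_prefix, ci)
    minus <- ci %% 2L == 0L
    if (minus) cseq <- revcomp(cseq)
    assembly[cname] <- cseq
    for (j in seq_len(k)) {
      vstart <- tss_v[j]
      vend <- min(tss_v[j] + body_len, clen)
      if (minus) {
        genes[[length(genes) + 1L]] <- tibble(
          gene_id = gene_ids[idx[j]], contig = cname, strand = "-",
          start = clen - vend + 1L, end = clen - vstart + 1L,
          tss = clen - vstart + 1L)
      } else {
        genes[[length(genes) + 1L]] <- tibble(
          gene_id = gene_ids[idx[j]], contig = cname, strand = "+",
          start = vstart, end = vend, tss = vstart)
      }
    }
  }
  list(assembly = assembly, genes = dplyr::bind_rows(genes))
}

#' Generate a complete synthetic scenario with ground truth
#'
#' Builds ancestral promoters from the background composition, plants motif
#' words at non-overlapping positions, evolves each comparator species
#' independently (substitutions at `d_bg` outside sites and `d_mot` inside
#' selected sites; disjoint indels that never split a selected site), embeds
#' all promoters in multi-gene contigs on both strands, and emits the
#' ortholog table, GO annotations with one planted enriched term, ACRs
#' enriched for selected sites, and group-structured variants. A truth table
#' records, per (site, species), whether the planted word survived intact --
#' the realized ground truth the conservation pipeline is scored against.
#'
#' @param cfg a [scenario_config()].
#' @param out_dir optional directory; when given the bundle is also written
#'   to disk ([write_scenario()]).
#' @return list of class `promcons_scenario`: `config`, `assemblies` (named
#'   list of named character vectors, `focal` first), `genes` (named list of
#'   gene-model tibbles), `orthologs`, `motifs`, `go`, `acrs`, `variants`,
#'   `groups`, and `truth` (list with `sites` and `variants` tibbles).
#' @export
generate_scenario <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "promcons_scenario_config"))
  if (max(cfg$motifs$width) > cfg$up + cfg$down) {
    stop("motif wider than the promoter window", call. = FALSE)
  }
  bundle <- with_seed(cfg$seed, .generate_scenario_impl(cfg))
  if (!is.null(out_dir)) write_scenario(bundle, out_dir)
  bundle
}

.generate_scenario_impl <- function(cfg) {
  L <- cfg$up + cfg$down
  n <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  base_rates <- rate_profile(cfg)

  # ancestral promoters with planted sites
  anc_seqs <- character(n)
  site_rows <- list()
  for (gi in seq_len(n)) {
    seq <- random_dna(L, cfg$background)
    n_sites <- stats::rpois(1, cfg$mean_sites_per_promoter)
    placed <- list()
    taken_s <- integer(0); taken_e <- integer(0)
    for (k in seq_len(n_sites)) {
      mi <- sample.int(nrow(cfg$motifs), 1)
      w <- cfg$motifs$width[mi]
      ok <- FALSE
      for (try in 1:20) {
        pos <- sample.int(L - w + 1L, 1) - 1L
        if (!any(pos < taken_e & pos + w > taken_s)) { ok <- TRUE; break }
      }
      if (!ok) next
      strand <- sample(c("+", "-"), 1)
      word <- sample_word(cfg$motifs$ppm[[mi]])
      planted <- if (strand == "+") word else revcomp(word)
      substr(seq, pos + 1L, pos + w) <- planted
      taken_s <- c(taken_s, pos); taken_e <- c(taken_e, pos + w)
      placed[[length(placed) + 1L]] <- tibble(
        gene_id = gene_ids[gi], motif_id = cfg$motifs$motif_id[mi],
        tf_family = cfg$motifs$tf_family[mi], start = pos, width = w,
        strand = strand, word = word)
    }
    anc_seqs[gi] <- seq
    if (length(placed) > 0L) site_rows[[length(site_rows) + 1L]] <-
        dplyr::bind_rows(placed)
  }
  planted_sites <- if (length(site_rows) > 0L) dplyr::bind_rows(site_rows) else
    tibble(gene_id = character(), motif_id = character(), tf_family = character(),
           start = integer(), width = integer(), strand = character(),
           word = character())

  # focal = ancestor; evolve each comparator species independently
  truth_rows <- list()
  target_seqs <- list()
  target_tss <- list()
  win_len <- cfg$up + cfg$down
  for (sp in cfg$species) {
    seqs_sp <- character(n)
    tss_sp <- integer(n)
    for (gi in seq_len(n)) {
      g <- gene_ids[gi]
      gs <- planted_sites[planted_sites$gene_id == g, , drop = FALSE]
      selected <- if (nrow(gs) > 0L) {
        stats::runif(nrow(gs)) < cfg$conserved_fraction
      } else logical(0)
      ev <- evolve_promoter(anc_seqs[gi],
                            dplyr::mutate(gs, selected = selected),
                            base_rates, cfg)
      seqs_sp[gi] <- ev$seq
      tss_sp[gi] <- ev$tss_local
      if (nrow(gs) > 0L) {
        # realized conservation: the planted word survived intact and sits
        # inside the extraction window [tss - up, tss + down) of the
        # descendant promoter
        planted_word <- ifelse(gs$strand == "+", gs$word, revcomp(gs$word))
        at_pos <- substring(ev$seq, ev$new_start + 1L, ev$new_start + gs$width)
        wstart <- ev$tss_local - cfg$up
        tgt <- ev$new_start - wstart
        in_window <- tgt >= 0L & tgt + gs$width <= win_len
        conserved <- ev$intact & at_pos == planted_word & in_window
        truth_rows[[length(truth_rows) + 1L]] <- dplyr::bind_cols(
          gs, tibble(species = sp, selected = selected, conserved = conserved,
                     target_start = ifelse(conserved, tgt, NA_integer_)))
      }
    }
    target_seqs[[sp]] <- seqs_sp
    target_tss[[sp]] <- tss_sp
  }
  truth_sites <- if (length(truth_rows) > 0L) dplyr::bind_rows(truth_rows) else
    tibble()

  # embed in contigs
  focal_embed <- embed_promoters(gene_ids, anc_seqs, rep(cfg$up, n), cfg,
                                 "focal")
  assemblies <- list(focal = focal_embed$assembly)
  genes <- list(focal = focal_embed$genes)
  orth_rows <- list()
  for (sp in cfg$species) {
    tgt_ids <- paste0(sp, "_", gene_ids)
    emb <- embed_promoters(tgt_ids, target_seqs[[sp]], target_tss[[sp]], cfg, sp)
    assemblies[[sp]] <- emb$assembly
    genes[[sp]] <- emb$genes
    orth_rows[[length(orth_rows) + 1L]] <- tibble(
      query_gene = gene_ids, target_gene = tgt_ids, species = sp,
      homology_type = "one2one",
      protein_pct_id = round(stats::runif(n, 35, 95), 1),
      goc = sample(50:100, n, replace = TRUE),
      wga = sample(50:100, n, replace = TRUE))
  }
  orthologs <- dplyr::bind_rows(orth_rows)

  # focal promoter window coordinates (for ACR / variant genomic positions)
  fp <- extract_promoters(genes$focal, assemblies$focal, cfg$up, cfg$down)
  fp_idx <- setNames(seq_len(nrow(fp)), fp$gene_id)
  local_to_genomic_1b <- function(g, lp) {
    row <- fp[fp_idx[[g]], ]
    if (row$strand == "+") row$win_start + lp + 1L else row$win_end - lp
  }

  # genes whose planted sites survive in >= 1 species (for GO / ACR structure)
  conserved_genes <- if (nrow(truth_sites) > 0L) {
    unique(truth_sites$gene_id[truth_sites$conserved])
  } else character(0)

  # ACRs: one per promoter, biased toward selected sites
  acr_len <- as.integer(round(cfg$acr_fraction * L))
  acr_rows <- list()
  sel_by_gene <- if (nrow(truth_sites) > 0L) {
    split(truth_sites[truth_sites$conserved, , drop = FALSE],
          truth_sites$gene_id[truth_sites$conserved])
  } else list()
  for (gi in seq_len(n)) {
    g <- gene_ids[gi]
    gsel <- sel_by_gene[[g]]
    if (!is.null(gsel) && nrow(gsel) > 0L && stats::runif(1) < cfg$acr_site_bias) {
      anchor <- gsel$start[sample.int(nrow(gsel), 1)]
      a <- max(0L, min(L - acr_len, anchor - sample.int(acr_len, 1) + 1L))
    } else {
      a <- sample.int(L - acr_len + 1L, 1) - 1L
    }
    row <- fp[fp_idx[[g]], ]
    if (row$strand == "+") {
      gs <- row$win_start + a; ge <- gs + acr_len
    } else {
      ge <- row$win_end - a; gs <- ge - acr_len
    }
    acr_rows[[gi]] <- tibble(contig = row$contig, start = gs, end = ge,
                             name = sprintf("acr_%s", g))
  }
  acrs <- dplyr::bind_rows(acr_rows)

  # GO annotations with one planted enriched term among genes carrying
  # conserved sites of one TF family (a proper subset of all genes)
  go_target <- if (nrow(truth_sites) > 0L) {
    unique(truth_sites$gene_id[truth_sites$conserved &
                                 truth_sites$tf_family == cfg$go_family])
  } else character(0)
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  go_rows <- list()
  for (ti in seq_len(cfg$n_go_terms)) {
    if (ti == 1L) {
      rate <- rep(cfg$go_offtarget_rate, n)
      rate[gene_ids %in% go_target] <- cfg$go_target_rate
    } else {
      rate <- rep(cfg$go_base_rate, n)
    }
    hit <- stats::runif(n) < rate
    if (!any(hit)) next
    go_rows[[length(go_rows) + 1L]] <- tibble(
      gene_id = gene_ids[hit], go_id = terms[ti],
      go_name = sprintf("synthetic process %d", ti),
      level = 2L + ti %% 4L)
  }
  go <- dplyr::bind_rows(go_rows)

  # accessions and variants
  groups <- tibble(
    accession = unlist(purrr::imap(as.list(cfg$group_sizes), function(k, nm)
      sprintf("%s_%03d", substr(nm, 1, 3), seq_len(k)))),
    group = rep(names(cfg$group_sizes), unname(cfg$group_sizes)))
  make_genotypes <- function(freqs) {
    dos <- integer(nrow(groups))
    for (grp in names(freqs)) {
      sel <- groups$group == grp
      carrier <- stats::runif(sum(sel)) < freqs[[grp]]
      dos[sel] <- ifelse(carrier, sample(1:2, sum(sel), replace = TRUE), 0L)
    }
    dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA_integer_
    setNames(dos, groups$accession)
  }
  var_rows <- list(); truth_var_rows <- list()
  cons_sites <- if (nrow(truth_sites) > 0L) {
    dplyr::distinct(truth_sites[truth_sites$conserved, , drop = FALSE],
                    .data$gene_id, .data$start, .keep_all = TRUE)
  } else tibble()
  n_sv <- min(cfg$n_site_variants, nrow(cons_sites))
  if (n_sv > 0L) {
    pick <- sample.int(nrow(cons_sites), n_sv)
    for (i in pick) {
      g <- cons_sites$gene_id[i]
      lp <- cons_sites$start[i] + sample.int(cons_sites$width[i], 1) - 1L
      row <- fp[fp_idx[[g]], ]
      pos <- local_to_genomic_1b(g, lp)
      ref <- substr(assemblies$focal[[row$contig]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      var_rows[[length(var_rows) + 1L]] <- tibble(
        contig = row$contig, pos = pos, ref = ref, alt = alt,
        genotypes = list(make_genotypes(as.list(cfg$site_alt_freqs))))
      truth_var_rows[[length(truth_var_rows) + 1L]] <- tibble(
        contig = row$contig, pos = pos, ref = ref, alt = alt,
        gene_id = g, in_site = TRUE)
    }
  }
  for (k in seq_len(cfg$n_background_variants)) {
    g <- gene_ids[sample.int(n, 1)]
    row <- fp[fp_idx[[g]], ]
    site_spans <- planted_sites[planted_sites$gene_id == g, , drop = FALSE]
    repeat {
      lp <- sample.int(L, 1) - 1L
      if (!any(lp >= site_spans$start & lp < site_spans$start + site_spans$width))
        break
    }
    pos <- local_to_genomic_1b(g, lp)
    ref <- substr(assemblies$focal[[row$contig]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    freqs <- setNames(as.list(rep(cfg$background_alt_freq,
                                  length(cfg$group_sizes))),
                      names(cfg$group_sizes))
    var_rows[[length(var_rows) + 1L]] <- tibble(
      contig = row$contig, pos = pos, ref = ref, alt = alt,
      genotypes = list(make_genotypes(freqs)))
    truth_var_rows[[length(truth_var_rows) + 1L]] <- tibble(
      contig = row$contig, pos = pos, ref = ref, alt = alt,
      gene_id = g, in_site = FALSE)
  }
  variants <- dplyr::bind_rows(var_rows) |>
    dplyr::arrange(.data$contig, .data$pos)
  truth_variants <- dplyr::bind_rows(truth_var_rows) |>
    dplyr::arrange(.data$contig, .data$pos)

  structure(list(
    config = cfg, assemblies = assemblies, genes = genes,
    orthologs = orthologs, motifs = cfg$motifs, go = go, acrs = acrs,
    variants = variants, groups = groups,
    truth = list(sites = truth_sites, variants = truth_variants)
  ), class = "promcons_scenario")
}

#' Write a scenario bundle to disk
#'
#' Emits FASTA + GFF3 per species, the ortholog / GO / groups TSVs, the MEME
#' motif file, the ACR BED, a VCF and the truth tables. Output is
#' byte-identical for a given bundle.
#'
#' @param bundle a `promcons_scenario` from [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(bundle$assemblies)) {
    write_fasta(bundle$assemblies[[sp]], file.path(dir, paste0(sp, ".fa")))
    gm <- bundle$genes[[sp]]
    lines <- sprintf("%s\tpromcons\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     gm$contig, gm$start, gm$end, gm$strand, gm$gene_id)
    writeLines(c("##gff-version 3", lines), file.path(dir, paste0(sp, ".gff3")))
  }
  write.table(as.data.frame(bundle$orthologs), file.path(dir, "orthologs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_meme_motifs(bundle$motifs, file.path(dir, "motifs.meme"))
  write.table(as.data.frame(bundle$go), file.path(dir, "go.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(bundle$acrs, file.path(dir, "acrs.bed"))
  write.table(as.data.frame(bundle$groups), file.path(dir, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_vcf(bundle$variants, file.path(dir, "variants.vcf"))
  ts <- as.data.frame(bundle$truth$sites)
  write.table(ts, file.path(dir, "truth_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle$truth$variants),
              file.path(dir, "truth_variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Minimal VCF 4.2 writer (GT only).
write_vcf <- function(variants, path) {
  accs <- if (nrow(variants) > 0L) names(variants$genotypes[[1]]) else character(0)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", accs), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    dos <- variants$genotypes[[i]]
    gt <- ifelse(is.na(dos), "./.",
                 ifelse(dos == 0L, "0/0", ifelse(dos == 1L, "0/1", "1/1")))
    paste(c(variants$contig[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Site-level recovery metrics against planted truth
#'
#' Matches pipeline conservation calls to truth records by (gene, species,
#' motif, strand) with greedy nearest start assignment within a tolerance.
#' Precision with no calls is reported as 1 by convention (with a warning).
#'
#' @param calls conservation calls ([conservation_calls()]); only rows with
#'   `conserved = TRUE` are used.
#' @param truth_sites truth tibble (`bundle$truth$sites`); only rows with
#'   `conserved = TRUE` are used.
#' @param tolerance maximum |start difference| for a match (nt).
#' @return tibble with `precision`, `recall`, `f1`, `n_calls`, `n_truth`,
#'   `n_matched`.
#' @export
recovery_metrics <- function(calls, truth_sites, tolerance = 3L) {
  cc <- calls[calls$conserved, , drop = FALSE]
  tt <- truth_sites[truth_sites$conserved, , drop = FALSE]
  key <- function(d) paste(d$gene_id, d$species, d$motif_id, d$strand)
  cc_split <- split(seq_len(nrow(cc)), key(cc))
  tt_split <- split(seq_len(nrow(tt)), key(tt))
  matched <- 0L
  for (k in names(tt_split)) {
    t_starts <- tt$start[tt_split[[k]]]
    c_idx <- cc_split[[k]]
    if (is.null(c_idx)) next
    c_starts <- cc$start[c_idx]
    used <- logical(length(c_starts))
    for (ts in t_starts) {
      d <- abs(c_starts - ts)
      d[used] <- NA
      j <- which.min(d)
      if (length(j) == 1L && !is.na(d[j]) && d[j] <= tolerance) {
        used[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  n_calls <- nrow(cc); n_truth <- nrow(tt)
  precision <- if (n_calls == 0L) {
    warning("no conserved calls; precision reported as 1 by convention",
            call. = FALSE)
    1
  } else matched / n_calls
  recall <- if (n_truth == 0L) NA_real_ else matched / n_truth
  tibble(precision = precision, recall = recall,
         f1 = ifelse(precision + recall > 0,
                     2 * precision * recall / (precision + recall), 0),
         n_calls = n_calls, n_truth = n_truth, n_matched = matched)
}
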