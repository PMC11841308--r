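---
title: "Detecting conserved TF binding sites in orthologous promoters with promcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved TF binding sites in orthologous promoters with promcons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promcons)
```

## The problem

Computational prediction of transcription-factor binding sites (TFBSs) from
position weight matrices alone has a notoriously high false-positive rate:
binding motifs are short and degenerate, so a genome-sized sequence is full
of words that score well by chance. Phylogenetic footprinting filters these
predictions by requiring that a predicted site also be present in the
promoter of an orthologous gene in a related species — functional sites sit
under purifying selection and diverge more slowly than the surrounding
promoter sequence.

`promcons` implements this comparative pipeline for plant promoters:

1. extract TSS-anchored promoter windows (by default −2000..+200 nt) from a
   genome and its gene models;
2. select one ortholog per gene and comparator species from an ortholog
   table (one-to-one and one-to-many relations, protein identity > 25%,
   gene-order-conservation and whole-genome-alignment scores ≥ 50 when
   available; for one-to-many relations the target with the highest protein
   identity, ties broken lexicographically);
3. align each promoter to its ortholog promoter with an exact affine-gap
   local aligner, keeping CIGAR strings and masked secondary alignments;
4. scan the focal promoters with a PWM library under a 0-order Markov
   background, with analytic p-values;
5. call a site conserved in a species when its exact matched word occurs on
   the same strand within ±100 nt of the alignment-projected position in the
   ortholog promoter;
6. aggregate per-species calls into unique conserved sites with a
   conservation level (the number of species supporting the site), and feed
   the downstream statistics (similarity–identity regression, GO binomial
   enrichment with FDR control, TF-family occurrence tests, chromatin
   accessibility association, variant intersection, co-occurrence networks
   and per-gene regulatory reports).

Every stage takes and returns plain tibbles, so the pipeline composes with
dplyr verbs, and each result type has an `autoplot()` method.

## The aligner

Promoter windows are at most a few kilobases, so instead of a heuristic
k-mer mapper the package uses exact Smith–Waterman with Gotoh affine gaps
(Rcpp implementation). A gap of length $L$ costs
$\mathrm{open} + (L-1)\,\mathrm{extend}$; the defaults
(match $+2$, mismatch $-4$, open $-4$, extend $-2$) resemble the presets of
short-read mappers and give an expected per-column score of
$2 - 6d$ for a pair diverged at rate $d$: alignments extend while local
divergence stays below $1/3$ and break off beyond it.

Design choices worth noting:

* **Secondary alignments** are found by masking already-aligned query
  columns (their substitution scores become effectively $-\infty$) and
  re-running the DP until the score drops below `min_score` (default 40,
  about 20 matched nt) or `max_secondary` (default 5) is reached. This is
  deterministic and lets a property test compare every reported score
  against a brute-force DP oracle.
* **Traceback ties** are fixed — match over deletion over insertion, and the
  first maximum in row-major order — so CIGAR strings are reproducible to
  the byte.
* **"Similar promoter"** is operationalised as "has at least one alignment
  with score ≥ `min_score`". The score threshold is the one knob that
  defines the similar-promoter universe; it is exposed everywhere it is
  consumed.
* `N` scores as a mismatch against every letter, including `N`.

## Motif scanning

`scan_promoters()` is a self-contained PWM scanner: log-odds scores
$\log_2\frac{p_{ib}(1-4c)+c}{b_b}$ with pseudocount $c = 0.01$
(entries below −30 bits are capped so that zero-probability entries with
`pseudocount = 0` stay finite), and analytic p-values obtained by
discretising scores to a granularity of $10^{-3}$ bits and convolving the
per-position score distributions under the background. Because the observed
window scores are computed from the same discretised integer matrix, the
p-values are *exactly* the enumeration p-values at that granularity — a
property the tests check against full $4^w$ word enumeration for widths up
to 6.

Both strands are scanned; minus-strand windows are scored with the
reverse-complemented matrix and share the plus-strand null distribution, so
scanning a promoter and its reverse complement yields mirrored site sets.
The background is estimated from the focal promoter set with one pseudocount
per letter, `N` excluded; windows containing `N` are skipped (the downstream
exact-match conservation test could never confirm them anyway). The default
threshold `alpha = 1e-4` is the conventional scanning default and is
recorded with the results.

## The conservation test

For each site and species, the expected position in the ortholog promoter is
obtained by projecting the site start through the best-scoring alignment
covering it (CIGAR walk; positions inside an insertion map to the column
after the last aligned one). Where no alignment covers the site the package
falls back to the same TSS-relative coordinate (`anchor_mode = "auto"`,
the default); a strict `anchor_mode = "projection"` treats uncovered sites
as not conserved. The site is conserved if its exact matched word — the
genomic word of the site, not the motif consensus — occurs on the same
strand (relative to promoter orientation) with start within ±100 nt of the
anchor; the nearest occurrence wins, ties toward the smaller coordinate.

Unique sites are keyed by (gene, motif, start, strand); the conservation
level is the number of comparator species supporting the site. Sites are
annotated, not filtered, when they fall inside the body of an upstream gene
— regulatory elements inside gene bodies are a documented part of the plant
regulatory landscape — and, when ACR intervals are supplied, by chromatin
accessibility (half-open interval semantics; abutting intervals do not
overlap).

## Statistics

* **Similarity ~ protein identity:** ortholog pairs are binned by rounded
  integer protein percent identity; the per-bin proportion of similar
  promoters is regressed on the bin percent by least squares weighted with
  bin counts. `tidy()` returns the bin table, `glance()` the coefficients
  and the weighted $R^2$.
* **GO enrichment:** upper-tail binomial test per term,
  $P(X \ge k),\, X \sim \mathrm{Bin}(n, K/N)$, against the term's frequency
  in the annotated universe, with Benjamini–Hochberg correction at
  $q \le 0.05$. The unit is the gene (a gene counts once however many sites
  it carries); the universe defaults to all annotated genes. One-sided
  because the question is over-representation only.
* **TF-family occurrence:** same binomial machinery, with the background
  rate taken over all genes that carry conserved sites.
* **ACR association:** Pearson chi-square (df = 1, no continuity
  correction — nucleotide counts are large in intended use) on conserved vs
  non-conserved nucleotides inside vs outside ACRs, where conserved
  nucleotides are the union of positions covered by conserved sites.
* **Evidence codes:** Kruskal–Wallis with tie correction on per-family
  conserved-site counts grouped by literature evidence codes (1 = none,
  2 = indirect, 3 = described in plants).

## The synthetic scenario generator

Real genomes, ortholog tables and curated motif collections are too large
to ship or download in a test environment, so `generate_scenario()` builds
complete, file-consistent scenarios with known ground truth. Defaults are
the package's standard study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | focal genes |
| `species` | 3 comparators | star phylogeny, independent evolution |
| `up`, `down` | 2000, 200 nt | promoter window |
| `background` | A/T 0.32, C/G 0.18 | AT-rich plant promoter composition |
| `mean_sites_per_promoter` | 6 | Poisson; conserved-site densities per promoter in real plant promoters are of this order or higher |
| `conserved_fraction` | 0.8 | probability a planted site is under purifying selection in a species |
| `d_bg` | 0.15 | background substitution rate, the divergence regime of closely related legumes |
| `d_mot` | 0.01 | substitution rate inside selected sites |
| `indel_rate`, `indel_mean_len` | 0.01, 2 | disjoint indels, geometric lengths, never splitting a selected site |

The default motif library contains eight informative consensus-based PPMs
(widths 13–14, consensus probability 0.97) built around core boxes of
common plant TF families (GCC-box, DRE, MYB box, G-box, W-box, CArG box).
The consensus strings were chosen so that no two motifs — nor any motif and
a reverse complement — share more than 8 aligned letters at any ungapped
offset; without this, near-palindromic or mutually similar motifs produce
systematic double counting (the same planted word detected under two motif
identities or on both strands), which is a scanner artifact rather than a
property of the conservation test.

Ground truth is the *realized* conservation state: a truth record is marked
conserved exactly when the planted word survived evolution intact in that
species, whether or not the site had been selected for purifying selection
(a neutral site survives $0.85^{13}$ ≈ 13% of the time at the default
rates). Scoring against realized truth keeps precision and recall
well-defined: the pipeline cannot be penalised for correctly detecting a
word that genuinely is conserved.

What the generator deliberately does **not** emulate: phylogenetic tree
structure (a star phylogeny suffices for per-species conservation calls),
recombination and CNVs, motif co-evolution and turnover (a lost site does
not re-appear elsewhere), GC-content heterogeneity along the promoter, and
dependence between neighbouring substitutions. Passing tests on these
scenarios therefore demonstrates correctness of the machinery under the
stated model, not performance on any particular real genome.

Two structural features mirror what is expected of real data and give the
statistics positive controls: the per-promoter ACR (19% of the window
length) is centred on a selected site 70% of the time, and one GO term
(`GO:0000001`) marks a family-specific regulon: genes carrying conserved
sites of one TF family (`go_family`, default ERF — about half the genes)
are annotated with it at rate 0.4, all other genes at 0.02. The family
restriction matters: nearly every gene carries *some* conserved site at
these densities, so an enrichment planted on "genes with conserved sites"
would compare the universe to itself and be undetectable by construction.
The 0.4/0.02 profile is what a coherent, specifically regulated process
looks like, and — because the target set is half the universe and so
inflates the genome-wide rate it is compared against — it is about the
weakest contrast reliably detectable at 200 genes under BH at
$q \le 0.05$. In-site variants
are planted with group-differentiated carrier
frequencies (0.9 vs 0.08) across two accession groups of 50 and 75 — the
shape of a domestication-differentiated SNP across independently evolved
gene pools.

Residual false positives in recovery scoring come from chance scanner hits
whose word happens to survive in the ortholog; at `alpha = 1e-4` their
expected density is `alpha × 2 strands × window length × library size ×
0.85^w` per promoter and species, about 0.3–0.4 — an order of magnitude
below the planted-site density, which is what keeps precision above 0.9.

## Numerical and degeneracy choices

* Promoter windows are clipped (not dropped) at contig boundaries, with the
  truncation recorded in `up_len`/`down_len`; genes missing from one
  assembly in the cross-assembly filter are excluded with a message, not an
  error.
* The 90% cross-assembly identity filter uses local-alignment identity
  (matches / alignment columns) — recorded in output metadata, since global
  identity over the full window is the other defensible reading.
* Derangements for the orthology shuffle are drawn by rejection sampling
  (uniform over derangements); species with fewer than two pairs are left
  unshuffled with a warning.
* Remapping and conservation ties (equidistant occurrences) resolve toward
  the smaller coordinate.
* Multiallelic VCF records are split per alternate allele; a "carrier" has
  alternate dosage ≥ 1; missing genotypes are excluded from group
  denominators.
* Empty inputs: no alignments → `similar = FALSE`, span 0; empty call set →
  precision 1 by convention (with a warning); zero-site genes appear as
  zero rows in report matrices.

## Problem sizes used in the test-suite

The shared test scenario uses the standard conditions above (200 genes,
3 species). The decay-of-similarity and divergence-monotonicity property
tests use scaled-down windows (−1000..+100 and −500..+100) with 15–25 genes
per replicate — these test qualitative orderings for which the window span
is immaterial — and state their scenario settings inline. The null
enrichment control runs 1000 seeded replicates on a 200-gene universe with
15 terms.

## Limitations

* The conservation rule is exact word matching; a site with even one
  substitution in the ortholog is not conserved. This follows the
  conservative design of the approach (and the deduplication key), but it
  means divergence-tolerant conservation requires re-scanning, which is out
  of scope.
* p-values from scanning are per-window and not corrected across the scan;
  genome-wide q-values are out of scope.
* The binned regression treats bins as observations; it inherits the usual
  caveats of aggregated regressions.
* The aligner is exact but quadratic; it is sized for promoter windows (a
  2200×2200 problem takes tens of milliseconds), not whole genomes.
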