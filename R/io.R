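#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and any letter outside `A/C/G/T/N` is mapped to
#' `N`; contig names are taken up to the first whitespace of the header.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate contig name(s) in ", path, ": ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only lines with feature type `gene` are used; each must carry an `ID`
#' attribute. The TSS is the `start` coordinate for plus-strand genes and
#' `end` for minus-strand genes.
#'
#' @param path path to a GFF3 file.
#' @return tibble with columns `gene_id`, `contig`, `strand`, `start`, `end`,
#'   `tss` (1-based inclusive coordinates).
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  rows <- vector("list", length(idx))
  n_out <- 0L
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) next
    if (f[3] != "gene") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("malformed coordinate at line ", i, " of ", path, call. = FALSE)
    }
    strand <- f[7]
    if (!strand %in% c("+", "-")) {
      stop("invalid strand '", strand, "' at line ", i, " of ", path, call. = FALSE)
    }
    mm <- regmatches(f[9], regexpr("(?:^|;)ID=[^;]+", f[9]))
    if (length(mm) == 0L) {
      stop("gene without ID attribute at line ", i, " of ", path, call. = FALSE)
    }
    id <- sub("^;?ID=", "", mm)
    n_out <- n_out + 1L
    rows[[n_out]] <- list(gene_id = id, contig = f[1], strand = strand,
                          start = start, end = end)
  }
  if (n_out == 0L) {
    return(tibble(gene_id = character(), contig = character(), strand = character(),
                  start = integer(), end = integer(), tss = integer()))
  }
  out <- dplyr::bind_rows(rows[seq_len(n_out)])
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  as_tibble(out)
}

#' Read motifs in MEME minimal format
#'
#' One motif per `MOTIF` block; the TF family is taken from the motif's
#' alternate-name field when present, else `"unknown"`. Probability rows must
#' sum to 1 within 1e-3 and motifs must have width >= 2.
#'
#' @param path path to a MEME minimal file.
#' @return tibble with columns `motif_id`, `tf_family`, `width` and a
#'   list-column `ppm` of width x 4 probability matrices (columns A,C,G,T).
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) stop("MEME file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal file (no 'MEME version' line): ", path, call. = FALSE)
  }
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0L) {
    return(tibble(motif_id = character(), tf_family = character(),
                  width = integer(), ppm = list()))
  }
  blocks_end <- c(motif_idx[-1] - 1L, length(lines))
  res <- purrr::map2(motif_idx, blocks_end, function(s, e) {
    hdr <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    motif_id <- if (length(hdr) >= 2) hdr[2] else stop("MOTIF line without id", call. = FALSE)
    tf_family <- if (length(hdr) >= 3) hdr[3] else "unknown"
    block <- lines[s:e]
    lp <- grep("^letter-probability matrix", block)
    if (length(lp) == 0L) stop("motif ", motif_id, ": no letter-probability matrix", call. = FALSE)
    rows <- list()
    for (j in seq(from = lp[1] + 1L, length.out = length(block) - lp[1])) {
      ln <- trimws(block[j])
      if (!nzchar(ln) || !grepl("^[0-9.eE+-]", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals)) {
        stop("motif ", motif_id, ": malformed probability row '", ln, "'", call. = FALSE)
      }
      if (abs(sum(vals) - 1) > 1e-3) {
        stop("motif ", motif_id, ": probability row sums to ", format(sum(vals)),
             " (not 1 within 1e-3)", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- vals
    }
    if (length(rows) < 2L) stop("motif ", motif_id, ": width ", length(rows), " < 2", call. = FALSE)
    ppm <- do.call(rbind, rows)
    colnames(ppm) <- c("A", "C", "G", "T")
    tibble(motif_id = motif_id, tf_family = tf_family,
           width = nrow(ppm), ppm = list(ppm))
  })
  dplyr::bind_rows(res)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs tibble as returned by [read_meme_motifs()].
#' @param path output path.
#' @param background optional background vector (A,C,G,T) for the header.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", background[1], background[2],
            background[3], background[4]), ""
  ), con)
  for (i in seq_len(nrow(motifs))) {
    ppm <- motifs$ppm[[i]]
    writeLines(sprintf("MOTIF %s %s", motifs$motif_id[i], motifs$tf_family[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(ppm)), con)
    writeLines(apply(ppm, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an ortholog table
#'
#' Expects a TSV with header columns `query_gene`, `target_gene`, `species`,
#' `homology_type`, `protein_pct_id` and optional `goc`, `wga`.
#'
#' @param path path to the TSV.
#' @return tibble of ortholog pairs.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("query_gene", "target_gene", "species", "homology_type", "protein_pct_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("ortholog table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  # unknown homology types are carried through; select_pairs() filters them
  if (any(df$protein_pct_id < 0 | df$protein_pct_id > 100, na.rm = TRUE)) {
    stop("protein_pct_id outside [0, 100]", call. = FALSE)
  }
  if (!"goc" %in% names(df)) df$goc <- NA_real_
  if (!"wga" %in% names(df)) df$wga <- NA_real_
  as_tibble(df[, c(need, "goc", "wga")])
}

#' Read a BED file of intervals
#'
#' @param path path to a BED (3+ column, 0-based half-open) file.
#' @return tibble with `contig`, `start`, `end` (0-based half-open) and
#'   `name` when a 4th column is present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- purrr::imap(fields, function(f, i) {
    if (length(f) < 3L) stop("BED line ", i, ": fewer than 3 columns", call. = FALSE)
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0L || e < s) {
      stop("BED line ", i, ": malformed coordinates '", f[2], "', '", f[3], "'",
           call. = FALSE)
    }
    tibble(contig = f[1], start = s, end = e,
           name = if (length(f) >= 4L) f[4] else NA_character_)
  })
  dplyr::bind_rows(out)
}

#' Write intervals to BED
#'
#' @param x tibble with `contig`, `start`, `end` (0-based half-open) and
#'   optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$contig, x$start, x$end)
  if ("name" %in% names(x) && !all(is.na(x$name))) df$name <- x$name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Plain-text VCF 4.x with a GT FORMAT field. Multiallelic records are split
#' into one row per alternate allele; genotypes are recoded as alt-allele
#' dosage in `{0, 1, 2, NA}` with respect to that alternate allele.
#'
#' @param path path to an (uncompressed) VCF.
#' @return tibble with `contig`, `pos`, `ref`, `alt` and a list-column
#'   `genotypes` of named integer dosage vectors (one entry per accession).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt_raw[i, ]
    for (a_idx in seq_along(alts)) {
      dos <- vapply(gts, function(g) {
        if (is.na(g)) return(NA_integer_)
        al <- strsplit(g, "[/|]")[[1]]
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(a_idx))
      }, integer(1))
      rows[[length(rows) + 1L]] <- tibble(
        contig = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i],
        alt = alts[a_idx],
        genotypes = list(dos)
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), genotypes = list()))
  }
  dplyr::bind_rows(rows)
}

#' Read a gene-to-GO annotation table
#'
#' TSV with columns `gene_id`, `go_id` and optional `go_name`, `level`.
#' GO identifiers must match `GO:\\d{7}`.
#'
#' @param path path to the TSV.
#' @return tibble of annotations.
#' @export
read_go_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "go_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("GO table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- !grepl("^GO:\\d{7}$", df$go_id)
  if (any(bad)) {
    stop("malformed GO identifier(s): ", paste(head(df$go_id[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  if (!"go_name" %in% names(df)) df$go_name <- NA_character_
  if (!"level" %in% names(df)) df$level <- NA_integer_
  as_tibble(df[, c("gene_id", "go_id", "go_name", "level")])
}

#' Read an accession-to-group table
#'
#' TSV with columns `accession`, `group`; each accession may belong to at
#' most one group.
#'
#' @param path path to the TSV.
#' @return tibble with `accession`, `group`.
#' @export
read_groups_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "group") %in% names(df))) {
    stop("groups table must have columns 'accession' and 'group'", call. = FALSE)
  }
  if (anyDuplicated(df$accession)) {
    stop("accession(s) assigned to more than one group: ",
         paste(unique(df$accession[duplicated(df$accession)]), collapse = ", "),
         call. = FALSE)
  }
  as_tibble(df[, c("accession", "group")])
}

#' Write sites to disk
#'
#' `format = "bed"` writes the genomic interval columns (`genomic_contig`,
#' `genomic_start`, `genomic_end`; 0-based half-open) with a composite name;
#' `format = "tsv"` writes all columns.
#'
#' @param sites tibble of sites (conserved or scanned).
#' @param path output path.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    need <- c("genomic_contig", "genomic_start", "genomic_end")
    if (!all(need %in% names(sites))) {
      stop("BED output needs columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    nm <- paste(sites$gene_id, sites$motif_id, sites$start, sites$strand, sep = "|")
    write_bed(tibble(contig = sites$genomic_contig, start = sites$genomic_start,
                     end = sites$genomic_end, name = nm), path)
  } else {
    df <- as.data.frame(sites)
    listcols <- vapply(df, is.list, logical(1))
    for (cn in names(df)[listcols]) {
      df[[cn]] <- vapply(df[[cn]], function(x) paste(x, collapse = ","), character(1))
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
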