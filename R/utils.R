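#' Reverse complement of DNA strings
#'
#' Vectorised over its input; `N` maps to `N`. Input must already be
#' normalised to the `ACGTN` alphabet (see [read_fasta()]).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Parse a CIGAR string over M/I/D into a data frame of (len, op).
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MID])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  runs <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  data.frame(
    len = as.integer(sub("[MID]$", "", runs)),
    op = sub("^\\d+", "", runs),
    stringsAsFactors = FALSE
  )
}

# Consumed query / target lengths of a CIGAR.
cigar_spans <- function(cigar) {
  r <- parse_cigar(cigar)
  c(
    q = sum(r$len[r$op %in% c("M", "I")]),
    t = sum(r$len[r$op %in% c("M", "D")])
  )
}

# Total length of the union of 0-based half-open intervals given as a
# two-column matrix/data.frame (start, end).
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    } else if (ends[i] > cur_e) {
      cur_e <- ends[i]
    }
  }
  as.integer(total + (cur_e - cur_s))
}

# Run code under a local RNG state seeded with `seed`; restores the caller's
# RNG afterwards so generators do not perturb user code.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# All match start positions (1-based, overlapping) of a fixed pattern in a
# subject string. Exact letter matching: N only matches N, and scanned words
# never contain N, so N in the subject can never be part of a hit.
fixed_matches <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(subject) < nchar(pattern)) return(integer(0))
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject), fixed = TRUE)
  as.integer(IRanges::start(hits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
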