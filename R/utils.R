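#' @import data.table
#' @importFrom stats runif setNames median pnorm
#' @importFrom utils head tail write.table read.table
NULL

# DNA complement table; every IUPAC ambiguity symbol other than N has already
# been collapsed to N by read_fasta(), so only these five symbols circulate.
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector of sequences over `{A,C,G,T,N}`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Fast reverse complement for a character vector representation of a sequence.
.revcomp_chars <- function(chars) rev(unname(.COMP[chars]))

# Clean a free-form nucleotide string: uppercase, U -> T, ambiguity -> N.
.normalize_dna <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Karlin-Altschul expectation for an ungapped-style nucleotide search.
# Parameters fixed to the classical +2/-3 set so E-value filtering is
# reproducible bit for bit: lambda = 0.625, K = 0.41.
.KA_LAMBDA <- 0.625
.KA_K <- 0.41

#' Karlin-Altschul E-value
#'
#' Expectation `E = K * m * n * exp(-lambda * S)` for a local alignment of raw
#' score `S` between a query of length `m` and a search space of length `n`,
#' with the classical nucleotide parameters for match +2 / mismatch -3
#' (`lambda = 0.625`, `K = 0.41`).
#'
#' @param score raw alignment score under the +2/-3 scheme.
#' @param m query length (bp).
#' @param n search-space length (bp).
#' @return numeric E-value.
#' @export
karlin_altschul_evalue <- function(score, m, n) {
  .KA_K * as.numeric(m) * as.numeric(n) * exp(-.KA_LAMBDA * score)
}

# Coverage (in positions) of the integer interval [lo, hi] by a set of
# closed integer spans given as a two-column matrix (start, end), 1-based.
.span_coverage <- function(spans, lo, hi) {
  if (hi < lo) return(0L)
  if (is.null(spans) || nrow(spans) == 0L) return(0L)
  s <- pmax(spans[, 1L], lo)
  e <- pmin(spans[, 2L], hi)
  keep <- s <= e
  if (!any(keep)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = s[keep], end = e[keep]))
  sum(IRanges::width(ir))
}

# Merge closed integer intervals; returns matrix with columns start, end.
.merge_spans <- function(start, end) {
  if (length(start) == 0L) return(matrix(integer(0), ncol = 2L))
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  cbind(IRanges::start(ir), IRanges::end(ir))
}

# Internal RNG discipline: every stochastic phase reseeds from the user seed
# plus a fixed phase offset, so adding a phase never shuffles earlier draws.
.with_phase_seed <- function(seed, offset, expr) {
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}

# Random DNA of length n with a given GC fraction.
.random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Full-width rows of a batched global alignment. pairwiseAlignment's
# pattern()/subject() accessors clip terminal gap columns; this pads the
# unaligned sequence tails back so both rows span every column, terminal
# gaps included (needed for iddef-1 identity and coordinate maps).
.global_alignment_rows <- function(aln, pat_seqs, sub_seq) {
  pat_str <- as.character(Biostrings::pattern(aln))
  sub_str <- as.character(Biostrings::subject(aln))
  p_lo <- IRanges::start(aln@pattern@range)
  p_hi <- IRanges::end(aln@pattern@range)
  s_lo <- IRanges::start(aln@subject@range)
  s_hi <- IRanges::end(aln@subject@range)
  gaps <- function(n) strrep("-", n)
  n_sub <- nchar(sub_seq)
  out_p <- character(length(pat_str))
  out_s <- character(length(pat_str))
  for (i in seq_along(pat_str)) {
    p_pre <- substring(pat_seqs[i], 1L, p_lo[i] - 1L)
    p_suf <- substring(pat_seqs[i], p_hi[i] + 1L, nchar(pat_seqs[i]))
    s_pre <- substring(sub_seq, 1L, s_lo[i] - 1L)
    s_suf <- substring(sub_seq, s_hi[i] + 1L, n_sub)
    out_p[i] <- paste0(p_pre, gaps(nchar(s_pre)), pat_str[i],
                       p_suf, gaps(nchar(s_suf)))
    out_s[i] <- paste0(gaps(nchar(p_pre)), s_pre, sub_str[i],
                       gaps(nchar(p_suf)), s_suf)
  }
  list(pattern = out_p, subject = out_s)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
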