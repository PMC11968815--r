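# Shared pairwise-alignment primitive.
#
# One alignment definition is fixed and documented for the whole package
# (clustering and sequence search): Smith-Waterman local alignment with
# match +2, mismatch -1, gap opening 4, gap extension 1. Identity is
# matches / alignment columns (gap columns included); coverage of a
# sequence is the aligned span on that sequence divided by its length.

.align_env <- new.env(parent = emptyenv())

.aa_submat <- function() {
  if (!is.null(.align_env$mat)) return(.align_env$mat)
  alpha <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V",
             "X", "*", "U", "O", "B", "Z", "J")
  mat <- matrix(-1L, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(mat) <- 2L
  # unknown residues never score as matches
  mat["X", "X"] <- -1L
  mat["*", "*"] <- -1L
  .align_env$mat <- mat
  mat
}

#' Local-alignment statistics of many sequences against one
#'
#' @param patterns AAStringSet (or named character vector).
#' @param subject Single amino-acid string.
#' @return data.frame, one row per pattern: id, identity (matches /
#'   alignment columns), pat_cov and sub_cov (aligned span / sequence
#'   length), cov_shorter (span on the shorter sequence / its length),
#'   aln_cols. Patterns or subjects with an empty optimal alignment get
#'   identity 0.
#' @export
alignment_stats <- function(patterns, subject) {
  if (!methods::is(patterns, "AAStringSet")) {
    patterns <- Biostrings::AAStringSet(patterns)
  }
  subject <- as.character(subject)
  pa <- Biostrings::pairwiseAlignment(
    patterns, Biostrings::AAString(subject), type = "local",
    substitutionMatrix = .aa_submat(), gapOpening = 4, gapExtension = 1)
  cols <- Biostrings::nchar(pa)
  nm <- Biostrings::nmatch(pa)
  p_span <- IRanges::end(Biostrings::pattern(pa)) -
    IRanges::start(Biostrings::pattern(pa)) + 1L
  s_span <- IRanges::end(Biostrings::subject(pa)) -
    IRanges::start(Biostrings::subject(pa)) + 1L
  plen <- Biostrings::width(patterns)
  slen <- nchar(subject)
  empty <- cols <= 0L
  identity <- ifelse(empty, 0, nm / pmax(cols, 1L))
  pat_cov <- ifelse(empty, 0, p_span / plen)
  sub_cov <- ifelse(empty, 0, s_span / slen)
  shorter_is_pat <- plen <= slen
  cov_shorter <- ifelse(shorter_is_pat, pat_cov, sub_cov)
  data.frame(id = if (!is.null(names(patterns))) names(patterns) else
               as.character(seq_along(patterns)),
             identity = identity, pat_cov = pat_cov, sub_cov = sub_cov,
             cov_shorter = cov_shorter, aln_cols = as.integer(cols),
             stringsAsFactors = FALSE)
}

# Longest run of exact-match columns guaranteed for any alignment passing
# (id_threshold, cov_threshold) on sequences of length >= min_len. Used to
# pick a k-mer prefilter size that provably cannot lose a true member:
# an alignment with m columns and identity >= t has at most floor((1-t)m)
# non-match columns, splitting >= ceil(t*m) matches into at most
# floor((1-t)m)+1 runs, hence a run of shared k-mers of the length below.
.safe_kmer <- function(id_threshold, cov_threshold, min_len,
                       max_cols = 100000L) {
  m_min <- max(1L, as.integer(ceiling(cov_threshold * min_len)))
  m <- seq.int(m_min, max(m_min, max_cols))
  nonmatch <- floor((1 - id_threshold) * m)
  bound <- floor((m - nonmatch) / (nonmatch + 1L))
  max(1L, min(bound))
}
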