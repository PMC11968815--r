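# Genetic code tables and code-aware ORF scanning.
#
# Tables are shipped as a plain-text file (inst/extdata/genetic_codes.tsv)
# holding, per NCBI translation-table number, the 64-amino-acid string and
# the start-codon mask in the canonical TCAG codon order (first base slowest).

.codes_env <- new.env(parent = emptyenv())

#' All 64 codons in canonical NCBI order
#'
#' First codon base cycles slowest over T, C, A, G (TTT, TTC, TTA, ...).
#'
#' @return Character vector of length 64.
#' @export
codon_order <- function() {
  b <- c("T", "C", "A", "G")
  out <- character(64)
  i <- 1L
  for (x in b) for (y in b) for (z in b) {
    out[i] <- paste0(x, y, z)
    i <- i + 1L
  }
  out
}

.load_code_file <- function() {
  if (!is.null(.codes_env$tables)) return(.codes_env$tables)
  path <- system.file("extdata", "genetic_codes.tsv", package = "proteogut")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("integer", "character",
                                          "character", "character"))
  codons <- codon_order()
  tables <- list()
  for (i in seq_len(nrow(raw))) {
    aa <- strsplit(raw$aa[i], "")[[1]]
    st <- strsplit(raw$starts[i], "")[[1]]
    stopifnot(length(aa) == 64L, length(st) == 64L)
    codon_to_aa <- stats::setNames(aa, codons)
    tab <- list(
      table_id = raw$table_id[i],
      name = raw$name[i],
      codon_to_aa = codon_to_aa,
      start_codons = codons[st == "M"],
      stop_codons = codons[aa == "*"]
    )
    class(tab) <- "genetic_code_table"
    tables[[as.character(raw$table_id[i])]] <- tab
  }
  .codes_env$tables <- tables
  tables
}

#' Retrieve an NCBI genetic code table
#'
#' Tables 1 (standard), 4 (Mold/Protozoan/Mycoplasma; TGA encodes
#' tryptophan) and 11 (bacterial/archaeal) are shipped. Tables 4 and 11
#' differ only at TGA, which is the difference that makes lineage-aware
#' translation matter for gut microbes such as \emph{Mycoplasma}.
#'
#' @param table_id Integer NCBI translation-table number.
#' @return A \code{genetic_code_table}: list with \code{table_id},
#'   \code{codon_to_aa} (named length-64 character vector, \code{"*"} for
#'   stops), \code{start_codons} and \code{stop_codons}.
#' @examples
#' genetic_code(11)$codon_to_aa[["TGA"]]  # "*"
#' genetic_code(4)$codon_to_aa[["TGA"]]   # "W"
#' @export
genetic_code <- function(table_id) {
  tables <- .load_code_file()
  key <- as.character(as.integer(table_id))
  tab <- tables[[key]]
  if (is.null(tab)) {
    stop("unknown genetic code table_id: ", table_id,
         " (available: ", paste(names(tables), collapse = ", "), ")")
  }
  tab
}

#' @export
print.genetic_code_table <- function(x, ...) {
  cat("NCBI genetic code table", x$table_id, paste0("(", x$name, ")"), "\n")
  cat("  starts:", paste(x$start_codons, collapse = " "), "\n")
  cat("  stops: ", paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

.split_codons <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence under a genetic code table
#'
#' One amino acid per codon. Codons containing characters outside
#' A/C/G/T (ambiguity codes, N) translate to \code{"X"}. Internal stops
#' render as \code{"*"}; validity is the caller's decision.
#'
#' @param nt Nucleotide string; length must be a multiple of 3.
#' @param table_id NCBI translation-table number.
#' @param trim_stop If TRUE (default) a single terminal stop is removed.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTAA", 11)               # "M"
#' translate_cds("ATGTGATAA", 4)             # "MW"
#' translate_cds("ATGTGATAA", 11, trim_stop = FALSE)  # "M**"
#' @export
translate_cds <- function(nt, table_id, trim_stop = TRUE) {
  nt <- toupper(as.character(nt))
  if (nchar(nt) %% 3L != 0L) {
    stop("sequence length (", nchar(nt), ") is not a multiple of 3")
  }
  tab <- genetic_code(table_id)
  codons <- .split_codons(nt)
  aa <- unname(tab$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  if (trim_stop && length(aa) > 0L && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

.revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Scan a contig for open reading frames in all six frames
#'
#' Deterministic code-aware ORF caller used as the built-in predictor and
#' as a fixture source. For each in-frame stop codon, the longest upstream
#' start (first start after the previous stop) is reported, matching the
#' longest-start semantics of the downstream consensus merge. There is no
#' statistical gene model: every maximal start..stop span passing the
#' length filter is returned.
#'
#' Coordinates are 1-based inclusive on the forward strand with
#' \code{start <= end}; for minus-strand ORFs the start codon occupies
#' forward positions \code{end-2..end}. The minimum length includes the
#' stop codon, so the default 21 nt corresponds to proteins of >= 6 aa.
#'
#' @param seq Contig nucleotide string (or DNAString).
#' @param table_id NCBI translation-table number.
#' @param min_len_nt Minimum ORF length in nucleotides, stop included.
#'   Must be >= 6; rounded up to a multiple of 3.
#' @param contig_id Identifier recorded in the output.
#' @param atg_only If TRUE restrict initiators to ATG instead of the
#'   table's full start-codon set.
#' @return data.frame with columns contig_id, start, end, strand,
#'   table_id; ordered by (strand, start). Zero rows when no ORF exists.
#' @export
find_orfs <- function(seq, table_id, min_len_nt = 21L, contig_id = "contig",
                      atg_only = FALSE) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty contig sequence")
  if (min_len_nt < 6L) stop("min_len_nt must be >= 6")
  min_codons <- as.integer(ceiling(min_len_nt / 3))
  tab <- genetic_code(table_id)
  starts_set <- if (atg_only) "ATG" else tab$start_codons
  stops_set <- tab$stop_codons
  L <- nchar(seq)

  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else .revcomp(seq)
    for (f in 0:2) {
      first <- 1L + f
      if (first + 2L > L) next
      pos <- seq.int(first, L - 2L, by = 3L)
      codons <- substring(s, pos, pos + 2L)
      is_stop <- codons %in% stops_set
      is_start <- codons %in% starts_set
      stop_idx <- which(is_stop)
      prev <- 0L
      for (j in stop_idx) {
        if (j - prev >= min_codons) {
          cand <- which(is_start[(prev + 1L):(j - 1L)])
          if (length(cand) > 0L) {
            i <- prev + cand[1L]
            if (j - i + 1L >= min_codons) {
              cs <- pos[i]
              ce <- pos[j] + 2L
              if (strand == "+") {
                res[[length(res) + 1L]] <- c(cs, ce, 1L)
              } else {
                res[[length(res) + 1L]] <- c(L - ce + 1L, L - cs + 1L, 2L)
              }
            }
          }
        }
        prev <- j
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      table_id = integer(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, res)
  out <- data.frame(contig_id = contig_id, start = m[, 1], end = m[, 2],
                    strand = c("+", "-")[m[, 3]],
                    table_id = as.integer(table_id),
                    stringsAsFactors = FALSE)
  out <- out[order(out$strand, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the coding-strand sequence of a gene
#'
#' @param seq Contig sequence (forward strand).
#' @param start,end 1-based inclusive forward-strand coordinates.
#' @param strand "+" or "-".
#' @return Nucleotide string in coding orientation.
#' @export
extract_cds <- function(seq, start, end, strand) {
  seq <- toupper(as.character(seq))
  cds <- substring(seq, start, end)
  if (strand == "-") cds <- .revcomp(cds)
  cds
}
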