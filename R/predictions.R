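# Normalised gene-prediction records and the standardised protein name.
#
# External predictors emit many dialects; everything is normalised on read
# to one record shape: contig_id, start, end (1-based inclusive, forward
# strand), strand, tool, partial flags. Lines that cannot be normalised are
# skipped, counted and reported, never silently dropped.

.valid_domains <- c("Archaea", "Bacteria", "Eukaryota", "Viruses", "Unknown")

.check_tool_token <- function(tool) {
  if (!is.character(tool) || length(tool) != 1L || !nzchar(tool)) {
    stop("tool token must be a non-empty string")
  }
  if (grepl("[|-]", tool)) {
    stop("tool token may not contain '|' or '-' (both are name separators): ",
         tool)
  }
  tool
}

.empty_predictions <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), tool = character(),
             partial_5p = logical(), partial_3p = logical(),
             stringsAsFactors = FALSE)
}

#' Read gene predictions from a file
#'
#' Supported formats: \code{"gff3"} (CDS features; the \code{partial=}
#' attribute in Prodigal style, e.g. \code{partial=10}, sets the
#' truncation flags) and \code{"tabular"}, a 6-column dialect
#' contig/start/end/strand/frame/score covering FragGeneScan-like outputs.
#' The frame column is accepted but ignored downstream: coordinates are
#' authoritative.
#'
#' Malformed lines (wrong field count, non-numeric or inverted
#' coordinates, bad strand) are skipped; one warning reports how many.
#'
#' @param path File path.
#' @param format "gff3" or "tabular".
#' @param tool Tool-name token attached to every record (no '|' or '-').
#' @param feature_types GFF3 feature types treated as gene calls.
#' @return data.frame of predictions with attribute \code{n_skipped}.
#' @export
read_predictions <- function(path, format = c("gff3", "tabular"), tool,
                             feature_types = c("CDS", "gene", "ORF")) {
  format <- match.arg(format)
  .check_tool_token(tool)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (format == "gff3") {
    # stop at an embedded ##FASTA section if present
    recs <- lapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
    keep <- vapply(recs, length, 0L) >= 8L
    n_skipped <- sum(!keep)
    recs <- recs[keep]
    if (length(recs) > 0L) {
      type <- vapply(recs, `[`, "", 3L)
      recs <- recs[type %in% feature_types]
    }
    rows <- list()
    for (r in recs) {
      start <- suppressWarnings(as.integer(r[4]))
      end <- suppressWarnings(as.integer(r[5]))
      strand <- r[7]
      if (is.na(start) || is.na(end) || start > end ||
          !(strand %in% c("+", "-"))) {
        n_skipped <- n_skipped + 1L
        next
      }
      attr_str <- if (length(r) >= 9L) r[9] else ""
      partial <- regmatches(attr_str,
                            regexpr("partial=[01]{2}", attr_str))
      p5 <- p3 <- FALSE
      if (length(partial) == 1L) {
        bits <- substring(sub("partial=", "", partial), 1:2, 1:2)
        p5 <- bits[1] == "1"
        p3 <- bits[2] == "1"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(contig_id = r[1], start = start, end = end,
                   strand = strand, tool = tool,
                   partial_5p = p5, partial_3p = p3,
                   stringsAsFactors = FALSE)
    }
  } else {
    n_skipped <- 0L
    rows <- list()
    for (ln in lines) {
      r <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(r) < 4L) { n_skipped <- n_skipped + 1L; next }
      start <- suppressWarnings(as.integer(r[2]))
      end <- suppressWarnings(as.integer(r[3]))
      strand <- r[4]
      if (is.na(start) || is.na(end) || start > end ||
          !(strand %in% c("+", "-"))) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(contig_id = r[1], start = start, end = end,
                   strand = strand, tool = tool,
                   partial_5p = FALSE, partial_3p = FALSE,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else .empty_predictions()
  rownames(out) <- NULL
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed line(s) skipped in ", path)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write predictions or merged genes as GFF3
#'
#' @param x data.frame with contig_id, start, end, strand and optionally
#'   name/tools columns (as produced by \code{\link{merge_predictions}}).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return Invisibly, the path.
#' @export
write_gff3 <- function(x, path, source = "proteogut") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(x) > 0L) {
    attrs <- if (!is.null(x$name)) {
      paste0("ID=", x$name)
    } else if (!is.null(x$tool)) {
      paste0("ID=", x$contig_id, "_", seq_len(nrow(x)), ";tool=", x$tool)
    } else {
      paste0("ID=", x$contig_id, "_", seq_len(nrow(x)))
    }
    writeLines(paste(x$contig_id, source, "CDS", x$start, x$end, ".",
                     x$strand, "0", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Construct the standardised protein name
#'
#' Serialisation is \code{index|dataset|domain|table_id|tool1[-tool2...]}:
#' the running index of the protein within its dataset file, the dataset
#' token, the taxonomic domain of the source contig, the NCBI translation
#' table used, and the predicting tools joined by hyphens when several
#' tools called the identical protein.
#'
#' @param index Positive integer, unique within the dataset.
#' @param dataset Dataset token (no '|').
#' @param domain One of Archaea, Bacteria, Eukaryota, Viruses, Unknown.
#' @param table_id NCBI translation-table number.
#' @param tools Character vector of tool tokens (no '|' or '-'); stored
#'   sorted for determinism.
#' @return Single string.
#' @examples
#' name_protein(55401, "ChengpingW_2017__AS130raw", "Bacteria", 11,
#'              "MetaGeneAnnotator")
#' @export
name_protein <- function(index, dataset, domain, table_id, tools) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stop("index must be a positive integer")
  if (grepl("|", dataset, fixed = TRUE)) stop("dataset may not contain '|'")
  if (!nzchar(dataset)) stop("dataset token must be non-empty")
  if (!(domain %in% .valid_domains)) {
    stop("domain must be one of: ", paste(.valid_domains, collapse = ", "))
  }
  if (length(tools) < 1L) stop("at least one tool required")
  for (t in tools) .check_tool_token(t)
  tools <- sort(unique(tools))
  paste(index, dataset, domain, as.integer(table_id),
        paste(tools, collapse = "-"), sep = "|")
}

#' Parse a standardised protein name
#'
#' Inverse of \code{\link{name_protein}}: \code{parse_name(name_protein(...))}
#' recovers every field.
#'
#' @param s Serialized name.
#' @return List with index, dataset, domain, table_id, tools.
#' @export
parse_name <- function(s) {
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5L) {
    stop("expected 5 '|'-separated fields, got ", length(parts), ": ", s)
  }
  index <- suppressWarnings(as.integer(parts[1]))
  table_id <- suppressWarnings(as.integer(parts[4]))
  if (is.na(index) || is.na(table_id)) {
    stop("non-numeric index or table_id in name: ", s)
  }
  if (!(parts[3] %in% .valid_domains)) stop("unknown domain in name: ", s)
  list(index = index, dataset = parts[2], domain = parts[3],
       table_id = table_id, tools = strsplit(parts[5], "-", fixed = TRUE)[[1]])
}

#' Dataset (sample) token of a protein name
#'
#' Convenience accessor used by the ecology module to map corpus hits back
#' to the sample the protein was predicted from.
#'
#' @param s Character vector of serialized names.
#' @return Character vector of dataset tokens.
#' @export
sample_of_protein <- function(s) {
  vapply(strsplit(s, "|", fixed = TRUE), `[`, "", 2L)
}

#' Write proteins to FASTA
#'
#' @param proteins Named character vector or AAStringSet; names are the
#'   serialized protein names.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_protein_fasta <- function(proteins, path) {
  if (!methods::is(proteins, "AAStringSet")) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}
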