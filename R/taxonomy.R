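# Taxonomy routing: contig -> (domain, genetic code) group.
#
# The classifier itself (Kraken 2 in the original workflow) is out of
# scope; its per-contig output is consumed. Routing is a pure lookup in a
# flat taxid -> (domain, table) rule table, optionally walking a
# taxid -> parent table upward so that rules stated at clade level (e.g.
# Mycoplasmatota -> code 4) cover every descendant taxid supplied.

#' Read Kraken-2-style contig classifications
#'
#' Standard Kraken 2 output: C/U flag, sequence id, taxid, length, LCA
#' k-mer string. Only the first three columns are used; "U" rows become
#' unclassified (taxid 0).
#'
#' @param path File path.
#' @return data.frame with contig_id, taxid.
#' @export
read_kraken <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("expected >= 3 tab-separated columns: ", path)
  taxid <- suppressWarnings(as.integer(raw[[3]]))
  taxid[raw[[1]] == "U" | is.na(taxid)] <- 0L
  data.frame(contig_id = as.character(raw[[2]]), taxid = taxid,
             stringsAsFactors = FALSE)
}

#' Read a plain contig/taxid table
#'
#' Two tab-separated columns: contig_id, taxid (0 or empty =
#' unclassified). A header line is detected and skipped.
#'
#' @param path File path.
#' @return data.frame with contig_id, taxid.
#' @export
read_contig_taxa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected 2 tab-separated columns: ", path)
  if (is.na(suppressWarnings(as.integer(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  taxid <- suppressWarnings(as.integer(raw[[2]]))
  taxid[is.na(taxid)] <- 0L
  data.frame(contig_id = as.character(raw[[1]]), taxid = taxid,
             stringsAsFactors = FALSE)
}

#' Load a lineage rule table
#'
#' Columns: taxid, domain (Archaea/Bacteria/Eukaryota/Viruses/Host),
#' table_id (NA allowed for Host). The shipped default covers the four
#' domain roots, the TGA-recoded Mycoplasmatota clade (code 4) and the
#' human host.
#'
#' @param path Path to a TSV, or NULL for the shipped default.
#' @return data.frame of rules.
#' @export
read_lineage_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lineage_rules.tsv", package = "proteogut")
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxid", "domain", "table_id") %in% names(rules)))
  rules$taxid <- as.integer(rules$taxid)
  rules$table_id <- suppressWarnings(as.integer(rules$table_id))
  bad <- !(rules$domain %in% c(.valid_domains, "Host"))
  if (any(bad)) stop("unknown domain in rule table: ",
                     paste(unique(rules$domain[bad]), collapse = ", "))
  if (anyDuplicated(rules$taxid)) stop("duplicate taxid in rule table")
  rules
}

#' Load a taxid -> parent table
#'
#' @param path Path to a 2-column TSV (taxid, parent), or NULL for the
#'   shipped default covering the clades referenced by the default rules.
#' @return Named integer vector: names are taxids, values parents.
#' @export
read_lineage_parents <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lineage_parents.tsv", package = "proteogut")
  }
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(p$parent), as.character(p$taxid))
}

.resolve_taxid <- function(taxid, rule_idx, parents, max_depth = 50L) {
  t <- taxid
  for (i in seq_len(max_depth)) {
    hit <- rule_idx[[as.character(t)]]
    if (!is.null(hit)) return(hit)
    nxt <- parents[[as.character(t)]]
    if (is.null(nxt) || is.na(nxt) || nxt == t) return(NULL)
    t <- nxt
  }
  NULL
}

#' Route contigs to (domain, genetic code) groups
#'
#' Each contig's taxid is resolved against the rule table, walking the
#' parent table upward to the nearest rule on its lineage path.
#' Unclassified contigs (taxid 0) and taxids with no resolvable rule take
#' the default route: domain "Unknown", predicted with the bacterial
#' toolset and genetic code 11 (the Unknown label is retained in protein
#' names). Host-routed contigs are excluded from the output; their count
#' is recorded in attribute \code{n_host_excluded}. Duplicate assignments
#' for one contig keep the first and warn.
#'
#' Routing is a pure function of (taxid, rules): input order never
#' changes a contig's route.
#'
#' @param assignments data.frame with contig_id, taxid (from
#'   \code{\link{read_kraken}} or \code{\link{read_contig_taxa}}).
#' @param rules Rule table from \code{\link{read_lineage_rules}}.
#' @param parents Parent map from \code{\link{read_lineage_parents}}, or
#'   NULL to disable lineage walking.
#' @return data.frame contig_id, domain, table_id (host contigs absent),
#'   in the input contig order; attributes n_host_excluded, n_unknown.
#' @export
route_contigs <- function(assignments, rules = read_lineage_rules(),
                          parents = read_lineage_parents()) {
  stopifnot(all(c("contig_id", "taxid") %in% names(assignments)))
  dup <- duplicated(assignments$contig_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate contig assignment(s); first kept")
    assignments <- assignments[!dup, , drop = FALSE]
  }
  rule_idx <- stats::setNames(as.list(seq_len(nrow(rules))),
                              as.character(rules$taxid))
  if (is.null(parents)) parents <- stats::setNames(integer(), character())

  n <- nrow(assignments)
  domain <- character(n)
  table_id <- integer(n)
  is_host <- logical(n)
  n_unknown <- 0L
  for (i in seq_len(n)) {
    t <- assignments$taxid[i]
    hit <- if (!is.na(t) && t > 0L) .resolve_taxid(t, rule_idx, parents) else NULL
    if (is.null(hit)) {
      domain[i] <- "Unknown"
      table_id[i] <- 11L
      n_unknown <- n_unknown + 1L
    } else if (rules$domain[hit] == "Host") {
      is_host[i] <- TRUE
    } else {
      domain[i] <- rules$domain[hit]
      table_id[i] <- rules$table_id[hit]
    }
  }
  out <- data.frame(contig_id = assignments$contig_id[!is_host],
                    domain = domain[!is_host],
                    table_id = table_id[!is_host],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_host_excluded") <- sum(is_host)
  attr(out, "n_unknown") <- n_unknown
  out
}
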