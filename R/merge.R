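# Consensus merge of multi-tool gene predictions.
#
# The rules, in order:
#   1. group predictions by (strand, 3' stop terminus); per group keep the
#      longest span, crediting as co-predictors only tools whose call had
#      the winner's exact coordinates;
#   2. groups with distinct stops are all retained;
#   3. drop edge-partial genes (start codon within the first or last three
#      contig bases, where assembly errors concentrate);
#   4. drop genes shorter than 21 nt (six amino acids plus stop);
#   5. translate with the contig's routed genetic code; drop survivors
#      whose translation still carries an internal stop.

#' Merge gene predictions from multiple tools on one contig
#'
#' @param contig_seq Contig nucleotide sequence (forward strand).
#' @param preds data.frame of predictions (contig_id, start, end, strand,
#'   tool) as from \code{\link{read_predictions}} or
#'   \code{\link{find_orfs}} (a \code{tool} column is added if absent).
#' @param table_id NCBI translation-table number routed to this contig.
#' @param min_len_nt Minimum gene length in nt, stop codon included.
#' @param keep_internal_stop If TRUE, genes translating with an internal
#'   stop are kept (stop rendered as '*') instead of dropped.
#' @param check_start If TRUE, drop kept genes whose 5' codon is not in
#'   the table's start set (off by default: external tools may use
#'   non-standard initiators).
#' @return data.frame of merged genes: contig_id, start, end, strand,
#'   tools (hyphen-joined, sorted), table_id, cds, protein; ordered by
#'   (strand, start). Attribute \code{filter_counts} logs per-rule drops.
#' @export
merge_predictions <- function(contig_seq, preds, table_id, min_len_nt = 21L,
                              keep_internal_stop = FALSE,
                              check_start = FALSE) {
  contig_seq <- toupper(as.character(contig_seq))
  L <- nchar(contig_seq)
  counts <- c(out_of_bounds = 0L, groups = 0L, edge = 0L, short = 0L,
              frame = 0L, internal_stop = 0L, bad_start = 0L)
  empty <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      tools = character(), table_id = integer(),
                      cds = character(), protein = character(),
                      stringsAsFactors = FALSE)
  if (is.null(preds) || nrow(preds) == 0L) {
    attr(empty, "filter_counts") <- counts
    return(empty)
  }
  if (is.null(preds$tool)) preds$tool <- "internal"
  if (length(unique(preds$contig_id)) > 1L) {
    stop("predictions span multiple contigs; merge one contig at a time")
  }

  oob <- preds$start < 1L | preds$end > L | preds$start > preds$end
  if (any(oob)) {
    warning(sum(oob), " prediction(s) outside contig bounds dropped")
    counts[["out_of_bounds"]] <- sum(oob)
    preds <- preds[!oob, , drop = FALSE]
  }
  if (nrow(preds) == 0L) {
    attr(empty, "filter_counts") <- counts
    return(empty)
  }

  # 3' terminus on the coding strand, in forward coordinates
  stop_pos <- ifelse(preds$strand == "+", preds$end, preds$start)
  key <- paste(preds$strand, stop_pos)
  groups <- split(seq_len(nrow(preds)), key)
  counts[["groups"]] <- length(groups)

  rows <- list()
  for (idx in groups) {
    g <- preds[idx, , drop = FALSE]
    len <- g$end - g$start + 1L
    w <- which.max(len)
    wstart <- g$start[w]; wend <- g$end[w]; strand <- g$strand[w]
    tools <- sort(unique(g$tool[g$start == wstart & g$end == wend]))

    # edge-partial: start codon in the first/last 3 contig bases
    if ((strand == "+" && wstart <= 3L) ||
        (strand == "-" && wend >= L - 2L)) {
      counts[["edge"]] <- counts[["edge"]] + 1L
      next
    }
    glen <- wend - wstart + 1L
    if (glen < min_len_nt) {
      counts[["short"]] <- counts[["short"]] + 1L
      next
    }
    if (glen %% 3L != 0L) {
      counts[["frame"]] <- counts[["frame"]] + 1L
      next
    }
    cds <- extract_cds(contig_seq, wstart, wend, strand)
    if (check_start) {
      tab <- genetic_code(table_id)
      if (!(substring(cds, 1L, 3L) %in% tab$start_codons)) {
        counts[["bad_start"]] <- counts[["bad_start"]] + 1L
        next
      }
    }
    protein <- translate_cds(cds, table_id, trim_stop = TRUE)
    if (grepl("*", protein, fixed = TRUE) && !keep_internal_stop) {
      counts[["internal_stop"]] <- counts[["internal_stop"]] + 1L
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(contig_id = g$contig_id[1], start = wstart, end = wend,
                 strand = strand, tools = paste(tools, collapse = "-"),
                 table_id = as.integer(table_id), cds = cds,
                 protein = protein, stringsAsFactors = FALSE)
  }
  if (counts[["frame"]] > 0L) {
    warning(counts[["frame"]], " merged gene(s) with length not a multiple",
            " of 3 dropped")
  }
  if (counts[["internal_stop"]] > 0L && !keep_internal_stop) {
    warning(counts[["internal_stop"]],
            " merged gene(s) with internal stop codons dropped")
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  out <- out[order(out$strand, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- counts
  out
}

#' Run the full prediction-and-merge pipeline on a dataset
#'
#' For every contig: route to a (domain, genetic code) group, gather the
#' per-tool predictions (or call the built-in ORF scanner), consensus
#' merge, and emit named proteins. Host-routed contigs are excluded
#' before prediction. Proteins are numbered sequentially in output order
#' (contig order as supplied, then strand, then start) and named
#' \code{index|dataset|domain|table_id|tools}.
#'
#' Datasets yielding fewer proteins than \code{min_proteins} are flagged
#' \code{rejected} in the summary (mirroring the exclusion of
#' under-sequenced metagenomes); the proteins are still returned so the
#' caller decides.
#'
#' @param contigs Named character vector / DNAStringSet, or path to a
#'   FASTA file.
#' @param assignments data.frame contig_id/taxid, or path to a Kraken
#'   output or 2-column TSV; NULL treats every contig as unclassified.
#' @param predictions data.frame of all per-tool predictions (any number
#'   of tools), or NULL to use the internal ORF caller.
#' @param dataset Dataset token used in protein names.
#' @param rules,parents Lineage routing tables (defaults shipped).
#' @param min_len_nt Minimum gene length (nt, stop included).
#' @param min_proteins Rejection threshold for the dataset (default 1000).
#' @param atg_only Passed to \code{\link{find_orfs}} when the internal
#'   caller is used.
#' @return List: \code{proteins} (named character vector),
#'   \code{genes} (data.frame with name column), \code{summary} (counts
#'   per domain, host exclusions, rejected flag).
#' @export
run_pipeline <- function(contigs, assignments = NULL, predictions = NULL,
                         dataset = "dataset",
                         rules = read_lineage_rules(),
                         parents = read_lineage_parents(),
                         min_len_nt = 21L, min_proteins = 1000L,
                         atg_only = FALSE) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- Biostrings::readDNAStringSet(contigs)
  }
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- stats::setNames(as.character(contigs),
                               sub("\\s.*$", "", names(contigs)))
  }
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("contigs must be named")
  }
  if (is.character(assignments) && length(assignments) == 1L) {
    first <- readLines(assignments, n = 1L)
    nf <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
    assignments <- if (nf >= 4L) read_kraken(assignments) else
      read_contig_taxa(assignments)
  }
  if (is.null(assignments)) {
    assignments <- data.frame(contig_id = names(contigs), taxid = 0L,
                              stringsAsFactors = FALSE)
  } else {
    missing <- setdiff(names(contigs), assignments$contig_id)
    if (length(missing) > 0L) {
      assignments <- rbind(assignments[, c("contig_id", "taxid")],
                           data.frame(contig_id = missing, taxid = 0L,
                                      stringsAsFactors = FALSE))
    }
  }
  routes <- route_contigs(assignments, rules = rules, parents = parents)
  route_map <- stats::setNames(seq_len(nrow(routes)), routes$contig_id)

  if (!is.null(predictions)) {
    unknown <- setdiff(unique(predictions$contig_id), names(contigs))
    if (length(unknown) > 0L) {
      stop("predictions reference missing contig(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    pred_by_contig <- split(predictions, predictions$contig_id)
  }

  all_genes <- list()
  for (cid in names(contigs)) {
    ri <- route_map[[cid]]
    if (is.null(ri) || is.na(ri)) next  # host-excluded
    tab <- routes$table_id[ri]
    preds <- if (is.null(predictions)) {
      find_orfs(contigs[[cid]], tab, min_len_nt = min_len_nt,
                contig_id = cid, atg_only = atg_only)
    } else {
      pred_by_contig[[cid]]
    }
    merged <- merge_predictions(contigs[[cid]], preds, tab,
                                min_len_nt = min_len_nt)
    if (nrow(merged) > 0L) {
      merged$domain <- routes$domain[ri]
      all_genes[[length(all_genes) + 1L]] <- merged
    }
  }

  if (length(all_genes) > 0L) {
    genes <- do.call(rbind, all_genes)
    genes$name <- vapply(seq_len(nrow(genes)), function(i) {
      name_protein(i, dataset, genes$domain[i], genes$table_id[i],
                   strsplit(genes$tools[i], "-", fixed = TRUE)[[1]])
    }, "")
    proteins <- stats::setNames(genes$protein, genes$name)
  } else {
    genes <- data.frame()
    proteins <- stats::setNames(character(), character())
  }

  by_domain <- if (nrow(genes) > 0L) table(genes$domain) else table(character())
  summary <- list(
    dataset = dataset,
    n_contigs = length(contigs),
    n_host_excluded = attr(routes, "n_host_excluded"),
    n_proteins = length(proteins),
    proteins_by_domain = by_domain,
    min_proteins = min_proteins,
    rejected = length(proteins) < min_proteins
  )
  list(proteins = proteins, genes = genes, summary = summary)
}
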