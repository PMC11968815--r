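# Metatranscriptomic quantification: aligned read fraction, RPKM, and
# expression prevalence of protein clusters. Read mapping is consumed
# from BLAST-style tabular files produced with best-hit settings
# (one target per read); no mapper is run here.

#' Construct per-sample alignment counts
#'
#' @param sample_id Sample identifier.
#' @param total_reads Total reads in the library.
#' @param per_target_reads Named integer vector: target (protein) ->
#'   mapped read count under best-hit counting.
#' @param aligned_reads Total aligned reads (default: sum of the
#'   per-target counts; may exceed it if targets were dropped upstream).
#' @return Object of class \code{alignment_counts}.
#' @export
alignment_counts <- function(sample_id, total_reads, per_target_reads,
                             aligned_reads = sum(per_target_reads)) {
  total_reads <- as.numeric(total_reads)
  if (total_reads <= 0) stop("total_reads must be positive")
  if (any(per_target_reads < 0)) stop("negative per-target count")
  if (aligned_reads > total_reads) {
    stop("aligned_reads exceeds total_reads")
  }
  if (sum(per_target_reads) > aligned_reads + 1e-9) {
    stop("per-target counts exceed aligned_reads")
  }
  structure(list(sample_id = sample_id, total_reads = total_reads,
                 aligned_reads = as.numeric(aligned_reads),
                 per_target_reads = per_target_reads),
            class = "alignment_counts")
}

#' Per-target read counts from a best-hit BLAST tabular file
#'
#' @param hits data.frame from \code{\link{read_blast_tab}} (or a path).
#' @param sample_id Sample identifier.
#' @param total_reads Total reads in the library.
#' @return \code{alignment_counts} object (each query read counted once,
#'   toward its first-listed best hit).
#' @export
counts_from_blast <- function(hits, sample_id, total_reads) {
  if (is.character(hits)) hits <- read_blast_tab(hits)
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  tab <- table(best$sseqid)
  alignment_counts(sample_id, total_reads,
                   stats::setNames(as.integer(tab), names(tab)))
}

#' Aligned read fraction of a sample
#'
#' (aligned reads / total reads) x 100.
#'
#' @param counts \code{alignment_counts} object.
#' @return Percentage in [0, 100].
#' @export
aligned_fraction <- function(counts) {
  stopifnot(inherits(counts, "alignment_counts"))
  100 * counts$aligned_reads / counts$total_reads
}

#' Reads per kilobase per million mapped reads
#'
#' aligned_to_gene / ((gene_length_nt / 1000) * (total_reads / 1e6)).
#'
#' @param aligned_to_gene Reads mapped to the gene (vectorised).
#' @param gene_length_nt Gene length in nucleotides (> 0).
#' @param total_reads Library size (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 500, 1e6)  # 20
#' @export
rpkm <- function(aligned_to_gene, gene_length_nt, total_reads) {
  if (any(gene_length_nt <= 0)) stop("gene_length_nt must be positive")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  aligned_to_gene / ((gene_length_nt / 1000) * (total_reads / 1e6))
}

#' Expression prevalence of protein clusters across samples
#'
#' A cluster counts as expressed in a sample when at least
#' \code{min_reads} (default 1) reads map to any of its members. Member
#' reads are summed per cluster; RPKM uses the representative length
#' (member lengths vary within a cluster).
#'
#' @param counts_list List of \code{alignment_counts}, one per sample.
#' @param cluster_members Named character vector: member (target) id ->
#'   cluster id. Targets without a cluster are warned about and ignored.
#' @param rep_lengths_nt Named numeric vector: cluster id ->
#'   representative length in nucleotides (for RPKM).
#' @param min_reads Expression threshold (reads per sample).
#' @param high_prevalence Prevalence above which a cluster is flagged
#'   highly prevalent (default 0.9).
#' @return List: \code{summary} (data.frame cluster_id,
#'   n_samples_expressed, prevalence, high_prevalence) and \code{rpkm}
#'   (matrix clusters x samples).
#' @export
expression_prevalence <- function(counts_list, cluster_members,
                                  rep_lengths_nt, min_reads = 1L,
                                  high_prevalence = 0.9) {
  n_samples <- length(counts_list)
  if (n_samples == 0L) stop("at least one sample required")
  clusters <- sort(unique(unname(cluster_members)))
  sample_ids <- vapply(counts_list, function(x) x$sample_id, "")
  reads <- matrix(0, nrow = length(clusters), ncol = n_samples,
                  dimnames = list(clusters, sample_ids))
  unmapped <- character()
  for (j in seq_len(n_samples)) {
    pt <- counts_list[[j]]$per_target_reads
    cl <- cluster_members[names(pt)]
    bad <- is.na(cl)
    if (any(bad)) {
      unmapped <- union(unmapped, names(pt)[bad])
      pt <- pt[!bad]; cl <- cl[!bad]
    }
    if (length(pt) > 0L) {
      agg <- tapply(as.numeric(pt), cl, sum)
      reads[names(agg), j] <- agg
    }
  }
  if (length(unmapped) > 0L) {
    warning(length(unmapped), " aligned target(s) without cluster ",
            "membership ignored")
  }
  expressed <- reads >= min_reads
  n_expr <- rowSums(expressed)
  totals <- vapply(counts_list, function(x) x$total_reads, 0)
  lens <- rep_lengths_nt[clusters]
  if (any(is.na(lens))) stop("missing representative length for cluster(s)")
  rpkm_mat <- sweep(reads / (lens / 1000), 2, totals / 1e6, "/")
  summary <- data.frame(cluster_id = clusters,
                        n_samples_expressed = as.integer(n_expr),
                        prevalence = n_expr / n_samples,
                        stringsAsFactors = FALSE)
  summary$high_prevalence <- summary$prevalence > high_prevalence
  rownames(summary) <- NULL
  list(summary = summary, rpkm = rpkm_mat)
}
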