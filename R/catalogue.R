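# Non-redundant protein catalogue construction.
#
# Greedy longest-first clustering in the linclust spirit: sequences are
# visited in order of decreasing length (ties broken by id); the first
# unassigned sequence becomes a representative, and every remaining
# unassigned sequence joining it must pass >= id_threshold identity and
# >= cov_threshold coverage of the SHORTER of the pair, verified by the
# package's fixed pairwise alignment. A shared-k-mer prefilter narrows the
# candidate list; its k is chosen from the thresholds so that it provably
# never discards a sequence the alignment would accept (see .safe_kmer),
# keeping greedy output identical to brute-force all-pairs verification.

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Cluster proteins at identity/coverage thresholds
#'
#' @param proteins Named character vector or AAStringSet with unique ids.
#' @param id_threshold Minimum identity (matches / alignment columns) in
#'   (0, 1]; default 0.9.
#' @param cov_threshold Minimum coverage of the shorter sequence in
#'   (0, 1]; default 0.8 (the shortest-sequence coverage mode).
#' @param spc_max_len Representative length (aa) at or below which a
#'   cluster is flagged a small protein cluster; default 50.
#' @return Object of class \code{protein_clusters}: list with
#'   \code{membership} (data.frame rep_id, member_id),
#'   \code{clusters} (data.frame rep_id, size, rep_len, is_singleton,
#'   is_spc) and the thresholds. Deterministic given the input.
#' @export
cluster_proteins <- function(proteins, id_threshold = 0.9,
                             cov_threshold = 0.8, spc_max_len = 50L) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  if (length(proteins) == 0L) stop("empty protein input")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("proteins must carry unique ids")
  }
  if (id_threshold <= 0 || id_threshold > 1 || cov_threshold <= 0 ||
      cov_threshold > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  ids <- names(proteins)
  len <- nchar(proteins)
  ord <- order(-len, ids)

  k <- min(4L, .safe_kmer(id_threshold, cov_threshold, min(len)))
  use_prefilter <- k >= 2L

  assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
  kmers <- if (use_prefilter) lapply(proteins, .kmer_set, k = k) else NULL

  for (pos in seq_along(ord)) {
    rid <- ids[ord[pos]]
    if (!is.na(assigned[[rid]])) next
    assigned[[rid]] <- rid
    cand <- ids[ord][is.na(assigned[ids[ord]])]
    if (length(cand) == 0L) next
    if (use_prefilter) {
      rk <- kmers[[rid]]
      hit <- vapply(cand, function(cid) {
        ck <- kmers[[cid]]
        length(ck) == 0L || length(rk) == 0L || any(ck %in% rk)
      }, TRUE)
      cand <- cand[hit]
    }
    if (length(cand) == 0L) next
    st <- alignment_stats(Biostrings::AAStringSet(proteins[cand]),
                          proteins[[rid]])
    ok <- st$identity >= id_threshold & st$cov_shorter >= cov_threshold
    assigned[cand[ok]] <- rid
  }

  membership <- data.frame(rep_id = unname(assigned), member_id = ids,
                           stringsAsFactors = FALSE)
  membership <- membership[order(membership$rep_id, membership$member_id), ]
  rownames(membership) <- NULL
  sizes <- table(membership$rep_id)
  reps <- names(sizes)
  clusters <- data.frame(
    rep_id = reps, size = as.integer(sizes),
    rep_len = unname(len[reps]),
    stringsAsFactors = FALSE)
  clusters$is_singleton <- clusters$size == 1L
  clusters$is_spc <- clusters$rep_len <= spc_max_len
  clusters <- clusters[order(-clusters$size, clusters$rep_id), ]
  rownames(clusters) <- NULL
  structure(list(membership = membership, clusters = clusters,
                 id_threshold = id_threshold, cov_threshold = cov_threshold,
                 spc_max_len = spc_max_len, n_proteins = length(proteins)),
            class = "protein_clusters")
}

#' @export
print.protein_clusters <- function(x, ...) {
  cat("protein_clusters:", x$n_proteins, "proteins in",
      nrow(x$clusters), "clusters",
      sprintf("(id >= %.2f, shorter-seq coverage >= %.2f)\n",
              x$id_threshold, x$cov_threshold))
  cat("  singletons:", sum(x$clusters$is_singleton),
      "| small protein clusters (<=", x$spc_max_len, "aa):",
      sum(x$clusters$is_spc), "\n")
  invisible(x)
}

#' Write cluster membership as TSV (rep_id, member_id)
#'
#' @param x protein_clusters object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_clusters_tsv <- function(x, path) {
  utils::write.table(x$membership, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Directed coverage between two protein catalogues
#'
#' The two catalogues are pooled (ids namespaced), co-clustered with the
#' same thresholds, and a protein of A counts as covered by B when its
#' cluster contains at least one B protein (and vice versa).
#'
#' @param catalogue_a,catalogue_b Named character vectors / AAStringSets.
#' @param id_threshold,cov_threshold Clustering thresholds.
#' @return List: frac_a_covered_by_b, frac_b_covered_by_a, n_a, n_b,
#'   clustering (the co-clustering object).
#' @export
overlap_catalogues <- function(catalogue_a, catalogue_b,
                               id_threshold = 0.9, cov_threshold = 0.8) {
  as_chr <- function(x) {
    if (methods::is(x, "AAStringSet")) stats::setNames(as.character(x),
                                                       names(x)) else x
  }
  a <- as_chr(catalogue_a); b <- as_chr(catalogue_b)
  pooled <- c(stats::setNames(a, paste0("A::", names(a))),
              stats::setNames(b, paste0("B::", names(b))))
  cl <- cluster_proteins(pooled, id_threshold, cov_threshold)
  mem <- cl$membership
  src <- substring(mem$member_id, 1L, 1L)
  has_a <- tapply(src == "A", mem$rep_id, any)
  has_b <- tapply(src == "B", mem$rep_id, any)
  covered_a <- sum(src == "A" & has_b[mem$rep_id])
  covered_b <- sum(src == "B" & has_a[mem$rep_id])
  list(frac_a_covered_by_b = covered_a / length(a),
       frac_b_covered_by_a = covered_b / length(b),
       n_a = length(a), n_b = length(b), clustering = cl)
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in .all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

#' Rarefaction (cluster accumulation) across samples
#'
#' Samples are added in random order; the mean cumulative number of
#' distinct clusters at each depth is reported together with the smallest
#' depth at which the mean curve reaches a requested fraction of the
#' total cluster count.
#'
#' @param sample_clusters Named list: per sample, a character vector of
#'   cluster ids present in it.
#' @param n_permutations Number of random orderings averaged (default
#'   100); ignored when \code{exact = TRUE}.
#' @param coverage_q Fractions of the total for which the required depth
#'   is reported.
#' @param exact If TRUE, average over all n! orderings (n <= 8 enforced).
#' @return List: curve (mean distinct clusters by depth), total,
#'   depth_for (named by coverage fraction), n_permutations.
#' @export
rarefaction_curve <- function(sample_clusters, n_permutations = 100L,
                              coverage_q = c(0.5, 0.9), exact = FALSE) {
  n <- length(sample_clusters)
  if (n < 1L) stop("at least one sample required")
  universe <- unique(unlist(sample_clusters, use.names = FALSE))
  total <- length(universe)
  idx_sets <- lapply(sample_clusters, function(x) {
    unique(match(x, universe))
  })
  one_curve <- function(ord) {
    seen <- logical(total)
    out <- integer(n)
    cum <- 0L
    for (d in seq_len(n)) {
      s <- idx_sets[[ord[d]]]
      new <- s[!seen[s]]
      seen[new] <- TRUE
      cum <- cum + length(new)
      out[d] <- cum
    }
    out
  }
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8 samples")
    orders <- .all_perms(n)
  } else {
    orders <- replicate(n_permutations, sample.int(n), simplify = FALSE)
  }
  curves <- vapply(orders, one_curve, integer(n))
  curve <- if (n == 1L) mean(curves) else rowMeans(curves)
  depth_for <- vapply(coverage_q, function(q) {
    d <- which(curve >= q * total)
    if (length(d) == 0L) NA_integer_ else d[1L]
  }, 0L)
  names(depth_for) <- as.character(coverage_q)
  list(curve = as.numeric(curve), total = total, depth_for = depth_for,
       n_permutations = length(orders))
}
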