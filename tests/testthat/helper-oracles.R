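# Independent oracles used by unit and acceptance tests. These stay
# deliberately naive: enumeration and closed forms, no shortcuts shared
# with the implementation paths they check.

# Brute-force greedy clustering: identical longest-first semantics but
# verifies EVERY candidate against the representative by full alignment
# (no k-mer prefilter). Returns membership data.frame like the package.
oracle_cluster <- function(proteins, id_threshold = 0.9,
                           cov_threshold = 0.8) {
  ids <- names(proteins)
  len <- nchar(proteins)
  ord <- order(-len, ids)
  assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (pos in seq_along(ord)) {
    rid <- ids[ord[pos]]
    if (!is.na(assigned[[rid]])) next
    assigned[[rid]] <- rid
    cand <- ids[ord][is.na(assigned[ids[ord]])]
    if (length(cand) == 0L) next
    st <- alignment_stats(Biostrings::AAStringSet(proteins[cand]),
                          proteins[[rid]])
    ok <- st$identity >= id_threshold & st$cov_shorter >= cov_threshold
    assigned[cand[ok]] <- rid
  }
  out <- data.frame(rep_id = unname(assigned), member_id = ids,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rep_id, out$member_id), ]
  rownames(out) <- NULL
  out
}

# Two-sided Fisher p by direct enumeration in plain (non-log) arithmetic
# with choose(); the same probability-mass tie rule as the conventional
# definition.
oracle_fisher <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  n <- row1 + row2
  if (n == 0 || row1 == 0 || row2 == 0 || col1 == 0 || col1 == n) return(1)
  lo <- max(0, col1 - row2); hi <- min(row1, col1)
  denom <- choose(n, col1)
  probs <- vapply(lo:hi, function(x) {
    choose(row1, x) * choose(row2, col1 - x) / denom
  }, 0)
  p_obs <- probs[(lo:hi) == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form expected rarefaction curve: at depth d, a cluster present
# in m of the n samples is missed with probability C(n-m, d)/C(n, d).
oracle_rarefaction <- function(sample_clusters) {
  n <- length(sample_clusters)
  universe <- unique(unlist(sample_clusters, use.names = FALSE))
  m <- vapply(universe, function(cl) {
    sum(vapply(sample_clusters, function(s) cl %in% s, TRUE))
  }, 0L)
  vapply(seq_len(n), function(d) {
    sum(1 - choose(n - m, d) / choose(n, d))
  }, 0)
}

# mirror ORF coordinates onto the reverse-complemented contig
mirror_orfs <- function(orfs, L) {
  out <- orfs
  out$start <- L - orfs$end + 1L
  out$end <- L - orfs$start + 1L
  out$strand <- ifelse(orfs$strand == "+", "-", "+")
  out[order(out$strand, out$start, out$end), ]
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}
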