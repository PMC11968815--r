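# Protein ecology across gut samples: query matching, prevalence with
# Fisher's exact test + Benjamini-Hochberg, multi-protein intersection,
# function-positive fraction, taxonomic range.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass rule: with margins fixed, the two-sided p-value is
#' the sum of hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table (within
#' relative tolerance 1e-7, the conventional tie guard). Probabilities
#' are computed in log space for stability.
#'
#' @param x 2x2 matrix of non-negative integer counts, or a length-4
#'   vector (a, b, c, d) read row-wise.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))  # 2/choose(10,5)
#' @export
fisher_exact <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("x must be a 2x2 table")
    a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  } else {
    if (length(x) != 4L) stop("x must be 2x2 or length 4")
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("all cells must be non-negative integers")
  }
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  n <- row1 + row2
  if (n == 0 || row1 == 0 || row2 == 0 || col1 == 0 || col1 == n) {
    return(1)
  }
  lo <- max(0, col1 - row2)
  hi <- min(row1, col1)
  xs <- lo:hi
  lp <- stats::dhyper(xs, row1, row2, col1, log = TRUE)
  lp_obs <- lp[xs == a]
  min(1, sum(exp(lp[lp <= lp_obs + log(1 + 1e-7)])))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min_{j >= i} ( p_(j) * m / j ), clipped to 1, returned in the
#' input order. NAs propagate and are excluded from m.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  qv <- numeric(m)
  qv[o] <- adj
  q[ok] <- qv
  q
}

#' Read BLAST/DIAMOND tabular output (outfmt 6)
#'
#' Default 12 columns: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore.
#'
#' @param path File path.
#' @return data.frame with the standard column names.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) stop("expected >= 12 tab-separated columns: ", path)
  raw <- raw[, 1:12]
  names(raw) <- cols
  raw
}

#' Match query proteins against a predicted-protein corpus
#'
#' Either aligns internally (package-fixed local alignment) or filters a
#' precomputed BLAST-style tabular hit set. A hit is valid only when
#' identity, query coverage and subject coverage all meet their
#' thresholds (defaults 0.9/0.9/0.9).
#'
#' @param queries Named character vector / AAStringSet of query proteins.
#' @param corpus Named character vector / AAStringSet of corpus proteins;
#'   NULL when \code{hits} is supplied.
#' @param hits Precomputed data.frame from \code{\link{read_blast_tab}};
#'   coverages are computed from the aligned spans and the supplied
#'   sequence lengths (\code{query_lengths}/\code{subject_lengths}).
#' @param id_min,qcov_min,scov_min Thresholds in (0, 1].
#' @param query_lengths,subject_lengths Named integer vectors of sequence
#'   lengths, required with \code{hits} (defaulted from
#'   \code{queries}/\code{corpus} when those are given).
#' @return data.frame: query_id, subject_id, identity, query_cov,
#'   subject_cov, sample (dataset token parsed from the subject's
#'   standardised name, NA when unparseable).
#' @export
search_hits <- function(queries, corpus = NULL, hits = NULL,
                        id_min = 0.9, qcov_min = 0.9, scov_min = 0.9,
                        query_lengths = NULL, subject_lengths = NULL) {
  stopifnot(id_min > 0, id_min <= 1, qcov_min > 0, qcov_min <= 1,
            scov_min > 0, scov_min <= 1)
  if (methods::is(queries, "AAStringSet")) {
    queries <- stats::setNames(as.character(queries), names(queries))
  }
  out <- list()
  if (is.null(hits)) {
    if (is.null(corpus) || length(corpus) == 0L) stop("empty corpus")
    if (methods::is(corpus, "AAStringSet")) {
      corpus <- stats::setNames(as.character(corpus), names(corpus))
    }
    corpus_set <- Biostrings::AAStringSet(corpus)
    for (qid in names(queries)) {
      st <- alignment_stats(corpus_set, queries[[qid]])
      ok <- st$identity >= id_min & st$sub_cov >= qcov_min &
        st$pat_cov >= scov_min
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          query_id = qid, subject_id = st$id[ok],
          identity = st$identity[ok], query_cov = st$sub_cov[ok],
          subject_cov = st$pat_cov[ok], stringsAsFactors = FALSE)
      }
    }
  } else {
    if (is.null(query_lengths)) {
      query_lengths <- stats::setNames(nchar(queries), names(queries))
    }
    if (is.null(subject_lengths) && !is.null(corpus)) {
      if (methods::is(corpus, "AAStringSet")) {
        corpus <- stats::setNames(as.character(corpus), names(corpus))
      }
      subject_lengths <- stats::setNames(nchar(corpus), names(corpus))
    }
    if (is.null(subject_lengths)) {
      stop("subject_lengths (or corpus) required with precomputed hits")
    }
    qlen <- query_lengths[hits$qseqid]
    slen <- subject_lengths[hits$sseqid]
    identity <- hits$pident / 100
    qcov <- (abs(hits$qend - hits$qstart) + 1L) / qlen
    scov <- (abs(hits$send - hits$sstart) + 1L) / slen
    ok <- !is.na(qlen) & !is.na(slen) & identity >= id_min &
      qcov >= qcov_min & scov >= scov_min
    if (any(ok)) {
      out[[1L]] <- data.frame(
        query_id = hits$qseqid[ok], subject_id = hits$sseqid[ok],
        identity = identity[ok], query_cov = unname(qcov[ok]),
        subject_cov = unname(scov[ok]), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(query_id = character(), subject_id = character(),
               identity = numeric(), query_cov = numeric(),
               subject_cov = numeric(), stringsAsFactors = FALSE)
  res$sample <- vapply(res$subject_id, function(s) {
    p <- tryCatch(parse_name(s), error = function(e) NULL)
    if (is.null(p)) NA_character_ else p$dataset
  }, "")
  rownames(res) <- NULL
  res
}

#' Per-sample presence from validated hits
#'
#' Presence is binary: one valid hit in a sample suffices.
#'
#' @param hits data.frame from \code{\link{search_hits}}.
#' @param samples Character vector of all sample ids (defines the
#'   universe; samples without hits are FALSE).
#' @param query_id Restrict to one query (default: any).
#' @return Named logical vector over \code{samples}.
#' @export
presence_from_hits <- function(hits, samples, query_id = NULL) {
  if (!is.null(query_id)) hits <- hits[hits$query_id == query_id, ]
  stats::setNames(samples %in% hits$sample, samples)
}

#' Intersection presence for a multi-protein query
#'
#' A sample counts as positive only when it contains every queried
#' protein (e.g. all chains of a complex).
#'
#' @param per_query_presence List of named logical vectors over the same
#'   samples.
#' @return Named logical vector (logical AND across queries).
#' @export
multi_protein_presence <- function(per_query_presence) {
  if (length(per_query_presence) < 1L) stop("at least one query required")
  nm <- names(per_query_presence[[1L]])
  for (v in per_query_presence) {
    if (!identical(names(v), nm)) stop("presence vectors must share samples")
  }
  Reduce(`&`, per_query_presence)
}

#' Default metadata variable configuration
#'
#' Age and BMI bin edges are configurable; defaults are life-stage bins
#' (0-18-40-60+) and the WHO BMI categories. Disease flags are compared
#' against healthy controls; all other variables are compared group
#' versus rest.
#'
#' @param age_breaks,bmi_breaks Numeric cut points (left-closed bins).
#' @param diseases Names of logical disease-flag columns.
#' @return List of variable descriptors consumed by
#'   \code{\link{prevalence_analysis}}.
#' @export
investigut_variables <- function(age_breaks = c(0, 18, 40, 60, Inf),
                                 bmi_breaks = c(0, 18.5, 25, 30, Inf),
                                 diseases = c("cd", "uc", "crc", "cdiff",
                                              "t2d", "ra", "fatty_liver")) {
  vars <- list(
    list(name = "age", type = "binned", breaks = age_breaks),
    list(name = "bmi", type = "binned", breaks = bmi_breaks),
    list(name = "sex", type = "categorical"),
    list(name = "country", type = "categorical"),
    list(name = "westernised", type = "categorical"),
    list(name = "antibiotics", type = "categorical"),
    list(name = "smoker", type = "categorical")
  )
  for (d in diseases) {
    vars[[length(vars) + 1L]] <- list(name = d, type = "disease")
  }
  vars
}

.fisher_group_vs_rest <- function(presence, in_group) {
  a <- sum(presence & in_group); b <- sum(!presence & in_group)
  c <- sum(presence & !in_group); d <- sum(!presence & !in_group)
  fisher_exact(c(a, b, c, d))
}

#' Prevalence of a protein across metadata groups
#'
#' For every configured variable, samples with missing metadata for that
#' variable are excluded (from that variable only), per-group presence
#' counts and prevalences are computed, and each group is tested with
#' Fisher's exact test: categorical/binned groups against all remaining
#' samples of the variable, disease flags against healthy controls
#' (samples with \code{healthy == TRUE}). Benjamini-Hochberg correction
#' is applied within each variable family (all disease comparisons form
#' one family); the family is reported so users can re-correct at a
#' different scope.
#'
#' @param presence Named logical vector: sample -> protein presence.
#' @param metadata data.frame with a \code{sample_id} column and the
#'   variable columns; a logical \code{healthy} column marks controls
#'   for the disease comparisons.
#' @param variables Descriptor list from
#'   \code{\link{investigut_variables}} (variables absent from the
#'   metadata are skipped).
#' @return data.frame: variable, group, n_present, n_total, prevalence,
#'   comparison, p_value, q_value, family.
#' @export
prevalence_analysis <- function(presence, metadata,
                                variables = investigut_variables()) {
  stopifnot("sample_id" %in% names(metadata))
  metadata <- metadata[metadata$sample_id %in% names(presence), ,
                       drop = FALSE]
  pres <- presence[metadata$sample_id]
  rows <- list()
  for (v in variables) {
    if (!(v$name %in% names(metadata))) next
    col <- metadata[[v$name]]
    if (v$type == "binned") {
      col <- cut(as.numeric(col), breaks = v$breaks, right = FALSE,
                 include.lowest = TRUE)
      col <- as.character(col)
    }
    if (v$type == "disease") {
      if (!("healthy" %in% names(metadata))) {
        warning("no 'healthy' column; disease variable ", v$name,
                " skipped")
        next
      }
      case <- !is.na(col) & (col %in% c(TRUE, "yes", "TRUE", 1))
      ctrl <- !is.na(metadata$healthy) & metadata$healthy
      if (sum(ctrl) == 0L) {
        warning("zero healthy controls; disease variable ", v$name,
                " skipped")
        next
      }
      if (sum(case) == 0L) next
      p <- fisher_exact(c(sum(pres & case), sum(!pres & case),
                          sum(pres & ctrl), sum(!pres & ctrl)))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v$name, group = v$name,
        n_present = sum(pres & case), n_total = sum(case),
        prevalence = sum(pres & case) / sum(case),
        comparison = "healthy", p_value = p, family = "disease",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v$name, group = "healthy",
        n_present = sum(pres & ctrl), n_total = sum(ctrl),
        prevalence = sum(pres & ctrl) / sum(ctrl),
        comparison = "", p_value = NA_real_, family = "disease",
        stringsAsFactors = FALSE)
    } else {
      keep <- !is.na(col) & nzchar(as.character(col))
      if (sum(keep) == 0L) next
      cc <- as.character(col[keep])
      pp <- pres[keep]
      for (g in sort(unique(cc))) {
        in_g <- cc == g
        if (sum(in_g) == 0L) next
        p <- if (sum(!in_g) > 0L) .fisher_group_vs_rest(pp, in_g) else
          NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v$name, group = g,
          n_present = sum(pp & in_g), n_total = sum(in_g),
          prevalence = sum(pp & in_g) / sum(in_g),
          comparison = "rest", p_value = p, family = v$name,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(variable = character(), group = character(),
                      n_present = integer(), n_total = integer(),
                      prevalence = numeric(), comparison = character(),
                      p_value = numeric(), q_value = numeric(),
                      family = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$q_value[sel] <- bh_adjust(out$p_value[sel])
  }
  rownames(out) <- NULL
  out[, c("variable", "group", "n_present", "n_total", "prevalence",
          "comparison", "p_value", "q_value", "family")]
}

#' Function-positive fraction per individual
#'
#' The cumulative relative abundance, within each individual, of the
#' genomes that carry the queried function.
#'
#' @param positive_genomes Character vector of genome ids carrying the
#'   function.
#' @param abundances Numeric matrix, genomes x individuals, of relative
#'   abundances; every column must sum to <= 1 (tolerance 1e-6).
#' @return Named numeric vector: per-individual fraction in [0, 1].
#' @export
function_positive_fraction <- function(positive_genomes, abundances) {
  if (!is.matrix(abundances)) abundances <- as.matrix(abundances)
  if (any(abundances < 0)) stop("abundances must be non-negative")
  cs <- colSums(abundances)
  if (any(cs > 1 + 1e-6)) {
    stop("per-individual abundance sums exceed 1")
  }
  missing <- setdiff(positive_genomes, rownames(abundances))
  if (length(missing) > 0L) {
    warning(length(missing), " positive genome(s) absent from the ",
            "abundance matrix ignored")
  }
  keep <- intersect(positive_genomes, rownames(abundances))
  if (length(keep) == 0L) {
    return(stats::setNames(rep(0, ncol(abundances)),
                           colnames(abundances)))
  }
  colSums(abundances[keep, , drop = FALSE])
}

#' Taxonomic range of a protein cluster
#'
#' Counts the distinct species, genera, families and phyla among the
#' genomes carrying the cluster; the cluster is flagged as widely shared
#' when it occurs in >= 10 species spanning >= 2 phyla.
#'
#' @param member_genomes Character vector of genome ids carrying the
#'   cluster.
#' @param genome_taxonomy data.frame: genome_id, species, genus, family,
#'   phylum. Genomes without taxonomy are skipped with a warning.
#' @param min_species,min_phyla Sharing thresholds (defaults 10 and 2).
#' @return List: n_species, n_genus, n_family, n_phylum, shared.
#' @export
taxonomic_range <- function(member_genomes, genome_taxonomy,
                            min_species = 10L, min_phyla = 2L) {
  idx <- match(unique(member_genomes), genome_taxonomy$genome_id)
  if (any(is.na(idx))) {
    warning(sum(is.na(idx)), " genome(s) without taxonomy skipped")
    idx <- idx[!is.na(idx)]
  }
  tx <- genome_taxonomy[idx, , drop = FALSE]
  res <- list(n_species = length(unique(tx$species)),
              n_genus = length(unique(tx$genus)),
              n_family = length(unique(tx$family)),
              n_phylum = length(unique(tx$phylum)))
  res$shared <- res$n_species >= min_species && res$n_phylum >= min_phyla
  res
}
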