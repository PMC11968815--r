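# Seeded synthetic-data generation: contigs with planted genes under a
# chosen genetic code, simulated tool outputs with controlled error
# modes, protein families, ecology metadata/abundance fixtures.
#
# Every generator ships its ground truth so downstream tests are
# oracle-based. Determinism: each generator seeds the RNG from its
# config, so a fixed config yields byte-identical output.
#
# Planted genes are flanked by in-frame stop "guards" in the adjacent
# spacer so that each gene is a maximal ORF: the built-in six-frame
# scanner recovers planted coordinates exactly, which downstream
# planted-truth tests rely on.

#' Simulation configuration for contig/gene fixtures
#'
#' @param seed RNG seed; a fixed config reproduces byte-identical output.
#' @param n_contigs Number of ordinary contigs.
#' @param genes_per_contig Planted genes per ordinary contig.
#' @param gene_len_codons Range of gene lengths in codons, stop included
#'   (default 30-100, i.e. 90-300 nt: typical short bacterial genes).
#' @param intergenic_range Spacer length range (nt) between genes.
#' @param table_id NCBI translation table for all contigs.
#' @param p_minus Probability a planted gene lies on the minus strand.
#' @param n_edge_genes Extra contigs carrying one edge-partial gene
#'   (start codon within 3 bases of a contig end) that the merge must
#'   remove.
#' @param n_short_genes Extra planted genes under 21 nt (3-6 codons)
#'   that the length filter must remove.
#' @param n_tga_genes Number of planted genes forced to contain an
#'   in-frame TGA codon (sense under table 4, stop under table 11).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_contigs = 20L, genes_per_contig = 5L,
                       gene_len_codons = c(30L, 100L),
                       intergenic_range = c(20L, 120L), table_id = 11L,
                       p_minus = 0.5, n_edge_genes = 0L,
                       n_short_genes = 0L, n_tga_genes = 0L) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              genes_per_contig = as.integer(genes_per_contig),
              gene_len_codons = as.integer(gene_len_codons),
              intergenic_range = as.integer(intergenic_range),
              table_id = as.integer(table_id), p_minus = p_minus,
              n_edge_genes = as.integer(n_edge_genes),
              n_short_genes = as.integer(n_short_genes),
              n_tga_genes = as.integer(n_tga_genes))
  stopifnot(cfg$gene_len_codons[1] >= 3L, cfg$p_minus >= 0, cfg$p_minus <= 1)
  class(cfg) <- "sim_config"
  cfg
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# gene in coding orientation: ATG + sense codons + stop
.make_gene_seq <- function(n_codons, tab, force_tga = FALSE) {
  sense <- names(tab$codon_to_aa)[tab$codon_to_aa != "*"]
  sense_mid <- setdiff(sense, tab$start_codons)  # avoid ambiguity, keep simple
  n_mid <- n_codons - 2L
  mid <- if (n_mid > 0L) sample(sense_mid, n_mid, replace = TRUE) else
    character()
  if (force_tga) {
    if (!("TGA" %in% sense)) stop("TGA is not a sense codon under table ",
                                  tab$table_id)
    if (n_mid < 1L) stop("gene too short to host an internal TGA")
    mid[ceiling(n_mid / 2)] <- "TGA"
  }
  stop_codon <- sample(tab$stop_codons, 1L)
  paste(c("ATG", mid, stop_codon), collapse = "")
}

#' Generate contigs with planted genes
#'
#' Ordinary contigs carry \code{genes_per_contig} genes separated by
#' random spacers; additional contigs carry edge-partial genes, and
#' short (< 21 nt) genes are appended to ordinary contigs, per the
#' config. Every planted gene is a valid, maximal ORF under the config's
#' genetic code.
#'
#' @param cfg \code{\link{sim_config}} object.
#' @return List: \code{contigs} (named character vector) and
#'   \code{truth} (data.frame gene_id, contig_id, start, end, strand,
#'   table_id, edge, short, tga).
#' @export
make_contigs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tab <- genetic_code(cfg$table_id)
  contigs <- character()
  truth <- list()
  gene_n <- 0L
  tga_left <- cfg$n_tga_genes
  short_left <- cfg$n_short_genes

  add_truth <- function(contig_id, start, end, strand, edge = FALSE,
                        short = FALSE, tga = FALSE) {
    gene_n <<- gene_n + 1L
    truth[[gene_n]] <<- data.frame(
      gene_id = sprintf("g%05d", gene_n), contig_id = contig_id,
      start = start, end = end, strand = strand,
      table_id = cfg$table_id, edge = edge, short = short, tga = tga,
      stringsAsFactors = FALSE)
  }

  for (ci in seq_len(cfg$n_contigs)) {
    cid <- sprintf("ctg%04d", ci)
    pieces <- character()
    pos <- 0L
    n_genes <- cfg$genes_per_contig
    extra_short <- if (short_left > 0L) { short_left <- short_left - 1L; 1L } else 0L
    for (gi in seq_len(n_genes + extra_short)) {
      short <- extra_short == 1L && gi > n_genes
      n_codons <- if (short) sample(3:6, 1L) else
        sample(cfg$gene_len_codons[1]:cfg$gene_len_codons[2], 1L)
      force_tga <- !short && tga_left > 0L && n_codons > 2L
      if (force_tga) tga_left <- tga_left - 1L
      strand <- if (stats::runif(1) < cfg$p_minus) "-" else "+"
      gene <- .make_gene_seq(n_codons, tab, force_tga)
      glen <- nchar(gene)
      spacer_len <- sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1L)
      spacer <- .random_dna(spacer_len)
      if (strand == "+") {
        # guard: in-frame stop immediately upstream of the start codon
        substr(spacer, spacer_len - 2L, spacer_len) <- "TAA"
        pieces <- c(pieces, spacer, gene)
        start <- pos + spacer_len + 1L
        end <- start + glen - 1L
      } else {
        # guard after the gene in forward coords = upstream on coding strand
        spacer2 <- spacer
        substr(spacer2, 1L, 3L) <- "TTA"  # revcomp(TAA)
        pieces <- c(pieces, .random_dna(12L), .revcomp(gene), spacer2)
        start <- pos + 12L + 1L
        end <- start + glen - 1L
        pos <- pos + 12L + spacer_len
      }
      if (strand == "+") pos <- pos + spacer_len
      pos <- pos + glen
      add_truth(cid, start, end, strand, short = short, tga = force_tga)
    }
    pieces <- c(pieces, .random_dna(sample(30:60, 1L)))
    contigs[[cid]] <- paste(pieces, collapse = "")
  }

  # contigs carrying one edge-partial gene each (alternating +/- edge)
  for (ei in seq_len(cfg$n_edge_genes)) {
    cid <- sprintf("edge%04d", ei)
    n_codons <- sample(cfg$gene_len_codons[1]:cfg$gene_len_codons[2], 1L)
    gene <- .make_gene_seq(n_codons, tab)
    glen <- nchar(gene)
    lead <- sample(0:2, 1L)
    if (ei %% 2L == 1L) {
      seq <- paste0(.random_dna(lead), gene, "TAA", .random_dna(80L))
      add_truth(cid, lead + 1L, lead + glen, "+", edge = TRUE)
    } else {
      seq <- paste0(.random_dna(80L), "TTA", .revcomp(gene), .random_dna(lead))
      add_truth(cid, 84L, 83L + glen, "-", edge = TRUE)
    }
    contigs[[cid]] <- seq
  }

  truth <- if (gene_n > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               table_id = integer(), edge = logical(), short = logical(),
               tga = logical(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(contigs = contigs, truth = truth)
}

#' Simulate per-tool prediction outputs from planted truth
#'
#' Each tool's output is the truth minus missed genes, with a fraction of
#' starts shifted downstream in frame (stop preserved, shifted length
#' kept >= 21 nt, emulating start misprediction), plus spurious
#' predictions drawn from real ORFs of the contigs that do not share a
#' stop with any planted gene (so the merge cannot trivially drop them).
#'
#' @param contigs Named character vector from \code{\link{make_contigs}}.
#' @param truth Truth data.frame from \code{\link{make_contigs}}.
#' @param error_models Named list: tool -> c(miss=, start_shift=,
#'   spurious=) probabilities.
#' @param seed RNG seed.
#' @param max_shift_codons Maximum start shift in codons.
#' @return Named list of per-tool prediction data.frames (contig_id,
#'   start, end, strand, tool, gene_id [NA for spurious], shifted);
#'   attribute \code{error_counts} logs per-tool missed/shifted/spurious.
#' @export
simulate_tool_outputs <- function(contigs, truth, error_models,
                                  seed = 1L, max_shift_codons = 8L) {
  set.seed(seed)
  stopifnot(length(error_models) >= 1L)
  table_id <- if (nrow(truth) > 0L) truth$table_id[1] else 11L

  truth_keys <- paste(truth$contig_id, truth$strand,
                      ifelse(truth$strand == "+", truth$end, truth$start))
  pool <- list()
  for (cid in names(contigs)) {
    orfs <- find_orfs(contigs[[cid]], table_id, contig_id = cid)
    if (nrow(orfs) == 0L) next
    keys <- paste(orfs$contig_id, orfs$strand,
                  ifelse(orfs$strand == "+", orfs$end, orfs$start))
    orfs <- orfs[!(keys %in% truth_keys), , drop = FALSE]
    if (nrow(orfs) > 0L) pool[[length(pool) + 1L]] <- orfs
  }
  pool <- if (length(pool) > 0L) do.call(rbind, pool) else NULL

  out <- list()
  counts <- list()
  for (tool in names(error_models)) {
    em <- error_models[[tool]]
    miss <- stats::runif(nrow(truth)) < em[["miss"]]
    kept <- truth[!miss, , drop = FALSE]
    shifted <- logical(nrow(kept))
    if (nrow(kept) > 0L) {
      do_shift <- stats::runif(nrow(kept)) < em[["start_shift"]]
      # edge-planted genes are never shifted: an inward-shifted start
      # would no longer sit at the contig edge, silently converting an
      # edge-partial into an ordinary gene
      if (!is.null(kept$edge)) do_shift <- do_shift & !kept$edge
      for (i in which(do_shift)) {
        len <- kept$end[i] - kept$start[i] + 1L
        kmax <- min(max_shift_codons, (len - 21L) %/% 3L)
        if (kmax < 1L) next
        k <- sample.int(kmax, 1L)
        if (kept$strand[i] == "+") {
          kept$start[i] <- kept$start[i] + 3L * k
        } else {
          kept$end[i] <- kept$end[i] - 3L * k
        }
        shifted[i] <- TRUE
      }
    }
    n_sp <- stats::rbinom(1L, max(nrow(truth), 1L), em[["spurious"]])
    sp <- NULL
    if (!is.null(pool) && n_sp > 0L) {
      take <- sample.int(nrow(pool), min(n_sp, nrow(pool)))
      sp <- pool[take, , drop = FALSE]
    }
    df <- data.frame(contig_id = kept$contig_id, start = kept$start,
                     end = kept$end, strand = kept$strand,
                     tool = rep(tool, nrow(kept)),
                     gene_id = kept$gene_id, shifted = shifted,
                     stringsAsFactors = FALSE)
    if (!is.null(sp)) {
      df <- rbind(df, data.frame(contig_id = sp$contig_id, start = sp$start,
                                 end = sp$end, strand = sp$strand,
                                 tool = tool, gene_id = NA_character_,
                                 shifted = FALSE, stringsAsFactors = FALSE))
    }
    rownames(df) <- NULL
    out[[tool]] <- df
    counts[[tool]] <- c(missed = sum(miss), shifted = sum(shifted),
                        spurious = if (is.null(sp)) 0L else nrow(sp))
  }
  attr(out, "error_counts") <- counts
  out
}

#' Generate planted protein families for clustering tests
#'
#' Each family is a random representative plus members carrying
#' substitutions at evenly spaced positions (so every alignment window
#' sees the nominal substitution rate: a 5 percent family stays above a
#' 90 percent identity threshold everywhere, a 15 percent family falls
#' below it everywhere).
#'
#' @param n_families Number of families.
#' @param members_per_family Members per family (representative included).
#' @param substitution_rate Per-position substitution probability applied
#'   at evenly spaced positions.
#' @param len_range Representative length range (aa).
#' @param n_singletons Unrelated random sequences added as singletons.
#' @param seed RNG seed.
#' @return List: \code{proteins} (named character vector) and
#'   \code{truth} (data.frame id, family; singletons get their own
#'   family label).
#' @export
make_protein_families <- function(n_families = 5L, members_per_family = 6L,
                                  substitution_rate = 0.05,
                                  len_range = c(80L, 160L),
                                  n_singletons = 5L, seed = 1L) {
  set.seed(seed)
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  proteins <- character()
  truth <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%03d", f)
    len <- sample(len_range[1]:len_range[2], 1L)
    rep_seq <- sample(aa20, len, replace = TRUE)
    id <- paste0(fam, "_m01")
    proteins[[id]] <- paste(rep_seq, collapse = "")
    truth[[length(truth) + 1L]] <- data.frame(id = id, family = fam,
                                              stringsAsFactors = FALSE)
    n_sub <- max(1L, ceiling(substitution_rate * len))
    pos <- unique(pmin(len, pmax(1L, round(seq(1, len,
                                               length.out = n_sub + 2L)[
                                             2:(n_sub + 1L)]))))
    for (m in seq_len(members_per_family - 1L)) {
      s <- rep_seq
      for (p in pos) {
        s[p] <- sample(setdiff(aa20, rep_seq[p]), 1L)
      }
      id <- sprintf("%s_m%02d", fam, m + 1L)
      proteins[[id]] <- paste(s, collapse = "")
      truth[[length(truth) + 1L]] <- data.frame(id = id, family = fam,
                                                stringsAsFactors = FALSE)
    }
  }
  for (s in seq_len(n_singletons)) {
    id <- sprintf("S%03d", s)
    len <- sample(len_range[1]:len_range[2], 1L)
    proteins[[id]] <- paste(sample(aa20, len, replace = TRUE),
                            collapse = "")
    truth[[length(truth) + 1L]] <- data.frame(
      id = id, family = paste0("single_", id), stringsAsFactors = FALSE)
  }
  list(proteins = proteins, truth = do.call(rbind, truth))
}

#' Generate an ecology fixture: metadata, presence, abundances, reads
#'
#' Presence of a designated protein is planted with a chosen odds ratio
#' between cases of one disease and healthy controls; all other metadata
#' variables are drawn independently of presence (null). The abundance
#' matrix is Dirichlet-like (normalised gamma) per individual, scaled so
#' each column sums to \code{abundance_total} < 1 (the unassigned
#' remainder of a real profile).
#'
#' @param n_case,n_control Group sizes (default 20/20).
#' @param prevalence_control Baseline presence probability in controls.
#' @param odds_ratio Planted case/control odds ratio (1 = null).
#' @param disease Disease flag column the effect is planted in.
#' @param n_genomes,n_individuals Abundance matrix dimensions.
#' @param abundance_total Per-individual abundance sum (< 1).
#' @param concentration Gamma shape controlling abundance evenness.
#' @param seed RNG seed.
#' @return List: metadata (data.frame), presence (named logical),
#'   abundance (matrix genomes x individuals), positive_genomes,
#'   truth (planted parameters).
#' @export
make_ecology_fixture <- function(n_case = 20L, n_control = 20L,
                                 prevalence_control = 0.3,
                                 odds_ratio = 1, disease = "uc",
                                 n_genomes = 30L, n_individuals = 40L,
                                 abundance_total = 0.95,
                                 concentration = 0.8, seed = 1L) {
  set.seed(seed)
  n <- n_case + n_control
  sample_id <- sprintf("S%04d", seq_len(n))
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))
  p0 <- prevalence_control
  odds1 <- odds_ratio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  presence <- stats::setNames(
    stats::runif(n) < ifelse(is_case, p1, p0), sample_id)

  metadata <- data.frame(
    sample_id = sample_id,
    age = sample(18:85, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    bmi = round(stats::rnorm(n, 26, 4), 1),
    country = sample(c("NLD", "ISR", "USA", "CHN", "JPN"), n,
                     replace = TRUE),
    westernised = sample(c("yes", "no"), n, replace = TRUE,
                         prob = c(0.8, 0.2)),
    antibiotics = sample(c("yes", "no"), n, replace = TRUE,
                         prob = c(0.2, 0.8)),
    smoker = sample(c("yes", "no"), n, replace = TRUE,
                    prob = c(0.25, 0.75)),
    healthy = !is_case,
    stringsAsFactors = FALSE)
  metadata[[disease]] <- is_case

  genomes <- sprintf("g%03d", seq_len(n_genomes))
  individuals <- sprintf("I%04d", seq_len(n_individuals))
  raw <- matrix(stats::rgamma(n_genomes * n_individuals,
                              shape = concentration),
                nrow = n_genomes, dimnames = list(genomes, individuals))
  abundance <- sweep(raw, 2, colSums(raw), "/") * abundance_total
  positive_genomes <- sample(genomes, max(1L, round(n_genomes * 0.2)))

  list(metadata = metadata, presence = presence, abundance = abundance,
       positive_genomes = positive_genomes,
       truth = list(p_case = p1, p_control = p0, odds_ratio = odds_ratio,
                    disease = disease))
}
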