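# Handcrafted contig: gene1 at 10..99 (+), gene2 at 120..200 (+), both
# stop-free inside; random elsewhere. Built once per file.
set.seed(101)
.sense <- setdiff(codon_order(), genetic_code(11)$stop_codons)
.rnd <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
.gene <- function(n_codons) paste(c("ATG",
  sample(.sense, n_codons - 2, TRUE), "TAA"), collapse = "")
ctg <- paste0(.rnd(9), .gene(30), .rnd(20), .gene(27), .rnd(40))
stopifnot(nchar(ctg) == 240)

pred <- function(start, end, strand, tool, contig = "ctg1") {
  data.frame(contig_id = contig, start = start, end = end,
             strand = strand, tool = tool, stringsAsFactors = FALSE)
}

test_that("same-stop conflicts keep the longest start, distinct stops all survive", {
  m <- merge_predictions(ctg, rbind(pred(10, 99, "+", "toolA"),
                                    pred(31, 99, "+", "toolB")), 11)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 10L)
  expect_equal(m$tools, "toolA")  # losing shorter start gets no credit

  m2 <- merge_predictions(ctg, rbind(pred(10, 99, "+", "toolA"),
                                     pred(120, 200, "+", "toolB")), 11)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$start, c(10L, 120L))

  # identical coordinates collapse with hyphen-joined, sorted tool credit
  m3 <- merge_predictions(ctg, rbind(pred(10, 99, "+", "toolB"),
                                     pred(10, 99, "+", "toolA")), 11)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$tools, "toolA-toolB")
  expect_equal(m3$protein, translate_cds(substring(ctg, 10, 99), 11))
})

test_that("edge-partial, short, empty and out-of-bounds predictions drop", {
  expect_equal(nrow(merge_predictions(ctg, pred(2, 61, "+", "toolA"), 11)),
               0L)
  expect_equal(nrow(merge_predictions(ctg, pred(50, 67, "+", "toolA"), 11)),
               0L)
  expect_equal(nrow(merge_predictions(ctg, NULL, 11)), 0L)
  expect_warning(
    m <- merge_predictions(ctg, pred(230, 280, "+", "toolA"), 11),
    "outside contig bounds")
  expect_equal(nrow(m), 0L)
  # minus-strand edge rule mirrors the plus-strand one: start codon in
  # the LAST three bases
  m2 <- merge_predictions(ctg, pred(149, 238, "-", "toolA"), 11)
  expect_equal(nrow(m2), 0L)
  expect_equal(attr(m2, "filter_counts")[["edge"]], 1L)
})

test_that("survivors translating with internal stops are discarded", {
  # span crosses gene1's own stop codon in frame -> guaranteed internal stop
  expect_warning(
    m <- merge_predictions(ctg, pred(10, 105, "+", "toolA"), 11),
    "internal stop")
  expect_equal(nrow(m), 0L)
  m2 <- merge_predictions(ctg, pred(10, 105, "+", "toolA"), 11,
                          keep_internal_stop = TRUE)
  expect_equal(nrow(m2), 1L)
  expect_true(grepl("*", m2$protein, fixed = TRUE))
})

test_that("minus-strand groups key on the forward start coordinate", {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctg)))
  L <- nchar(ctg)
  # gene1 mirrored: minus-strand gene on rc at (L-99+1 .. L-10+1)
  s <- L - 99L + 1L; e <- L - 10L + 1L
  m <- merge_predictions(rc, rbind(pred(s, e, "-", "toolA"),
                                   pred(s, e - 21L, "-", "toolB")), 11)
  expect_equal(nrow(m), 1L)  # same stop (forward start), longest kept
  expect_equal(m$end, e)
  expect_equal(m$protein, translate_cds(substring(ctg, 10, 99), 11))
})

test_that("merge invariants hold on a simulated 3-tool fixture", {
  cfg <- sim_config(seed = 21, n_contigs = 8, genes_per_contig = 4,
                    n_edge_genes = 2, n_short_genes = 2)
  sim <- make_contigs(cfg)
  em <- c(miss = 0.2, start_shift = 0.2, spurious = 0.1)
  tools <- simulate_tool_outputs(sim$contigs, sim$truth,
                                 list(tA = em, tB = em, tC = em), seed = 22)
  all_preds <- do.call(rbind, tools)
  for (cid in names(sim$contigs)) {
    p <- all_preds[all_preds$contig_id == cid, ]
    m <- suppressWarnings(merge_predictions(sim$contigs[[cid]], p, 11))
    # no two output genes share (strand, stop terminus)
    stop_pos <- ifelse(m$strand == "+", m$end, m$start)
    expect_false(anyDuplicated(paste(m$strand, stop_pos)) > 0)
    # merge never invents coordinates
    expect_true(all(paste(m$start, m$end, m$strand) %in%
                      paste(p$start, p$end, p$strand)))
    # idempotence on coordinates
    m2 <- suppressWarnings(merge_predictions(
      sim$contigs[[cid]],
      data.frame(contig_id = m$contig_id, start = m$start, end = m$end,
                 strand = m$strand, tool = rep("x", nrow(m)),
                 stringsAsFactors = FALSE),
      11))
    expect_equal(m2[, c("start", "end", "strand", "cds", "protein")],
                 m[, c("start", "end", "strand", "cds", "protein")])
    # count conservation across the logged filters
    fc <- attr(m, "filter_counts")
    expect_equal(nrow(m),
                 fc[["groups"]] - fc[["edge"]] - fc[["short"]] -
                   fc[["frame"]] - fc[["internal_stop"]] -
                   fc[["bad_start"]])
    # monotonicity: adding a tool never removes a surviving stop-group
    pA <- tools$tA[tools$tA$contig_id == cid, ]
    mA <- suppressWarnings(merge_predictions(sim$contigs[[cid]], pA, 11))
    if (nrow(mA) > 0L) {
      keysA <- paste(mA$strand, ifelse(mA$strand == "+", mA$end, mA$start))
      expect_true(all(keysA %in% paste(m$strand, stop_pos)))
    }
  }
})

test_that("run_pipeline with the internal caller equals find_orfs + filters", {
  cfg <- sim_config(seed = 31, n_contigs = 1, genes_per_contig = 3)
  sim <- make_contigs(cfg)
  res <- run_pipeline(sim$contigs, dataset = "toy", min_proteins = 0L)
  orfs <- find_orfs(sim$contigs[[1]], 11, contig_id = names(sim$contigs))
  manual <- merge_predictions(sim$contigs[[1]], orfs, 11)
  expect_equal(unname(res$proteins), manual$protein)
  expect_false(res$summary$rejected)
  # names parse and carry the Unknown domain / table 11 default route
  p1 <- parse_name(names(res$proteins)[1])
  expect_equal(p1$domain, "Unknown")
  expect_equal(p1$table_id, 11L)
  expect_equal(p1$index, 1L)
})

test_that("run_pipeline flags datasets under the protein threshold", {
  cfg <- sim_config(seed = 32, n_contigs = 1, genes_per_contig = 2)
  sim <- make_contigs(cfg)
  res <- run_pipeline(sim$contigs, dataset = "tiny")  # default 1000
  expect_true(res$summary$rejected)
  expect_gt(res$summary$n_proteins, 0L)
})

test_that("run_pipeline recovers planted truth from zero-error tools", {
  cfg <- sim_config(seed = 33, n_contigs = 6, genes_per_contig = 4,
                    n_edge_genes = 2, n_short_genes = 2)
  sim <- make_contigs(cfg)
  zero <- c(miss = 0, start_shift = 0, spurious = 0)
  tools <- simulate_tool_outputs(sim$contigs, sim$truth,
                                 list(tA = zero, tB = zero), seed = 34)
  preds <- do.call(rbind, tools)[, c("contig_id", "start", "end",
                                     "strand", "tool")]
  res <- run_pipeline(sim$contigs, predictions = preds, dataset = "ds",
                      min_proteins = 0L)
  keep <- sim$truth[!sim$truth$edge & !sim$truth$short, ]
  expect_equal(nrow(res$genes), nrow(keep))
  got <- res$genes[order(res$genes$contig_id, res$genes$start), ]
  want <- keep[order(keep$contig_id, keep$start), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$strand, want$strand)
  expect_true(all(got$tools == "tA-tB"))
})
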