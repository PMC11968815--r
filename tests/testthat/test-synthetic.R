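test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_contigs = 4, genes_per_contig = 3,
                    n_edge_genes = 1, n_short_genes = 1)
  expect_identical(make_contigs(cfg), make_contigs(cfg))
  sim <- make_contigs(cfg)
  em <- list(t1 = c(miss = 0.3, start_shift = 0.3, spurious = 0.2))
  expect_identical(simulate_tool_outputs(sim$contigs, sim$truth, em, seed = 9),
                   simulate_tool_outputs(sim$contigs, sim$truth, em, seed = 9))
  expect_identical(make_ecology_fixture(seed = 3),
                   make_ecology_fixture(seed = 3))
  expect_identical(make_protein_families(seed = 5),
                   make_protein_families(seed = 5))
})

test_that("planted genes honour their declared structure", {
  cfg <- sim_config(seed = 17, n_contigs = 5, genes_per_contig = 3,
                    n_edge_genes = 2, n_short_genes = 2)
  sim <- make_contigs(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$edge), 2L)
  expect_equal(sum(tr$short), 2L)
  for (i in seq_len(nrow(tr))) {
    g <- tr[i, ]
    cds <- extract_cds(sim$contigs[[g$contig_id]], g$start, g$end, g$strand)
    expect_equal(nchar(cds), g$end - g$start + 1L)
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substring(cds, 1, 3), "ATG")
    aa <- translate_cds(cds, g$table_id, trim_stop = TRUE)
    expect_false(grepl("*", aa, fixed = TRUE))
    if (g$short) expect_lt(nchar(cds), 21L)
    L <- nchar(sim$contigs[[g$contig_id]])
    if (g$edge) {
      expect_true((g$strand == "+" && g$start <= 3L) ||
                    (g$strand == "-" && g$end >= L - 2L))
    }
  }
})

test_that("table-4 fixtures contain in-frame TGA when requested", {
  cfg <- sim_config(seed = 19, n_contigs = 2, genes_per_contig = 2,
                    table_id = 4, n_tga_genes = 3)
  sim <- make_contigs(cfg)
  tga <- sim$truth[sim$truth$tga, ]
  expect_gte(nrow(tga), 1L)
  for (i in seq_len(nrow(tga))) {
    g <- tga[i, ]
    cds <- extract_cds(sim$contigs[[g$contig_id]], g$start, g$end, g$strand)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_true("TGA" %in% codons[-length(codons)])
  }
})

test_that("tool simulation error modes behave at their extremes", {
  cfg <- sim_config(seed = 23, n_contigs = 4, genes_per_contig = 4)
  sim <- make_contigs(cfg)
  zero <- simulate_tool_outputs(sim$contigs, sim$truth,
                                list(t = c(miss = 0, start_shift = 0,
                                           spurious = 0)), seed = 1)
  expect_equal(zero$t[, c("contig_id", "start", "end", "strand")],
               sim$truth[, c("contig_id", "start", "end", "strand")])
  all_miss <- simulate_tool_outputs(sim$contigs, sim$truth,
                                    list(t = c(miss = 1, start_shift = 0,
                                               spurious = 0)), seed = 1)
  expect_equal(nrow(all_miss$t), 0L)
  # shifted starts stay in frame, preserve the stop, keep length >= 21
  sh <- simulate_tool_outputs(sim$contigs, sim$truth,
                              list(t = c(miss = 0, start_shift = 1,
                                         spurious = 0)), seed = 2)$t
  tr <- sim$truth
  for (i in seq_len(nrow(sh))) {
    g <- tr[tr$gene_id == sh$gene_id[i], ]
    if (sh$strand[i] == "+") {
      expect_equal(sh$end[i], g$end)
      expect_equal((sh$start[i] - g$start) %% 3, 0)
    } else {
      expect_equal(sh$start[i], g$start)
      expect_equal((g$end - sh$end[i]) %% 3, 0)
    }
    expect_gte(sh$end[i] - sh$start[i] + 1L, 21L)
  }
})

test_that("error counts match binomial expectation at n = 1000", {
  cfg <- sim_config(seed = 29, n_contigs = 200, genes_per_contig = 5)
  sim <- make_contigs(cfg)
  expect_equal(nrow(sim$truth), 1000L)
  em <- c(miss = 0.2, start_shift = 0.2, spurious = 0.1)
  out <- simulate_tool_outputs(sim$contigs, sim$truth, list(t = em),
                               seed = 30)
  cnt <- attr(out, "error_counts")$t
  sigma <- sqrt(1000 * 0.2 * 0.8)
  expect_lt(abs(cnt[["missed"]] - 200), 3 * sigma)
  # shifts apply to kept genes; compare against the realised kept count
  kept <- 1000 - cnt[["missed"]]
  expect_lt(abs(cnt[["shifted"]] - 0.2 * kept),
            3 * sqrt(kept * 0.2 * 0.8) + 3)  # +3: shift-infeasible genes
  expect_lt(abs(cnt[["spurious"]] - 100), 3 * sqrt(1000 * 0.1 * 0.9))
})

test_that("ecology fixture plants the requested effect", {
  # abundance columns always sum to <= 1
  fx <- make_ecology_fixture(seed = 37)
  expect_true(all(colSums(fx$abundance) <= 1 + 1e-9))
  expect_true(all(fx$abundance >= 0))
  expect_equal(sort(unique(fx$metadata$healthy)), c(FALSE, TRUE))
  # planted OR 81 at n=20/20: median Fisher p across seeds is tiny
  ps <- vapply(1:15, function(s) {
    fx <- make_ecology_fixture(odds_ratio = 81, seed = s)
    case <- !fx$metadata$healthy
    fisher_exact(c(sum(fx$presence & case), sum(!fx$presence & case),
                   sum(fx$presence & !case), sum(!fx$presence & !case)))
  }, 0)
  expect_lt(stats::median(ps), 0.001)
})
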