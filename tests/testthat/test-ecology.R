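test_that("fisher_exact matches hand values and enumeration", {
  expect_equal(fisher_exact(matrix(c(0, 10, 0, 10), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact(c(5, 0, 0, 5)), 2 / choose(10, 5))
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "non-negative")
  set.seed(81)
  for (i in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    expect_equal(fisher_exact(cells),
                 oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact symmetries: row/col swap and transpose", {
  set.seed(82)
  for (i in 1:20) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    p <- fisher_exact(m)
    expect_equal(fisher_exact(m[2:1, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(t(m)), p, tolerance = 1e-12)
  }
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(0.5), 0.5)  # m = 1 identity
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(83)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_true(all(q >= p))              # never decreases a p
    expect_true(all(diff(sort(q)) >= -1e-15))
    expect_true(all(q <= 1))
  }
  # NA handling: propagated, excluded from m
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
})

test_that("search_hits finds exact matches and honours thresholds", {
  corpus <- c("1|sampleA|Bacteria|11|t" = random_aa(100, seed = 91),
              "2|sampleB|Bacteria|11|t" = random_aa(100, seed = 92))
  q <- c(query1 = corpus[[1]])
  h <- search_hits(q, corpus)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1)
  expect_equal(h$query_cov, 1)
  expect_equal(h$sample, "sampleA")

  # 15 evenly spaced substitutions in 100 aa: ~85% identity everywhere
  s <- strsplit(corpus[[1]], "")[[1]]
  pos <- round(seq(4, 97, length.out = 15))
  for (p in pos) s[p] <- if (s[p] == "A") "W" else "A"
  q85 <- c(query85 = paste(s, collapse = ""))
  expect_equal(nrow(search_hits(q85, corpus)), 0L)             # 0.9 default
  h2 <- search_hits(q85, corpus, id_min = 0.8, qcov_min = 0.8,
                    scov_min = 0.8)
  expect_equal(h2$subject_id, "1|sampleA|Bacteria|11|t")       # 0.8 passes
  expect_error(search_hits(q, corpus = character()), "empty corpus")
})

test_that("precomputed BLAST tabular hits filter on all three thresholds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\ts1\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-50\t200",   # valid
    "q1\ts2\t85.0\t100\t15\t0\t1\t100\t1\t100\t1e-40\t150",  # identity low
    "q1\ts3\t95.0\t50\t2\t0\t1\t50\t1\t50\t1e-20\t90"), f)   # coverage low
  hits <- read_blast_tab(f)
  got <- search_hits(queries = NULL, hits = hits,
                     query_lengths = c(q1 = 100),
                     subject_lengths = c(s1 = 100, s2 = 100, s3 = 100))
  expect_equal(got$subject_id, "s1")
  expect_equal(got$identity, 0.95)
})

test_that("prevalence analysis composes counts and Fisher correctly", {
  md <- data.frame(
    sample_id = sprintf("S%02d", 1:20),
    uc = rep(c(TRUE, FALSE), each = 10),
    healthy = rep(c(FALSE, TRUE), each = 10),
    stringsAsFactors = FALSE)
  pres <- stats::setNames(c(rep(TRUE, 9), FALSE,
                            TRUE, rep(FALSE, 9)), md$sample_id)
  out <- prevalence_analysis(pres, md)
  uc <- out[out$variable == "uc" & out$group == "uc", ]
  expect_equal(uc$n_present, 9L)
  expect_equal(uc$n_total, 10L)
  expect_equal(uc$prevalence, 0.9)
  expect_equal(uc$p_value, fisher_exact(matrix(c(9, 1, 1, 9), 2,
                                               byrow = TRUE)))
  # all-present protein: prevalence 1 everywhere, p = 1
  all_pres <- stats::setNames(rep(TRUE, 20), md$sample_id)
  out2 <- prevalence_analysis(all_pres, md)
  expect_true(all(out2$prevalence == 1))
  expect_true(all(out2$p_value[!is.na(out2$p_value)] == 1))
})

test_that("prevalence analysis: grouping, totals, missing data, controls", {
  fx <- make_ecology_fixture(seed = 95)
  md <- fx$metadata
  md$bmi[1:4] <- NA
  out <- prevalence_analysis(fx$presence, md)
  # totals conserve per variable: sum of group n_total = complete samples
  bmi <- out[out$variable == "bmi", ]
  expect_equal(sum(bmi$n_total), nrow(md) - 4L)
  sex <- out[out$variable == "sex", ]
  expect_equal(sum(sex$n_total), nrow(md))
  # q >= p within every family
  ok <- !is.na(out$p_value)
  expect_true(all(out$q_value[ok] >= out$p_value[ok] - 1e-12))
  # zero healthy controls: disease comparison skipped with warning
  md2 <- md
  md2$healthy <- FALSE
  expect_warning(out2 <- prevalence_analysis(fx$presence, md2),
                 "zero healthy controls")
  expect_false("uc" %in% out2$variable)
})

test_that("multi-protein mode is the intersection across queries", {
  s <- sprintf("S%d", 1:4)
  a <- stats::setNames(c(TRUE, TRUE, FALSE, TRUE), s)
  b <- stats::setNames(c(TRUE, FALSE, TRUE, TRUE), s)
  c3 <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE), s)
  expect_equal(multi_protein_presence(list(a)), a)          # identity
  expect_equal(unname(multi_protein_presence(list(a, b))),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(multi_protein_presence(list(a, b, c3))),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_error(multi_protein_presence(list()), "at least one")
  expect_error(multi_protein_presence(list(a, b[c(2, 1, 3, 4)])),
               "share samples")
})

test_that("function-positive fraction sums abundances of positive genomes", {
  ab <- matrix(c(0.2, 0.3, 0.1,
                 0.4, 0.1, 0.2), nrow = 3,
               dimnames = list(c("g1", "g2", "g3"), c("i1", "i2")))
  expect_equal(unname(function_positive_fraction(c("g1", "g3"), ab)),
               c(0.3, 0.6))
  expect_equal(unname(function_positive_fraction(character(), ab)),
               c(0, 0))
  expect_equal(function_positive_fraction(rownames(ab), ab), colSums(ab))
  expect_warning(r <- function_positive_fraction(c("g1", "gX"), ab),
                 "absent")
  expect_equal(unname(r), c(0.2, 0.4))
  # monotone in the positive set
  fx <- make_ecology_fixture(seed = 96)
  small <- fx$positive_genomes[1:2]
  expect_true(all(function_positive_fraction(fx$positive_genomes,
                                             fx$abundance) >=
                    function_positive_fraction(small, fx$abundance)))
  bad <- ab; bad[, 1] <- c(0.6, 0.6, 0.2)
  expect_error(function_positive_fraction("g1", bad), "exceed 1")
})

test_that("taxonomic range counts ranks and flags wide sharing", {
  tax <- data.frame(
    genome_id = sprintf("g%02d", 1:12),
    species = c(sprintf("sp%02d", 1:10), "sp01", "sp02"),
    genus = c(sprintf("gen%d", c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)), "gen1",
              "gen1"),
    family = rep(c("famA", "famB"), 6),
    phylum = c(rep("Bacillota", 8), rep("Bacteroidota", 4)),
    stringsAsFactors = FALSE)
  one <- taxonomic_range("g01", tax)
  expect_equal(one[c("n_species", "n_genus", "n_family", "n_phylum")],
               list(n_species = 1L, n_genus = 1L, n_family = 1L,
                    n_phylum = 1L))
  expect_false(one$shared)
  all12 <- taxonomic_range(tax$genome_id, tax)
  expect_equal(all12$n_species, 10L)
  expect_equal(all12$n_genus, 5L)
  expect_equal(all12$n_family, 2L)
  expect_equal(all12$n_phylum, 2L)
  expect_true(all12$shared)  # >= 10 species and >= 2 phyla
  expect_warning(taxonomic_range(c("g01", "zz"), tax), "without taxonomy")
})
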