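---
title: "proteogut: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteogut: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteogut)
```

# The problem

Assembled metagenomes mix DNA from bacteria, archaea, eukaryotes and
viruses, yet gene calling is usually run with one prokaryotic tool and
one genetic code. Two kinds of error follow. First, lineages that recode
codons — most prominently *Mycoplasma* and relatives, where TGA encodes
tryptophan (NCBI translation table 4) rather than stop (table 11) — have
their genes truncated or discarded. Second, every individual predictor
has blind spots, so a single tool both misses real genes and reports
spurious ones. `proteogut` implements a lineage-aware remedy: route each
contig by its taxonomic assignment to a (domain, genetic code) group,
merge the predictions of several tools into a consensus gene set, build
a non-redundant protein catalogue, and analyse the ecology of the
resulting proteins across samples and hosts.

# The pipeline

## Taxonomy routing

`route_contigs()` maps each contig's taxid to a `(domain, table_id)`
pair through a flat rule table (`inst/extdata/lineage_rules.tsv`),
optionally walking a taxid→parent table up the lineage to the nearest
rule. The shipped defaults cover the four domain roots, the
TGA-recoding Mycoplasmatota clade (code 4) and the human host (whose
contigs are excluded before prediction). The classifier itself is out of
scope: Kraken-2-style output or a plain contig/taxid TSV is consumed,
and classifier confidence values are accepted but not re-thresholded —
the upstream classifier already applied its own cutoff and filtering
twice would double-count. Unclassified contigs keep a distinct
**Unknown** domain label in protein names but are predicted with the
bacterial route and code 11, which is the least-wrong default for gut
metagenomes where bacteria dominate.

Routing is a pure function of `(taxid, rules)`: permuting the input
never changes any contig's route, and the output groups plus the host
exclusions partition the input contig set. Both properties are tested.

## Gene calling and translation

Genetic code tables 1, 4 and 11 ship as a plain-text file (64-codon
amino-acid string plus start-codon mask in canonical TCAG order) and are
verified in the test suite against an independent reference. The
built-in caller `find_orfs()` is a deterministic six-frame scanner: for
each in-frame stop it reports the longest upstream start after the
previous stop. It deliberately has *no* statistical gene model — no RBS
scoring, no GC bias, no intron/exon structure — because its role is to
be a transparent stand-in predictor and fixture source, not a Prodigal
replacement. A `atg_only` switch restricts initiators to ATG for
conservative calling; by default the table's full NCBI start set is
used. Codons containing ambiguity characters translate to `X` and never
match start or stop sets.

Coordinates are 1-based inclusive on the forward strand (GFF3
convention); minus-strand genes keep `start <= end`, with the start
codon occupying forward positions `end-2..end`.

## Consensus merging

`merge_predictions()` applies the consensus rules in a fixed order:

1. group predictions by **(strand, 3' stop terminus)** — "same stop"
   without strand awareness would conflate opposite-strand genes, so
   strand-aware grouping is the only biologically coherent reading;
2. within a group keep the longest span; tools are credited (and joined
   by hyphens in the protein name) only when their call had the winner's
   exact coordinates — a tool that predicted a shorter start did not
   predict *the same protein*;
3. groups with distinct stops are all retained;
4. drop genes whose start codon lies in the first or last three contig
   bases (assembly-edge partials); the minus-strand rule mirrors the
   plus-strand wording. Genes whose *stop* abuts the edge are kept: the
   rule is stated for start codons and is applied as stated;
5. drop genes shorter than 21 nt — six amino acids plus the stop codon,
   so emitted proteins have ≥ 6 aa;
6. translate with the routed table and drop survivors whose translation
   still contains an internal stop. Truncating instead would fabricate
   coordinates no tool reported. Start codons of external predictions
   are *not* verified by default, since several tools emit non-standard
   initiators.

Each filter's count is logged in the `filter_counts` attribute, and the
tested bookkeeping identity `|output| = |stop groups| − edge − short −
frame − internal-stop` holds exactly. Useful consequences, all tested:
no two output genes share a (strand, stop); the merge never invents
coordinates; merging its own output is a fixed point; and adding a
tool's predictions never removes a surviving stop group.

`run_pipeline()` chains routing, per-contig merging and naming. Protein
names follow `index|dataset|domain|table|tool1[-tool2..]`; datasets
yielding fewer than `min_proteins` (default 1000) proteins are flagged
`rejected` rather than silently dropped, mirroring the exclusion of
under-sequenced metagenomes while leaving the decision to the caller.

## Catalogue clustering

`cluster_proteins()` performs greedy longest-first clustering (linclust
style): the longest unassigned sequence (ties broken by id for
determinism) becomes a representative; remaining sequences join it when
they pass **identity ≥ 0.9** and **coverage ≥ 0.8 of the shorter
sequence** — the shortest-sequence coverage mode. One alignment
definition is fixed package-wide: Smith–Waterman local alignment, match
+2, mismatch −1, gap opening 4, gap extension 1; identity is matches
over alignment columns (gaps included), coverage is the aligned span on
a sequence over its length, and unknown residues (`X`) never score as
matches. External clusterers defer these definitions to their engines;
fixing one makes every threshold reproducible.

The candidate prefilter requires a shared k-mer, with k derived from
the thresholds rather than copied from linclust's `--k-mer-per-seq`
heuristic: any alignment of `m` columns with identity ≥ t has at most
`floor((1−t)m)` non-match columns, which split the matches into runs of
which the longest has a provable minimum length; k is capped at 4 and
at that bound, and the prefilter is disabled entirely if no safe k ≥ 2
exists. The prefilter therefore cannot lose a true member, which is why
greedy clustering is *identical* — not approximately equal — to
brute-force all-pairs verification in the acceptance tests. Exact
correspondence with MMseqs2's order-heuristic cluster counts is
unattainable and not attempted.

Clusters whose representative is ≤ 50 aa are flagged small protein
clusters (SPCs); size-1 clusters are singletons. `overlap_catalogues()`
measures directed coverage between two catalogues by pooling and
re-clustering with the same thresholds, counting a protein as covered
when its co-cluster contains a protein of the other catalogue.
`rarefaction_curve()` averages cluster accumulation over random sample
orderings; an `exact` mode enumerates all `n!` orderings (n ≤ 8) so
small cases can be checked against the closed form
`E[distinct at d] = Σ_c (1 − C(n−m_c, d)/C(n, d))`.

## Protein ecology

`search_hits()` matches query proteins to a corpus, either by internal
alignment or by filtering precomputed BLAST/DIAMOND tabular hits, with
defaults identity ≥ 0.9 and both query and subject coverage ≥ 0.9.
Presence in a sample is binary — one valid hit suffices; no
copy-number weighting. Multi-protein queries intersect: a sample counts
only when every chain of the queried complex is present.

`fisher_exact()` implements the two-sided test by the probability-mass
rule (sum over tables with probability ≤ observed, with the
conventional `1 + 1e-7` tie guard), computed in log space; it is checked
against exhaustive plain-arithmetic enumeration for every table with
n ≤ 30. The alternative "doubling" two-sided rule gives different
values, which is why the definition is pinned. `bh_adjust()` is the
step-up `q_(i) = min_{j≥i} p_(j)·m/j`, clipped to 1, NA-tolerant.

`prevalence_analysis()` computes per-group counts, prevalence and tests
for the configured variables: age and BMI (binned; default edges
0/18/40/60+ years and the WHO BMI categories 18.5/25/30 — the source
figures show bins without stating edges, so the edges are configurable
and documented), sex, country, westernisation, antibiotics and smoking
(each group versus the rest), and disease flags (CD, UC, CRC,
*C. difficile*, T2D, rheumatoid arthritis, fatty liver) versus healthy
controls. Benjamini–Hochberg correction is applied **within each
variable family**, with all disease comparisons forming one family:
the correction scope is not stated upstream, per-variable is the least
surprising choice, and the family column is reported so users can
re-correct at any other scope. Samples missing a variable are excluded
from that variable only.

The **function-positive fraction** of an individual is the summed
relative abundance of the genomes carrying the queried function; it is
monotone in the positive set and bounded by the column sum of the
abundance matrix. `taxonomic_range()` counts distinct
species/genus/family/phylum among carrier genomes and flags clusters
present in ≥ 10 species across ≥ 2 phyla as widely shared.

## Expression

`aligned_fraction()` is `100·aligned/total`. `rpkm()` is
`reads / ((length/1000)·(total/10^6))` — the standard RPKM reading. The
formula as typeset in the source methods multiplies rather than divides
by the library-size term; since RPKM is a defined quantity, the
standard reading is implemented and this note records the discrepancy.
A cluster is "expressed" in a sample at ≥ 1 mapped read (no minimum is
stated upstream; the threshold is a documented argument), member reads
are summed per cluster, and RPKM uses the representative's length since
member lengths vary. Clusters expressed in > 90% of samples are flagged
highly prevalent.

## Evaluation

`evaluate_predictions()` scores a prediction set against a reference by
the same (strand, stop) key the merge uses: *perfect* (start and stop
match), *partial* (stop only), *missed*, *spurious*. This is a
deliberate simplification of the richer ORForise-style metric suite —
sufficient to rank tools and combinations, and stated as our own
definition rather than inferred from theirs.
`evaluate_combinations()` merges every k-subset of tools and ranks by
perfect, then partial, then fewest spurious.

# The synthetic world

The generator exists so that every analysis is testable offline, with
ground truth shipped alongside every fixture.

* **Contigs/genes** (`make_contigs`): genes are built codon-wise —
  ATG, sense codons of the chosen table, a stop — so they are valid by
  construction; an in-frame stop "guard" is placed in the adjacent
  spacer so each planted gene is a *maximal* ORF and the six-frame
  scanner recovers its coordinates exactly. Defaults: 30–100 codons per
  gene (typical short bacterial genes), 20–120 nt spacers, strands
  balanced. Edge-partial and sub-21-nt genes are planted on request and
  flagged in the truth table.
* **Tool outputs** (`simulate_tool_outputs`): per-tool miss,
  start-shift and spurious probabilities. Start shifts are downstream,
  in frame, stop-preserving and keep ≥ 21 nt — the common real failure
  mode of start misprediction, and the one the merge's longest-start
  rule is designed to fix. Edge-planted genes are never shifted: an
  inward-shifted start would no longer sit at the contig edge,
  silently turning an edge-partial into an ordinary gene. Spurious
  calls are sampled from *real* ORFs of the same contigs (excluding
  truth stops), because random-coordinate noise would be removed
  trivially and test nothing.
* **Protein families** (`make_protein_families`): members substitute
  the representative at *evenly spaced* positions, so a nominal 5%
  family stays above 90% identity in every alignment window and a 15%
  family falls below it everywhere — making
  recovered/excluded assertions deterministic instead of probabilistic.
* **Ecology fixtures** (`make_ecology_fixture`): presence is planted
  with a chosen case/control odds ratio (defaults 20/20 samples at 30%
  control prevalence); all other metadata are drawn independently of
  presence, so they are true nulls. Abundances are normalised gammas
  scaled to sum to 0.95 per individual, standing in for a profile with
  an unassigned remainder.

What the generator does **not** emulate: real community composition,
sequencing error, assembly chimerism, correlated metadata (age–disease
confounding and the like), or homology structure between families. A
green test therefore establishes that the algorithms implement their
stated rules and statistics — not that the defaults reproduce any
published corpus-scale number, which the build explicitly does not
attempt.

# Numerical choices, in one place

* Alignment scoring +2/−1, gap open 4, extend 1; identity =
  matches/columns; coverage = span/length of the covered sequence.
* Clustering ties (equal length) break lexicographically by id; greedy
  order is descending length.
* Fisher two-sided: probability-mass rule with `1+1e-7` relative tie
  tolerance, log-space accumulation, result clamped to 1 (the raw sum
  can exceed 1 by ~1e-16); degenerate margins return 1.
* BH within variable family; diseases form one family.
* The 21-nt minimum includes the stop codon; `find_orfs` requires
  `min_len_nt ≥ 6` and rounds up to whole codons.
* Translation-table routing default: Unknown → (bacterial toolset,
  table 11); Viruses → table 1 (the NCBI root assignment).
* RNG: generators call `set.seed` with the seed in their config; a
  fixed config yields byte-identical output, which the CLI determinism
  test verifies end-to-end.

# Known limitations

* The internal ORF caller over-predicts relative to a model-based tool;
  it is a scanner by design.
* Multi-exon eukaryotic genes are treated per CDS span; there is no
  intron stitching.
* Clustering is quadratic in the worst case and is intended for
  desk-scale inputs (10^3–10^4 proteins), not the 10^8-protein regime
  of the published catalogues.
* The q-value family scope, age/BMI bin edges, and the one-read
  expression threshold are choices; all are arguments with documented
  defaults rather than constants.
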