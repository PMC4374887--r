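---
title: "Comparative NBS-LRR gene family analysis with nbskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative NBS-LRR gene family analysis with nbskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbskit)
library(dplyr)
```

## The problem

Plant disease resistance (R) genes of the NBS-LRR family are among the most
numerous and most dynamic gene families in plant genomes. A typical R protein
carries an N-terminal signalling domain (a Toll/interleukin-receptor domain,
TIR, or a coiled coil, CC), a central nucleotide-binding site (NBS) domain
with a ladder of short conserved motifs (P-loop, Kinase-2, RNBS motifs, GLPL,
MHDV), and a C-terminal leucine-rich repeat (LRR) region built from `LxxLxLxx`
units that mediates pathogen recognition. Comparative studies of this family
ask a recurring set of questions: how many NBS genes does each genome carry
and in which architecture classes (CNL, TNL, NL, CN, TN, N); how do the genes
group into phylogenetic clades and are those clades shared between genomes;
how strongly are the genes physically clustered into tandem arrays; which
genes are orthologous across genomes and what are their dN/dS ratios; how
often does gene conversion homogenize paralogs inside a cluster; and which
genes are retained or deleted in re-sequenced accessions.

`nbskit` packages that entire analysis as composable, tested R functions with
tibble inputs and outputs, together with a synthetic-data generator that
plants a known truth for every stage, so each algorithm can be validated
end-to-end without any external data or search tools.

## Domain annotation and architecture classes

Architecture classification rests on three scanners.

**Motif scan.** Each motif in the library (`default_motif_library()`) is a
consensus string — `x` for any residue, `[VL]`-style sets for alternatives —
compiled into a log-odds position weight matrix: a match carries probability
0.7 (split over the allowed set) against a uniform 1/20 background, so a
matched position scores about 3.8 bits and a mismatched one about −1.7. A hit
requires a fixed fraction of the motif's maximum score (0.9 for motifs under
8 residues, 0.6 otherwise): short anchors such as GLPL or MHD[VL] must be
near-exact, while long N-terminal motifs tolerate substantial divergence. On
a 500-residue protein the threshold sits more than ten standard deviations
above the random-score mean, so unplanted hits are effectively impossible —
which is what makes planted-truth recovery on synthetic proteins exact. The
NBS span is delimited by the first and last NBS-region motif hit.

**Coiled-coil scan.** A sliding-window heptad method: for windows of 21 and
28 residues and each of the seven register frames, the geometric mean of
per-residue, per-heptad-position propensities (`cc_propensity_table()`) is
transformed into a probability by a two-Gaussian contrast (coiled-coil
population mean 1.9, sd 0.35, versus a 30x-weighted globular background,
mean 0.95, sd 0.25). The propensity table is the package's own: aliphatic
residues are favoured at core positions a/d, charged residues at the
interface positions e/g, and glycine/proline are penalized where they break
helices. Residues keep the maximum probability over all windows and frames,
and runs at or above 0.9 become CC segments. An ideal heptad such as
`(LEALEGK)x6` scores > 0.99; poly-proline stays near 0.

**LRR scan.** Eight-residue windows matching `LxxLxLxx` (L ∈ {L, I, V, F})
are merged; runs of at least 16 residues (two stacked core units) count as
repeats.

Classification is then a lookup: TIR present (at least two of the TIR1–4
motifs before the NBS span — single-motif TIR calls are noisy, and published
surveys find individual TIR motifs in only 76–90% of TIR-class genes) gives
the `T` prefix and takes precedence over CC; otherwise a CC segment starting
before the NBS span gives `C`; an LRR repeat after the NBS span appends `L`.
The QC filter for phylogenetic work keeps proteins whose NBS span is at
least 200 aa with both P-loop and MHDV hit.

Because no profile-HMM engine is in scope, Pfam-style TIR/LRR calls can be
imported through the `external_calls` argument of `annotate_domains()` and
are OR-ed into the scan-based flags. The N-/C-terminal boundary for domain
search is the NBS span itself; the scan regions are therefore approximate
where the span is short.

## Clade partitioning

`partition_clades()` implements a depth-first partition of a gene tree under
a patristic-distance threshold (default 0.025, the standard operating point
for NBS-domain trees). From the root downward, a subtree is accepted as a
clade as soon as the median (configurable to any percentile) of its
within-subtree pairwise patristic distances falls at or below the threshold;
accepted subtrees are not descended into, so each reported clade is maximal.
Leaves never captured by any accepted subtree of size ≥ 2 are orphans.
Unrooted trees are midpoint-rooted first (deterministic), or rooted on a
user-supplied outgroup. The partition is a pure function of (tree,
threshold, statistic); tests verify it against an exhaustive
every-subtree oracle on 100 random 20-leaf trees, and verify monotonicity
(raising the threshold never increases the number of parts).

The distance statistic is computed on patristic (tree-path) distances; an
alignment-distance variant would be a drop-in replacement for the matrix but
is not implemented.

Top-level groups (the TIR / CC1 / CC2 trichotomy familiar from NBS
phylogenies) come from `assign_groups()`: either cut the k−1 longest
internal edges, or supply seed genes whose minimal covering subtrees define
the groups.

## Physical clusters, tandem pairs, orthologs, synteny

`cluster_genes()` applies the 200-kb rule: genes on one scaffold link when
the gap between their nearest span edges (configurable to start-to-start) is
at most `max_gap`, and clusters are connected components of size ≥ 2 —
single linkage, so a chain of genes each within 200 kb of the next is one
cluster even when its ends are megabases apart. On a line this reduces to
sorted chaining with a running maximum end, which the tests confirm equals
brute-force union-find over all pairs. `tandem_pairs()` reports same-clade
members of one cluster separated by at most `max_intervening` genes
(default 0, i.e. adjacent homologs, the usual tandem notion).

`rbh_orthologs()` takes two directed hit tables (BLAST outfmt-6 or the
built-in Needleman–Wunsch scorer `builtin_scores()`, whose rank-based pseudo
e-values are flagged `provenance = "builtin"` and which any real hit table
overrides) and returns reciprocal best hits below e-value 1e-20, ties broken
by e-value then subject id. `synteny_blocks()` chains ortholog anchors into
maximal collinear runs — strictly monotone ranks on both scaffolds, fewer
than 25 intervening genes on each — extracted best-first by dynamic
programming so each anchor pair joins at most one block; blocks need at
least 5 pairs. `conserved_clusters()` matches clusters across genomes
greedily by ortholog-link count (ties: smaller combined size, then ids) and
labels a pair `complete` when every member of both clusters has an ortholog
in the partner cluster, `partial` otherwise.

## Molecular evolution

**dN/dS.** `ng86_dnds()` is the Nei–Gojobori counting method: per-codon
synonymous site fractions (changes to stop codons count as nonsynonymous),
expected sites averaged over the two sequences, observed differences in
multi-hit codons averaged over all equally weighted minimal pathways with
stop-traversing pathways excluded when avoidable, and a Jukes–Cantor
correction with an explicit `saturated` flag at p ≥ 3/4. ω is undefined at
dS = 0. The implementation is checked against an independent
pathway-enumeration oracle on random 30-codon pairs. NG86 stands in for
codon-model maximum likelihood; at the low divergences of within-genus
orthologs the two agree closely, which is the regime this package targets.
`backthread()` produces the codon alignments from protein alignments plus
CDS, verifying the translation at every position.

**Gene conversion.** `geneconv_scan()` condenses an alignment of ≥ 3
sequences to its polymorphic, gap-free columns; for each pair the fragment
score is the longest run of agreement (optionally allowing mismatches). The
null distribution permutes condensed columns — exchangeable under no
conversion — and each pair's permutation P is Bonferroni-corrected across
pairs into a global P, mirroring the max-statistic construction of the
classical identical-fragment test. Events at global P ≤ 0.05 are reported
with tract coordinates in both condensed and original alignment frames
(published tract sizes do not say which frame they use, so both are kept).
The default 10,000 permutations match standard practice; validation runs use
fewer (600 for the power check, 300 for the false-positive check) since the
P values needed there are far from the resolution limit.

**Selected sites.** Positively selected site positions are consumed, not
inferred (site-model inference is out of scope); `site_region_summary()`
assigns each position to the N-terminal, NBS or C-terminal region and
recomputes the percentages.

## Presence/absence from re-sequencing coverage

`coverage_fractions()` computes, per gene and sample, covered bases over the
gene span and over exons only — the exon denominator matters because introns
drop out of short-read mappings long before exons do. Depth is binarized.
`call_presence()` applies strict thresholds: Present above 0.85, Deleted
below 0.15 ("more than 85%" and "below 15%" are both strict, and
configurable). `cross_sample_summary()` reports the all-samples /
any-sample / mid-tier (default 50%) / deleted tiers with percentages
recomputed from counts, and `parental_support()` labels each gene by which
parental taxon's samples retain it (Present in at least half, rounded up, of
a parent's samples; unsupported genes with Partial calls are `ambiguous`
rather than `neither`). The narrative rule "high coverage in at least two of
three" is exactly the ceiling-half default for three samples.

## The synthetic generator

`simulate_nbs()` builds the study conditions every test runs under:

* 12 families with 2–6 members plus 2 orphan genes, each family assigned an
  architecture class (default mixture CNL:TNL:NL = 117:82:68 with the
  LRR-less remainder split evenly over CN/TN/N, the census shape of a
  citrus-like genome of ~618 NBS genes).
* Proteins are concatenations of real building blocks — CC heptads or the
  TIR1–4 consensi, an NBS core with P-loop/Kinase-2/RNBS-B/GLPL/MHDV and
  ≥ 200 aa span, 0 or 4 LRR units — with i.i.d. substitutions applied only
  to spacer residues (domains are masked so QC stays deterministic;
  testability over realism). CDS are back-translated per gene, with
  single-base synonymous swaps at `syn_subs_rate`.
* The emitted tree nests tips (branch 0.002) inside family stems (0.3)
  inside group stems (1.5): within-family patristic distances (~0.004) sit
  far below the 0.025 partition threshold and between-family distances far
  above — the separation-of-scales regime in which recovery must be exact.
* Genomic layout: one scaffold per genome, families as tandem arrays with
  50-kb intra-cluster gaps and 500-kb inter-cluster gaps, straddling the
  200-kb rule from both sides. Exon counts are class-typical (5 exons for
  TNL/TN, 2 for CNL/CN/NL, 1 for N), matching the observed median of four
  introns in TNL against one in CNL genes.
* Genome B is a speciation copy with optional per-gene loss, giving ortholog
  pairs, one whole-scaffold collinear block, and complete (or, with loss,
  partial) conserved clusters by construction.
* Coverage: six samples (three pomelo-like, three mandarin-like) with a
  planted deletion matrix (rate 0.08) and noiseless intervals — deleted
  genes get no coverage, retained genes full coverage — so presence calls
  must recover the matrix exactly.

What the generator does **not** emulate: indels and alignment error,
rate heterogeneity along the sequence, pseudogenes, transposon insertions,
assembly fragmentation, and read-level coverage noise. Passing the recovery
suite therefore demonstrates algorithmic correctness under clean separation
of scales, not robustness to messy real data; on real genomes the same
thresholds will sit much closer to the data's own scales.

Separate helpers make focused fixtures: `sim_paralog_alignment()` (i.i.d.
diverged paralogs for conversion power tests), `plant_conversion()` (copies
a donor tract into an acceptor and records the truth),
`sim_synonymous_pair()` (exactly-n synonymous events, single-base swaps
only, so dN is identically zero and the realized event count is the dS
truth).

## Numerical and design choices

* Coordinates are 0-based half-open everywhere inside the package; GFF3
  converts at the boundary, BED passes through. Gene order is span start
  with gene-id tie-breaks; strand never affects clustering or coverage.
* Report percentages are rounded half-even to one decimal, with the raw
  fraction retained in a machine column, since published tables sometimes
  truncate (84.95 printed as 84.9); comparisons should use ±0.1.
* All tie-breaks (best hits, cluster matching, chain extraction, clade
  ordering) are deterministic and documented in the function docs; every
  stochastic routine takes an explicit seed.
* Validation problem sizes are chosen to keep the whole suite desk-scale:
  oracle checks run at 12–20 leaves, 200 genes, ≤ 12 anchors, 30 codons,
  ≤ 200 condensed columns; the conversion power check uses 10 seeds at 600
  permutations and the false-positive check 100 seeds at 300 permutations.

## Known limitations

* The coiled-coil table is a plausibility-ranked propensity matrix, not a
  fitted one; its absolute probabilities are calibrated only in the sense
  that ideal heptads exceed 0.9 and non-coiled sequence stays far below.
* MHD[VL] is a 4-residue anchor; on real (non-masked) proteins short motifs
  at near-exact thresholds will occasionally miss diverged instances —
  the library is fully user-overridable for that reason.
* NG86 underestimates rates at high divergence relative to codon ML; the
  `saturated` flag marks where the correction breaks down entirely.
* The conversion scan's Bonferroni correction is conservative when many
  pairs are scanned; with 15 pairs and the defaults it still detects a
  60-polymorphic-site tract between 5%-diverged paralogs in ≥ 9/10 runs.
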