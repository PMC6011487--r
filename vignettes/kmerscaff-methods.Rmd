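---
title: "Scaffolding draft genomes with linked-read barcodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding draft genomes with linked-read barcodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A draft genome assembly is a set of contigs whose order, orientation and
separation along the chromosomes are unknown. Linked-read sequencing tags
every short read with the barcode of the long DNA molecule (tens of kbp) it
came from; reads of one barcode therefore co-locate on the genome even
though each molecule is sequenced to well under 1x depth. Two contig ends
that face each other across a small gap are crossed by many of the same
molecules and hence share many barcodes, while distant ends share only the
background coincidence caused by barcode reuse (each barcode tags several
unrelated molecules). `kmerscaff` turns this signal into a scaffold graph
and merged scaffold sequences, using exact k-mer matching throughout: no
read alignment, no base-level coordinates.

## The pipeline

**1. Indexing contig ends.** Only a fixed-length window at each contig end
is a mapping target (parameter `e`, default 30 kbp; the interior is
masked). Each window is shredded into canonical k-mers — the
lexicographic minimum of a k-mer and its reverse complement — and loaded
into a hash table mapping k-mer to contig end. K-mers found in more than
one end are discarded as ambiguous; repeats within a single end are kept.
Contigs shorter than `z` (default 3000 bp) are excluded from the graph and
passed through unscaffolded; contigs shorter than `2e` are split at the
midpoint into two non-overlapping half-windows, so that a molecule
spanning the whole contig can still discriminate its ends. Canonical
(strand-folded) k-mers make mapping independent of sequencing strand,
which the barcode-sharing logic requires; the alternative of indexing both
strands doubles memory for no informational gain.

**2. Mapping read pairs.** Each read is shredded the same way and scored
against every end hit by at least one of its k-mers:
`score_j = matched / total` distinct valid read k-mers. The denominator
counts *all* valid read k-mers, including those the index discarded as
multimapped, so scores are comparable across reads. A read maps to the
unique best-scoring end with `score_j >= j` (default 0.55); ties are
discarded as ambiguous. Both mates of a pair must map to the *same contig
end* — the stricter reading of the same-target rule, chosen because a
head/tail disagreement usually means the pair straddles masked interior
and carries no reliable end assignment. Barcodes whose total pair count
lies outside the multiplicity window `m` (default 50–6000) are dropped
(degenerate or over-amplified barcodes), and each (barcode, end)
association needs at least `c` supporting pairs (default 5).

**3. Pairing and orientation.** For every pair of contigs sharing a
barcode, one orientation cell (HH/HT/TH/TT) is incremented, so the four
cells of a pair sum to the number of shared barcodes. When a barcode is
associated with both ends of one contig — a molecule spanning the whole
contig — the end with the larger mapped-pair count carries its vote, and
equal counts are treated as uninformative. We deliberately do *not* let
such a barcode increment several cells at once: double counting makes the
orientation cells strongly dependent whenever molecules are as long as
contigs, and the orientation test below then rejects almost every true
join in exactly the datasets where scaffolding is hardest. The winning
orientation must beat the runner-up in an exact two-sided binomial test
(null: the two best-supported orientations are equally likely) at
`p < r` (default 0.05). A pair supported in only one orientation is
accepted outright and annotated with the degenerate p-value of c1
successes in c1 trials; the test exists to arbitrate between competing
orientations, and vetoing single-orientation pairs would silence exactly
the unambiguous evidence. Accepted pairs whose winning count strictly
exceeds `l` (default 0) become edges.

**4. Gap estimation (`-D`).** Shared-barcode counts decay with distance,
but the decay depends on coverage and molecule lengths, so it is learned
from the data: every contig longer than `2e` contributes one training
sample — the known span between its own head and tail windows
(`length − 2e`) and the Jaccard index of their barcode sets. The gap
behind an edge is estimated as the median training distance of the `B`
samples (default 20) with the closest Jaccard index. Numerical choices:
the empty-versus-empty Jaccard is defined as 0; `B` is capped at the
sample count; ties in Jaccard distance resolve by training order; an even
median is the rounded-half-up mean of the central pair. Estimates are
therefore always inside the training distance range — the estimator
interpolates, never extrapolates, which matters below.

**5. Path building.** A full-featured graph scaffolder is out of scope
here; the built-in layout stage is deliberately conservative. A contig end
may be extended only through an edge that is the best (most shared
barcodes) for *both* of its endpoints, and only if the runner-up support
at each endpoint is at most `a` times the best (default 0.5). Chains of
such links become scaffolds; cycles are broken at their weakest edge;
everything else is emitted as a singleton. Joined sequences are separated
by `N` runs of the estimated gap length (floored at 10 so joins stay
visible to downstream tools) or 100 `N` without an estimate. Raising `a`
can only add joins, never remove them.

## The simulator

`sim_config()` defaults describe the benchmark the package is validated
on: a 2 Mbp random genome cut into 40 contigs of ~50 kbp (uniform
partition with a 40 kbp floor) separated by gaps drawn from U(0, 5000) bp,
then shuffled and randomly strand-flipped as a draft assembler would
present them. Reads emulate a Chromium library: 400 barcodes of 10
molecules each, molecule lengths exponential with mean 50 kbp, read pairs
(2 x 150 bp, insert ~N(400, 50)) drawn at 2/3 pairs per molecule-kbp.
That yields ~0.2x per-molecule coverage, ~100x genome-wide molecule
coverage — matching the molecule coverage of published linked-read
simulation profiles — and ~20x genome-wide read coverage. Reads are
error-free by default because mapping is by exact k-mer match; a
configurable substitution rate exists as a stress axis. Barcode reuse (10
molecules per barcode) is modelled because it is the dominant noise source
for both pairing and gap estimation.

What the simulator does **not** model: sequencing-error profiles of real
instruments, barcode whitelists and barcode sequencing errors (assumed
corrected upstream, e.g. by Long Ranger), GC or mappability bias,
repeats (beyond an optional planted tandem duplication), and chimeric
molecules. Tests passing on this generator therefore show algorithmic
correctness and behaviour under the stated coverage geometry, not
robustness to real-data artefacts.

## What the benchmark shows — and where the method saturates

On the reference benchmark (seeds 1 and 42; `scripts/acceptance.R`
recomputes everything), joins are essentially always correct: join
precision and orientation accuracy are 100% in our runs, and the pipeline
completes in about a minute on one CPU. Adjacency recall, however,
plateaus at roughly 65–80%, and the gap estimates collapse to a constant.
Both effects are properties of the *regime*, not bugs, and are worth
understanding before applying the tool:

* **Orientation evidence vanishes when molecules are as long as
  contigs.** A molecule that crosses a junction and also spans the entire
  neighbouring contig deposits reads at both of its ends; which end gets
  more reads is then a coin flip, so the barcode's orientation vote is
  noise. With exponential molecules of mean 50 kbp over ~50 kbp contigs,
  a large fraction of the junction-crossing barcodes are uninformative,
  leaving the winning orientation cell with only part of the barcodes the
  two contigs actually share. The binomial test at
  `r = 0.05` then cannot reject equality for a minority of junctions, and
  those joins are (correctly, given the evidence) withheld. The method is
  designed for drafts whose contigs are much longer than the molecules —
  megabase-scale inputs — where spanning is rare; on short-contig drafts
  expect high precision but moderate recall, and consider relaxing `r`
  only with independent validation.

* **The gap estimator cannot extrapolate below its training range.** The
  training distances are `length − 2e` of contigs longer than `2e`; with
  ~50 kbp contigs and `e = 10` kbp they start around 20 kbp, while the
  true gaps in this benchmark are 0–5 kbp. Every query Jaccard then
  exceeds every training Jaccard, the `B`-nearest set is the same for all
  queries, and all edges receive the same (over-)estimate. The estimator
  is accurate exactly when the assembly contains contigs whose own
  head-to-tail spans bracket the gaps being estimated: on such a fixture
  (mixed 12–90 kbp contigs, gaps 0.5–8 kbp, `B = 5`) the estimated gaps
  correlate with truth at Pearson r = 0.82 and the training scatter decays
  monotonically with distance, as the test suite checks. On real drafts,
  whose length distributions are broad, this condition usually holds; on
  uniform short-contig drafts the estimates should be read as upper
  bounds.

## Problem sizes and reproducibility

The test suite validates each stage on fixtures of 50 kbp–1.2 Mbp and the
full benchmark at 2 Mbp/~130k read pairs, sizes at which every oracle
(brute-force mapping over literal k-mer sets, exact binomial enumeration,
truth-table comparison) stays exact and cheap. All randomness flows from a
single integer seed per dataset (genome, fragmentation and reads use fixed
offsets of it), so every simulation, pipeline run and output file is
byte-reproducible; the mapping and graph stages contain no randomness at
all. The `t` (threads) option is accepted for interface compatibility and
does not change results; the current implementation is sequential.

## Known limitations

Beyond the two regime effects above: the path builder is intentionally
simpler than dedicated graph scaffolders (no multi-round distance-aware
walks, no node-degree pruning); barcode error correction is out of scope
(exact string comparison is assumed valid after upstream processing); the
k-mer hash table lives in memory, which for mammalian-scale drafts with
`e = 30` kbp requires tens of gigabytes — masking interiors is what keeps
it feasible; and misassembled input contigs are not detected or broken.
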