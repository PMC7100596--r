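---
title: "Clustering linked-read barcodes by unique k-mer similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering linked-read barcodes by unique k-mer similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Co-barcoded ("linked-read") libraries — BGI's stLFR, 10X Genomics Chromium —
shear input DNA into long fragments of 10–100 kb and tag all short reads from
one fragment with a shared barcode. Three coverages describe such data: the
*local* coverage of a fragment by its own reads (very low, 0.1–0.3x), the
*fragment* coverage of the genome by long fragments (high, e.g. 300x for a
1 ng human library), and the *global* read coverage (ordinary, 50x-ish).
Because local coverage is far too low to assemble a fragment from its own
barcode, the long-range information is only usable if one can pool *all*
barcodes whose fragments overlap a target region — and that pooling is
confounded because a single barcode typically carries several fragments from
unrelated loci (about 1.18 fragments per barcode for stLFR, 8.32 for 10X).

`lfrclust` solves this *barcode clustering* problem without a reference or
alignments: given a seed barcode it captures the barcodes overlapping the
seed's region, splits away co-barcoded material from other regions, and
filters residual non-target reads, producing per-region read sets fit for
independent ("divide-and-conquer") assembly. Clusters of reads are the
output; the assembly itself is downstream and out of scope.

## The model

**Unique k-mers as barcode features.** Every canonical k-mer (lexicographic
minimum of a k-mer and its reverse complement; reads sample both strands) is
counted genome-wide across all reads. K-mers whose count falls in a
frequency window consistent with single-copy sequence — above the
sequencing-error noise, below the repeat tail — are *unique k-mers*. A
barcode's feature set K(b) is the set of unique k-mers present in its reads.
Two barcodes sharing fragment overlap share genomic k-mers, so the distance
is simply

> Dist(b1, b2) = |K(b1) ∩ K(b2)|.

Restricting to unique k-mers is what makes this overlap signal specific:
repeat-derived k-mers would connect unrelated loci.

**Inverted-index adjacency.** Computing Dist for all pairs directly is
O(n²) in the number of barcodes. Instead, an inverted index maps each unique
k-mer to the barcodes containing it; every posting list of length d
contributes one shared k-mer to each of its d(d−1)/2 pairs, and d is bounded
by the sequencing depth, so accumulating all pairs is linear in the number
of unique k-mers. Pairs are stored only at weight ≥ `store_floor`
(default 10) to keep the matrix sparse; posting lists beyond a sanity cap
(default 10x the mean posting length) are skipped as repeats that leaked
through the frequency window.

**Iterative enrichment with the frequency-diversity model.** A cluster grows
from a seed barcode in rounds:

1. *Direct capture*: all barcodes with Dist(seed, b) > `g` join the target
   set T (read off the adjacency graph).
2. *Feature selection*: each unique k-mer is scored by its support — the
   number of members of T carrying it. K-mers with support > `f_min` form
   the feature set F. The rationale is a diversity argument: members of T
   all overlap the seed's region, so region k-mers recur across members,
   while each member's *other* fragments are scattered over the genome and
   their k-mers stay at support 1–2. Disabling this filter (`use_freq_model
   = FALSE`) makes F the plain union of member k-mers and lets non-target
   fragments recruit false positives — the package's simulation study
   reproduces that contrast.
3. *Iterated capture*: for `k_iters` rounds, barcodes sharing > `g` k-mers
   with F join T; |K(b) ∩ F| is recomputed against the profiles (F is a
   k-mer set, not a barcode, so the graph cannot supply it), scanning only
   the "optional set" of barcodes adjacent to a current member. F is then
   re-selected and grows by union, never shrinking. The spatial reach of a
   cluster thus grows by roughly one fragment length per round.

**Markov clustering of mixed captures.** If the seed itself carries
fragments from two loci, T mixes two groups, densely connected within and
weakly connected between. A transition matrix over T is built from the
pairwise weights, column-normalized, and iterated with alternating
*expansion* (M ← M^s, simulating s random-walk steps) and *inflation*
(entrywise power r followed by column renormalization), which concentrates
the walk within dense groups. Converged attractor rows define subclusters;
each subcluster is then enriched independently.

**FalseRemove.** After clustering, a member's non-target reads are removed
by depth: k-mers are counted over the cluster's reads only, each read pair
is scored by the mean within-cluster depth of its k-mers, and pairs below a
threshold are dropped. Target-region reads sit near the cluster's modal
depth; non-target reads near singleton depth.

**Evaluation.** With a truth table of barcode fragment positions
(alignment-derived for real data; exact for simulated data), a seed's target
region is the union extent of its *valid* fragments (> 500 bp span, > 30
read pairs) extended by `ext` on both sides; a barcode is in-region if a
fragment with > 5 pairs overlaps it. Precision = TP/(TP+FP) over members,
recall = TP/(TP+FN) over in-region barcodes, macro-averaged per region and
across seeds. Because member provenance records each capture iteration, a
single `k_iters = 3` run can be re-read at any smaller cutoff, which is how
recall-vs-iteration curves are produced without re-clustering.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | k-mer length (bases) | 17 | 13/15 supported; larger k is more specific but costlier |
| `freq_lo`, `freq_hi` | unique-k-mer count window | 20–80 (stLFR), 20–60 (10X), 2–24 (desk) | scale with global depth: roughly 0.4–2x the modal k-mer depth for deep data |
| `min_pairs` | barcode QC, keep n_pairs > this | 10 (stLFR), 0 (10X) | strict inequality |
| `store_floor` | min stored edge weight | 10 | below it, co-counts are computed but discarded |
| `n_min`, `r_min` | seed quality: \|K(b)\| >, unique fraction ≥ | 3000, 0.3 | 20000 for 10X; 1500 desk |
| `g` | capture threshold on shared k-mers | 200 (stLFR), 130 (10X), 50 (desk) | strict (> g); high enough to reject repeat/error overlap, low enough for slight fragment overlap |
| `f_min` | feature support threshold | 3 | strict (> f_min); 0 disables the diversity model |
| `k_iters` | enrichment rounds after direct capture | 3 (stLFR), 2 (10X) | cluster reach grows ~1 fragment length per round |
| `s`, `r` | MCL expansion / inflation | 2, 2 | |
| `mcl_iters` | max MCL rounds | 20 | early exit at max entrywise change < 1e-6 |
| `min_mean_depth` | FalseRemove cutoff | mean score / 3 | see below |
| `ext` | evaluation region extension (bp) | 200000 | protocol range 80–400 kb |

**Desk-scale parameters.** The published thresholds are calibrated to ~50x
human data and are depth-dependent. The desk preset rescales them to the
simulator's defaults (~6x global coverage) by the same coverage arithmetic:
the modal k-mer depth is ≈ global coverage x (1 − (k−1)/read length) ≈ 5, so
the unique window [2, 24] spans ~0.4–5x the mode (excluding error
singletons and repeats); |K(b)| for a one-fragment barcode is ≈ fragment
length x P(position sampled) ≈ 20000 x 0.155 ≈ 3100, so `n_min` 1500 keeps
ordinary barcodes eligible; shared k-mers between barcodes overlapping by v
bases are ≈ v x 0.155², so `g` = 50 corresponds to ~2 kb of fragment overlap
(and `store_floor` 10 to ~0.4 kb).

**The FalseRemove default.** Scores are bounded below by ~1 because a
pair's own k-mers are part of the cluster depth table. The default cutoff of
one third of the cluster's mean pair score lands in the valley between the
contaminant mode (singleton depth plus the background that members' stray
fragments spread over the genome) and the target mode; fractions much
smaller than that can fall below the score floor and keep everything.

## The simulator

`simulate_linked_reads()` generates: a uniform-random ACGT genome
(optionally with injected repeat copies); fragments with uniform starts and
normal lengths (default 20 ± 7 kb, clamped at 1 kb) drawn until the summed
length reaches the fragment coverage (default 30x); a partition of
fragments into barcodes with shifted-Poisson counts (`1 + Poisson(mean−1)`,
presets 1.18 stLFR-like / 8.32 10X-like, desk default 1.2); and FR read
pairs (100 bp, 300 ± 30 bp inserts) at 0.2x local coverage with 0.1%
substitution errors. The truth table records each (barcode, fragment) with
its exact emitted pair count. A single seed fixes all randomness;
regeneration is byte-identical.

It emulates the *structure* that matters to the algorithm — the three
coverages, fragments-per-barcode mixing, low local coverage, substitution
noise — and deliberately not: the heavy-tailed read-count distribution of
real stLFR barcodes (only the means are matched), PCR duplicates, barcode
sequencing errors, chimeric fragments, or realistic repeat landscapes.
Passing tests on this generator therefore demonstrate algorithmic
correctness and the qualitative precision/recall behavior, not performance
on real genomes; the fragment-length spread (sd 7 kb) is what gives the
upper tail of fragments enough read pairs to qualify as evaluation seeds
under the > 30-pair validity rule at 0.2x local coverage.

## Numerical and design choices

- All thresholds are strict (`> g`, `> f_min`, `> min_pairs`, span `> 500`,
  pairs `> 30` and `> 5`), following the capture rule's "greater than"
  semantics throughout.
- K-mers are packed into 2-bit numeric codes (exact for k ≤ 26 in a
  double); numeric order equals lexicographic order, so canonicalization is
  locale-independent. Windows containing non-ACGT bases are skipped and
  counted.
- Determinism: candidate seeds are ordered by |K(b)| descending with
  lexicographic tie-break; captured barcodes and feature sets are kept
  sorted; MCL subclusters are ordered by size then first member; ties in
  attractor assignment go to the lowest-indexed attractor. Results are
  identical at any thread count (threads only affect data.table
  internals).
- MCL self-loops: loop weight equals the node's maximum incident weight
  (1 for isolated nodes). Loops prevent the parity oscillation of bipartite
  random walks while keeping the coupling scale of the node's edges.
  Singleton subclusters are merged into the largest subcluster only when
  the original matrix couples them; isolated singletons are kept.
- F is unioned across rounds (never reset): a k-mer once validated by
  support stays a feature. The alternative (re-selecting F from scratch
  each round) could drop early features when the cluster grows past them;
  union keeps capture monotone, which also makes iteration-cutoff
  re-reading sound.
- Multi-seed orchestration: a barcode consumed as a member of one cluster
  is never used as a later seed, but remains capturable, so clusters may
  overlap (the manifest records every membership). For evaluation studies,
  seeds are instead sampled independently and enriched via
  `enrich_seeds()`, matching the protocol of scoring randomly selected
  seeds.
- Degenerate inputs: empty read streams give empty tables; singleton
  clusters give a 1x1 transition matrix; enrichment stops early on a
  stalled round; undefined precision/recall (empty denominators) is `NA`,
  never an error.
- Problem sizes: the test suite runs its study on a 1 Mb genome (~1500
  fragments, ~1250 barcodes, ~30000 read pairs, ~0.9 M unique 17-mers),
  evaluating 30 seeds — large enough for the frequency-diversity and
  recall-vs-iteration contrasts to be stable, small enough to run in
  minutes; oracle-equivalence checks use 200–500 barcodes where O(n²)
  brute force is feasible.

## Limitations

- Captured reads cover one locus across *all* haplotypes; the method is
  unsuitable for haplotype phasing by construction.
- A single capture threshold `g` is used in every round, although later
  rounds compare against a much larger F; an adaptive threshold is a known
  improvement direction.
- The feature-set recomputation (|K(b) ∩ F| per candidate per round) is the
  runtime bottleneck at scale; sketching techniques could trade exactness
  for speed.
- The unique-k-mer window is a global filter: regions whose depth deviates
  strongly from the genome mode (CNVs, high-copy repeats) are
  under-represented in K(b) and harder to capture.
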