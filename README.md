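# lfrclust

Reference- and alignment-free clustering of linked-read (co-barcoded)
sequencing barcodes.

Linked-read libraries — BGI stLFR, 10X Genomics Chromium — shear DNA into
10–100 kb fragments and tag every short read from a fragment with a shared
barcode. Each fragment is covered only sparsely by its own reads (local
coverage 0.1–0.3x), and each barcode typically mixes fragments from several
unrelated loci (~1.18 fragments/barcode for stLFR, ~8.32 for 10X), so the
long-range information cannot be used region by region without first
*deconvolving* it. `lfrclust` clusters the barcodes that originate from the
same genomic region — the preprocessing that makes divide-and-conquer
(per-region) de novo assembly of such data possible — for people working
with stLFR/Chromium FASTQ who need per-region read sets without a reference
genome.

## Method

The package is built around four ideas:

1. **Unique-k-mer similarity.** Canonical k-mers (k = 17 by default) are
   counted over all reads; k-mers whose genome-wide count lies in a window
   consistent with single-copy sequence (e.g. 20–80 at 56x) are "unique".
   With K(b) the unique-k-mer set of barcode b, the barcode distance is

   ```
   Dist(b1, b2) = |K(b1) ∩ K(b2)|
   ```

2. **Linear-time adjacency.** An inverted index (unique k-mer → barcodes
   containing it) turns pairwise counting into an accumulation over short
   posting lists (bounded by sequencing depth), avoiding the O(n²) scan.
   Edges are stored at weight ≥ 10.

3. **Iterative enrichment with a frequency-diversity model.** From a seed
   barcode, capture every barcode sharing > g unique k-mers; then select as
   features the k-mers carried by > f members of the captured set (region
   k-mers recur across members; k-mers of members' unrelated fragments stay
   at low support), and capture against the feature set for k further
   rounds. A Markov-clustering step (expansion `M ← M^s`, inflation
   `M_pq ← M_pq^r / Σ_i M_iq^r`, defaults s = r = 2) splits captures mixing
   several regions; each subcluster is enriched independently.

4. **FalseRemove.** Within a finished cluster, each read pair is scored by
   the mean within-cluster depth of its k-mers; low-depth (non-target)
   pairs are dropped at a data-driven threshold.

A simulator with exact ground truth (stLFR-like and 10X-like presets) and a
precision/recall harness (seed regions from truth fragments, extended
80–400 kb; P = TP/(TP+FP), R = TP/(TP+FN), macro-averaged over seeds) make
the whole pipeline testable offline. See the vignette
(`vignettes/linked-read-clustering.Rmd`) for the model, parameter meanings,
and design choices.

## Worked example

```r
library(lfrclust)

# simulate a small stLFR-like dataset with ground truth
sim <- simulate_linked_reads(sim_config(genome_length = 2e5, fragment_coverage = 10, seed = 7))
sim
#> # Simulated linked reads: 2011 pairs, 81 barcodes, 105 fragments over 2e+05 bp

# desk-scale analysis parameters (thresholds rescaled to this depth)
pp <- preset_params("desk", n_min = 800)
res <- run_linked_pipeline(sim$reads, pp, truth = sim$truth, max_seeds = 3)
glance(res)
#> # A tibble: 1 × 6
#>   n_barcodes n_unique_kmers n_edges n_clusters mean_precision mean_recall
#>        <int>          <int>   <int>      <int>          <dbl>       <dbl>
#> 1         72          93473     664          3              1       0.424

glance(res$clusters)
#> # A tibble: 3 × 6
#>   cluster_id seed   n_members n_subclusters n_iterations n_features
#>        <int> <chr>      <int>         <int>        <int>      <int>
#> 1          1 B00078        26             1            3       4392
#> 2          2 B00054        31             1            2       5299
#> 3          3 B00047        37             3            2       3468
```

Reading the output: 72 of 81 barcodes survive the >10-pair QC; ~93k unique
17-mers define the similarity; three clusters were grown (the third seed
carried fragments from several loci — Markov clustering split it into 3
subclusters). With the simulator's truth table attached, the evaluation
reports mean precision 1.0 and recall 0.42 over the seeds whose fragments
qualify as evaluation anchors. Iteration provenance lets one sweep the
iteration count after the fact:

```r
pr_sweep(res$clusters, sim$truth, ext = 50000, k_iters = c(0, 3))
#> # A tibble: 2 × 6
#>     ext k_iters n_seeds mean_precision mean_recall mean_fp_rate
#>   <dbl>   <int>   <int>          <dbl>       <dbl>        <dbl>
#> 1 50000       0       2          0.809       0.415        0.191
#> 2 50000       3       2          0.792       0.445        0.208
```

`tidy(res$clusters)` gives the flat member manifest; `autoplot()` methods
plot the k-mer spectrum, cluster growth by iteration, and PR sweeps. A thin
command-line front end is included:

```sh
Rscript inst/cli/lfrclust simulate --out sim/ --preset desk --seed 42
Rscript inst/cli/lfrclust run --r1 sim/reads_1.fq.gz --r2 sim/reads_2.fq.gz \
    --preset desk --truth sim/truth.tsv --out out/
Rscript inst/cli/lfrclust evaluate --clusters out/clusters.tsv --truth sim/truth.tsv --out pr.tsv
```

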