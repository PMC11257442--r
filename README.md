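# perichrom

Quantitative analysis of H3K9me2 domains from spike-in-controlled CUT&RUN
coverage, for researchers studying peripheral heterochromatin dynamics in
pluripotent cells and beyond.

Broad domains of H3K9 dimethylation cover more than half of a mammalian
genome in kilobase-to-megabase tracts. perichrom implements the
quantitative chain needed to compare them across genotypes and cell
states:

* **Spike-in normalization** of binned coverage tracks: per-library scale
  factor `constant / spike-in reads` (constant 30,000), applied
  multiplicatively, with rebinning and replicate averaging.
* **Four-state HMM segmentation**: Gaussian emissions on log1p signal with
  states for background, intermediate ("class 1") and high ("class 2")
  H3K9me2 density plus a very-high-signal artifact ("blacklist") state.
  Baum–Welch fitting with seeded restarts (compiled forward/backward/
  Viterbi kernels), hard Viterbi decoding, emission-mean state labelling,
  and run extraction into BED-ready domain sets.
* **Replicate consensus**: multi-way interval intersection with support
  counting; union / majority / intersection merge rules.
* **Domain analytics**: coverage and contiguous-length statistics,
  UpSet-style cross-condition sharing (bp or reciprocal-overlap domain
  mode), scaled meta-domain density profiles, and within-domain signal
  dispersion against a reference domain set.
* **Gene and TE accounting**: majority-bp gene/domain assignment, TPM with
  a 5-TPM expressed threshold, expressed fractions per domain class, gene
  flow between cell states (constitutive / gained / lost), median-of-ratios
  size factors, Kruskal–Wallis + Dunn group comparisons, and per-copy
  transposable-element derepression calls (≥10-fold, adjusted p < 0.05)
  with H3K9me2 contrasts between affected and unaffected copies.
* **A synthetic-data generator** that plants a sticky-Markov domain map,
  replicate tracks with spike-in-dependent depth, negative-binomial count
  tables, repression of domain-resident genes and ≥10-fold induction of a
  marked TE subset — with full ground truth, so every stage is scored
  against what was planted.

## Worked example

```r
library(perichrom)

cfg   <- synth_config(seed = 11, n_chromosomes = 2, chrom_length_bp = 2e7,
                      n_genes = 500, n_te_copies = 300)
truth <- generate_truth(cfg)                      # planted 60%-coverage map
libs  <- simulate_tracks(truth, "wild-type")      # 3 spike-in-scaled replicates
dc    <- call_condition_domains(libs)             # normalize + HMM + consensus
domain_stats(dc$consensus, truth$layout)
#>    class n       bp  min_bp median_bp  max_bp
#> 1 class1 8 17060000  340000   1720000 4490000
#> 2 class2 1  6940000 6940000   6940000 6940000
#> coverage 60.0% of genome; median contiguous length 2,340,000 bp
interval_jaccard(dc$consensus, truth$domains)
#> [1] 1
```

The consensus recovers the planted map exactly (bp Jaccard 1.0) and the
60% planted genome coverage. Downstream, repression planted on
domain-resident genes shows up as an ordered expressed fraction, and the
planted ten-fold-induced TE copies are recovered:

```r
counts <- simulate_counts(truth)
tp     <- tpm(counts$genes, truth$genes)
assign <- assign_genes(truth$genes, dc$consensus)
round(expressed_fraction(assign, tp, counts$genes, "wild-type"), 3)
#> outside  class1  class2
#>   0.986   0.957   0.897
calls <- call_derepressed(truth$te, counts$te, "wild-type", "mutant")
sum(calls$called == "up")   # 28 of 30 planted copies called, none spurious
#> [1] 28
```

A thin command-line wrapper is installed at `inst/cli/perichrom.R`
(`Rscript perichrom.R all --config config.yaml --seed 1 --out run/`).

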