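---
title: "Calling and analysing H3K9me2 domains with perichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analysing H3K9me2 domains with perichrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perichrom)
```

## The problem

Dimethylation of histone H3 lysine 9 (H3K9me2) marks broad heterochromatic
domains that are enriched at the nuclear lamina. Quantifying how these
domains change between cell states or genotypes requires a chain of
quantitative steps: making spike-in-controlled CUT&RUN coverage comparable
across libraries, segmenting each genome into domains of absent,
intermediate (class 1) and high (class 2) H3K9me2 density, merging
replicate-level calls into per-condition consensus domains, and relating
the resulting domain maps to gene expression and to individual
transposable-element (TE) copies. perichrom implements that chain as a set
of composable functions, together with a synthetic-data generator that
plants a known domain map and known expression effects so that every stage
can be scored against ground truth.

## Spike-in normalization and binned tracks

A `binned_track` holds fixed-width per-bin signal over a `genome_layout`
(two resolutions are used in practice: 10 kb for segmentation, 1 kb for
density profiles). Per-library comparability comes from a spike-in scale
factor, an arbitrary constant (30,000 by default) divided by the number of
properly paired reads mapping to the spike-in genome:

```{r scale}
compute_scale_factor(15000)$factor
```

The factor is applied multiplicatively (`normalize_track()`), so its
composition with any upstream per-bin normalization (such as RPKM) is
order-independent; the package is agnostic to the units of the incoming
track. Partial trailing bins are averaged over the source bins that exist
when rebinning, and bins without signal are 0 (bedGraph gap semantics). A
track can only be spike-in-scaled once; a second scaling is an error.

## The four-state hidden Markov model

Segmentation fits a hidden Markov model with four states - background,
class 1 (low signal), class 2 (high signal) and a "blacklist" state for
rare bins of very high artifact signal - to each replicate's 10-kb track
independently, then decodes a hard state path.

Model choices, where the procedure is genuinely open:

* **Emission family.** Univariate Gaussians on log1p-transformed signal.
  Coverage is nonnegative and heavy-tailed; the log1p transform makes
  near-Gaussian emissions a reasonable approximation while keeping zero
  bins finite. Emission standard deviations are floored at `1e-3` so a
  state cannot collapse onto repeated values.
* **Initialization.** Emission means start at the 20/50/80/99.95
  percentiles of the transformed signal, with a uniform initial vector and
  a sticky transition prior (0.95 self-transition). The top state's anchor
  must sit deep in the upper tail: the artifact component typically holds
  well under 1% of bins, and an anchor near the class2/blacklist boundary
  makes EM merge the two domain classes and split the artifact state.
  Because percentile anchors assume a particular occupancy profile,
  restarts (3 by default) instead take 1-D k-means centers of a signal
  subsample with a small seeded jitter; the restart with the best final
  log-likelihood wins. All of this is deterministic given the seed.
* **Fitting.** Baum-Welch with each chromosome as an independent
  observation sequence; the forward/backward/Viterbi kernels are compiled
  (Rcpp) with per-step scaling, and the per-iteration log-likelihood trace
  is retained and checked to be non-decreasing. Convergence is declared at
  a relative improvement below `tol` (1e-6); non-convergence returns the
  best iterate with a warning.
* **Decoding.** Viterbi by default (a hard path is what BED export
  requires); ties break toward the lower state index so decoding is
  deterministic. States are then labelled by ascending emission mean;
  tied means break by smaller sd, then index, with a warning.
* **Segmentation.** Maximal runs of class1/class2 bins become intervals;
  background and blacklist bins are excluded, so an artifact run splits a
  domain. By default no post-filtering is applied (`min_domain_bins = 1`,
  `max_gap_bins = 0`); both are exposed.

`forward_loglik()` exposes the exact scaled forward recursion and is
verified in the test suite against brute-force enumeration over all state
paths for short sequences, to 1e-9.

## Replicate consensus

`multi_intersect()` partitions the union of replicate domain calls at
every interval boundary and annotates each fragment with per-replicate
presence and class - the multi-way intersection familiar from bedtools
multiinter. `consensus_filter()` keeps fragments supported by at least
`min_support` replicates (default 2 of 3, a majority; the union and
intersection limits are `min_support = 1` and `= n`), assigns each
fragment the majority class among supporting replicates with ties going
conservatively to class1, and coalesces adjacent same-class fragments.
The exact merge rule behind published "merged" replicate calls is rarely
stated, which is why the rule here is a parameter with both limits
available.

## Domain analytics

`domain_stats()` gives exact integer bp accounting per class, the median
contiguous domain length (class-agnostic, after coalescing abutting
domains), and genome coverage. `condition_sharing()` partitions the union
of several conditions' domains by membership pattern (UpSet-style); bp
mode assigns every boundary fragment exactly, and domain mode counts a
union region as shared under a reciprocal-overlap rule (50% by default).
`meta_domain_profile()` rescales each domain body to a fixed number of
positions by linear interpolation and appends fixed-width flanks, and
`signal_dispersion()` reports the mean and population sd of bin values
within a region set, selecting bins by midpoint containment - evaluating
any condition's averaged track inside a *reference* domain set (e.g.
wild-type domains) is how cross-condition density is compared without
confounding by per-sample segmentation quality.

## Genes, expression and flow

Genes are assigned to `outside` / `class1` / `class2` by majority
gene-body bp; a class1/class2 bp tie goes to the denser class2 and a
domain/outside tie to the domain class (an any-overlap rule is available).
Expression uses TPM (counts over effective length in kb, normalized to one
million per sample), and a gene counts as expressed at a mean TPM of at
least 5 across a condition's replicates. `domain_flow()` cross-tabulates
in-domain status between two cell states into constitutive / gained /
lost / never, conserving the gene universe exactly. Count tables are
normalized by median-of-ratios size factors; group-wise H3K9me2
comparisons use the tie-corrected Kruskal-Wallis test with Dunn's pairwise
z statistics (Holm adjustment by default; Bonferroni and BH selectable,
since the correction used alongside "Dunn's test" in figure legends is
usually unstated).

## Per-copy TE derepression

`call_derepressed()` works on uniquely-assignable per-copy counts (the
family-level multi-mapping reassignment problem is out of scope; the
counts table is the interface boundary). Folds are
`(mean_B + 1) / (mean_A + 1)` on normalized counts - a pseudocount of one
normalized count, because zeros dominate at copy level - and a copy is
called up at a fold of at least the threshold (10 by default, inclusive)
with an adjusted significance below 0.05. Significance comes from an
injected external differential-expression table when available; otherwise
a deliberately simple stand-in (Welch t on log1p normalized counts,
Benjamini-Hochberg) is used - the package does not reimplement a
dispersion-shrinkage DE engine. `k9_on_copy_sets()` then contrasts
normalized H3K9me2 on up-called versus unchanged copies.

## What the synthetic generator emulates

`synth_config()` defaults define the study conditions the validation runs
under:

* a 500-Mb genome (5 x 100 Mb) at 10-kb bins - 50,000 bins;
* a domain map sampled per chromosome from a two-block sticky Markov
  chain (self-transition 0.99; the background leave rate is set so the
  stationary domain fraction equals the 60% target), domain runs assigned
  class2 with probability 0.4, then whole runs flipped until the realized
  fraction is within 0.5% of target - so the planted fraction is always
  inside the +/-2% tolerance the tests assert;
* blacklist artifact bins planted as isolated 1-3 bin runs inside
  background, 0.5% of the genome, with an extreme emission mean;
* ordered emissions (1, 2.5, 4.5, 8 on the log1p scale, sd 0.5) plus
  replicate noise (sd 0.1); raw signal is `expm1` of the transformed draw,
  clipped at zero. The background mean sits at 1 rather than 0 so the
  clip affects ~2% of background draws and biases nothing measurably;
* three replicates whose raw library depth is proportional to their
  spike-in read counts (15,000 / 20,000 / 30,000), so skipping spike-in
  normalization visibly shifts the recovered emission means;
* 2,000 genes with lognormal base expression (sdlog 2, wide enough that
  the 5-TPM threshold bisects the population as it does in real
  transcriptomes); class2 residents repressed to 0.10x in the tethered
  ("wild-type") condition, class1 residents to the geometric midpoint
  sqrt(0.10); repression is lifted in the displaced ("mutant") condition;
* 1,000 TE copies, 10% marked as derepressible and planted inside class2
  domains; marked copies carry planted induction folds of
  `10^(1 + U(0, 1.5))` in the mutant - a population induced *at least*
  ten-fold, matching how ">= 10-fold up" copy sets are defined; setting
  the spread to 0 recovers a uniform planted fold. Per-copy H3K9me2
  counts follow the planted chromatin state, so derepression-sensitive
  copies are the heavily K9-marked ones;
* negative-binomial counts (size 20) with four RNA replicates per
  condition and optional per-sample depth multipliers.

What it does **not** emulate - and hence what passing tests do not show
about real data: mappability and GC structure, fragment-length effects,
copy-number variation, domain boundaries that move with condition
(both conditions share one planted map, matching preserved H3K9me2
deposition), partially methylated or graded domains, and multi-mapping TE
reads. Numbers recovered on synthetic data validate the algorithms, not
the biology.

## Problem sizes and determinism

The validation suite runs the full recovery at 50,000 bins x 3 replicates
(about half a minute including Baum-Welch restarts), with smaller genomes
(1,000-5,000 bins) for the per-module tests; brute-force oracles
(path enumeration, per-bp support counting, hand cross-tabulation) run at
sizes where exhaustive computation is trivial. Every stochastic step -
truth generation, track and count simulation, HMM restarts - derives its
stream from explicit integer seeds, and rerunning a pipeline with the
same configuration reproduces byte-identical outputs.

## Known limitations

Whether published domain calls decoded with Viterbi or posterior
thresholding, and whether artifact bins were removed before or after
merging, is typically unstated; perichrom uses Viterbi and removes
blacklist bins before run extraction. The stand-in significance test for
TE calls is less powerful than a shrinkage-based engine at very low
counts. Consensus class ties are resolved conservatively (class1), which
slightly deflates class2 bp when replicates disagree. Full-scale
reproduction of published domain statistics requires the deposited
sequencing data and is supported by the same functions via bedGraph
input, but is not part of the desk-scale suite.
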