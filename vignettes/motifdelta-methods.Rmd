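---
title: "motifdelta: models, normalization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{motifdelta: models, normalization and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The binding model

`motifdelta` treats a TF motif as a generative model of binding-site
sequence. A mononucleotide motif of length $L$ is a position-specific
probability matrix $P \in [0,1]^{L \times 4}$ with rows on the simplex; a
dinucleotide motif with $D$ positions covers $D + 1$ nucleotides and has 16
probabilities per position (symbol order AA, AC, ..., TT, first base
varying slowest). Together with a zero-order background $b$ over A,C,G,T,
probabilities become log-odds weights

$$W_{ji} = \log\frac{P_{ji}\,(1 - cA) + c}{b_i}$$

with pseudocount mass $c$ and alphabet width $A$ (for dinucleotide symbols
$XY$ the background counterpart is $b_X b_Y$). The match score of a motif
placement is the sum of its per-position weights — a convolution of the
one-hot-encoded sequence with $W$ — and a sequence variant is scored by
differencing the pooled, normalized scores of its two allelic windows.

Key simplifying assumptions: positions contribute independently (mono) or
with first-order neighbor dependence only (di); binding is
strand-symmetric; the background is a zero-order chain.

## Why normalize, and how

Equal differences in raw log-odds do not correspond to equal differences in
binding probability: the (unknown, context-dependent) monotone map from
score to occupancy is flat at low scores and steep near the top. The
package's principled option, *probnorm*, replaces the unknown map with the
cumulative distribution function of the motif's own score distribution
under the background model: a score becomes the probability that a random
background sequence matches no better. This has three useful properties —
it is exact (computed by dynamic programming, equal to exhaustive
enumeration), motif-specific, and bounded in $[0,1]$, so Diff scores are
comparable across motifs.

The *fabian* mode re-implements a min–max normalization in the style of the
FABIAN tool, from its published description: each column of $W$ is shifted
so its maximum is zero, the per-motif factor $F$ sums the column minima on
that scale, and a score $s$ maps to $1 - (s - \sum_j \max_i W_{ji})/F$. The
orientation (consensus $\to$ 1, worst match $\to$ 0) is this package's
convention, chosen so that Diff signs agree across all modes; the original
tool's exact min–max constants are not published in its paper, so this mode
should be read as "FABIAN-style", not as a bit-exact reproduction. The
degenerate case $F = 0$ (all columns constant) maps every score to 1.
Outputs are clamped to $[0,1]$ purely against float round-off; the algebra
already bounds them.

*none* passes raw log-odds through. Average pooling is refused in this mode
because a mean of raw log-odds over placements has no occupancy
interpretation; it is allowed (and meaningful) for both normalized modes.

## The exact score distribution

`score_distribution()` discretizes weights to integer multiples of a
granularity $\varepsilon$ (R's `round`, i.e. round-half-to-even, applied
per position) and convolves the per-position score distributions exactly.
For dinucleotide motifs the DP state is (last nucleotide, discretized
score): the first nucleotide is drawn from the background at score 0, each
position transitions $(x, s) \to (y, s + W_{j,xy})$ with probability
$b_y$, and the nucleotide state is marginalized at the end.

Numerical choices, in one place:

* $\varepsilon = 0.001$ by default. Per-position rounding error is at most
  $\varepsilon / 2$, so a length-$L$ match score is within
  $L\varepsilon/2 \approx 0.01$ of its unrounded value for typical motifs,
  while the integer support stays small enough to hold as a dense vector.
  A `max_bins` cap refuses granularities that would blow up the support.
* When a motif is scanned in probnorm mode, scanning uses the
  granularity-quantized weight matrix $\varepsilon\,\mathrm{round}(W /
  \varepsilon)$ rather than $W$. Match scores then lie exactly on the
  distribution's support grid, so CDF lookups are exact: the consensus
  placement maps to exactly 1 and enumerated-sequence tests hold to 1e-9
  rather than "within a half bin". The other modes scan the unquantized
  weights.
* `cdf_lookup()` returns the CDF at the largest support value at or below
  the query, with a $10^{-6}\varepsilon$ tolerance absorbing float error
  in on-grid sums; below-support queries give 0, above-support 1.
* CDF robustness across granularities is inherently limited by atom
  masses: with 64 equiprobable 3-mers each score atom carries mass
  $1/64$, and a coarse bin boundary can move a whole atom past a query.
  The tests therefore check that the mean CDF shift between
  $\varepsilon = 0.01$ and $0.001$ is below 0.01 and the maximum below
  two atom masses.
* Distributions are computed once per motif by `motif_pwm()` and carried
  in the motif tibble, amortizing the cost over all variants.

## Windows, strands, variants

For a variant at position $p$ with reference allele length $r$, windows
span $[p - (L-1) - f,\; p + r - 1 + (L-1) + f]$ with `extra_flank`
$f = 0$ by default, so exactly the motif placements overlapping the
variant are scored; for SNVs both windows have length $2L - 1$. Wider
windows are exposed (`extra_flank`) because the right choice depends on
the downstream question (a variant *near* a strong site scores 0 under
motif-length windows), but motif-length windows are the default.

Both strands are always scanned — TF binding is strand-symmetric and this
makes results independent of reference orientation — and pooled jointly
(one pool over the $2(n-L+1)$ placements); `both_strands = FALSE` gives a
forward-only scan. Placements overlapping ambiguous bases (N) are excluded
rather than scored, so assembly gaps cannot fabricate Diffs; an all-N
window yields `NA`. VCF coordinates are 1-based and all conversion is
isolated inside `extract_windows()`. Multi-allelic records are split into
bi-allelic variants; REF alleles are validated against the genome and
mismatches are hard errors listing the offending variants. Indels are
supported by the same window construction with unequal window lengths —
this is a natural generalization chosen by this package (the validated
primary path is SNVs) — and structural variants are out of scope.

SNVs sharing a contig are scored in a vectorized batch (one window matrix
per contig, one sub-window per motif); indels and boundary-truncated
variants take an identical-by-construction per-variant path, and the test
suite checks the two paths agree.

## Fine-tuning layer

The elastic net maps the variant × motif Diff matrix to a measured effect
(e.g. $-\log_{10} P \cdot \mathrm{sign}$). Configuration defaults, all
exposed: 80/20 train/holdout split, 5-fold cross-validation inside the
training split for the penalty path, mixing grid $\alpha \in \{0.1, 0.5,
0.9\}$, glmnet-internal standardization, missing Diffs imputed as 0 (a
missing placement means no scoreable binding change), all-missing columns
dropped. The split and fold assignment derive from a single seed, so fits
are exactly reproducible. Reported metrics are holdout Pearson correlation
and the AUROC of predictions against the sign of the measured effect;
single-class holdouts give `NA` AUROC. `single_motif_correlation()` is the
no-fitting baseline against one motif column.

## Gain/loss layer

EPPS for a motif is the proportion of variants with strictly positive Diff
among those with nonzero Diff; exact zeros are excluded because a zero is
neither gain nor loss (this matters for small samples and is therefore
stated here). The shift test is a two-sided one-sample Wilcoxon
signed-rank test against location 0, normal approximation with continuity
correction at every $n$ (so p-values are procedurally comparable across
motifs). The phrase "rank-sum test against a normal distribution" in the
literature this layer follows is ambiguous — rank-sum is a two-sample
test — so a two-sample variant against a deterministic matched-scale
normal quantile sample is available via `reference = "normal-sample"`;
neither is claimed to reproduce any specific prior tool. FDR control is
Benjamini–Hochberg. Columns with fewer than `min_n = 10` observations get
`NA` p-values but still report EPPS.

## What the simulator does and does not emulate

`simulate_genome()` draws i.i.d. nucleotides at a chosen GC content;
`simulate_motif()` builds PSPM columns as consensus/uniform mixtures tuned
to an information-content target (default 1.2 bits/position, typical of
curated TF motifs); `plant_sites_and_variants()` writes consensus sites
into the genome and emits site-disrupting SNVs (consensus base to the most
damaging alternative) plus neutral background SNVs; `simulate_labels()`
builds effects as a sparse linear model over Diffs plus Gaussian noise.

This emulates exactly the structure the scoring pipeline assumes — and no
more. Real genomes have repeat structure, GC heterogeneity, clustered and
overlapping sites, linkage between variants, and measured allelic effects
are noisy, winner's-curse-biased and confounded by co-factors and
chromatin context. Passing the planted-site and recovery tests therefore
demonstrates correctness of the computation, not expected predictive
performance on biological datasets.

## Problem sizes used by the test suite

The suite's end-to-end checks run at sizes chosen to exercise the
vectorized paths while keeping the default test run quick: enumeration
equivalence over 20 mononucleotide motifs (length ≤ 8) and 10 dinucleotide
motifs (span ≤ 6); bound checks over >1e5 placements; Diff algebra on
1,000 variants × 20 motifs; planted-site recovery on 200 disrupting + 400
background SNVs × 20 motifs; elastic-net recovery at n = 2000 with 200
features (10 causal); EPPS calibration on 1e4 null draws and 200 null
replicates of the shift test; and a throughput check scoring 10,000 SNVs ×
100 motifs in one R process.

## Known limitations

* Zero-order background only; no higher-order Markov chains (the DP state
  extends naturally, left as an extension point).
* No quantile (CDF inversion) interface; probnorm needs only the CDF.
* Soft-masking is ignored (lowercase = uppercase); only N masks.
* No structural variants, phased haplotypes, or liftover; indel handling
  is a documented generalization, not a validated benchmark path.
* The fabian mode matches the published *description* of FABIAN's
  normalization; constants hidden in that tool's supplement may differ.
* Average pooling queries the CDF per placement and is accordingly slower
  than max pooling on long windows.
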