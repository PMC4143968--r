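---
title: "Reconstructing and comparing brain-state networks with brainplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and comparing brain-state networks with brainplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A single-lead EEG decomposition can produce on the order of a hundred
activity-feature streams per recording — a feature-by-time matrix formally
identical to a gene-expression time course. brainplex treats it exactly
that way: it reconstructs a *relevance network* per recording (nodes =
features, links = feature pairs whose activity co-varies over the whole
series), stacks the per-state networks into a *multiplex* over the shared
node set, and quantifies which parts of the network persist across brain
states. A companion module carries the same "grouping" logic to gene-set
analysis: networks of pathways connected when their shared (interface)
genes carry a significant excess of differentially expressed genes.

## The reconstruction model

For a recording $X \in \mathbb{R}^{n \times T}$ the similarity step
computes the full $n \times n$ Pearson (or Spearman) correlation matrix
over the whole series. The layer network draws a link for $r_{ij} > t$
with $t = 0.8$ by default, strict inequality, on the signed coefficient.
Both choices are conventions the package documents rather than facts about
any dataset: an `absolute` mode (`|r| > t`) is available because relevance
networks are often read as capturing anti-correlation too, and the
`threshold_sweep()` operation reports link-set Jaccard across a band
(default 0.75–0.85) so a result can be shown to be threshold-robust rather
than an artifact of one cutoff.

Two validation routes are built in:

* **Permutation/surrogate nulls** (`permutation_null()`): each feature
  series is independently shuffled (white null) or circularly rotated by a
  random lag (autocorrelation-preserving null), and each pair's p-value is
  the add-one estimator $p = (1 + \#\{|r^\ast| \ge |r|\})/(B + 1)$, which
  is valid for any $B$. Benjamini–Hochberg correction across the
  $n(n-1)/2$ pairs is provided (`adjust_link_significance()`); note that
  with $B$ permutations the smallest attainable p-value is $1/(B+1)$, so
  $B$ must be large enough for any link to survive FDR correction over
  thousands of pairs (999 permutations suffice for 121 features).
* **Gaussian graphical view** (`compute_partial_correlation()`): partial
  correlations from the inverse correlation matrix,
  $p_{ij} = -w_{ij}/\sqrt{w_{ii} w_{jj}}$. With $n$ of the same order as
  $T$ the sample matrix is near-singular, so it is shrunk toward the
  identity, $R(\lambda) = (1-\lambda) R + \lambda I$. The default
  $\lambda$ is the analytic variance-minimising intensity
  $\hat\lambda = \sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij}) / \sum_{i \ne j} r_{ij}^2$,
  clamped to $[0,1]$ — a closed form, no tuning. $\lambda = 0$ reproduces
  the textbook three-variable recursion exactly on well-conditioned input
  and fails with explicit advice on singular input; $\lambda = 1$ zeroes
  all off-diagonal partial correlations.

## Multiplex comparison

`build_multiplex()` aligns layers by node label (order-insensitive,
set-mismatch is an error) so cell $(i,j)$ means the same feature pair in
every layer. The headline statistic is the **layer overlap**: the number
of off-diagonal adjacency cells equal to 1 in both layers, reported as a
fraction of the $N(N-1)$ possible ordered pairs. The networks are
undirected, so each shared link contributes two cells — but the
denominator double-counts identically, so the fraction equals the
unordered one; the ordered convention is kept because it is how such
overlaps are usually quoted for adjacency-matrix comparisons. Because
overlap conflates similarity with density, the Jaccard index over
unordered link sets is always reported alongside and is the default
metric for `match_state()`, which ranks a library of state layers by
similarity to a new recording (ties broken lexicographically for
determinism). Conventions for degenerate cases are fixed and tested:
Jaccard of two empty link sets is 1, overlap fraction 0, and an empty
query matches every non-empty layer at 0.

## What the synthetic generator emulates

No recording data ships with the package; the generator stands in for it
with the simplest model whose population correlations are known in closed
form — a latent block-factor model. A *state* is a partition of the $n$
features (default $n = 121$) into co-activation blocks; feature $i$ at
time $t$ is

$$x_{it} = \sqrt{\rho}\, z_{b(i)t} + \sqrt{1-\rho}\,\sigma\, e_{it},$$

so with $\sigma = 1$ co-blocked pairs have population correlation exactly
$\rho$ and cross-block pairs 0; in general the within-block correlation is
$\rho / (\rho + (1-\rho)\sigma^2)$, which the tests verify at
$T = 5000$ within $\pm 0.02$. The default `"contiguous"` layout mirrors
the empirical observation that nearby features tend to co-activate; the
`"interleaved"` layout ($i \mapsto i \bmod k$) provides a second state
sharing *no* co-blocked pair with the first when block counts match —
the cleanest possible "different brain state". Latent and noise series
are i.i.d. Gaussian; an optional AR(1) parameter adds temporal smoothness
(unit variance preserved) since real feature streams are autocorrelated,
but it is off by default because the correlation structure, not the
spectrum, is what the pipeline measures.

The study conditions used throughout the tests and the acceptance script
are 121 features, 11 blocks, $\rho = 0.9$, $\sigma = 1$, $T = 500$,
threshold 0.8, 20 replicate seeds. Under them the same-state overlap is
about 8.3% of ordered pairs (the 605 within-block links out of 7260
pairs) and the cross-state overlap is essentially 0 — a sharper version
of the qualitative pattern this analysis is meant to expose, where
same-state overlap exceeds cross-state overlap several-fold. What passing
these tests shows is that the pipeline's statistics separate states *when
state differences are pure co-activation structure*; real recordings add
nonstationarity, shared global rhythms (which inflate cross-state
overlap), volume conduction and feature redundancy, none of which the
generator models. The synthetic gene universe likewise plants exact
pairwise set overlaps (drawn from exclusive regions so third-party
overlaps stay at target) and a DE excess at a chosen odds ratio in a
chosen intersection; it does not model correlated expression within
pathways.

## Pathway-intersection networks

`enrich_sets()` is the standard one-sided Fisher / hypergeometric
over-representation test of DE genes in each set against the full
universe, BH-corrected. The pathway-level extension,
`intersection_network()`, treats each pairwise intersection (of size
$\ge$ `min_intersection`, default 1 — empty intersections are untestable
and skipped) as a gene set of its own, tests DE over-representation in it
against the same universe, BH-corrects across tested pairs, and draws an
edge at $q \le \alpha$. "Significant number of DE genes in the
intersection" is not otherwise specified anywhere we know of, and this
definition directly parallels the per-set test; the alternative of
conditioning on the parent pathways' union rather than the global
universe would penalise intersections of already-enriched pathways and is
left as future work. Interface genes (the intersection members, DE
flagged) ride on every edge, since they are the mechanistic reading of an
edge: the shared components through which imbalance propagates between
functions.

## Numerical and design choices

* Correlation matrices are symmetrised, clamped to $[-1, 1]$, unit
  diagonal; thresholds are strict (`>`); a coefficient exactly at the
  threshold does not link (tested).
* Histograms of coefficients use fixed equal-width bins on $[-1, 1]$ and
  count each unordered pair once, so histograms of different recordings
  are directly comparable.
* Hypergeometric tails use `phyper`; BH uses `p.adjust`. Both are checked
  against brute-force oracles (tail summation; rank step-up) in the test
  suite rather than re-implemented.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical outputs, and
  `run_pipeline()` reruns are byte-identical (tested on file hashes).
* `run_pipeline()` validates its config — unknown keys, out-of-range
  thresholds, malformed sweeps, missing inputs — before any computation,
  and writes its manifest (resolved config, package version, artifact
  md5s) last, so a complete run is distinguishable from an interrupted
  one.
* Known limitations: whole-series correlation assumes within-recording
  stationarity (a sliding-window option exists but windows are averaged,
  not modelled); the permutation null at feasible $B$ has granularity
  $1/(B+1)$; hypergeometric p-values are discrete, hence super-uniform
  under the null — calibration is therefore tested as a one-sided bound
  on the rejection rate, not as exact uniformity; mutual-information
  similarity and inter-layer coupling links are out of scope.

## Problem sizes

The shipped tests and the acceptance script run the full study grid —
20 seeds of three 121-feature, 500-point recordings for the overlap,
sweep and block-recovery checks; a 50-feature, 200-point null with 999
permutations for calibration; a 1000-gene universe with six 100-gene
pathways for the crosstalk check — chosen to keep every population
quantity estimable with comfortable margins at desk scale.
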