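---
title: "Regional epidemic risk classification on directed weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional epidemic risk classification on directed weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirisknet)
```

## The problem and the model

When a new infectious disease breaks out, authorities need a fast,
defensible way to grade every administrative region of the affected area as
high, medium or low risk, so that prevention measures can be targeted
rather than uniform. `epirisknet` implements a one-shot, deterministic
grading procedure built on three components:

1. **A social-connection network.** Regions are nodes; an undirected edge
   joins two regions with a meaningful social connection. Each edge carries
   a correlation strength $L_{m,s} \in [0,1]$ quantifying how strongly an
   epidemic in region $m$ would be felt in region $s$. Real region networks
   have heavy-tailed connectivity — a few hub regions concentrate most
   connections — so the package also ships a seeded preferential-attachment
   generator (`generate_scale_free()`): starting from two connected nodes,
   each new node attaches to existing nodes with probability proportional
   to their current degree, $P(k_s) = k_s / \sum_m k_m$, sampled without
   replacement with renormalisation after each draw.

2. **CRITIC indicator weighting.** The correlation strength is not
   observed directly; it is derived from $t$ raw indicators measured for
   every region pair. The default five are the distance between two
   regions (inverse direction: farther means less risk), personnel flow,
   economic traffic, transport convenience and logistics intensity (all
   proportional). Each indicator matrix is min–max normalised over all its
   $h \times h$ entries so that 1 means "most risk"; the CRITIC method
   then scores each indicator by its contrast intensity $P_i$ (sample
   standard deviation over all $h^2$ normalised entries, denominator
   $h^2 - 1$) and its conflict $R_i = \sum_j (1 - r_{ij})$ with $r_{ij}$
   the Pearson correlation between flattened indicators, and weights it by
   $w_i = P_i R_i / \sum_j P_j R_j$. The correlation function is the
   weighted sum $L_{m,s} = \sum_i w_i\, s_{i(ms)}$, a convex combination
   that stays in $[0,1]$.

3. **Layered risk propagation.** Outbreak regions get risk $p = 1$. Every
   other region's layer is its shortest-path distance (in edges) to the
   nearest outbreak, by multi-source breadth-first search; edges are
   oriented from lower to higher layer — the direction of spread — and
   same-layer edges are labelled *loop* edges, across which transmission
   is bidirectional. A region with a single upstream influence inherits
   $p_s = p_m L_{m,s}$; one with several parents receives the
   association-weighted combination
   $p_s = \sum_n p_n\, l_n\, L_n$ with $l_n = L_n / \sum_k L_k$,
   which is a convex combination of the attenuated parent risks and
   therefore never exceeds the largest of them. Finally each region is
   graded against two thresholds: high when $p \ge p_{s1}$, medium when
   $p_{s2} \le p < p_{s1}$, low otherwise, with defaults
   $(p_{s1}, p_{s2}) = (0.7, 0.4)$.

The procedure is a one-shot diffusion, not an epidemic simulation: there
is no time axis, no compartmental (SIR-type) dynamics and no stochastic
transmission. Given the network, the weights and the sources, every output
is deterministic.

## The loop-node rule (a reconstruction)

The layered rules above are well defined only when risk flows strictly
downhill. For two connected regions *in the same layer* there is no
order — each influences the other — and the plain rules do not apply. The
method this package implements leaves that case open, so the package had
to fix a rule. We use a **two-pass scheme**:

* **Pass 1 (pre-loop):** evaluate all regions in layer order using only
  downhill edges, giving every region a pre-loop risk value.
* **Pass 2 (loop resolution):** every region with loop partners is
  re-evaluated once by the multi-parent rule over its downhill parents
  *plus* its loop partners, the partners contributing their pass-1
  pre-loop values. Regions without loop partners keep their pass-1 value.

This choice was validated against the bundled group-1 reference
classifications (below): it is the simple member of the rule family that
reproduces *every* reference cell, including the asymmetric loop-pair
outcomes — region 13 low versus its loop partner 14 medium under a
single outbreak, and region 48 low versus 49 medium under two outbreaks.
Two natural alternatives were tested and rejected: iterating the mutual
update to a fixed point drives loop-pair values down (both members of a
pair attenuate each other repeatedly) and misplaces reference cells, and
applying the multi-parent rule with partners at their *final* values is
circular. The two-pass rule is therefore a documented reconstruction, not
a published formula; treat cross-study comparisons of loop-node values
with that in mind.

## Worked example

The package ships a 50-region benchmark network (49 tree edges plus three
same-layer loop edges) with two alternative weight sets, groups 1 and 2:

```{r}
bm <- benchmark_network(1)
fit <- epirisk(bm, sources = 1)
summary(fit)
```

With outbreaks at regions 1 and 22 simultaneously (both fixed at $p = 1$
before propagation), region 2 is fed by both sources and grades high:

```{r}
fit2 <- epirisk(bm, sources = c(1, 22))
risk_values(fit2)[c("2", "8", "28", "49")]
```

Both runs reproduce the bundled reference partitions exactly
(`benchmark_expected(1, 1)` and `benchmark_expected(1, 2)`).

## Numerical and design choices

* **Classification rounding.** Risk values are carried at full floating
  precision throughout propagation; rounding happens only at
  classification, half-up to `round_dp` decimals (default 2). The default
  matters at exactly one benchmark cell: region 28 under the two-outbreak
  group-1 run computes just below 0.4 and is medium only after rounding
  to 0.40, which is how the reference classification places it. Pass
  `round_dp = NULL` for strict full-precision grading.
* **Threshold boundaries are closed from below:** a rounded value exactly
  equal to $p_{s1}$ is high, exactly $p_{s2}$ is medium.
* **Parent sets.** A region's parents are *all* neighbours in strictly
  lower layers, not only those exactly one layer below. On the benchmark
  every parent happens to sit one layer below, so the two readings
  coincide there; the broader reading is the more general interpretation
  of "all nodes that affect the node" and is what `propagate()` uses.
* **Orientation is per-source-set.** Edge directions encode where risk
  flows for a given outbreak, so they are recomputed whenever the source
  set changes; the node order in the stored edge list is notational.
* **Degenerate inputs.** A constant (zero-variance) indicator has no
  information content and an undefined correlation; `critic_weights()`
  drops it with a warning and reports it with weight 0, and errors only
  when fewer than two usable indicators remain. A region whose only
  connections carry $L = 0$ is reachable but receives risk 0. Regions
  disconnected from every source get risk 0 and grade low (no path, no
  transmission). Diagonal entries of the indicator matrices are included
  in the normalisation statistics by default (`include_diag = FALSE`
  excludes them); the diagonal of $L$ is never used either way, since the
  network has no self-loops.
* **CRITIC conventions.** $r_{ij}$ is the Pearson product–moment
  correlation, the standard CRITIC choice; the conflict sum includes the
  $j = i$ term, which contributes exactly 0.
* **Seeding.** Both generators take an explicit integer seed, always
  produce the same output for the same seed, and restore the caller's RNG
  state afterwards.

## The benchmark data and a known discrepancy

The two benchmark weight sets are transcribed correlation tables; a
checksum over all 104 weights is pinned in the test suite to guard
against silent edits. For group 1 the bundled high/medium/low partitions
are reproduced exactly by `epirisk()` under thresholds (0.7, 0.4) and
2-decimal rounding, for both the one-outbreak and two-outbreak cases.

The group-2 reference lists are different: they are **internally
inconsistent** with any member of the propagation-rule family that
reproduces group 1. For example, under a single outbreak at region 1,
region 22's risk is necessarily
$0.8147 \times 0.6433 = 0.5241$ — medium — yet the group-2 list places it
high; under two outbreaks region 23 computes 0.6918, just below the high
bound, yet is listed high; loop regions 42 and 49 evaluate low but are
listed medium. The package therefore ships the group-2 lists with status
`"informational"`, asserts only the group-2 *first-layer* values (which
are exact products $p = 1 \times L$ and independent of any loop rule),
and treats the group-1 partitions as the reference behaviour. First-layer
values are exact for both groups.

## What the synthetic generator does and does not emulate

`generate_synthetic_indicators()` draws each indicator entry independently
and uniformly from a positive range (default $[0,1]$, symmetric matrices
by default), with the five default indicator names and directions above.
Uniform independence is the minimal assumption for data whose true
generating distributions are unavailable; it exercises every contract of
the pipeline (normalisation bounds, weight simplex, $L$ bounds,
propagation bounds) but does **not** emulate the spatial autocorrelation,
inter-indicator dependence or heavy tails of real mobility and logistics
data. Passing tests on synthetic data therefore demonstrate correctness
of the computation, not calibration of risk grades for any real region
system. One qualitative claim is checked statistically: on 50-region
synthetic pipelines with a single random outbreak, low-risk regions
outnumber medium-risk regions, which outnumber high-risk ones, in the
large majority of seeds — the pattern expected of multiplicative
attenuation with strengths centred well below 1.

## Problem sizes used by the test suite

The suite validates layering against an independent shortest-path oracle
and propagation against an independent recursive evaluator on hundreds of
random networks of up to 12 nodes (chosen small so the oracles stay
transparently correct), runs the CRITIC property checks over 100 seeded
instances with 10 regions, the count-ordering check over 50 seeded
50-region pipelines, and the benchmark reproductions on the full
50-region networks. All are deterministic given their fixed seeds.

## Limitations

* The loop-node rule is a reconstruction (see above); alternative
  resolutions of same-layer influence are conceivable and would change
  loop-node values, though not the downhill ones.
* Risk only attenuates: a region can never be graded higher than the
  sources that feed it, and multi-parent combination is averaging, not
  additive accumulation — two weak paths never sum to a strong one.
* The method is static; it says nothing about timing, case counts or
  intervention effects.
* CRITIC weights are objective in the sense of being data-driven, but
  they inherit whatever biases the indicator measurements carry.
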