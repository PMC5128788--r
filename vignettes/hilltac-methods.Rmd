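---
title: "Hill-number diversity estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hill-number diversity estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hilltac)
```

## The problem

Soil and other environmental bacterial communities are hyperdiverse, and a
large share of their richness sits in a rare biosphere of taxa observed
once or twice, if at all. Sampling by sequencing is an incomplete census:
at realistic read depths the observed OTU table is a random, truncated view
of the community, richness estimates keep climbing with effort, and
diversity numbers are not reproducible across depths. `hilltac` implements
a practical response: measure diversity with Hill numbers of several
orders, watch how each order's estimate accumulates with sampling effort,
and report diversity only at orders whose accumulation curves have
demonstrably flattened at the available depth.

## Hill numbers

For relative abundances $p_i$ (positive entries only), the Hill number of
order $a \ge 0$ is

$$N_a = \Big(\sum_{i:\,p_i>0} p_i^{\,a}\Big)^{1/(1-a)},$$

the reciprocal generalized-mean proportional abundance. It is an effective
number of taxa: a community of $S$ equally abundant taxa has $N_a = S$ for
every $a$. Order $a$ tunes the weight of rare taxa: $N_0$ is observed
richness, $N_1 = \exp(-\sum p_i \log p_i)$ (the $a \to 1$ limit, the
exponential Shannon index), and $N_2 = 1/\sum p_i^2$ is the reciprocal
Simpson index. $N_a$ is non-increasing in $a$, bounded by $[1, S_{obs}]$,
and invariant to depth replication and taxon order — properties the test
suite asserts on thousands of random vectors.

Numerical choices: `hillNumber` routes $|a - 1| < 10^{-6}$ to the entropy
limit because $1/(1-a)$ blows up in floating point near 1; $a = 0$ returns
the integer richness count exactly; zero-count taxa are excluded from all
sums, so $N_0$ is *observed* richness. Orders below 1 are supported but
their sampling uncertainty grows quickly in undersampled data, and results
there should be treated with caution.

The classical estimators that accompany the profile are
`chao1` ($S_{obs} + F_1^2 / 2F_2$, with the bias-corrected
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ when no doubletons exist — the classic
ratio is undefined there, and the fallback is reported via a message) and
`goodsCoverage` ($1 - F_1/N$), both driven by the singleton/doubleton
frequencies $F_1, F_2$ from `frequencyCounts`.

## Taxa-accumulation curves

`smoothedTAC` builds the curve of pooled ($\gamma$) diversity as samples
accumulate: for each $k$, pool the raw counts of the first $k$ samples of a
random ordering and evaluate $N_a$ of the pool, then average over orderings
(default `nPerm = 100`; `exhaustive = TRUE` enumerates all orderings for
small tables). Pooling counts before computing $N_a$ — rather than
averaging per-sample diversities — is what makes the curve rise toward a
study-wide asymptote. Monte-Carlo smoothing is used because an analytic
expectation exists only for order 0; that closed form (`expectedTAC`,
$E[S(k)] = \sum_i 1 - \binom{m - m_i}{k}/\binom{m}{k}$) is kept in the
package as a cross-check oracle, and the tests require the Monte-Carlo mean
to agree with it within Monte-Carlo error.

## Read-depth subsampling

`subsampleReads` draws a fixed number of reads *without replacement*
(multivariate hypergeometric, realized by sequential conditional
hypergeometric draws), which is the correct semantics for "what would a
shallower run of this same library have shown". The mean subsampled
richness matches the closed-form hypergeometric rarefaction expectation
$\sum_i 1 - \binom{N-n_i}{d}/\binom{N}{d}$ (`expectedRichness`); a
with-replacement multinomial option exists for extrapolated depths but is
never the default. `depthAnalysis` evaluates replicate subsamples (default
10) over a depth grid — by default 8 log-spaced depths spanning
25,000–400,000 reads, clipped to the data — and scores each order's mean
curve for stability.

## The stability criterion

"Asymptote reached" has no standard formal definition, so the package
declares one and applies it uniformly: a curve is stable at the first step
$s$ such that (i) the tail from $s$ to the end spans at least `windowFrac`
of the step range, and (ii) the relative change between the value at $s$
and every later value is at most `tol`. Defaults are `windowFrac = 0.1`
and `tol = 0.02` — at most 2% relative change, supported by at least the
final 10% of the effort range. A constant curve is stable at the first
eligible step; a steadily climbing curve is never stable. The tail-to-end
form (rather than a fixed-width sliding window) was chosen because on
log-spaced depth grids a fixed-width window can fall between grid points
and make the criterion vacuously true.

The expected scientific pattern, which the acceptance tests assert on
synthetic data, is that stability depth is non-increasing in the order:
$N_2$ settles first, $N_1$ later, and $N_0$ — dominated by the rare tail —
typically never settles at realistic depths. One caveat the tests surfaced
honestly: in the shallow Zipf study preset, the pooled $N_1$ accumulation
curve climbs by well under 2% across its final third, so a plateau
criterion with a 2% tolerance declares it stable even though it is still
drifting upward; a slope-sensitive criterion or stricter tolerance would
classify it as unsettled. The tolerance is a declared convention and is not
tuned per dataset.

## Taxon-abundance distribution models

Two TAD families are fitted by maximum likelihood to the positive counts:

* **Log-normal** — a distribution of log-abundances; counts are treated as
  continuous, and $(\hat\mu, \hat\sigma)$ are the ML mean and sd of
  $\log x$. No Poisson compounding and no veil-line truncation are
  applied; this is the simplest defensible reading, and it recovers the
  generating parameters within $\pm 0.05$ at $S = 5000$ in the tests.
* **Zipf** — a rank model: expected relative abundance $p_1 r^{-\gamma}$
  at rank $r$, with $\gamma$ fitted by maximizing the multinomial
  likelihood of the rank-ordered counts ($p_1$ is the normalization and is
  reported, not free).

Degenerate communities (all counts equal) drive $\sigma$ or $\gamma$ to
their zero boundary; fits are flagged rather than failed.

**Model selection.** The two native likelihoods are not comparable: the
log-normal's is a density summed over $S$ taxa, the Zipf's a multinomial
over $N$ reads, and their magnitudes differ by orders of magnitude
regardless of fit quality. `selectModel` therefore compares the families
on a common footing: the multinomial likelihood of the rank-ordered counts
under each fitted model's implied rank proportions (for the log-normal,
$p_r \propto \exp(\hat\sigma z_r)$ with $z_r$ the normal quantile at rank
$r$'s plotting position — the standard rank-model convention; the location
parameter cancels under normalization). Each fit object still carries its
model-native log-likelihood and AIC, which is what the likelihood-oracle
tests check; the common-scale comparison lives in the selection step and
recovers the generating family in $\ge 90\%$ of seeded simulations in both
directions.

**Deviation test.** Departure from the log-normal is measured by $D$, the
sup-norm distance between the empirical CDF of log observed abundances and
the fitted normal CDF, evaluated on both sides of every jump (so
$D \ge 1/2S$ always; $D = 0$ is unattainable for finite samples). Because
the parameters are estimated from the same data, a textbook one-sample
p-value would be invalid; the p-value comes from a parametric bootstrap
that re-draws counts from the fitted model (re-discretized by rounding,
zeros dropped — mirroring how integer read counts arise), refits, and
recomputes $D^*$ on each replicate (a Lilliefors-type correction), with
$p = (1 + \#\{D^* \ge D\})/(n_{boot}+1)$. Under the null the empirical
rejection rate at the 5% level stays within $[0.02, 0.10]$ across 200
seeded simulations, and Zipf-generated communities are rejected at
$p \le 0.01$ essentially always.

## The synthetic-data generator

`makeCommunity`/`sampleReads`/`makeStudy` generate what the analysis
assumes: a fixed true community (log-normal, Zipf, or uniform relative
abundances), multinomial sampling-by-sequencing, and multi-sample studies
with exact per-sample depths. Optional between-sample variability is a
Dirichlet jitter with concentration inversely proportional to the
`overdispersion` parameter (default 0: all samples share the true
proportions — real studies vary more). Two presets encode a deliberately
contrasting pair of designs: `"amazon"`, deep sampling of a log-normal
community (S = 5000, $\sigma = 2$, 66 samples × 6000 reads, ~396,000
total), and `"texas"`, shallow sampling of a heavy-tailed Zipf community
(S = 5000, $\gamma = 1.1$, 36 samples × 860 reads, ~31,000 total). The
true parameters of real soil communities are unknown; these values are
realistic conventions, fixed once, that reproduce the qualitative
deep-vs-shallow contrast.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: sequencing error (chimeras and homopolymer
errors that inflate singleton counts), variable 16S copy number,
compositional biases of primers and platforms, and an effectively unbounded
rare biosphere (the true S is capped, so synthetic communities are less
undersampled than comparably sized real ones; e.g. the shallow preset pools
to ~95% Good's coverage where a comparable real mine-soil study sits near
32%).

## Problem sizes and reproducibility

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state; identical seeds give bit-identical results, and
`runPipeline` reruns with an identical config are byte-identical (the run
log, which carries wall-clock timings, stays outside the manifest
checksums). The test suite's simulation sizes are chosen to make each
property decisive at desk scale: 1000 random vectors for the exact Hill
identities, 300–1000 subsample draws against the hypergeometric
expectation, $S$ = 500–5000 and $N = 10^5$ for parameter recovery, 50
seeded runs per family for model selection, and 200 runs × 199 bootstrap
replicates for the null calibration of the deviation test.

## Limitations

Chao1 is reported without a variance or interval; extrapolation beyond the
observed effort (rarefaction/extrapolation hybrids) is out of scope, as are
additional TAD families (geometric, broken-stick, Zipf–Mandelbrot,
Poisson-lognormal) and phylogenetic or functional Hill numbers. The
stability criterion is a convention — report it together with its
`windowFrac` and `tol`, and expect plateau-type criteria to be lenient
toward slowly drifting curves.
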